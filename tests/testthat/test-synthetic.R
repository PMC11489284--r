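test_that("generation is reproducible from the seed", {
  cfg <- synthetic_study_config()
  expect_identical(generate_study(cfg, seed = 9),
                   generate_study(cfg, seed = 9))
  ccfg <- synthetic_consumer_config("O_bicornis")
  expect_identical(generate_consumers(ccfg, seed = 9),
                   generate_consumers(ccfg, seed = 9))
})

test_that("the design produces the study-shaped measurement counts", {
  for (s in c(1, 2, 3)) {
    comp <- generate_study(synthetic_study_config(), seed = s)
    for (trt in c("aCO2", "eCO2")) {
      sub <- comp[comp$treatment == trt, ]
      n_c <- sum(sub$element == "C")
      expect_gte(n_c, 18)            # 3 trees x 6..10 subsamples
      expect_lte(n_c, 30)
      n_p <- sum(sub$element == "P")
      expect_gte(n_p, 9)             # 3 trees x 3..5 pooled subsamples
      expect_lte(n_p, 15)
      expect_equal(length(unique(sub$array_id)), 3L)
    }
    # C/N/S live on inflorescence subsamples, the rest on pooled ones
    cns_subs <- unique(comp$subsample_id[comp$element %in% c("C", "N", "S")])
    pool_subs <- unique(comp$subsample_id[!comp$element %in%
                                            c("C", "N", "S")])
    expect_length(intersect(cns_subs, pool_subs), 0L)
  }
})

test_that("configuration ranges are validated", {
  expect_error(synthetic_study_config(subsamples_cns = c(10, 6)),
               "min <= max")
  expect_error(synthetic_study_config(arrays_per_treatment = 0), ">= 1")
  bad <- default_element_params()
  bad$mean_aco2[1] <- -1
  expect_error(synthetic_study_config(elements = bad), "positive")
  expect_error(synthetic_consumer_config("O_bicornis", n_replicates = 0),
               ">= 1")
  expect_error(synthetic_consumer_config("O_bicornis",
                                         medians = c(N = -2)),
               "positive")
})

test_that("consumer generation honours replicate counts and spread", {
  cfg_o <- synthetic_consumer_config("O_bicornis")
  cons <- generate_consumers(cfg_o, seed = 10)
  expect_equal(unname(table(cons$element)["N"]), 30L)
  cfg_a <- synthetic_consumer_config("A_mellifera")
  expect_equal(nrow(generate_consumers(cfg_a, seed = 10)) /
                 length(cfg_a$medians), 45)

  # zero spread collapses to the configured median
  cfg0 <- synthetic_consumer_config("O_bicornis", medians = c(N = 3.5),
                                    sd_log = 0)
  cons0 <- generate_consumers(cfg0, seed = 11)
  expect_true(all(cons0$cx_value == 3.5))

  # large-sample median lands on the configured median
  cfg_big <- synthetic_consumer_config("O_bicornis",
                                       n_replicates = 10000,
                                       medians = c(N = 3.5))
  cons_big <- generate_consumers(cfg_big, seed = 12)
  expect_lt(abs(median(cons_big$cx_value) / 3.5 - 1), 0.02)
})

test_that("consumer medians back-calculate from food ratios and TSR targets", {
  food <- data.frame(element = "N", cx_value = 10.46)
  med <- back_calculate_consumer_medians(
    food, data.frame(element = "N", median = 3.02))
  expect_equal(unname(med), 10.46 / 3.02, tolerance = 1e-12)
  expect_equal(round(unname(med), 2), 3.46)

  # TSR median of 1 implies consumer equals food
  med1 <- back_calculate_consumer_medians(
    food, data.frame(element = "N", median = 1))
  expect_equal(unname(med1), 10.46)

  expect_error(back_calculate_consumer_medians(
    food, data.frame(element = "N", median = 0)), "non-zero")
  expect_error(back_calculate_consumer_medians(
    food, data.frame(element = "P", median = 2)), "share no elements")
})

test_that("generated consumers close the loop on the reference TSR medians", {
  # food held at the values used for the back-calculation: recomputed TSR
  # medians should land near the reference medians, consumer noise only
  ref <- reference_tsr_quartiles()
  ref_o <- ref[ref$species == "O_bicornis" & ref$treatment == "aCO2", ]
  cons <- generate_consumers(synthetic_consumer_config("O_bicornis"),
                             seed = 13)
  food <- pollenstoich:::default_food_cx()
  food$treatment <- "aCO2"
  food$array_id <- "a1"
  food$basis <- "mass"
  rec <- compute_tsr(food, cons)
  s <- summarize_tsr(rec)
  got <- s$median[match(ref_o$element, s$element)]
  expect_true(all(abs(got / ref_o$median - 1) < 0.10))
})

test_that("dominant array variance propagates to the Table-1 pattern", {
  comp <- generate_study(synthetic_study_config(), seed = 1)
  tab <- unique(build_table1(fit_study_lmms(comp))[
    c("response", "r2_marginal", "r2_conditional")])
  expect_true(all(tab$r2_marginal <= tab$r2_conditional))
  expect_true(all(tab$r2_conditional > 0.9))
  expect_lt(median(tab$r2_marginal), 0.4)
})
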