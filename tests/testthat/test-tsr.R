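make_food <- function(cx, elements = "N", treatments = "aCO2",
                      arrays = "a1") {
  grid <- expand.grid(treatment = treatments, array_id = arrays,
                      element = elements, stringsAsFactors = FALSE)
  grid$cx_value <- cx
  grid$basis <- "mass"
  grid
}

make_consumers <- function(cx, elements = "N", n = 1,
                           species = "O_bicornis") {
  grid <- expand.grid(replicate_id = sprintf("r%02d", seq_len(n)),
                      element = elements, stringsAsFactors = FALSE)
  grid$species <- species
  grid$cx_value <- cx
  consumer_profile(grid)
}

test_that("equal food and consumer ratios give TSR 1, not limiting", {
  rec <- compute_tsr(make_food(7.5), make_consumers(7.5))
  expect_equal(rec$tsr, 1)
  expect_equal(rec$tsr_adjusted, 1)
  expect_false(rec$limiting)
})

test_that("TSR record count is the food x consumer cross product", {
  comp <- generate_study(synthetic_study_config(), seed = 21)
  food <- aggregate_food_ratios(compute_cx_ratios(comp))
  osmia <- generate_consumers(synthetic_consumer_config("O_bicornis"),
                              seed = 22)
  apis <- generate_consumers(synthetic_consumer_config("A_mellifera"),
                             seed = 23)
  rec <- compute_tsr(food, consumer_profile(rbind(osmia, apis)))
  counts <- table(rec$species, rec$treatment, rec$element)
  expect_true(all(counts["O_bicornis", , ] == 90))   # 3 arrays x 30
  expect_true(all(counts["A_mellifera", , ] == 135)) # 3 arrays x 45

  # conservation under other design sizes
  rec2 <- compute_tsr(make_food(rep(5, 4), arrays = c("a1", "a2"),
                                treatments = c("aCO2", "eCO2")),
                      make_consumers(runif(7, 1, 3), n = 7))
  expect_equal(nrow(rec2), 2 * 2 * 7)
})

test_that("limitation threshold is 1/A_C with the boundary limiting", {
  assim <- assimilation_config()
  expect_identical(assim$threshold, 4)
  expect_true(classify_limitation(4.0, assim))
  expect_false(classify_limitation(3.99, assim))
  expect_error(classify_limitation(-1, assim), "positive|> 0")

  # published ambient median for N against the 75% assimilation preset
  expect_true(classify_limitation(3.02 / 0.75, assim))
  expect_equal(3.02 / 0.75, 4.0267, tolerance = 1e-4)
})

test_that("lower assimilation inflates adjusted TSR and grows the limiting set", {
  food <- make_food(seq(2, 6, length.out = 5), arrays = paste0("a", 1:5))
  cons <- make_consumers(1)
  ax_grid <- c(1, 0.9, 0.75, 0.5)
  n_limiting <- sapply(ax_grid, function(ax) {
    rec <- compute_tsr(food, cons, assimilation_config(a_x = ax))
    expect_true(all(rec$tsr_adjusted >= rec$tsr))
    sum(rec$limiting)
  })
  expect_true(all(diff(n_limiting) >= 0))
})

test_that("TSR is invariant to a common rescaling of food and consumer", {
  set.seed(41)
  cx <- runif(6, 1, 20)
  rec1 <- compute_tsr(make_food(cx[1:3], arrays = paste0("a", 1:3)),
                      make_consumers(cx[4:6], n = 3))
  rec2 <- compute_tsr(make_food(cx[1:3] * 1000, arrays = paste0("a", 1:3)),
                      make_consumers(cx[4:6] * 1000, n = 3))
  expect_equal(rec1$tsr, rec2$tsr, tolerance = 1e-12)
})

test_that("mismatched bases and disjoint element sets are rejected", {
  food <- make_food(5)
  food$basis <- "molar"
  expect_error(compute_tsr(food, make_consumers(5)), "bases")
  expect_error(compute_tsr(make_food(5, elements = "P"),
                           make_consumers(5, elements = "N")),
               "no elements shared")
})

test_that("TSR summaries match an independent quantile oracle", {
  rec <- compute_tsr(make_food(c(1, 2, 3), arrays = paste0("a", 1:3)),
                     make_consumers(1))
  s <- summarize_tsr(rec)
  expect_equal(s$median, 2)

  # all equal values collapse the quartiles
  rec_eq <- compute_tsr(make_food(rep(5, 3), arrays = paste0("a", 1:3)),
                        make_consumers(1))
  s_eq <- summarize_tsr(rec_eq)
  expect_equal(c(s_eq$q25, s_eq$median, s_eq$q75), rep(5, 3))

  # 90-value synthetic group vs sort-and-interpolate oracle
  set.seed(42)
  rec90 <- compute_tsr(make_food(runif(3, 2, 8), arrays = paste0("a", 1:3)),
                       make_consumers(runif(30, 0.5, 2), n = 30))
  s90 <- summarize_tsr(rec90)
  expect_equal(s90$n, 90)
  expect_equal(s90$median, quantile_oracle(rec90$tsr, 0.5))
  expect_equal(s90$q25, quantile_oracle(rec90$tsr, 0.25))
  expect_equal(s90$q75, quantile_oracle(rec90$tsr, 0.75))
  expect_true(s90$q25 <= s90$median && s90$median <= s90$q75)
})
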