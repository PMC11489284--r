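balanced_data <- function(effect = 0, sd_array = 0, sd_resid = 1,
                          n_sub = 6, arrays = 3, seed = 1) {
  set.seed(seed)
  out <- list()
  for (trt in c("aCO2", "eCO2")) {
    for (a in seq_len(arrays)) {
      id <- paste0(substr(trt, 1, 1), a)
      ae <- rnorm(1, 0, sd_array)
      out[[length(out) + 1]] <- data.frame(
        treatment = trt, array_id = id,
        value = 10 + (trt == "eCO2") * effect + ae +
          rnorm(n_sub, 0, sd_resid))
    }
  }
  do.call(rbind, out)
}

test_that("with zero array variance the fit collapses to ordinary least squares", {
  dat <- balanced_data(effect = 2, sd_array = 0, seed = 2)
  # force the between-array variation to exactly zero: recentre every
  # array on its treatment mean so only residual variance remains
  trt_mean <- tapply(dat$value, dat$treatment, mean)
  arr_mean <- tapply(dat$value, dat$array_id, mean)
  dat$value <- dat$value - arr_mean[dat$array_id] +
    trt_mean[dat$treatment]
  fit <- fit_lmm(dat, "value")
  ols <- summary(lm(value ~ treatment, data = dat))$coefficients
  expect_equal(fit$coefficients$estimate, unname(ols[, 1]),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$se[2], unname(ols[2, 2]),
               tolerance = 1e-8)
  expect_true(fit$singular)
})

test_that("treatment degrees of freedom follow the between-within rule", {
  dat <- balanced_data(sd_array = 1, seed = 3)
  fit <- fit_lmm(dat, "value")
  expect_equal(fit$coefficients$df[2], 4)           # 6 arrays - 2
  expect_equal(fit$coefficients$df[1], nrow(dat) - 6)
  expect_error(fit_lmm(dat[dat$array_id %in% c("a1", "e1"), ], "value"),
               "2 arrays per treatment")
})

test_that("a constant response yields a flagged degenerate fit", {
  dat <- balanced_data(sd_array = 0, sd_resid = 0, seed = 4)
  fit <- fit_lmm(dat, "value")
  expect_true(fit$degenerate)
  expect_equal(fit$sigma2_array, 0)
  expect_equal(fit$sigma2_resid, 0)
  expect_equal(fit$coefficients$estimate[2], 0)
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  expect_equal(unname(r2_nakagawa(sigma2_fixed = 1, sigma2_random = 1,
                                  sigma2_resid = 2)), c(0.25, 0.5))
  expect_equal(unname(r2_nakagawa(sigma2_fixed = 0, sigma2_random = 1,
                                  sigma2_resid = 1))[1], 0)
  r2 <- r2_nakagawa(sigma2_fixed = 0.3, sigma2_random = 0,
                    sigma2_resid = 0.7)
  expect_equal(unname(r2[1]), unname(r2[2]))   # no random variance
  expect_error(r2_nakagawa(sigma2_fixed = 0, sigma2_random = 0,
                           sigma2_resid = 0), "undefined|zero")

  dat <- balanced_data(effect = 1, sd_array = 2, seed = 5)
  fit <- fit_lmm(dat, "value")
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_equal(unname(r2_nakagawa(fit)),
               c(fit$r2_marginal, fit$r2_conditional))
})

test_that("the fitted CO2 effect recovers the generating value", {
  dat <- balanced_data(effect = -0.5, sd_array = 0.3, sd_resid = 0.2,
                       seed = 6)
  fit <- fit_lmm(dat, "value")
  expect_lt(abs(fit$coefficients$estimate[2] - (-0.5)), 1)
  # back-transformed group means are on the original scale
  expect_equal(unname(fit$group_means["aCO2"]),
               mean(dat$value[dat$treatment == "aCO2"]))
})

test_that("the full study table has two rows per response and is deterministic", {
  comp <- generate_study(synthetic_study_config(), seed = 25)
  fits <- fit_study_lmms(comp)
  tab <- build_table1(fits)
  expect_equal(nrow(tab), 30L)      # 15 responses x 2 coefficient rows
  expect_setequal(unique(tab$response),
                  c(element_info()$symbol, "C:N", "C:P", "N:P"))
  expect_length(attr(tab, "missing"), 0L)
  # pinned transforms applied
  expect_match(tab$transform[tab$response == "C"][1], "box_cox")
  expect_equal(tab$transform[tab$response == "Mn"][1], "log")

  tab2 <- build_table1(fit_study_lmms(generate_study(
    synthetic_study_config(), seed = 25)))
  expect_identical(tab, tab2)

  # dropping a response reports it as missing rather than failing
  tab3 <- build_table1(fits[setdiff(names(fits), "Fe")])
  expect_equal(attr(tab3, "missing"), "Fe")
})
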