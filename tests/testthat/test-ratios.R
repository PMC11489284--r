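test_that("C:X ratios divide commensurable concentrations", {
  tab <- tiny_cn_table(c_a = 50, n_a = 5)
  r <- compute_cx_ratios(tab, "N")
  expect_equal(r$cx_value[r$treatment == "aCO2"], 10)

  # mid-range study concentrations
  tab2 <- tiny_cn_table(c_a = 49.7, n_a = 4.75)
  r2 <- compute_cx_ratios(tab2, "N")
  expect_equal(r2$cx_value[r2$treatment == "aCO2"], 49.7 / 4.75,
               tolerance = 1e-12)
  expect_equal(round(r2$cx_value[r2$treatment == "aCO2"], 2), 10.46)
})

test_that("molar basis differs from mass basis by the atomic-mass factor", {
  tab <- tiny_cn_table(c_a = 50, n_a = 5)
  mass <- compute_cx_ratios(tab, "N", basis = "mass")
  molar <- compute_cx_ratios(tab, "N", basis = "molar")
  expect_equal(molar$cx_value, mass$cx_value * 14.007 / 12.011)
  expect_equal(molar$cx_value[1], 10 * 14.007 / 12.011, tolerance = 1e-12)

  # property: constant factor per element across a generated study
  comp <- generate_study(synthetic_study_config(), seed = 3)
  m1 <- compute_cx_ratios(comp, basis = "mass")
  m2 <- compute_cx_ratios(comp, basis = "molar")
  fac <- m2$cx_value / m1$cx_value
  expected <- atomic_mass(m1$element) / atomic_mass("C")
  expect_equal(fac, expected, tolerance = 1e-12)
})

test_that("ratios are invariant to the reporting unit of the inputs", {
  comp <- generate_study(synthetic_study_config(), seed = 5)
  r_pct <- compute_cx_ratios(to_common_units(comp, "mass_fraction"))
  r_mg <- compute_cx_ratios(to_common_units(comp, "mg_per_kg"))
  expect_equal(r_pct$cx_value, r_mg$cx_value, tolerance = 1e-12)
})

test_that("pooled-subsample elements pair with the array-mean carbon", {
  tab <- composition_table(rbind(
    comp_row("aCO2", "a1", subsample_id = "i1", element = "C",
             concentration = 48),
    comp_row("aCO2", "a1", subsample_id = "i2", element = "C",
             concentration = 52),
    comp_row("aCO2", "a1", subsample_id = "p1", element = "P",
             concentration = 0.5),
    comp_row("eCO2", "e1", subsample_id = "i1", element = "C",
             concentration = 50),
    comp_row("eCO2", "e1", subsample_id = "p1", element = "P",
             concentration = 0.25)))
  r <- compute_cx_ratios(tab, "P")
  expect_equal(r$cx_value[r$treatment == "aCO2"], 50 / 0.5)  # mean(48,52)
  expect_equal(r$c_source, c("array_mean", "array_mean"))
})

test_that("zero denominators are excluded with a warning, missing C errors", {
  tab <- composition_table(rbind(
    comp_row("aCO2", "a1", subsample_id = "s1", element = "C",
             concentration = 50),
    comp_row("aCO2", "a1", subsample_id = "s1", element = "N",
             concentration = 0),
    comp_row("aCO2", "a1", subsample_id = "s2", element = "C",
             concentration = 50),
    comp_row("aCO2", "a1", subsample_id = "s2", element = "N",
             concentration = 5)))
  expect_warning(r <- compute_cx_ratios(tab, "N"), "zero")
  expect_equal(nrow(r), 1L)
  expect_equal(nrow(attr(r, "excluded")), 1L)

  tab_noc <- composition_table(comp_row(element = "N", concentration = 5))
  expect_error(compute_cx_ratios(tab_noc, "N"), "numerator")
})

test_that("array aggregation averages subsamples and keeps 3 rows per group", {
  tab <- composition_table(rbind(
    comp_row("aCO2", "a1", subsample_id = "s1", element = "C",
             concentration = 10),
    comp_row("aCO2", "a1", subsample_id = "s1", element = "N",
             concentration = 5),
    comp_row("aCO2", "a1", subsample_id = "s2", element = "C",
             concentration = 20),
    comp_row("aCO2", "a1", subsample_id = "s2", element = "N",
             concentration = 5)))
  r <- compute_cx_ratios(tab, "N")
  agg <- aggregate_food_ratios(r)   # ratios 2 and 4 -> mean 3
  expect_equal(agg$cx_value, 3)
  expect_equal(agg$n_subsamples, 2)

  # single-subsample array: mean equals the value
  one <- aggregate_food_ratios(r[1, ])
  expect_equal(one$cx_value, r$cx_value[1])

  # commutes with subsample ordering
  shuffled <- aggregate_food_ratios(r[rev(seq_len(nrow(r))), ])
  expect_equal(shuffled, agg)

  # 3 arrays per treatment -> 3 array-level rows per treatment x element
  comp <- generate_study(synthetic_study_config(), seed = 11)
  food <- aggregate_food_ratios(compute_cx_ratios(comp))
  counts <- table(food$treatment, food$element)
  expect_true(all(counts == 3))
})
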