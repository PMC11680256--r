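test_that("seed determinism and value ranges", {
  sc <- synthetic_scenario(n_settings = 4, dimension_type = "nonordered",
                           n_subgroups = 8, effect_shape = "linear",
                           share_concentration = 3, noise_n = 500, seed = 5)
  a <- generate_series(sc)
  b <- generate_series(sc)
  expect_identical(lapply(a, `[[`, "data"), lapply(b, `[[`, "data"))
  for (s in a) {
    expect_true(all(s$data$estimate >= 0 & s$data$estimate <= 100))
    expect_equal(sum(s$data$share), 1, tolerance = 1e-12)
  }
})

test_that("effect shapes produce the stated true structure", {
  lin <- synthetic_scenario(effect_shape = "linear", gradient_size = 25,
                            base_level = 50, n_subgroups = 5)
  expect_equal(true_values(lin), c(40, 45, 50, 55, 60))
  # noise-free series recover the truth and the true linear SII = gradient
  s <- generate_series(synthetic_scenario(effect_shape = "linear",
                                          gradient_size = 25,
                                          noise_n = Inf))[[1]]
  expect_equal(s$data$estimate, c(40, 45, 50, 55, 60))
  expect_equal(est_of(measure_sii(s, ci = NULL)), 25, tolerance = 1e-12)
  expect_equal(s$data$se, rep(0, 5))

  expect_equal(true_values(synthetic_scenario(effect_shape = "null",
                                              base_level = 30)), rep(30, 5))
  st <- synthetic_scenario(effect_shape = "step", gradient_size = 20,
                           n_subgroups = 4, dimension_type = "nonordered")
  expect_equal(true_values(st), c(40, 40, 60, 60))
  out <- synthetic_scenario(effect_shape = "outlier", outlier_offset = 30,
                            outlier_share = 0.02, n_subgroups = 6,
                            dimension_type = "nonordered")
  expect_equal(true_values(out), c(rep(50, 5), 80))

  expect_error(synthetic_scenario(effect_shape = "linear", base_level = 95,
                                  gradient_size = 25), "infeasible")
})

test_that("null scenario: complex measures vanish as noise vanishes", {
  s <- generate_series(synthetic_scenario(effect_shape = "null",
                                          dimension_type = "nonordered",
                                          noise_n = Inf))[[1]]
  for (f in list(measure_mdmu, measure_mdmw, measure_bgv, measure_theil))
    expect_equal(est_of(f(s, ci = NULL)), 0)
  expect_equal(est_of(measure_ratio(s, ci = NULL)), 1)

  noisy <- generate_series(synthetic_scenario(effect_shape = "null",
                                              dimension_type = "nonordered",
                                              noise_n = 100, seed = 8))[[1]]
  hi_n <- generate_series(synthetic_scenario(effect_shape = "null",
                                             dimension_type = "nonordered",
                                             noise_n = 1e6, seed = 8))[[1]]
  expect_lt(est_of(measure_bgv(hi_n, ci = NULL)),
            est_of(measure_bgv(noisy, ci = NULL)))
  expect_lt(est_of(measure_bgv(hi_n, ci = NULL)), 0.1)
})

test_that("outlier scenario separates MDMU from MDMW", {
  s <- generate_series(synthetic_scenario(effect_shape = "outlier",
                                          dimension_type = "nonordered",
                                          n_subgroups = 10,
                                          outlier_offset = 40,
                                          outlier_share = 0.01,
                                          noise_n = Inf))[[1]]
  mdmu <- est_of(measure_mdmu(s, ci = NULL))
  mdmw <- est_of(measure_mdmw(s, ci = NULL))
  expect_gt(mdmu, 5 * mdmw)
})

test_that("reported SEs are consistent with the binomial noise model", {
  sc <- synthetic_scenario(n_settings = 300, effect_shape = "null",
                           base_level = 50, n_subgroups = 2,
                           dimension_type = "nonordered", noise_n = 1e4,
                           seed = 9)
  ss <- generate_series(sc)
  ests <- vapply(ss, function(s) s$data$estimate[1], 0)
  ses <- vapply(ss, function(s) s$data$se[1], 0)
  expect_lt(abs(sd(ests) - mean(ses)) / mean(ses), 0.15)
})

test_that("recover_parameters reports per-measure bias and rmse", {
  sc <- synthetic_scenario(effect_shape = "linear", gradient_size = 25,
                           noise_n = 2000)
  rep <- recover_parameters(sc, measures = c("D", "SII", "ACI"), reps = 40,
                            seed = 10)
  expect_setequal(rep$measure, c("D", "SII", "ACI"))
  expect_true(all(rep$n_defined == 40))
  expect_lt(abs(rep$bias[rep$measure == "D"]), 1.5)
  expect_equal(rep$truth[rep$measure == "SII"], 25)
  # BGV is positively biased under a null scenario, shrinking with n
  null_lo <- recover_parameters(
    synthetic_scenario(effect_shape = "null", dimension_type = "nonordered",
                       noise_n = 200), measures = "BGV", reps = 60, seed = 11)
  null_hi <- recover_parameters(
    synthetic_scenario(effect_shape = "null", dimension_type = "nonordered",
                       noise_n = 2e4), measures = "BGV", reps = 60, seed = 11)
  expect_gt(null_lo$bias, 0)
  expect_gt(null_lo$bias, null_hi$bias)
})
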