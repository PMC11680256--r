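test_that("ci_config validates its fields", {
  expect_error(ci_config(level = 1.2), "level")
  expect_error(ci_config(reps = 10), "reps")
  expect_error(ci_config(method = "magic"))
  expect_equal(ci_config()$level, 0.95)
})

test_that("difference: Wald CI with pooled SE", {
  s <- make_series(c(40, 60), se = c(3, 4), type = "ordered")
  d <- measure_difference(s)
  expect_equal(d$se, 5)
  expect_equal(d$ci_upper - d$estimate, d$estimate - d$ci_lower,
               tolerance = 1e-12)  # symmetric by construction
  expect_equal(d$ci_upper, 20 + qnorm(0.975) * 5)

  s0 <- make_series(c(40, 60), se = c(0, 0), type = "ordered")
  d0 <- measure_difference(s0)
  expect_equal(c(d0$ci_lower, d0$ci_upper), c(20, 20))
})

test_that("ratio: delta method on the log scale", {
  s <- make_series(c(25, 50), se = c(2.5, 5), type = "ordered")
  r <- measure_ratio(s)  # most advantaged / least: 50 / 25 = 2
  sel <- sqrt(0.01 + 0.01)
  expect_equal(r$estimate, 2)
  expect_equal(r$ci_lower, exp(log(2) - qnorm(0.975) * sel))
  expect_equal(r$ci_upper, exp(log(2) + qnorm(0.975) * sel))
  r0 <- measure_ratio(make_series(c(25, 50), se = c(0, 0), type = "ordered"))
  expect_equal(c(r0$ci_lower, r0$ci_upper), c(2, 2))
})

test_that("regression measures: analytic CI behaviour", {
  s0 <- make_series(c(40, 60), se = c(0, 0), type = "ordered")
  sii0 <- measure_sii(s0)
  expect_equal(c(sii0$ci_lower, sii0$ci_upper), c(40, 40))  # exact 2-point fit
  flat <- make_series(rep(50, 5), se = rep(2, 5), type = "ordered")
  sf <- measure_sii(flat)
  expect_lte(sf$ci_lower, 0)
  expect_gte(sf$ci_upper, 0)
  # analytic and bootstrap half-widths agree on a well-conditioned series
  s <- make_series(c(45, 50, 55, 60, 65), se = rep(1.5, 5), type = "ordered")
  an <- measure_sii(s, ci = ci_config(method = "analytic"))
  bo <- measure_sii(s, ci = ci_config(method = "bootstrap", reps = 4000,
                                      seed = 99))
  hw <- function(r) (r$ci_upper - r$ci_lower) / 2
  expect_lt(abs(hw(an) - hw(bo)) / hw(an), 0.15)
  # RII with a healthy intercept: delta CI contains the estimate
  rii <- measure_rii(s, ci = ci_config(method = "analytic"))
  expect_true(rii$ci_lower <= rii$estimate && rii$estimate <= rii$ci_upper)
})

test_that("bootstrap: determinism, degeneracy, and level monotonicity", {
  s <- make_series(c(30, 50, 70), se = c(2, 3, 2))
  b1 <- measure_bgv(s, ci = ci_config(seed = 7, reps = 300))
  b2 <- measure_bgv(s, ci = ci_config(seed = 7, reps = 300))
  expect_identical(c(b1$ci_lower, b1$ci_upper), c(b2$ci_lower, b2$ci_upper))

  s0 <- make_series(c(30, 50, 70), se = c(0, 0, 0))
  b0 <- measure_bgv(s0, ci = ci_config(seed = 1, reps = 200))
  expect_equal(c(b0$ci_lower, b0$ci_upper),
               rep(est_of(measure_bgv(s0, ci = NULL)), 2))

  w95 <- measure_theil(s, ci = ci_config(level = 0.95, seed = 3, reps = 500))
  w99 <- measure_theil(s, ci = ci_config(level = 0.99, seed = 3, reps = 500))
  expect_lte(w99$ci_lower, w95$ci_lower)
  expect_gte(w99$ci_upper, w95$ci_upper)
})

test_that("all intervals contain their point estimate", {
  set.seed(61)
  cfg <- ci_config(seed = 17, reps = 200)
  for (i in 1:20) {
    s <- random_series("nonordered", with_se = TRUE)
    for (f in list(measure_difference, measure_ratio, measure_mdmw,
                   measure_bgv, measure_theil, measure_cov, measure_par)) {
      r <- f(s, ci = cfg)
      if (r$defined && !is.na(r$ci_lower)) {
        expect_lte(r$ci_lower, r$estimate)
        expect_gte(r$ci_upper, r$estimate)
      }
    }
    o <- random_series("ordered", with_se = TRUE)
    for (f in list(measure_aci, measure_rci, measure_sii)) {
      r <- f(o, ci = cfg)
      expect_true(r$ci_lower <= r$estimate && r$estimate <= r$ci_upper)
    }
  }
})

test_that("missing SEs flag the CI undefined; measures still compute", {
  s <- make_series(c(30, 50, 70))  # no SEs
  r <- measure_bgv(s)
  expect_true(r$defined)
  expect_true(is.na(r$ci_lower))
  expect_match(r$ci_reason, "missing standard errors")
  d <- measure_difference(s)
  expect_match(d$ci_reason, "missing standard errors")
})

test_that("mostly-undefined bootstrap replicates give an undefined CI", {
  s <- make_series(c(50, 70), se = c(10, 1), type = "ordered")
  out <- healthineq:::boot_ci(
    s, function(x) if (x$data$estimate[1] < 55) NA_real_ else 1,
    estimate = 1, config = ci_config(seed = 5, reps = 400))
  expect_true(is.na(out$lower))
  expect_match(out$reason, ">50%")
})

test_that("explicit analytic method on a bootstrap-only measure errors", {
  s <- make_series(c(30, 50, 70), se = c(1, 1, 1))
  expect_error(measure_bgv(s, ci = ci_config(method = "analytic")),
               "no analytic CI")
})
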