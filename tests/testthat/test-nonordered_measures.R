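test_that("mean-difference family on worked cases", {
  s <- make_series(c(40, 60))
  expect_equal(est_of(measure_mdmu(s, ci = NULL)), 10)
  expect_equal(est_of(measure_mdmw(s, ci = NULL)), 10)
  expect_equal(est_of(measure_idisu(s, ci = NULL)), 20)
  expect_equal(est_of(measure_idisw(s, ci = NULL)), 20)

  s3 <- make_series(c(10, 50, 90))
  expect_equal(est_of(measure_mdmu(s3, ci = NULL)), 80 / 3)

  # small outlier: unweighted measure blows up, weighted barely moves
  out <- disagg_series(c(rep(50, 9), 90), c(rep(0.11, 9), 0.01),
                       dimension_type = "nonordered", setting_average = 50)
  expect_equal(est_of(measure_mdmw(out, ci = NULL)), 0.4)
  expect_equal(est_of(measure_mdmu(out, ci = NULL)), 4)

  flat <- flat_series(35)
  for (f in list(measure_mdmu, measure_mdmw, measure_idisu, measure_idisw))
    expect_equal(est_of(f(flat, ci = NULL)), 0)
})

test_that("variance family on worked cases", {
  s <- make_series(c(40, 60))
  expect_equal(est_of(measure_bgv(s, ci = NULL)), 100)
  expect_equal(est_of(measure_bgsd(s, ci = NULL)), 10)
  expect_equal(est_of(measure_cov(s, ci = NULL)), 20)
  flat <- flat_series(35)
  expect_equal(est_of(measure_bgv(flat, ci = NULL)), 0)
  expect_equal(est_of(measure_bgsd(flat, ci = NULL)), 0)
  expect_equal(est_of(measure_cov(flat, ci = NULL)), 0)
  # a single outlier dominates BGV
  out <- make_series(c(rep(50, 9), 90))
  mu <- setting_mean(out)
  expect_gt(0.1 * (90 - mu)^2 / est_of(measure_bgv(out, ci = NULL)), 0.85)
})

test_that("Theil index: worked value, zero subgroups, mu = 0", {
  s <- make_series(c(40, 60))
  expect_equal(est_of(measure_theil(s, ci = NULL)),
               1000 * (0.5 * 0.8 * log(0.8) + 0.5 * 1.2 * log(1.2)),
               tolerance = 1e-12)
  expect_equal(est_of(measure_theil(flat_series(25), ci = NULL)), 0)
  withzero <- make_series(c(0, 3, 1))
  ti <- measure_theil(withzero, ci = NULL)
  expect_true(ti$defined && is.finite(ti$estimate))
  allzero <- make_series(c(0, 0, 0))
  expect_false(measure_theil(allzero, ci = NULL)$defined)
})

test_that("oracle equivalence and structural identities on random series", {
  set.seed(41)
  for (i in 1:200) {
    s <- random_series("nonordered")
    mu <- oracle_mu(s)
    expect_equal(est_of(measure_mdmu(s, ci = NULL)), oracle_mdmu(s),
                 tolerance = 1e-9)
    expect_equal(est_of(measure_mdmw(s, ci = NULL)), oracle_mdmw(s),
                 tolerance = 1e-9)
    expect_equal(est_of(measure_bgv(s, ci = NULL)), oracle_bgv(s),
                 tolerance = 1e-9)
    expect_equal(est_of(measure_theil(s, ci = NULL)), oracle_theil(s),
                 tolerance = 1e-9)
    # identities
    bgv <- est_of(measure_bgv(s, ci = NULL))
    bgsd <- est_of(measure_bgsd(s, ci = NULL))
    expect_identical(bgsd, sqrt(bgv))  # BGSD is sqrt(BGV) by definition
    expect_equal(bgv, bgsd^2, tolerance = 1e-12)
    expect_equal(est_of(measure_cov(s, ci = NULL)), 100 * bgsd / mu,
                 tolerance = 1e-9)
    expect_equal(est_of(measure_idisw(s, ci = NULL)),
                 100 * est_of(measure_mdmw(s, ci = NULL)) / mu,
                 tolerance = 1e-9)
    expect_gte(bgsd, est_of(measure_mdmw(s, ci = NULL)))
    expect_gte(est_of(measure_theil(s, ci = NULL)), -1e-12)
  }
})

test_that("MDMU ignores shares; MDMW does not; order invariance", {
  s <- make_series(c(10, 40, 80), c(1, 1, 1))
  pert <- make_series(c(10, 40, 80), c(5, 1, 2),
                      setting_average = setting_mean(s))
  s_mu <- make_series(c(10, 40, 80), c(1, 1, 1),
                      setting_average = setting_mean(s))
  expect_equal(est_of(measure_mdmu(pert, ci = NULL)),
               est_of(measure_mdmu(s_mu, ci = NULL)))
  expect_false(est_of(measure_mdmw(pert, ci = NULL)) ==
                 est_of(measure_mdmw(s_mu, ci = NULL)))

  perm <- make_series(c(80, 10, 40), c(2, 5, 1))
  orig <- make_series(c(10, 40, 80), c(5, 1, 2))
  for (f in list(measure_mdmu, measure_mdmw, measure_bgv, measure_theil,
                 measure_cov, measure_idisu, measure_idisw))
    expect_equal(est_of(f(perm, ci = NULL)), est_of(f(orig, ci = NULL)),
                 tolerance = 1e-12)
})

test_that("quantile grouping helper collapses regions", {
  s <- make_series(seq(10, 90, length.out = 12), runif(12, 0.5, 2))
  g <- group_quantiles(s, k = 4)
  expect_s3_class(g, "disagg_series")
  expect_equal(nrow(g$data), 4)
  expect_equal(sum(g$data$population), sum(s$data$population))
  expect_equal(setting_mean(g), setting_mean(s), tolerance = 1e-9)
})
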