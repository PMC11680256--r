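test_that("structural violations are rejected with context", {
  expect_error(make_series(c(40, 60, 50, 55, 70), type = "ordered",
                           order = c(1, 2, 2, 4, 5)), "duplicate order ranks")
  expect_error(disagg_series(50, 1, dimension_type = "nonordered"),
               "at least 2 subgroups")
  expect_error(make_series(c(40, 101)), "\\[0, 100\\]")
  expect_error(make_series(c(40, -1)), "\\[0, 100\\]")
  expect_error(make_series(c(40, 60), se = c(-1, 2)), "non-negative")
  expect_error(make_series(c(40, 60), population = c(0, 0)),
               "positive population")
  expect_error(make_series(c(40, 60, 50), type = "binary", order = NULL),
               "exactly 2 subgroups")
  expect_error(make_series(c(40, 60, 50), type = "ordered",
                           order = c(1, 2, 4)), "contiguous")
  err <- tryCatch(disagg_series(c(40, 60), c(1, 1),
                                dimension_type = "ordered",
                                setting = "AFG", indicator = "dtp3",
                                dimension = "wealth"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "setting=AFG")
})

test_that("population normalization and idempotence", {
  s <- make_series(c(40, 60), population = c(3000, 1000))
  expect_equal(s$data$share, c(0.75, 0.25))
  expect_identical(validate_series(s)$data, s$data)
  expect_equal(s$data$population, c(3000, 1000))  # raw populations retained
})

test_that("midpoint ranks match the ridit construction", {
  s2 <- make_series(c(40, 60), c(0.5, 0.5), type = "ordered")
  expect_equal(compute_ranks(s2)$midpoint_rank, c(0.25, 0.75))
  q5 <- make_series(50:54, rep(1, 5), type = "ordered")
  expect_equal(compute_ranks(q5)$midpoint_rank, c(0.1, 0.3, 0.5, 0.7, 0.9))
  dom <- make_series(c(40, 60), c(0.9, 0.1), type = "ordered")
  expect_equal(compute_ranks(dom)$midpoint_rank, c(0.45, 0.95))
  expect_error(compute_ranks(make_series(c(1, 2), type = "nonordered")),
               "ordered dimensions only")
})

test_that("ranks are row-order invariant and share-weighted mean is 0.5", {
  s <- make_series(c(40, 60, 70), c(5, 2, 3), type = "ordered",
                   order = c(2, 1, 3))
  shuf <- make_series(c(60, 70, 40), c(2, 3, 5), type = "ordered",
                      order = c(1, 3, 2))
  expect_equal(compute_ranks(s)$midpoint_rank, compute_ranks(shuf)$midpoint_rank)
  set.seed(11)
  for (i in 1:50) {
    r <- compute_ranks(random_series("ordered"))
    expect_true(all(r$midpoint_rank > 0 & r$midpoint_rank < 1))
    expect_true(all(diff(r$midpoint_rank) > 0))
    expect_equal(sum(r$share * r$midpoint_rank), 0.5, tolerance = 1e-12)
  }
})

test_that("setting average: weighted mean unless supplied", {
  s <- make_series(c(40, 60), c(1, 3))
  expect_equal(setting_mean(s), 55)
  s2 <- make_series(c(40, 60), c(1, 3), setting_average = 48)
  expect_equal(setting_mean(s2), 48)
  # the supplied average flows through all relative/deviation measures
  expect_equal(est_of(measure_mdmw(s2, ci = NULL)),
               0.25 * 8 + 0.75 * 12)
  expect_equal(est_of(measure_cov(s2, ci = NULL)),
               100 * sqrt(0.25 * 64 + 0.75 * 144) / 48)
})

test_that("percent/proportion converters are explicit inverses", {
  x <- c(0, 12.5, 100)
  expect_equal(prop_to_pct(pct_to_prop(x)), x)
})
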