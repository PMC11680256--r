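#' Define a synthetic-data scenario
#'
#' Describes a controlled world of disaggregated series with known true
#' subgroup values, used to validate every measure and the full pipeline
#' without external data. The generator emulates the structure of
#' survey-derived immunization estimates: coverage-style percentages per
#' subgroup, binomial sampling noise with the implied standard error, and
#' (optionally) uneven population shares.
#'
#' Effect shapes:
#' \describe{
#'   \item{null}{all true subgroup values equal `base_level` — no inequality.}
#'   \item{linear}{true values increase linearly in the equal-share midpoint
#'     rank (2j - 1)/(2n) with slope `gradient_size`, i.e. from `base_level -
#'     gradient_size (n-1)/(2n)` (least advantaged) upward, so that with
#'     equal shares the true linear SII equals `gradient_size` exactly.}
#'   \item{outlier}{all subgroups at `base_level` except the last, offset by
#'     `outlier_offset` and holding population share `outlier_share` — the
#'     configuration that separates population-weighted from unweighted
#'     measures.}
#'   \item{step}{lower half at `base_level - gradient_size/2`, upper half at
#'     `base_level + gradient_size/2`.}
#' }
#'
#' @param n_settings Number of independent settings (series) to generate.
#' @param dimension_type `"ordered"`, `"nonordered"`, or `"binary"`.
#' @param n_subgroups Subgroups per series (2 for binary; 5 emulates wealth
#'   quintiles).
#' @param effect_shape One of `"null"`, `"linear"`, `"outlier"`, `"step"`.
#' @param gradient_size Percentage points between the extreme true values
#'   (linear/step shapes).
#' @param outlier_offset,outlier_share Offset (percentage points, may be
#'   negative) and population share of the outlying subgroup.
#' @param base_level Central true value, percent.
#' @param noise_n Effective sample size per subgroup for binomial noise;
#'   `Inf` for noise-free series. Typical DHS/MICS subgroup sizes are in
#'   the hundreds to low thousands; the default 1000 reflects that.
#' @param share_concentration Concentration parameter of the symmetric
#'   Dirichlet draw for population shares; `NULL` (default) gives equal
#'   shares — exact for wealth quintiles, idealized for regions. Smaller
#'   values give more uneven shares.
#' @param favourable Indicator favourability flag carried onto the series.
#' @param indicator,dimension Text labels for the generated series.
#' @param seed Integer seed; identical scenarios with identical seeds
#'   generate identical data.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_settings = 1L,
                               dimension_type = c("ordered", "nonordered",
                                                  "binary"),
                               n_subgroups = 5L,
                               effect_shape = c("null", "linear", "outlier",
                                                "step"),
                               gradient_size = 25, outlier_offset = 20,
                               outlier_share = 0.05, base_level = 50,
                               noise_n = 1000, share_concentration = NULL,
                               favourable = TRUE, indicator = "indicator",
                               dimension = NULL, seed = NULL) {
  dimension_type <- match.arg(dimension_type)
  effect_shape <- match.arg(effect_shape)
  n_subgroups <- as.integer(n_subgroups)
  if (dimension_type == "binary" && n_subgroups != 2L)
    stop("binary scenarios need exactly 2 subgroups", call. = FALSE)
  stopifnot(n_subgroups >= 2L, n_settings >= 1L, noise_n > 0,
            base_level >= 0, base_level <= 100,
            outlier_share > 0, outlier_share < 1)
  sc <- structure(list(
    n_settings = as.integer(n_settings), dimension_type = dimension_type,
    n_subgroups = n_subgroups, effect_shape = effect_shape,
    gradient_size = gradient_size, outlier_offset = outlier_offset,
    outlier_share = outlier_share, base_level = base_level,
    noise_n = noise_n, share_concentration = share_concentration,
    favourable = isTRUE(favourable), indicator = indicator,
    dimension = dimension %||% switch(dimension_type,
                                      binary = "residence",
                                      ordered = "wealth",
                                      nonordered = "region"),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "synthetic_scenario")
  tv <- true_values(sc)
  if (any(tv < 0 | tv > 100))
    stop("infeasible scenario: true values outside [0, 100]", call. = FALSE)
  sc
}

#' True subgroup values of a scenario
#'
#' @param scenario A [synthetic_scenario()].
#' @return Numeric vector of the noise-free subgroup values, in percent,
#'   ordered from least to most advantaged (first to last subgroup).
#' @export
true_values <- function(scenario) {
  n <- scenario$n_subgroups
  b <- scenario$base_level
  g <- scenario$gradient_size
  switch(scenario$effect_shape,
    null = rep(b, n),
    # linear in the equal-share midpoint rank (2j-1)/(2n), slope g: the true
    # linear SII under equal shares is exactly g
    linear = b + g * (2 * seq_len(n) - 1 - n) / (2 * n),
    outlier = c(rep(b, n - 1), b + scenario$outlier_offset),
    step = c(rep(b - g / 2, floor(n / 2)), rep(b + g / 2, n - floor(n / 2))))
}

scenario_shares <- function(scenario) {
  n <- scenario$n_subgroups
  if (scenario$effect_shape == "outlier") {
    s <- scenario$outlier_share
    return(c(rep((1 - s) / (n - 1), n - 1), s))
  }
  a <- scenario$share_concentration
  if (is.null(a)) return(rep(1 / n, n))
  g <- stats::rgamma(n, shape = a, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

#' Generate synthetic disaggregated series
#'
#' Draws `n_settings` independent series from a scenario: true values from
#' the effect shape, population shares equal or Dirichlet, and observed
#' estimates as binomial proportions with the scenario's effective sample
#' size, converted to percent with the binomial standard error attached.
#' Identical seeds give identical output. Each series carries its
#' noise-free truth as attribute `"truth"` (a list with `estimate` and
#' `share`) for recovery studies.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of `disagg_series`.
#' @export
generate_series <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  tv <- true_values(scenario)
  n <- scenario$n_subgroups
  labels <- switch(scenario$dimension_type,
    binary = c("rural", "urban"),
    ordered = paste0("q", seq_len(n)),
    nonordered = paste0("region_", seq_len(n)))
  with_local_seed(scenario$seed, function() {
    lapply(seq_len(scenario$n_settings), function(s) {
      shares <- scenario_shares(scenario)
      if (is.finite(scenario$noise_n)) {
        k <- stats::rbinom(n, size = scenario$noise_n, prob = tv / 100)
        phat <- k / scenario$noise_n
        est <- 100 * phat
        se <- 100 * sqrt(phat * (1 - phat) / scenario$noise_n)
      } else {
        est <- tv
        se <- rep(0, n)
      }
      out <- disagg_series(
        estimate = est, population = shares, se = se, subgroup = labels,
        order = if (scenario$dimension_type == "ordered") seq_len(n) else NULL,
        dimension_type = scenario$dimension_type,
        dimension = scenario$dimension, indicator = scenario$indicator,
        setting = sprintf("setting_%03d", s),
        favourable = scenario$favourable,
        group_of_interest = if (scenario$dimension_type == "binary")
          "urban" else NULL)
      attr(out, "truth") <- list(estimate = tv, share = shares)
      out
    })
  })
}

#' Parameter-recovery study for the summary measures
#'
#' Repeatedly generates data from a scenario, computes the requested
#' measures on each noisy series, and compares each estimate with the truth
#' for that replicate — the same measure evaluated on a noise-free copy of
#' the series (same realized shares, true subgroup values). Reports mean
#' truth, bias, and RMSE per measure.
#'
#' @param scenario A [synthetic_scenario()]; its `n_settings` is ignored
#'   (one series per replicate).
#' @param measures Character vector of measure codes.
#' @param reps Number of replicates.
#' @param sii_variant Passed through for SII/RII.
#' @param seed Integer seed for the whole study (overrides the scenario's).
#' @return A data frame with one row per measure: `truth` (mean over
#'   replicates), `mean_estimate`, `bias`, `rmse`, `n_defined`, `reps`.
#' @export
recover_parameters <- function(scenario, measures = c("D", "SII"),
                               reps = 100L, sii_variant = "linear",
                               seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  measures <- vapply(measures, function(m) match.arg(toupper(m),
                                                     MEASURE_CODES), "")
  one <- scenario
  one$n_settings <- 1L
  one$seed <- NULL
  est <- tru <- matrix(NA_real_, reps, length(measures),
                       dimnames = list(NULL, measures))
  with_local_seed(seed, function() {
    for (r in seq_len(reps)) {
      s <- generate_series(one)[[1]]
      truth <- attr(s, "truth")
      s0 <- s
      s0$data$estimate <- truth$estimate
      s0$data$se <- rep(0, length(truth$estimate))
      for (m in measures) {
        rm_ <- compute_measure(s, m, ci = NULL, sii_variant = sii_variant)
        rt_ <- compute_measure(s0, m, ci = NULL, sii_variant = sii_variant)
        est[r, m] <<- if (rm_$defined) rm_$estimate else NA_real_
        tru[r, m] <<- if (rt_$defined) rt_$estimate else NA_real_
      }
    }
  })
  out <- lapply(measures, function(m) {
    ok <- !is.na(est[, m]) & !is.na(tru[, m])
    err <- est[ok, m] - tru[ok, m]
    data.frame(measure = m, truth = mean(tru[ok, m]),
               mean_estimate = mean(est[ok, m]),
               bias = mean(err), rmse = sqrt(mean(err^2)),
               n_defined = sum(ok), reps = reps, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
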