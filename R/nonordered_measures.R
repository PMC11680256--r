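# Point kernels for the mean-difference, variance, and entropy families.
# All deviations are taken about the same setting average mu (the supplied
# setting_average if present, otherwise the population-weighted subgroup
# mean); MDMU/IDISU weight the deviations equally across subgroups while the
# weighted versions use population shares.

mdmu_point <- function(x) mean(abs(x$data$estimate - setting_mean(x)))

mdmw_point <- function(x) {
  mu <- setting_mean(x)
  sum(x$data$share * abs(x$data$estimate - mu))
}

idisu_point <- function(x) {
  mu <- setting_mean(x)
  if (mu == 0) return(NA_real_)
  100 * mdmu_point(x) / mu
}

idisw_point <- function(x) {
  mu <- setting_mean(x)
  if (mu == 0) return(NA_real_)
  100 * mdmw_point(x) / mu
}

bgv_point <- function(x) {
  mu <- setting_mean(x)
  sum(x$data$share * (x$data$estimate - mu)^2)
}

bgsd_point <- function(x) sqrt(bgv_point(x))

cov_point <- function(x) {
  mu <- setting_mean(x)
  if (mu == 0) return(NA_real_)
  100 * bgsd_point(x) / mu
}

theil_point <- function(x) {
  mu <- setting_mean(x)
  if (mu == 0) return(NA_real_)
  r <- x$data$estimate / mu
  terms <- ifelse(r > 0, r * log(r), 0)  # 0 * log(0) := 0
  1000 * sum(x$data$share * terms)
}

undef_mu0 <- function(x, code)
  new_result(x, code, defined = FALSE,
             undefined_reason = "setting average is zero")

simple_dispatch <- function(x, code, point_fun, ci, needs_mu = FALSE) {
  stopifnot(inherits(x, "disagg_series"))
  if (needs_mu && setting_mean(x) == 0) return(undef_mu0(x, code))
  est <- point_fun(x)
  civ <- resolve_ci(x, ci, est, point_fun)
  new_result(x, code, est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level, ci_reason = civ$reason)
}

#' Mean difference from mean, unweighted (MDMU) and weighted (MDMW)
#'
#' The average absolute difference between each subgroup's estimate and the
#' setting average mu, in percentage points. MDMU weights every subgroup
#' equally, MDMW weights by population share:
#'
#'   MDMU = (1/n) sum_j |y_j - mu|,   MDMW = sum_j p_j |y_j - mu|.
#'
#' Both use the same (population-weighted or supplied) mu; the asymmetry of
#' MDMU — weighted centre, unweighted deviations — is deliberate: the
#' question it answers is how far the typical region sits from the national
#' average. Small outlier regions therefore move MDMU much more than MDMW.
#' Zero indicates no inequality.
#'
#' @inheritParams measure_difference
#' @return A `measure_result`; CIs via parametric bootstrap.
#' @export
measure_mdmu <- function(x, ci = ci_config())
  simple_dispatch(x, "MDMU", mdmu_point, ci)

#' @rdname measure_mdmu
#' @export
measure_mdmw <- function(x, ci = ci_config())
  simple_dispatch(x, "MDMW", mdmw_point, ci)

#' Index of disparity, unweighted (IDISU) and weighted (IDISW)
#'
#' The relative versions of the mean difference from mean: the corresponding
#' MDM divided by the setting average and multiplied by 100. Undefined when
#' the setting average is zero.
#'
#' @inheritParams measure_difference
#' @return A `measure_result`.
#' @export
measure_idisu <- function(x, ci = ci_config())
  simple_dispatch(x, "IDISU", idisu_point, ci, needs_mu = TRUE)

#' @rdname measure_idisu
#' @export
measure_idisw <- function(x, ci = ci_config())
  simple_dispatch(x, "IDISW", idisw_point, ci, needs_mu = TRUE)

#' Between-group variance (BGV) and standard deviation (BGSD)
#'
#' BGV = sum_j p_j (y_j - mu)^2 summarizes all squared deviations of the
#' subgroup estimates from the setting average and is reported in the
#' squared unit of the indicator (squared percentage points); squaring makes
#' it markedly sensitive to outlying subgroups. BGSD = sqrt(BGV) retains the
#' outlier sensitivity but is reported on the indicator's own scale. For any
#' series, BGSD >= MDMW (a weighted root-mean-square deviation is never
#' smaller than the weighted mean absolute deviation about the same centre).
#'
#' @inheritParams measure_difference
#' @return A `measure_result`.
#' @export
measure_bgv <- function(x, ci = ci_config())
  simple_dispatch(x, "BGV", bgv_point, ci)

#' @rdname measure_bgv
#' @export
measure_bgsd <- function(x, ci = ci_config())
  simple_dispatch(x, "BGSD", bgsd_point, ci)

#' Coefficient of variation (COV)
#'
#' The relative version of BGSD: 100 * BGSD / mu. Undefined when the setting
#' average is zero. Unlike the extreme-subgroup ratio, COV is population
#' weighted, so a tiny subgroup with a near-zero estimate inflates it far
#' less than it inflates R.
#'
#' @inheritParams measure_difference
#' @return A `measure_result`.
#' @export
measure_cov <- function(x, ci = ci_config())
  simple_dispatch(x, "COV", cov_point, ci, needs_mu = TRUE)

#' Theil index (TI)
#'
#' An entropy-based disproportionality measure contrasting each subgroup's
#' share of the indicator with its share of the population:
#'
#'   TI = 1000 * sum_j p_j (y_j / mu) ln(y_j / mu),
#'
#' scaled by 1000 for easier reading. TI >= 0 for non-negative estimates
#' (convexity of x ln x), with equality exactly when every subgroup sits at
#' the setting average. Subgroups with a zero estimate contribute zero (the
#' x ln x -> 0 limit convention), so TI stays finite on zero-dose data with
#' empty subgroups; it is undefined only when the setting average itself is
#' zero.
#'
#' @inheritParams measure_difference
#' @return A `measure_result`.
#' @export
measure_theil <- function(x, ci = ci_config())
  simple_dispatch(x, "TI", theil_point, ci, needs_mu = TRUE)

#' Group subgroups into quantile bins (pre-processing helper)
#'
#' Collapses a non-ordered series with many subgroups into `k` bins of
#' (approximately) equal subgroup counts by the indicator estimate, with
#' populations summed and estimates population-weight averaged within bins.
#' This is an optional pre-processing step for comparing settings whose
#' region counts differ greatly; no measure applies it implicitly.
#'
#' @param x A `disagg_series`.
#' @param k Number of bins (default 5).
#' @return A new `disagg_series` with `k` subgroups.
#' @export
group_quantiles <- function(x, k = 5L) {
  stopifnot(inherits(x, "disagg_series"))
  d <- x$data[order(x$data$estimate), ]
  n <- nrow(d)
  if (k < 2L || k > n)
    stop("k must be between 2 and the number of subgroups", call. = FALSE)
  bin <- ceiling(seq_len(n) / n * k)
  est <- tapply(d$estimate * d$population, bin, sum) /
    tapply(d$population, bin, sum)
  pop <- tapply(d$population, bin, sum)
  disagg_series(estimate = as.numeric(est), population = as.numeric(pop),
                subgroup = paste0("bin_", seq_len(k)),
                dimension_type = x$dimension_type,
                dimension = paste0(x$dimension, "_binned"),
                indicator = x$indicator, setting = x$setting,
                favourable = x$favourable,
                setting_average = if (is.na(x$setting_average)) NULL else
                  x$setting_average)
}
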