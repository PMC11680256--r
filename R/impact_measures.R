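# Reference subgroup for the impact measures: the most advantaged subgroup
# for ordered dimensions (even when it is not the best performer), the
# best-performing subgroup otherwise (max estimate for favourable
# indicators, min for adverse).
par_reference <- function(x) {
  d <- x$data
  if (x$dimension_type == "ordered") which.max(d$order)
  else if (x$favourable) which.max(d$estimate)
  else which.min(d$estimate)
}

# Signed, truncated PAR. Raw value is y_ref - mu; for favourable indicators
# the achievable improvement is positive, for adverse indicators negative (a
# reduction in prevalence). When the reference performs worse than the
# average the raw value points the "wrong" way and is truncated to 0.
par_raw <- function(x) x$data$estimate[par_reference(x)] - setting_mean(x)

par_point <- function(x) {
  raw <- par_raw(x)
  if (x$favourable) max(raw, 0) else min(raw, 0)
}

paf_point <- function(x) {
  mu <- setting_mean(x)
  if (mu == 0) return(NA_real_)
  100 * par_point(x) / mu
}

#' Population attributable risk (PAR)
#'
#' The absolute improvement in the setting average achievable if every
#' subgroup had the same indicator level as the reference subgroup: the most
#' advantaged subgroup for ordered dimensions, the best-performing subgroup
#' for non-ordered (and binary) dimensions. For favourable indicators PAR =
#' y_ref - mu >= 0 (coverage could rise by PAR points); for adverse
#' indicators PAR is reported as a signed, negative change in prevalence,
#' with [par_magnitude()] giving the absolute size of the improvement.
#'
#' When the reference subgroup performs worse than the setting average
#' (possible for ordered dimensions, where the most advantaged subgroup need
#' not be the best performer), the raw value is truncated to 0 and the
#' result carries `truncated = TRUE` plus the pre-truncation `raw_par` in
#' its metadata, so that correlation analyses can use either version.
#'
#' @inheritParams measure_difference
#' @return A `measure_result` with metadata fields `reference`, `raw_par`,
#'   and `truncated`.
#' @export
measure_par <- function(x, ci = ci_config()) {
  stopifnot(inherits(x, "disagg_series"))
  ref <- par_reference(x)
  raw <- par_raw(x)
  est <- par_point(x)
  civ <- resolve_ci(x, ci, est, par_point)
  new_result(x, "PAR", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level, ci_reason = civ$reason,
             metadata = list(reference = x$data$subgroup[ref],
                             raw_par = raw, truncated = (est != raw)))
}

#' Population attributable fraction (PAF)
#'
#' The relative counterpart of [measure_par()]: PAF = 100 * PAR / mu, the
#' percentage change in the setting average achievable by eliminating
#' inequality. Shares PAR's sign convention and truncation; undefined when
#' the setting average is zero.
#'
#' @inheritParams measure_difference
#' @return A `measure_result`.
#' @export
measure_paf <- function(x, ci = ci_config()) {
  stopifnot(inherits(x, "disagg_series"))
  mu <- setting_mean(x)
  if (mu == 0)
    return(new_result(x, "PAF", defined = FALSE,
                      undefined_reason = "setting average is zero"))
  ref <- par_reference(x)
  est <- paf_point(x)
  civ <- resolve_ci(x, ci, est, paf_point)
  new_result(x, "PAF", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level, ci_reason = civ$reason,
             metadata = list(reference = x$data$subgroup[ref],
                             truncated = (par_point(x) != par_raw(x))))
}

#' Absolute magnitude of a PAR/PAF result
#'
#' @param result A `measure_result` from [measure_par()] or [measure_paf()].
#' @return `abs(estimate)`; for adverse indicators the size of the
#'   achievable reduction.
#' @export
par_magnitude <- function(result) {
  stopifnot(inherits(result, "measure_result"),
            result$measure %in% c("PAR", "PAF"))
  abs(result$estimate)
}

#' Aggregate PAR across settings
#'
#' Population-weighted cross-setting view of the impact of eliminating
#' inequality: each setting contributes its current average mu_s and its
#' signed PAR_s, weighted by the applicable population w_s (for
#' immunization indicators, the number of children aged one year). Returns
#' the weighted current average, the weighted potential average
#' sum(w_s (mu_s + PAR_s)) / sum(w_s), and the gain between them.
#'
#' @param mu Numeric vector of setting averages, in percent.
#' @param par Numeric vector of signed PAR estimates (same length).
#' @param weight Positive weights (applicable populations); default equal.
#' @return A list with `current`, `potential`, and `gain`, all in percent
#'   (gain in percentage points, negative for adverse indicators).
#' @export
aggregate_par <- function(mu, par, weight = rep(1, length(mu))) {
  stopifnot(length(mu) == length(par), length(mu) == length(weight),
            all(weight >= 0), sum(weight) > 0)
  current <- sum(weight * mu) / sum(weight)
  potential <- sum(weight * (mu + par)) / sum(weight)
  list(current = current, potential = potential, gain = potential - current)
}
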