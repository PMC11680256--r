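# Built-in orientation for common binary dimensions: the first label is the
# group of interest, the second the reference, so D = interest - reference
# (urban - rural for place of residence).
BINARY_ORIENTATION <- list(c("urban", "rural"))

# Resolve the two compared subgroups for a series.
# Returns list(ia, ib, tie_max, tie_min, orientation) with row indices of the
# group of interest / numerator (ia) and the reference / denominator (ib).
comparison_pair <- function(x) {
  d <- x$data
  if (x$dimension_type == "binary") {
    lab <- tolower(trimws(d$subgroup))
    if (!is.null(x$group_of_interest)) {
      ia <- match(tolower(trimws(x$group_of_interest)), lab)
      if (is.na(ia))
        stop("group_of_interest '", x$group_of_interest,
             "' does not match a subgroup label ", series_context(x),
             call. = FALSE)
      return(list(ia = ia, ib = setdiff(1:2, ia), orientation = "declared"))
    }
    for (pair in BINARY_ORIENTATION) {
      if (setequal(lab, pair))
        return(list(ia = match(pair[1], lab), ib = match(pair[2], lab),
                    orientation = "built-in"))
    }
    return(list(ia = 1L, ib = 2L, orientation = "input-order"))
  }
  if (x$dimension_type == "ordered") {
    return(list(ia = which.max(d$order), ib = which.min(d$order),
                orientation = "most vs least advantaged"))
  }
  # non-ordered: extreme estimates, max vs min; ties broken by first
  # occurrence, with the full tie sets recorded
  ia <- which.max(d$estimate)
  ib <- which.min(d$estimate)
  list(ia = ia, ib = ib,
       tie_max = d$subgroup[d$estimate == d$estimate[ia]],
       tie_min = d$subgroup[d$estimate == d$estimate[ib]],
       orientation = "max vs min estimate")
}

pair_metadata <- function(pr) {
  md <- list(orientation = pr$orientation)
  if (length(pr$tie_max %||% character(0)) > 1L) md$tie_max <- pr$tie_max
  if (length(pr$tie_min %||% character(0)) > 1L) md$tie_min <- pr$tie_min
  md
}

difference_point <- function(x) {
  pr <- comparison_pair(x)
  x$data$estimate[pr$ia] - x$data$estimate[pr$ib]
}

ratio_point <- function(x) {
  pr <- comparison_pair(x)
  den <- x$data$estimate[pr$ib]
  if (den == 0) return(NA_real_)
  x$data$estimate[pr$ia] / den
}

#' Difference between two extreme subgroups (D)
#'
#' The simple absolute measure: for binary dimensions the group of interest
#' minus the reference (urban minus rural for place of residence); for
#' ordered dimensions the most advantaged minus the least advantaged
#' subgroup (richest minus poorest quintile, highest minus lowest HDI
#' region); for non-ordered dimensions the maximum minus the minimum
#' estimate (always non-negative). A difference of 0 indicates no
#' inequality. Reported in percentage points.
#'
#' The favourable/adverse indicator flag does not change D or R for binary
#' and ordered dimensions: orientation is fixed by subgroup identity, so an
#' adverse indicator concentrated among the disadvantaged simply shows up
#' with the opposite sign.
#'
#' @param x A validated `disagg_series`.
#' @param ci A [ci_config()], or `NULL` to skip interval computation. The
#'   analytic SE is `sqrt(se_a^2 + se_b^2)` with a symmetric Wald interval.
#' @return A `measure_result`.
#' @examples
#' s <- disagg_series(c(40, 60), c(1, 1), order = 1:2,
#'                    dimension_type = "ordered")
#' measure_difference(s, ci = NULL)
#' @export
measure_difference <- function(x, ci = ci_config()) {
  stopifnot(inherits(x, "disagg_series"))
  pr <- comparison_pair(x)
  d <- x$data
  est <- d$estimate[pr$ia] - d$estimate[pr$ib]
  analytic <- function() wald_ci(est, sqrt(d$se[pr$ia]^2 + d$se[pr$ib]^2),
                                 ci$level)
  civ <- resolve_ci(x, ci, est, difference_point, analytic)
  new_result(x, "D", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level,
             compared = d$subgroup[c(pr$ia, pr$ib)], ci_reason = civ$reason,
             metadata = pair_metadata(pr))
}

#' Ratio between two extreme subgroups (R)
#'
#' The simple relative measure, using the same subgroup pairing as
#' [measure_difference()]: R = interest / reference for binary, most / least
#' advantaged for ordered, and max / min (therefore at least 1) for
#' non-ordered dimensions. A ratio of 1 indicates no inequality. When the
#' denominator subgroup has an estimate of zero the ratio is undefined and
#' the result is returned with `defined = FALSE` rather than an error —
#' zero-valued subgroups occur in real zero-dose data.
#'
#' @inheritParams measure_difference
#' @return A `measure_result`. The analytic CI uses the delta method on the
#'   log scale and requires both estimates to be positive; with a
#'   zero-valued numerator the interval falls back to the bootstrap.
#' @export
measure_ratio <- function(x, ci = ci_config()) {
  stopifnot(inherits(x, "disagg_series"))
  pr <- comparison_pair(x)
  d <- x$data
  ya <- d$estimate[pr$ia]; yb <- d$estimate[pr$ib]
  if (yb == 0)
    return(new_result(x, "R", defined = FALSE,
                      undefined_reason = "zero denominator",
                      compared = d$subgroup[c(pr$ia, pr$ib)],
                      metadata = pair_metadata(pr)))
  est <- ya / yb
  analytic <- function() {
    if (ya <= 0) return(NULL)  # log-delta needs positive estimates
    sel <- sqrt((d$se[pr$ia] / ya)^2 + (d$se[pr$ib] / yb)^2)
    z <- stats::qnorm(1 - (1 - ci$level) / 2)
    list(se = est * sel,  # delta-method SE on the natural scale
         lower = exp(log(est) - z * sel), upper = exp(log(est) + z * sel),
         reason = NULL)
  }
  civ <- resolve_ci(x, ci, est, ratio_point, analytic)
  new_result(x, "R", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level,
             compared = d$subgroup[c(pr$ia, pr$ib)], ci_reason = civ$reason,
             metadata = pair_metadata(pr))
}
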