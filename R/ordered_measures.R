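# --- point-estimate kernels -------------------------------------------------

aci_point <- function(x) {
  r <- compute_ranks(x)
  d <- x$data[order(x$data$order), ]
  sum(r$share * d$estimate * (2 * r$midpoint_rank - 1))
}

rci_point <- function(x) {
  mu <- setting_mean(x)
  if (mu == 0) return(NA_real_)
  100 * aci_point(x) / mu
}

# Weighted least-squares fit of estimate on midpoint rank, with population
# shares as weights. Closed form; returns the slope, intercept, predictions
# at rank 0 and 1, and the linear coefficients of each on the subgroup
# estimates (used for delta-method SEs). The share-weighted mean rank is 0.5
# by construction.
sii_fit_linear <- function(x) {
  r <- compute_ranks(x)
  d <- x$data[order(x$data$order), ]
  w <- r$share; X <- r$midpoint_rank; y <- d$estimate
  xbar <- sum(w * X)
  sxx <- sum(w * (X - xbar)^2)
  if (sxx <= 0) return(NULL)  # degenerate design
  cj <- w * (X - xbar) / sxx          # slope = sum(cj * y)
  aj <- w - xbar * cj                 # intercept = sum(aj * y)
  beta <- sum(cj * y)
  alpha <- sum(aj * y)
  list(beta = beta, alpha = alpha, pred0 = alpha, pred1 = alpha + beta,
       cj = cj, aj = aj, se = d$se)
}

# Logit-link variant: weighted GLM on the proportion scale, predictions
# back-transformed to percent. Quasi-binomial because the responses are
# aggregated proportions, not Bernoulli outcomes.
sii_fit_logit <- function(x) {
  r <- compute_ranks(x)
  d <- x$data[order(x$data$order), ]
  prop <- pct_to_prop(d$estimate)
  fit <- tryCatch(
    suppressWarnings(stats::glm(prop ~ r$midpoint_rank,
                                family = stats::quasibinomial(),
                                weights = r$share)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  co <- stats::coef(fit)
  if (anyNA(co)) return(NULL)
  p0 <- stats::plogis(co[[1]])
  p1 <- stats::plogis(co[[1]] + co[[2]])
  list(pred0 = prop_to_pct(p0), pred1 = prop_to_pct(p1))
}

sii_point_linear <- function(x) {
  f <- sii_fit_linear(x)
  if (is.null(f)) NA_real_ else f$beta
}
sii_point_logit <- function(x) {
  f <- sii_fit_logit(x)
  if (is.null(f)) NA_real_ else f$pred1 - f$pred0
}
rii_point_linear <- function(x) {
  f <- sii_fit_linear(x)
  if (is.null(f) || f$pred0 <= 0) NA_real_ else f$pred1 / f$pred0
}
rii_point_logit <- function(x) {
  f <- sii_fit_logit(x)
  if (is.null(f) || f$pred0 <= 0) NA_real_ else f$pred1 / f$pred0
}

# --- user-facing measures ---------------------------------------------------

#' Absolute concentration index (ACI)
#'
#' Captures the extent to which the indicator is concentrated among more or
#' less advantaged subgroups of an ordered dimension. With population shares
#' p_j, estimates y_j, and midpoint (ridit) ranks X_j running from least to
#' most advantaged,
#'
#'   ACI = sum_j p_j * y_j * (2 * X_j - 1),
#'
#' equivalently twice the share-weighted covariance of y and X. Positive
#' values indicate higher indicator values among the most advantaged,
#' negative values among the least advantaged; 0 indicates no inequality.
#' Reported in percentage points.
#'
#' @inheritParams measure_difference
#' @return A `measure_result`. The CI is bootstrap-based.
#' @export
measure_aci <- function(x, ci = ci_config()) {
  stopifnot(inherits(x, "disagg_series"))
  est <- aci_point(x)
  civ <- resolve_ci(x, ci, est, aci_point)
  new_result(x, "ACI", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level, ci_reason = civ$reason)
}

#' Relative concentration index (RCI)
#'
#' The relative counterpart of [measure_aci()]: the absolute concentration
#' index divided by the setting average and, as with the disparity indices,
#' multiplied by 100 so that values read as a percent-style quantity.
#' Undefined when the setting average is zero.
#'
#' @inheritParams measure_difference
#' @return A `measure_result` with estimate 100 * ACI / mu.
#' @export
measure_rci <- function(x, ci = ci_config()) {
  stopifnot(inherits(x, "disagg_series"))
  mu <- setting_mean(x)
  if (mu == 0)
    return(new_result(x, "RCI", defined = FALSE,
                      undefined_reason = "setting average is zero"))
  est <- rci_point(x)
  civ <- resolve_ci(x, ci, est, rci_point)
  new_result(x, "RCI", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level, ci_reason = civ$reason)
}

#' Slope index of inequality (SII)
#'
#' The gap between the predicted indicator values of the most and the least
#' advantaged, taking all subgroups into account: subgroup estimates are
#' regressed on their midpoint ranks X_j in \[0, 1\] with population shares
#' as weights, and SII is the prediction at X = 1 minus the prediction at
#' X = 0, in percentage points.
#'
#' Two fitting variants are provided, because different software fits this
#' regression differently and the results need not agree exactly:
#' `"linear"` (default) is weighted least squares on the percent scale;
#' `"logit"` fits a quasi-binomial GLM with a logit link on the proportion
#' scale and back-transforms the predictions. The variant used is recorded
#' in the result metadata.
#'
#' @inheritParams measure_difference
#' @param variant `"linear"` or `"logit"`.
#' @return A `measure_result`. The linear variant has an analytic SE from
#'   propagating the subgroup SEs through the WLS slope; the logit variant
#'   uses the bootstrap.
#' @export
measure_sii <- function(x, ci = ci_config(), variant = c("linear", "logit")) {
  stopifnot(inherits(x, "disagg_series"))
  variant <- match.arg(variant)
  if (variant == "linear") {
    f <- sii_fit_linear(x)
    if (is.null(f))
      return(new_result(x, "SII", defined = FALSE,
                        undefined_reason = "degenerate design (no rank spread)",
                        metadata = list(variant = variant)))
    est <- f$beta
    analytic <- function() wald_ci(est, sqrt(sum((f$cj * f$se)^2)), ci$level)
    civ <- resolve_ci(x, ci, est, sii_point_linear, analytic)
  } else {
    f <- sii_fit_logit(x)
    if (is.null(f))
      return(new_result(x, "SII", defined = FALSE,
                        undefined_reason = "logit fit did not converge",
                        metadata = list(variant = variant)))
    est <- f$pred1 - f$pred0
    civ <- resolve_ci(x, ci, est, sii_point_logit)
  }
  new_result(x, "SII", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level, ci_reason = civ$reason,
             metadata = list(variant = variant))
}

#' Relative index of inequality (RII)
#'
#' The relative counterpart of [measure_sii()]: the ratio of the predicted
#' indicator value at rank 1 (most advantaged) to the prediction at rank 0
#' (least advantaged). RII = 1 indicates no inequality. Under the linear
#' variant a steep negative gradient can push the predicted value at rank 0
#' to or below zero, in which case the ratio is undefined; the logit variant
#' keeps predictions strictly inside (0, 100) and remains defined.
#'
#' @inheritParams measure_sii
#' @return A `measure_result`. The linear-variant CI uses the delta method
#'   on the log predicted ratio, falling back to the bootstrap when the
#'   prediction at rank 0 is within two standard errors of zero.
#' @export
measure_rii <- function(x, ci = ci_config(), variant = c("linear", "logit")) {
  stopifnot(inherits(x, "disagg_series"))
  variant <- match.arg(variant)
  f <- if (variant == "linear") sii_fit_linear(x) else sii_fit_logit(x)
  if (is.null(f))
    return(new_result(x, "RII", defined = FALSE,
                      undefined_reason = if (variant == "linear")
                        "degenerate design (no rank spread)" else
                        "logit fit did not converge",
                      metadata = list(variant = variant)))
  if (f$pred0 <= 0)
    return(new_result(x, "RII", defined = FALSE,
                      undefined_reason = "non-positive predicted value at rank 0",
                      metadata = list(variant = variant)))
  est <- f$pred1 / f$pred0
  if (variant == "linear") {
    analytic <- function() {
      se_pred0 <- sqrt(sum((f$aj * f$se)^2))
      if (f$pred1 <= 0 || f$pred0 <= 2 * se_pred0) return(NULL)  # bootstrap
      gj <- (f$aj + f$cj) / f$pred1 - f$aj / f$pred0
      sel <- sqrt(sum((gj * f$se)^2))
      z <- stats::qnorm(1 - (1 - ci$level) / 2)
      list(se = est * sel,
           lower = exp(log(est) - z * sel), upper = exp(log(est) + z * sel),
           reason = NULL)
    }
    civ <- resolve_ci(x, ci, est, rii_point_linear, analytic)
  } else {
    civ <- resolve_ci(x, ci, est, rii_point_logit)
  }
  new_result(x, "RII", est, se = civ$se, ci_lower = civ$lower,
             ci_upper = civ$upper, level = civ$level, ci_reason = civ$reason,
             metadata = list(variant = variant))
}
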