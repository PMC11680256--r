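#' Confidence-interval configuration
#'
#' Controls how standard errors and confidence intervals are attached to
#' measure results. Difference, ratio, and the linear-variant slope and
#' relative indices of inequality have stable closed-form (Wald or
#' delta-method) intervals; all other measures use a parametric bootstrap
#' that resamples each subgroup estimate from Normal(y_j, se_j) truncated to
#' \[0, 100\] and recomputes the measure. `method = "auto"` (the default)
#' picks the analytic form where one exists and the bootstrap otherwise.
#'
#' @param level Coverage probability, strictly between 0 and 1 (default 0.95).
#' @param method `"auto"`, `"analytic"`, or `"bootstrap"`.
#' @param reps Number of bootstrap replicates (at least 100; default 1000).
#' @param seed Integer seed making bootstrap intervals reproducible; the
#'   global RNG state is restored afterwards.
#' @return A `ci_config` list.
#' @export
ci_config <- function(level = 0.95, method = c("auto", "analytic", "bootstrap"),
                      reps = 1000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  reps <- as.integer(reps)
  stopifnot(reps >= 100L)
  structure(list(level = level, method = method, reps = reps,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ci_config")
}

has_all_se <- function(x) !anyNA(x$data$se)

# Evaluate `fun` with the RNG seeded locally, restoring global state.
with_local_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# Parametric bootstrap CI for an arbitrary point-estimate kernel.
# `point_fun(series)` must return a single numeric (NA when undefined).
# Returns list(se, lower, upper, reason). Percentile interval, clamped so it
# always contains the point estimate (documented behaviour: percentile
# intervals of biased statistics such as BGV can otherwise exclude it).
boot_ci <- function(x, point_fun, estimate, config) {
  if (!has_all_se(x))
    return(list(se = NA_real_, lower = NA_real_, upper = NA_real_,
                reason = "missing standard errors"))
  d <- x$data
  J <- nrow(d)
  reps <- config$reps
  vals <- with_local_seed(config$seed, function() {
    ymat <- matrix(stats::rnorm(reps * J, mean = rep(d$estimate, each = reps),
                                sd = rep(d$se, each = reps)), reps, J)
    ymat[ymat < 0] <- 0
    ymat[ymat > 100] <- 100
    xb <- x
    vapply(seq_len(reps), function(i) {
      xb$data$estimate <- ymat[i, ]
      point_fun(xb)
    }, numeric(1))
  })
  if (mean(is.na(vals)) > 0.5)
    return(list(se = NA_real_, lower = NA_real_, upper = NA_real_,
                reason = "measure undefined in >50% of bootstrap replicates"))
  a <- (1 - config$level) / 2
  qq <- stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(se = stats::sd(vals, na.rm = TRUE),
       lower = min(qq[1], estimate), upper = max(qq[2], estimate),
       reason = NULL)
}

# Wald interval from a point estimate and its SE.
wald_ci <- function(estimate, se, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(se = se, lower = estimate - z * se, upper = estimate + z * se,
       reason = NULL)
}

no_se_ci <- function() list(se = NA_real_, lower = NA_real_,
                            upper = NA_real_,
                            reason = "missing standard errors")

# Attach a CI computed by `boot_ci` or an analytic closure, honouring the
# config method. `analytic_fun()` returns list(se, lower, upper, reason) or
# NULL when no analytic form exists for the measure.
resolve_ci <- function(x, config, estimate, point_fun, analytic_fun = NULL) {
  if (is.null(config)) return(list(se = NA_real_, lower = NA_real_,
                                   upper = NA_real_, reason = NULL,
                                   level = NA_real_))
  method <- config$method
  if (method == "analytic" && is.null(analytic_fun))
    stop("no analytic CI is available for this measure; use method 'bootstrap' or 'auto'",
         call. = FALSE)
  out <- if (method %in% c("auto", "analytic") && !is.null(analytic_fun)) {
    if (has_all_se(x)) analytic_fun() else no_se_ci()
  } else {
    boot_ci(x, point_fun, estimate, config)
  }
  # analytic route may itself defer to the bootstrap (e.g. RII near-zero
  # intercept) by returning NULL
  if (is.null(out)) out <- boot_ci(x, point_fun, estimate, config)
  out$level <- config$level
  out
}
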