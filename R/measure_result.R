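MEASURE_CODES <- c("D", "R", "ACI", "RCI", "SII", "RII", "MDMU", "MDMW",
                   "IDISU", "IDISW", "BGV", "BGSD", "COV", "TI", "PAR", "PAF")

# Internal constructor. A result is always created in the context of the
# series it was computed from, so setting/indicator/dimension travel with it.
new_result <- function(x, measure, estimate = NA_real_, se = NA_real_,
                       ci_lower = NA_real_, ci_upper = NA_real_,
                       level = NA_real_, compared = NULL, defined = TRUE,
                       undefined_reason = NULL, ci_reason = NULL,
                       metadata = list()) {
  stopifnot(measure %in% MEASURE_CODES)
  if (!defined) {
    estimate <- NA_real_
    se <- ci_lower <- ci_upper <- NA_real_
    if (is.null(undefined_reason))
      stop("undefined results need a reason", call. = FALSE)
  }
  structure(list(
    measure = measure,
    estimate = estimate, se = se,
    ci_lower = ci_lower, ci_upper = ci_upper, level = level,
    compared = compared,
    defined = defined, undefined_reason = undefined_reason,
    ci_reason = ci_reason,
    setting = x$setting, indicator = x$indicator,
    dimension = x$dimension, dimension_type = x$dimension_type,
    favourable = x$favourable,
    metadata = metadata
  ), class = "measure_result")
}

#' @export
print.measure_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("%s: undefined (%s)\n", x$measure, x$undefined_reason))
    return(invisible(x))
  }
  cat(sprintf("%s = %.4g", x$measure, x$estimate))
  if (!is.na(x$ci_lower))
    cat(sprintf("  [%g%% CI %.4g, %.4g]", 100 * x$level, x$ci_lower, x$ci_upper))
  else if (!is.null(x$ci_reason))
    cat(sprintf("  (CI undefined: %s)", x$ci_reason))
  if (!is.null(x$compared))
    cat(sprintf("  (%s vs %s)", x$compared[1], x$compared[2]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.measure_result <- function(x, ...) {
  data.frame(setting = x$setting, indicator = x$indicator,
             dimension = x$dimension, dimension_type = x$dimension_type,
             measure = x$measure,
             estimate = x$estimate, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             level = x$level,
             defined = x$defined,
             undefined_reason = x$undefined_reason %||% NA_character_,
             compared = if (is.null(x$compared)) NA_character_ else
               paste(x$compared, collapse = " vs "),
             flags = if (length(x$metadata)) paste(
               names(x$metadata), vapply(x$metadata, function(v)
                 paste(format(v), collapse = "|"), ""),
               sep = "=", collapse = ";") else NA_character_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bind measure results into a long results table
#'
#' @param results A list of `measure_result` objects (possibly nested lists,
#'   e.g. the output of [compute_all()] over several series).
#' @return A data frame with one row per result: setting, indicator,
#'   dimension, measure, estimate, se, CI bounds, definedness flags, and
#'   compacted metadata flags.
#' @export
results_table <- function(results) {
  if (inherits(results, "measure_result")) results <- list(results)
  flat <- list()
  rec <- function(r) {
    if (inherits(r, "measure_result")) flat[[length(flat) + 1L]] <<- r
    else lapply(r, rec)
    invisible(NULL)
  }
  rec(results)
  do.call(rbind, lapply(flat, as.data.frame))
}
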