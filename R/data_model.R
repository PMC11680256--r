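#' Construct a disaggregated series
#'
#' A disaggregated series holds one setting's estimates of a single health
#' indicator across the subgroups of one dimension of inequality (for
#' example, DTP3 coverage across wealth quintiles in one country). It is the
#' input unit consumed by every summary measure in the package.
#'
#' Estimates are held on the percent scale (0-100), the scale on which
#' immunization coverage and zero-dose prevalence are reported. Populations
#' may be counts or shares; they are normalized internally to shares that
#' sum to one, while the raw values are retained for cross-setting
#' population weighting of impact measures.
#'
#' @param estimate Numeric vector of subgroup indicator values, in percent
#'   (each in \[0, 100\]).
#' @param population Numeric vector of subgroup population counts or shares;
#'   non-negative with a positive total.
#' @param se Optional numeric vector of standard errors of `estimate`, on
#'   the percent scale. Measures compute without them, but confidence
#'   intervals are then flagged undefined.
#' @param subgroup Optional character vector of subgroup labels; defaults to
#'   `"subgroup_1"`, `"subgroup_2"`, ...
#' @param order Integer rank of each subgroup from least advantaged (1,
#'   e.g. poorest quintile or lowest-HDI region) to most advantaged
#'   (largest rank). Required for (and only meaningful for) ordered
#'   dimensions; ranks must be unique and contiguous.
#' @param dimension_type One of `"binary"`, `"ordered"`, `"nonordered"`.
#' @param dimension,indicator,setting Text identifiers.
#' @param favourable Logical; `TRUE` when higher indicator values are
#'   desirable (coverage), `FALSE` for adverse indicators (zero-dose
#'   prevalence). Governs the reference-subgroup rule for PAR/PAF.
#' @param setting_average Optional setting-level (national) average of the
#'   indicator, in percent. When supplied (e.g. from survey-weighted
#'   microdata) it overrides the population-weighted subgroup mean in all
#'   relative and deviation measures.
#' @param group_of_interest For binary dimensions, the label of the subgroup
#'   reported first in difference/ratio comparisons (e.g. `"urban"` for
#'   place of residence, so that D = urban - rural). When omitted, labels
#'   are matched against a small built-in orientation table; if no match is
#'   found the first subgroup is used and this choice is recorded.
#' @param year Optional integer survey year.
#' @param income_group Optional income-group label used for stratified
#'   summaries.
#'
#' @return An object of class `disagg_series`: a list with a `data` data
#'   frame (columns `subgroup`, `estimate`, `se`, `population`, `share`,
#'   `order`) and the series metadata.
#' @examples
#' s <- disagg_series(estimate = c(40, 60), population = c(1, 1),
#'                    order = c(1, 2), dimension_type = "ordered")
#' setting_mean(s)
#' @export
disagg_series <- function(estimate, population, se = NULL, subgroup = NULL,
                          order = NULL,
                          dimension_type = c("nonordered", "binary", "ordered"),
                          dimension = "dimension", indicator = "indicator",
                          setting = "setting", favourable = TRUE,
                          setting_average = NULL, group_of_interest = NULL,
                          year = NULL, income_group = NULL) {
  dimension_type <- match.arg(dimension_type)
  n <- length(estimate)
  if (is.null(subgroup)) subgroup <- paste0("subgroup_", seq_len(n))
  if (is.null(se)) se <- rep(NA_real_, n)
  if (is.null(order)) order <- rep(NA_integer_, n)
  x <- structure(list(
    data = data.frame(subgroup = as.character(subgroup),
                      estimate = as.numeric(estimate),
                      se = as.numeric(se),
                      population = as.numeric(population),
                      share = NA_real_,
                      order = as.integer(order),
                      stringsAsFactors = FALSE),
    dimension_type = dimension_type,
    dimension = dimension, indicator = indicator, setting = setting,
    favourable = isTRUE(favourable),
    setting_average = if (is.null(setting_average)) NA_real_ else as.numeric(setting_average),
    group_of_interest = group_of_interest,
    year = if (is.null(year)) NA_integer_ else as.integer(year),
    income_group = if (is.null(income_group)) NA_character_ else as.character(income_group)
  ), class = "disagg_series")
  validate_series(x)
}

series_context <- function(x) {
  sprintf("[setting=%s indicator=%s dimension=%s]",
          x$setting, x$indicator, x$dimension)
}

#' Validate a disaggregated series
#'
#' Checks all structural invariants (estimate range, subgroup counts per
#' dimension type, rank uniqueness/contiguity for ordered dimensions,
#' non-negative standard errors and populations) and normalizes populations
#' to shares summing to one. Raw populations are retained. Validation is
#' idempotent.
#'
#' @param x A `disagg_series` (or a list with the same structure).
#' @return The validated series, with `data$share` filled in.
#' @export
validate_series <- function(x) {
  stopifnot(inherits(x, "disagg_series"))
  d <- x$data
  ctx <- series_context(x)
  n <- nrow(d)
  if (n < 2L)
    stop("series must have at least 2 subgroups ", ctx, call. = FALSE)
  if (anyNA(d$estimate) || any(d$estimate < 0 | d$estimate > 100))
    stop("estimates must lie in [0, 100] ", ctx, call. = FALSE)
  if (any(!is.na(d$se) & d$se < 0))
    stop("standard errors must be non-negative ", ctx, call. = FALSE)
  if (anyNA(d$population) || any(d$population < 0))
    stop("populations must be non-negative ", ctx, call. = FALSE)
  tot <- sum(d$population)
  if (tot <= 0)
    stop("at least one subgroup must have positive population ", ctx, call. = FALSE)
  if (x$dimension_type == "binary" && n != 2L)
    stop("binary series must have exactly 2 subgroups ", ctx, call. = FALSE)
  if (x$dimension_type == "ordered") {
    if (anyNA(d$order))
      stop("ordered series require an order rank for every subgroup ", ctx,
           call. = FALSE)
    if (anyDuplicated(d$order))
      stop("duplicate order ranks ", ctx, call. = FALSE)
    if (!setequal(d$order, seq_len(n)))
      stop("order ranks must be contiguous 1..n ", ctx, call. = FALSE)
  }
  if (!is.na(x$setting_average) &&
      (x$setting_average < 0 || x$setting_average > 100))
    stop("setting_average must lie in [0, 100] ", ctx, call. = FALSE)
  d$share <- d$population / tot
  x$data <- d
  x
}

#' Midpoint (ridit) ranks for an ordered series
#'
#' Places the subgroups of an ordered dimension on \[0, 1\] using the
#' standard ridit construction: each subgroup's rank is the cumulative
#' population share of all less-advantaged subgroups plus half its own
#' share. The share-weighted mean of the midpoint ranks is exactly 0.5 for
#' any share vector. These ranks drive the concentration and regression
#' based measures (ACI, RCI, SII, RII).
#'
#' @param x An ordered `disagg_series`.
#' @return A data frame with one row per subgroup, sorted from least to
#'   most advantaged: `subgroup`, `order`, `share` (p_j) and
#'   `midpoint_rank` (X_j in (0, 1)).
#' @export
compute_ranks <- function(x) {
  stopifnot(inherits(x, "disagg_series"))
  if (x$dimension_type != "ordered")
    stop("midpoint ranks are defined for ordered dimensions only ",
         series_context(x), call. = FALSE)
  d <- x$data[order(x$data$order), ]
  p <- d$share
  xj <- cumsum(p) - p / 2
  data.frame(subgroup = d$subgroup, order = d$order, share = p,
             midpoint_rank = xj, stringsAsFactors = FALSE)
}

#' Setting-level average of a series
#'
#' Returns the setting (national) average mu used by all relative and
#' deviation-from-mean measures: the supplied `setting_average` when one is
#' present, otherwise the population-share-weighted mean of the subgroup
#' estimates.
#'
#' @param x A `disagg_series`.
#' @return The average, in percent.
#' @export
setting_mean <- function(x) {
  stopifnot(inherits(x, "disagg_series"))
  if (!is.na(x$setting_average)) return(x$setting_average)
  sum(x$data$share * x$data$estimate)
}

#' Convert between percent and proportion scales
#'
#' Estimates are always held in percent; these explicit converters are the
#' only supported way to move to and from the proportion scale (used
#' internally by the logit variant of the slope index).
#'
#' @param x Numeric vector.
#' @return `pct_to_prop`: x / 100. `prop_to_pct`: 100 x.
#' @export
pct_to_prop <- function(x) x / 100

#' @rdname pct_to_prop
#' @export
prop_to_pct <- function(x) 100 * x

#' @export
print.disagg_series <- function(x, ...) {
  cat(sprintf("<disagg_series> %s | %s | %s (%s, %s)\n",
              x$setting, x$indicator, x$dimension, x$dimension_type,
              if (x$favourable) "favourable" else "adverse"))
  if (!is.na(x$setting_average))
    cat(sprintf("  setting average: %.4g (supplied)\n", x$setting_average))
  print(x$data, row.names = FALSE)
  invisible(x)
}
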