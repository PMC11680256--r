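#' Compute the full measure set appropriate to a series
#'
#' Dispatches exactly the canonical measure battery for the series'
#' dimension type: binary dimensions get the two simple measures
#' \{D, R\}; ordered dimensions get \{D, R, ACI, RCI, SII, RII, PAR, PAF\};
#' non-ordered dimensions get \{D, R, MDMU, MDMW, IDISU, IDISW, BGV, BGSD,
#' COV, TI, PAR, PAF\}.
#'
#' @inheritParams measure_difference
#' @param sii_variant Fitting variant passed to [measure_sii()] and
#'   [measure_rii()] for ordered series.
#' @return A named list of `measure_result` objects, one per measure code.
#' @export
compute_all <- function(x, ci = ci_config(), sii_variant = "linear") {
  stopifnot(inherits(x, "disagg_series"))
  res <- list(D = measure_difference(x, ci), R = measure_ratio(x, ci))
  if (x$dimension_type == "ordered") {
    res <- c(res, list(
      ACI = measure_aci(x, ci), RCI = measure_rci(x, ci),
      SII = measure_sii(x, ci, variant = sii_variant),
      RII = measure_rii(x, ci, variant = sii_variant),
      PAR = measure_par(x, ci), PAF = measure_paf(x, ci)))
  } else if (x$dimension_type == "nonordered") {
    res <- c(res, list(
      MDMU = measure_mdmu(x, ci), MDMW = measure_mdmw(x, ci),
      IDISU = measure_idisu(x, ci), IDISW = measure_idisw(x, ci),
      BGV = measure_bgv(x, ci), BGSD = measure_bgsd(x, ci),
      COV = measure_cov(x, ci), TI = measure_theil(x, ci),
      PAR = measure_par(x, ci), PAF = measure_paf(x, ci)))
  }
  res
}

#' Compute a single measure by its code
#'
#' @inheritParams compute_all
#' @param code One of the sixteen measure codes (see [results_table()]):
#'   D, R, ACI, RCI, SII, RII, MDMU, MDMW, IDISU, IDISW, BGV, BGSD, COV,
#'   TI, PAR, PAF.
#' @return A `measure_result`.
#' @export
compute_measure <- function(x, code, ci = ci_config(), sii_variant = "linear") {
  code <- match.arg(toupper(code), MEASURE_CODES)
  switch(code,
    D = measure_difference(x, ci), R = measure_ratio(x, ci),
    ACI = measure_aci(x, ci), RCI = measure_rci(x, ci),
    SII = measure_sii(x, ci, variant = sii_variant),
    RII = measure_rii(x, ci, variant = sii_variant),
    MDMU = measure_mdmu(x, ci), MDMW = measure_mdmw(x, ci),
    IDISU = measure_idisu(x, ci), IDISW = measure_idisw(x, ci),
    BGV = measure_bgv(x, ci), BGSD = measure_bgsd(x, ci),
    COV = measure_cov(x, ci), TI = measure_theil(x, ci),
    PAR = measure_par(x, ci), PAF = measure_paf(x, ci))
}

#' Eligibility filter for cross-setting analysis
#'
#' Reproduces the completeness rules used before comparing settings: a
#' binary series must have both subgroups, an ordered (wealth-quintile
#' style) series must have all `expected_ordered` levels, and a non-ordered
#' (subnational region) series is excluded when more than 15% of the
#' setting's expected regions are missing — exactly 15% missing is kept.
#' Expected region counts cannot be inferred from the data (a region absent
#' from the table is invisible), so they must be supplied; when they are
#' not, the region rule is skipped with a warning.
#'
#' @param series A list of `disagg_series`.
#' @param expected_regions Named numeric vector mapping setting ids to the
#'   expected number of subnational regions, or `NULL` to skip that rule.
#' @param expected_ordered Required number of levels for ordered series
#'   (default 5, wealth quintiles).
#' @param max_missing Maximum tolerated missing fraction for non-ordered
#'   series (default 0.15, exclusion strictly above).
#' @return A list with `kept` (list of series) and `excluded` (data frame
#'   with setting, indicator, dimension, and reason).
#' @export
eligibility_filter <- function(series, expected_regions = NULL,
                               expected_ordered = 5L, max_missing = 0.15) {
  stopifnot(is.list(series))
  warned <- FALSE
  reasons <- vapply(series, function(s) {
    stopifnot(inherits(s, "disagg_series"))
    n <- nrow(s$data)
    if (s$dimension_type == "binary" && n != 2L)
      return("missing binary subgroup")
    if (s$dimension_type == "ordered" && n < expected_ordered)
      return(sprintf("missing ordered subgroup (%d of %d present)",
                     n, expected_ordered))
    if (s$dimension_type == "nonordered") {
      exp_n <- if (is.null(expected_regions)) NA_real_
               else unname(expected_regions[s$setting])
      if (is.na(exp_n)) {
        if (!warned && !is.null(expected_regions)) {
          warning("no expected region count for setting '", s$setting,
                  "'; region completeness rule skipped", call. = FALSE)
          warned <<- TRUE
        } else if (is.null(expected_regions) && !warned) {
          warning("expected region counts not supplied; ",
                  "region completeness rule skipped", call. = FALSE)
          warned <<- TRUE
        }
        return(NA_character_)
      }
      missing_frac <- (exp_n - n) / exp_n
      if (missing_frac > max_missing)
        return(sprintf("more than %d%% of regions missing (%d of %d present)",
                       round(100 * max_missing), n, as.integer(exp_n)))
    }
    NA_character_
  }, character(1))
  keep <- is.na(reasons)
  excluded <- data.frame(
    setting = vapply(series[!keep], `[[`, "", "setting"),
    indicator = vapply(series[!keep], `[[`, "", "indicator"),
    dimension = vapply(series[!keep], `[[`, "", "dimension"),
    reason = reasons[!keep], stringsAsFactors = FALSE)
  list(kept = series[keep], excluded = excluded)
}

strength_class <- function(rho) {
  cut(abs(rho), breaks = c(-Inf, 0.4, 0.7, 0.9, Inf), right = FALSE,
      labels = c("weak", "moderate", "strong", "very strong"))
}

# Exact permutation p-value for Spearman's rho (two-sided), used for n < 10.
# Works on (possibly tied) ranks; the permutation distribution of
# cor(rank_x, perm(rank_y)) is enumerated completely.
perm_spearman_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perm_apply <- function(remaining, chosen) {
    if (!length(remaining)) {
      r <- suppressWarnings(stats::cor(rx, chosen))
      return(if (is.na(r)) 0L else as.integer(abs(r) >= abs(rho_obs) - 1e-12))
    }
    sum(vapply(seq_along(remaining), function(i)
      perm_apply(remaining[-i], c(chosen, remaining[i])), integer(1)))
  }
  hits <- perm_apply(ry, numeric(0))
  hits / factorial(n)
}

# Spearman rho with two-sided p-value: t-approximation with tie correction
# (rho is computed on midranks) for n >= 10, exact permutation below.
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  p <- if (n < 10L) {
    perm_spearman_p(rx, ry, rho)
  } else if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Cross-setting correlation of summary measures
#'
#' Builds the pairwise Spearman rank-correlation matrix of measure estimates
#' across settings, with two-sided p-values and the conventional strength
#' classes: |rho| >= 0.9 very strong, >= 0.7 strong, >= 0.4 moderate,
#' < 0.4 weak. Spearman's rho is used because relationships between
#' measures (e.g. BGV against MDMW) are monotone but not linear; BGV and
#' BGSD, a strictly monotone transform pair, always correlate at exactly 1.
#'
#' @param tbl A results table (see [results_table()]) for one indicator and
#'   dimension: columns `setting`, `measure`, `estimate`.
#' @param measures Measure codes to include; default all present.
#' @param use_absolute Correlate absolute values instead of signed
#'   estimates (default `FALSE`, signed).
#' @return An object of class `ineq_correlation`: list of matrices `rho`,
#'   `p`, `n`, and `class` (symmetric, unit diagonal).
#' @export
correlate_measures <- function(tbl, measures = NULL, use_absolute = FALSE) {
  stopifnot(all(c("setting", "measure", "estimate") %in% names(tbl)))
  if (is.null(measures)) measures <- intersect(MEASURE_CODES,
                                               unique(tbl$measure))
  wide <- stats::reshape(
    tbl[tbl$measure %in% measures, c("setting", "measure", "estimate")],
    idvar = "setting", timevar = "measure", direction = "wide")
  cols <- paste0("estimate.", measures)
  missing_cols <- setdiff(cols, names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA_real_
  m <- as.matrix(wide[, cols, drop = FALSE])
  colnames(m) <- measures
  if (use_absolute) m <- abs(m)
  k <- length(measures)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) next
    st <- if (i == j) list(rho = 1, p = 0, n = sum(!is.na(m[, i])))
          else spearman_test(m[, i], m[, j])
    rho[i, j] <- rho[j, i] <- st$rho
    p[i, j] <- p[j, i] <- st$p
    nmat[i, j] <- nmat[j, i] <- st$n
  }
  cls <- matrix(as.character(strength_class(rho)), k, k,
                dimnames = dimnames(rho))
  structure(list(rho = rho, p = p, n = nmat, class = cls,
                 use_absolute = use_absolute),
            class = "ineq_correlation")
}

#' @export
print.ineq_correlation <- function(x, digits = 4, ...) {
  cat("Spearman correlation of summary measures across settings",
      if (x$use_absolute) "(absolute values)" else "(signed)", "\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' @export
as.data.frame.ineq_correlation <- function(x, ...) {
  meas <- rownames(x$rho)
  idx <- which(upper.tri(x$rho, diag = TRUE), arr.ind = TRUE)
  data.frame(measure_a = meas[idx[, 1]], measure_b = meas[idx[, 2]],
             rho = x$rho[idx], p_value = x$p[idx], n = x$n[idx],
             class = x$class[idx], stringsAsFactors = FALSE)
}

#' Medians and interquartile ranges across settings
#'
#' Summarizes measure estimates across settings — the cross-country view of
#' the overall level of inequality — by the median and the 25th/75th
#' percentiles (type-7 linear interpolation), overall and optionally
#' stratified (typically by income group).
#'
#' @param tbl A results table with columns `measure`, `estimate`, and any
#'   grouping columns.
#' @param by Character vector of additional grouping columns present in
#'   `tbl` (e.g. `c("indicator", "dimension", "income_group")`); default
#'   groups by indicator and dimension when present.
#' @return A data frame with one row per group: n, median, q25, q75.
#' @export
summarize_measures <- function(tbl, by = intersect(c("indicator", "dimension",
                                                     "income_group"),
                                                   names(tbl))) {
  stopifnot(all(c("measure", "estimate") %in% names(tbl)))
  keys <- c(by, "measure")
  groups <- split(tbl, tbl[keys], drop = TRUE)
  out <- lapply(groups, function(g) {
    v <- g$estimate[!is.na(g$estimate)]
    q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7,
                                        names = FALSE) else rep(NA_real_, 3)
    cbind(g[1, keys, drop = FALSE],
          data.frame(n = length(v), median = q[2], q25 = q[1], q75 = q[3]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
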