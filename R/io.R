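# Canonical long-format dialect: one row per setting x indicator x
# dimension x subgroup.
REQUIRED_COLUMNS <- c("setting", "indicator", "dimension", "dimension_type",
                      "subgroup", "estimate", "population")
OPTIONAL_COLUMNS <- c("year", "se", "subgroup_order", "favourable",
                      "setting_average", "income_group", "group_of_interest")

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stop("empty file: ", path,
                                               call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

as_logical_flag <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  tolower(trimws(as.character(v))) %in% c("true", "t", "1", "yes")
}

#' Read a long-format disaggregated data table
#'
#' Parses delimiter-separated text (comma default, tab auto-detected) with
#' one row per subgroup and groups the rows into validated series. The
#' canonical columns are `setting, year, indicator, dimension,
#' dimension_type, subgroup, estimate, se, population, subgroup_order,
#' favourable, setting_average, income_group`; only setting, indicator,
#' dimension, dimension_type, subgroup, estimate, and population are
#' required. `dimension_type` must be one of binary / ordered / nonordered.
#' A `subgroup_order` column on a non-ordered dimension is ignored with a
#' warning. Structural problems are reported with their series context.
#'
#' @param path Path to the text file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param mapping Optional named character vector renaming file columns to
#'   canonical ones, e.g. `c(setting = "country", estimate = "coverage")`
#'   (names are canonical, values are the file's column names).
#' @param config Optional path to a JSON file with a `mapping` object used
#'   the same way.
#' @return A list of validated `disagg_series`.
#' @export
read_disaggregated <- function(path, sep = NULL, mapping = NULL,
                               config = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!is.null(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(cfg$mapping)) mapping <- unlist(cfg$mapping)
  }
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!nrow(df)) stop("no data rows in ", path, call. = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop("mapped column '", src, "' not found in ", path, call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  missing_req <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  for (col in OPTIONAL_COLUMNS) if (!col %in% names(df)) df[[col]] <- NA
  bad_type <- !df$dimension_type %in% c("binary", "ordered", "nonordered")
  if (any(bad_type))
    stop("unknown dimension_type '", df$dimension_type[which(bad_type)[1]],
         "' at row ", which(bad_type)[1], call. = FALSE)
  for (col in c("estimate", "se", "population", "setting_average")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & df[[col]] != "" & is.na(v)
    if (any(bad))
      stop("non-numeric ", col, " '", df[[col]][which(bad)[1]], "' at row ",
           which(bad)[1], call. = FALSE)
    df[[col]] <- v
  }
  key <- paste(df$setting, ifelse(is.na(df$year), "", df$year),
               df$indicator, df$dimension, sep = "\r")
  lapply(split(df, key), function(g) {
    dtype <- unique(g$dimension_type)
    if (length(dtype) > 1L)
      stop("inconsistent dimension_type within series [setting=",
           g$setting[1], " dimension=", g$dimension[1], "]", call. = FALSE)
    has_order <- !all(is.na(g$subgroup_order))
    if (dtype == "nonordered" && has_order) {
      warning("subgroup_order ignored for non-ordered dimension [setting=",
              g$setting[1], " dimension=", g$dimension[1], "]",
              call. = FALSE)
      has_order <- FALSE
    }
    fav <- if (all(is.na(g$favourable))) TRUE else
      as_logical_flag(g$favourable[1])
    sa <- g$setting_average[!is.na(g$setting_average)]
    goi <- g$group_of_interest[!is.na(g$group_of_interest) &
                                 nzchar(as.character(g$group_of_interest))]
    disagg_series(
      estimate = g$estimate, population = g$population,
      se = if (all(is.na(g$se))) NULL else g$se,
      subgroup = g$subgroup,
      order = if (has_order) as.integer(g$subgroup_order) else NULL,
      dimension_type = dtype, dimension = g$dimension[1],
      indicator = g$indicator[1], setting = g$setting[1],
      favourable = fav,
      setting_average = if (length(sa)) sa[1] else NULL,
      group_of_interest = if (length(goi)) as.character(goi[1]) else NULL,
      year = if (all(is.na(g$year))) NULL else g$year[1],
      income_group = if (all(is.na(g$income_group))) NULL else
        as.character(g$income_group[1]))
  })
}

#' Write disaggregated series to the long-format dialect
#'
#' Emits the same table [read_disaggregated()] consumes; a write-then-read
#' round trip reproduces every value (decimal text up to the precision of
#' the default 15-significant-digit rendering).
#'
#' @param series A `disagg_series` or list of them.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_disaggregated <- function(series, path, sep = ",") {
  if (inherits(series, "disagg_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    d <- s$data
    data.frame(setting = s$setting, year = s$year,
               indicator = s$indicator, dimension = s$dimension,
               dimension_type = s$dimension_type,
               subgroup = d$subgroup, estimate = d$estimate, se = d$se,
               population = d$population, subgroup_order = d$order,
               favourable = s$favourable,
               setting_average = s$setting_average,
               income_group = s$income_group,
               group_of_interest = s$group_of_interest %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(setting = character(), year = integer(),
                      indicator = character(), dimension = character(),
                      dimension_type = character(), subgroup = character(),
                      estimate = numeric(), se = numeric(),
                      population = numeric(), subgroup_order = integer(),
                      favourable = logical(), setting_average = numeric(),
                      income_group = character(),
                      group_of_interest = character())
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' Write a results or summary table
#'
#' @param tbl A data frame (e.g. from [results_table()],
#'   [summarize_measures()], or `as.data.frame` of a correlation object).
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_results <- function(tbl, path, sep = ",") {
  utils::write.table(tbl, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}
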