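sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c(",", "\t", ";"), function(d)
    lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))), integer(1))
  if (all(counts == 0)) {
    stop("Could not sniff the delimiter of '", path,
         "' (tried comma, tab, semicolon).", call. = FALSE)
  }
  names(counts)[which.max(counts)]
}

#' Read long-format subject-level center data
#'
#' One row per subject (or visit): a center label column and an outcome
#' column. Missing outcome values are retained and flagged, not dropped, so
#' that missingness itself can be analyzed (see
#' [derive_missingness_indicator()]).
#'
#' @param path Delimited text file.
#' @param center_col,value_col Column names in the file.
#' @param delim Field delimiter; `NULL` sniffs among comma, tab, semicolon.
#' @return A tibble with columns `center`, `value`, `missing`, plus any
#'   remaining columns of the file; provenance (file, rows, missing count)
#'   is stored in attributes.
#' @export
read_long_table <- function(path, center_col = "center",
                            value_col = "value", delim = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("Empty file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (!nrow(d)) stop("No data rows in: ", path, call. = FALSE)
  for (col in c(center_col, value_col)) {
    if (!col %in% names(d)) {
      stop("Column '", col, "' not found in '", path, "'. Available: ",
           paste(names(d), collapse = ", "), call. = FALSE)
    }
  }
  out <- d
  names(out)[match(c(center_col, value_col), names(d))] <- c("center",
                                                             "value")
  out$center <- as.character(out$center)
  out$value <- suppressWarnings(as.numeric(out$value))
  out$missing <- is.na(out$value)
  out <- tibble::as_tibble(out)
  attr(out, "provenance") <- list(file = path, rows = nrow(out),
                                  n_missing = sum(out$missing))
  out
}

#' Read aggregated binomial center data
#'
#' One row per center with event and total counts.
#'
#' @param path Delimited text file.
#' @param center_col,events_col,total_col Column names in the file.
#' @param delim Field delimiter; `NULL` sniffs among comma, tab, semicolon.
#' @return A validated tibble (`center`, `events`, `total`).
#' @export
read_binomial_table <- function(path, center_col = "center",
                                events_col = "events", total_col = "total",
                                delim = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("Empty file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  for (col in c(center_col, events_col, total_col)) {
    if (!col %in% names(d)) {
      stop("Column '", col, "' not found in '", path, "'.", call. = FALSE)
    }
  }
  as_binomial_data(d, center = .data[[center_col]],
                   events = .data[[events_col]],
                   total = .data[[total_col]])
}

#' Per-center missingness as a binomial outcome
#'
#' Derives, from long-format data, a per-center binomial dataset in which
#' the events are the missing outcome values and the totals are the number
#' of subjects - a data-quality indicator suitable for the binomial
#' backends (typically `bayesglm` or `brglm`, since centers with complete
#' data have zero events).
#'
#' @param data Long-format data (e.g. from [read_long_table()]).
#' @param center,value Columns (tidy-eval).
#' @return A tibble (`center`, `events`, `total`).
#' @export
derive_missingness_indicator <- function(data, center = center,
                                         value = value) {
  d <- dplyr::transmute(as.data.frame(data),
                        center = as.character({{ center }}),
                        missing = is.na({{ value }}))
  if (!nrow(d)) stop("No rows in `data`.", call. = FALSE)
  out <- dplyr::summarise(dplyr::group_by(d, .data$center),
                          events = sum(.data$missing),
                          total = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$center)
}

#' Reduce visit-level records to one per patient
#'
#' Registry variables recorded at every visit are reduced to a single
#' record per patient before center comparisons: the value at the latest
#' visit (default), the first visit, or - for event indicators - whether
#' the event occurred at any visit.
#'
#' @param data Visit-level data frame.
#' @param center,patient,value Columns (tidy-eval).
#' @param visit Ordering column (tidy-eval); row order is used if absent.
#' @param rule `"latest"`, `"first"` or `"any"`.
#' @return One row per patient: `center`, `patient`, `value`.
#' @export
reduce_visits <- function(data, center = center, patient = patient,
                          value = value, visit = NULL,
                          rule = c("latest", "first", "any")) {
  rule <- match.arg(rule)
  d <- dplyr::transmute(as.data.frame(data),
                        center = as.character({{ center }}),
                        patient = as.character({{ patient }}),
                        value = {{ value }},
                        .visit = if (rlang::quo_is_null(rlang::enquo(visit)))
                          dplyr::row_number() else {{ visit }})
  g <- dplyr::group_by(d, .data$center, .data$patient)
  out <- switch(rule,
    latest = dplyr::slice_max(g, .data$.visit, n = 1, with_ties = FALSE),
    first = dplyr::slice_min(g, .data$.visit, n = 1, with_ties = FALSE),
    any = dplyr::summarise(g, value = as.numeric(any(.data$value > 0,
                                                     na.rm = TRUE)),
                           .groups = "drop"))
  out <- dplyr::ungroup(out)
  out$.visit <- NULL
  dplyr::arrange(tibble::as_tibble(out), .data$center, .data$patient)
}

#' Serialize / restore a deviation report
#'
#' `write_gm_report()` writes the per-center table as delimited text and,
#' optionally, a JSON document that also embeds the analysis settings
#' (method, scale, alpha, critical value, df, margins) for auditability.
#' `read_gm_report()` restores the JSON document to a `gm_report` with all
#' numeric fields at full precision.
#'
#' @param report A `gm_report`.
#' @param csv Path for the delimited table (`NULL` to skip).
#' @param json Path for the JSON document (`NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_gm_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "gm_report"))
  if (!is.null(csv)) {
    readr::write_csv(tibble::as_tibble(report), csv)
  }
  if (!is.null(json)) {
    m <- attr(report, "margins")
    doc <- list(
      settings = list(method = attr(report, "method"),
                      scale = attr(report, "scale"),
                      alpha = attr(report, "alpha"),
                      critical_value = attr(report, "critical_value"),
                      # Inf is not representable in JSON; restored on read
                      df = if (is.finite(attr(report, "df")))
                        attr(report, "df") else "Inf",
                      grand_mean = attr(report, "grand_mean"),
                      margins = if (is.null(m)) NULL else
                        list(lower = m$lower, upper = m$upper),
                      integration_seed =
                        attr(report, "settings")$integration_seed),
      centers = tibble::as_tibble(report))
    jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(report)
}

#' @rdname write_gm_report
#' @param path JSON file written by `write_gm_report()`.
#' @export
read_gm_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(doc$centers)
  out$flag <- factor(out$flag, levels = c("significant_deviation",
                                          "equivalent", "inconclusive",
                                          "not_assessed"))
  if (!"within_margins" %in% names(out)) out$within_margins <- NA
  out$within_margins <- as.logical(out$within_margins)
  s <- doc$settings
  margins <- if (!is.null(s$margins))
    gm_margins(lower = s$margins$lower, upper = s$margins$upper)
  structure(out,
            class = c("gm_report", class(out)),
            method = s$method, scale = s$scale, alpha = s$alpha,
            critical_value = as.numeric(s$critical_value),
            df = if (is.null(s$df)) Inf else as.numeric(s$df),
            grand_mean = s$grand_mean, margins = margins,
            settings = gm_settings(alpha = s$alpha,
                                   integration_seed = s$integration_seed))
}
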