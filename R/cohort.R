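#' Construct a validated cohort table
#'
#' Wraps a patient-per-row data frame with its schema and a label. Values are
#' checked against the variable dictionary: numeric kinds must be numeric
#' (times non-negative), categorical kinds must use declared labels, missing
#' values (`NA`) are allowed only where the dictionary permits, and per row
#' EFS time must not exceed OS time when both are observed.
#'
#' @param data Data frame with one column per schema variable.
#' @param schema A [cohort_schema()].
#' @param label Free-text provenance label (`"original"`, `"synthetic"`,
#'   `"fixture"`, ...).
#' @return An object of class `cohort_table` with elements `data`, `schema`,
#'   `label` and `n`.
#' @export
cohort_table <- function(data, schema, label = "cohort") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(schema_names(schema), names(data))
  if (length(missing_cols))
    stop("cohort is missing schema columns: ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(data), schema_names(schema))
  if (length(extra))
    stop("unknown columns not in schema: ", paste(extra, collapse = ", "))
  data <- data[schema_names(schema)]
  for (s in schema$specs) {
    v <- data[[s$name]]
    if (s$kind %in% c("continuous", "time")) {
      if (!is.numeric(v)) {
        suppressWarnings(vn <- as.numeric(v))
        if (sum(is.na(vn)) > sum(is.na(v) | v == ""))
          stop("non-numeric values in numeric variable '", s$name, "'")
        v <- vn
      }
      if (s$kind == "time" && any(v < 0, na.rm = TRUE))
        stop("negative times in '", s$name, "' (rows ",
             paste(utils::head(which(v < 0), 5), collapse = ","), ")")
    } else {
      v <- as.character(v)
      v[!is.na(v) & v == ""] <- NA_character_
      v[!is.na(v) & v == "na"] <- NA_character_
      bad <- !is.na(v) & !v %in% setdiff(s$categories, "na")
      if (any(bad))
        stop("undeclared categories in '", s$name, "': ",
             paste(unique(v[bad]), collapse = ", "))
    }
    if (!s$missing_allowed && anyNA(v))
      stop("missing values not allowed in '", s$name, "'")
    data[[s$name]] <- v
  }
  ep <- schema$endpoints
  if (!is.null(ep$efs) && !is.null(ep$os)) {
    efs_t <- data[[ep$efs[1]]]; os_t <- data[[ep$os[1]]]
    bad <- which(!is.na(efs_t) & !is.na(os_t) & efs_t > os_t + 1e-9)
    if (length(bad))
      stop("EFS exceeds OS in rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  structure(list(data = data, schema = schema, label = label,
                 n = nrow(data)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table '", x$label, "': ", x$n, " patients, ",
      length(x$schema$specs), " variables\n", sep = "")
  invisible(x)
}

#' Load a cohort CSV with its schema sidecar
#'
#' Reads a UTF-8 CSV (header row, empty cell = missing) and validates it
#' against the JSON schema sidecar. Missing cells are mapped to the reserved
#' missing state.
#'
#' @param path Cohort CSV path.
#' @param schema_path JSON schema sidecar path (see [write_schema()]).
#' @param label Provenance label for the loaded table.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, schema_path, label = basename(path)) {
  schema <- read_schema(schema_path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "na", "NA"))
  for (s in schema$specs) {
    if (!s$name %in% names(raw)) next
    if (s$kind %in% c("continuous", "time"))
      raw[[s$name]] <- as.numeric(raw[[s$name]])
  }
  cohort_table(raw, schema, label = label)
}

#' Write a cohort CSV (and optionally its schema sidecar)
#'
#' Times are written with one decimal; missing values become empty cells.
#'
#' @param cohort A [cohort_table()].
#' @param path Output CSV path.
#' @param schema_path Optional sidecar path; written when non-`NULL`.
#' @export
write_cohort <- function(cohort, path, schema_path = NULL) {
  out <- cohort$data
  for (s in cohort$schema$specs) {
    if (s$kind == "time")
      out[[s$name]] <- ifelse(is.na(out[[s$name]]), NA,
                              sprintf("%.1f", out[[s$name]]))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(schema_path)) write_schema(cohort$schema, schema_path)
  invisible(path)
}

#' Bin numeric variables onto reference deciles
#'
#' Replaces every continuous and time variable by a 10-level categorical
#' variable whose bin edges are the empirical deciles of a reference
#' cohort's non-missing values, so that two cohorts binned against the same
#' reference share one label space (as required for Hamming-distance
#' comparisons). Values outside the reference range clamp to the first/last
#' bin; missing maps to the `"na"` label.
#'
#' @param cohort A [cohort_table()] to bin.
#' @param n_bins Number of bins (default 10).
#' @param edges_from Reference cohort supplying the edge distribution
#'   (defaults to `cohort` itself).
#' @return A `binned_cohort`: all columns categorical label vectors, with a
#'   `bin_edges` element recording the `n_bins + 1` edges per variable.
#' @export
bin_numeric <- function(cohort, n_bins = 10, edges_from = cohort) {
  stopifnot(n_bins >= 2)
  data <- cohort$data
  edges_list <- list()
  for (s in cohort$schema$specs) {
    if (!s$kind %in% c("continuous", "time")) {
      v <- data[[s$name]]
      v[is.na(v)] <- "na"
      data[[s$name]] <- v
      next
    }
    ref <- edges_from$data[[s$name]]
    ref <- ref[!is.na(ref)]
    if (length(ref) == 0 || diff(range(ref)) == 0) {
      warning("variable '", s$name, "' has zero spread; single bin")
      lab <- ifelse(is.na(data[[s$name]]), "na", "b01")
      data[[s$name]] <- lab
      edges_list[[s$name]] <- rep(if (length(ref)) ref[1] else NA_real_, 2)
      next
    }
    probs <- seq(0, 1, length.out = n_bins + 1)
    edges <- unname(stats::quantile(ref, probs = probs, type = 7))
    edges <- cummax(edges)                    # guard non-monotone ties
    x <- data[[s$name]]
    # clamp outside reference range, then cut on interior edges
    xc <- pmin(pmax(x, edges[1]), edges[n_bins + 1])
    idx <- findInterval(xc, edges[2:n_bins]) + 1L   # 1..n_bins
    lab <- ifelse(is.na(x), "na", sprintf("b%02d", idx))
    data[[s$name]] <- lab
    edges_list[[s$name]] <- edges
  }
  structure(list(data = data, schema = cohort$schema, label = cohort$label,
                 n = nrow(data), n_bins = n_bins, bin_edges = edges_list),
            class = "binned_cohort")
}

#' Per-variable cohort summary
#'
#' Continuous and time variables are summarized by median and interquartile
#' range (linear-interpolation quartiles); binary and categorical variables
#' by per-category counts and percentages of the full cohort size, with the
#' missing count reported separately.
#'
#' @param cohort A [cohort_table()].
#' @return Data frame with one row per variable (or per category level),
#'   columns `variable`, `level`, `median`, `q1`, `q3`, `count`, `percent`,
#'   `n_missing`. The quartile convention is recorded in the
#'   `quantile_type` attribute.
#' @export
summarize_cohort <- function(cohort) {
  n <- cohort$n
  rows <- list()
  for (s in cohort$schema$specs) {
    v <- cohort$data[[s$name]]
    n_miss <- sum(is.na(v))
    if (s$kind %in% c("continuous", "time")) {
      obs <- v[!is.na(v)]
      if (length(obs) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = s$name, level = NA_character_, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, count = NA_integer_,
          percent = NA_real_, n_missing = n_miss)
      } else {
        q <- unname(stats::quantile(obs, c(0.25, 0.5, 0.75), type = 7))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = s$name, level = NA_character_, median = q[2],
          q1 = q[1], q3 = q[3], count = NA_integer_, percent = NA_real_,
          n_missing = n_miss)
      }
    } else {
      for (lv in setdiff(s$categories, "na")) {
        cnt <- sum(!is.na(v) & v == lv)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = s$name, level = lv, median = NA_real_, q1 = NA_real_,
          q3 = NA_real_, count = cnt, percent = 100 * cnt / n,
          n_missing = n_miss)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "quantile_type") <- "linear interpolation (R type 7)"
  out
}
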