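#' Declare a cohort variable
#'
#' A `variable_spec` is one entry of the cohort variable dictionary. It fixes
#' the variable's kind, measurement units, category labels (for binary and
#' categorical kinds, where the reserved label `"na"` encodes the explicit
#' missing state), whether missing values are allowed, and — for time
#' variables — the name of the paired event indicator.
#'
#' @param name Variable name (unique within a schema).
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`,
#'   `"event_indicator"`, `"time"`.
#' @param units Free-text units (e.g. `"years"`, `"GPt/l"`, `"months"`).
#' @param categories Ordered character vector of category labels for
#'   binary/categorical kinds. `"na"` may appear at most once and only when
#'   `missing_allowed` is `TRUE`; it is appended automatically when missing
#'   values are allowed.
#' @param missing_allowed Logical; may this variable carry missing values?
#' @param pair For `kind = "time"`, the name of the event-indicator partner.
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind, units = "", categories = NULL,
                          missing_allowed = TRUE, pair = NULL) {
  kind <- match.arg(kind, c("continuous", "binary", "categorical",
                            "event_indicator", "time"))
  if (kind %in% c("binary", "event_indicator") && is.null(categories))
    categories <- c("0", "1")
  if (kind == "categorical" && is.null(categories))
    stop("categorical variable '", name, "' needs explicit categories")
  if (!is.null(categories)) {
    categories <- as.character(categories)
    if (missing_allowed && !"na" %in% categories)
      categories <- c(categories, "na")
    if (sum(categories == "na") > 1L)
      stop("'na' may appear at most once in categories of '", name, "'")
    if (!missing_allowed && "na" %in% categories)
      stop("'na' category requires missing_allowed for '", name, "'")
    if (anyDuplicated(categories))
      stop("duplicate categories in '", name, "'")
  }
  if (kind == "time" && is.null(pair))
    stop("time variable '", name, "' must name its event_indicator pair")
  structure(list(name = name, kind = kind, units = units,
                 categories = categories,
                 missing_allowed = isTRUE(missing_allowed),
                 pair = pair),
            class = "variable_spec")
}

#' Assemble a cohort schema
#'
#' A schema is the ordered variable dictionary driving validation, binning,
#' the generator and all evaluation modules, together with the endpoint
#' declarations: the complete-remission (CR) indicator and the two paired
#' time-to-event endpoints, event-free survival (EFS) and overall survival
#' (OS).
#'
#' @param specs List of [variable_spec()] objects.
#' @param cr Name of the binary CR endpoint (or `NULL` if absent).
#' @param efs,os Length-2 character vectors `c(time, event)` naming the time
#'   variable and its event indicator (or `NULL`).
#'
#' @return An object of class `cohort_schema`.
#' @export
cohort_schema <- function(specs, cr = NULL, efs = NULL, os = NULL) {
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate variable names in schema")
  names(specs) <- nms
  for (s in specs) {
    if (s$kind == "time") {
      if (!s$pair %in% nms)
        stop("time variable '", s$name, "' pairs with unknown '", s$pair, "'")
      if (specs[[s$pair]]$kind != "event_indicator")
        stop("pair of '", s$name, "' is not an event_indicator")
    }
  }
  for (ep in list(cr, efs, os)) {
    if (!is.null(ep) && !all(ep %in% nms))
      stop("declared endpoint not present in schema: ",
           paste(setdiff(ep, nms), collapse = ", "))
  }
  structure(list(specs = specs,
                 endpoints = list(cr = cr, efs = efs, os = os)),
            class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  kinds <- table(vapply(x$specs, `[[`, character(1), "kind"))
  cat("cohort_schema:", length(x$specs), "variables (",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Variable names of a schema
#' @param schema A [cohort_schema()].
#' @return Character vector in schema order.
#' @export
schema_names <- function(schema) names(schema$specs)

schema_kinds <- function(schema)
  vapply(schema$specs, `[[`, character(1), "kind")

#' Write a schema sidecar file
#'
#' Serializes the variable dictionary and endpoint declarations as JSON so a
#' cohort CSV can travel with its typing information.
#'
#' @param schema A [cohort_schema()].
#' @param path Output file path.
#' @export
write_schema <- function(schema, path) {
  vars <- lapply(unname(schema$specs), function(s) {
    s[!vapply(s, is.null, logical(1))]
  })
  jsonlite::write_json(list(variables = vars, endpoints = schema$endpoints),
                       path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a schema sidecar file
#'
#' @param path Path to a JSON sidecar written by [write_schema()] (or
#'   hand-authored with the same fields).
#' @return A [cohort_schema()].
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path)
  specs <- lapply(raw$variables, function(v) {
    variable_spec(name = v$name, kind = v$kind,
                  units = if (is.null(v$units)) "" else v$units,
                  categories = if (is.null(v$categories)) NULL
                               else unlist(v$categories),
                  missing_allowed = isTRUE(v$missing_allowed),
                  pair = v$pair)
  })
  ep <- raw$endpoints
  cohort_schema(specs,
                cr = if (is.null(ep$cr)) NULL else unlist(ep$cr),
                efs = if (is.null(ep$efs)) NULL else unlist(ep$efs),
                os = if (is.null(ep$os)) NULL else unlist(ep$os))
}
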