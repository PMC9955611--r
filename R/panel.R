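#' Construct a daily feature panel
#'
#' A feature panel is the package's central data container: a long-format
#' table of daily feature values per unit (a unit is typically a city), with
#' columns `date`, `unit`, `feature`, `value`. All downstream stages —
#' cross-map curves, hyperparameter tuning, the full study — consume this
#' object.
#'
#' @param x a data.frame with columns `date` (Date or ISO-8601 string),
#'   `unit` (character), `feature` (character) and `value` (numeric).
#' @return an object of class `feature_panel` (a data.frame).
#' @examples
#' sim <- gen_coupled_logistic(coupling_spec("x_to_y"), n = 300, seed = 1)
#' head(sim$panel)
#' panel_features(sim$panel)
#' @export
feature_panel <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("date", "unit", "feature", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("panel contains unparseable dates")
  x$unit <- as.character(x$unit)
  x$feature <- as.character(x$feature)
  x$value <- as.numeric(x$value)
  dup <- duplicated(x[c("date", "unit", "feature")])
  if (any(dup))
    stop("duplicate (date, unit, feature) rows in panel; first at row ",
         which(dup)[1L])
  x <- x[order(x$unit, x$feature, x$date), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("feature_panel", "data.frame")
  x
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf("<feature_panel> %d units x %d features, %s to %s (%d days)\n",
              length(panel_units(x)), length(panel_features(x)),
              min(x$date), max(x$date), length(unique(x$date))))
  cat("  units:    ", paste(panel_units(x), collapse = ", "), "\n")
  cat("  features: ", paste(panel_features(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname feature_panel
#' @param panel a `feature_panel`.
#' @export
panel_units <- function(panel) sort(unique(panel$unit))

#' @rdname feature_panel
#' @export
panel_features <- function(panel) sort(unique(panel$feature))

#' Extract one unit's series for one feature, ordered by date
#'
#' @param panel a `feature_panel`.
#' @param unit,feature scalars naming the series.
#' @param interpolate logical; linearly interpolate interior missing days
#'   (the reservoir recursion needs gap-free input). Leading/trailing gaps
#'   are dropped. The positions filled are returned in the
#'   `"interpolated"` attribute.
#' @return numeric vector, dates as names.
#' @export
panel_series <- function(panel, unit, feature, interpolate = FALSE) {
  rows <- panel[panel$unit == unit & panel$feature == feature, , drop = FALSE]
  if (!nrow(rows))
    stop("no rows for unit '", unit, "', feature '", feature, "'")
  rows <- rows[order(rows$date), , drop = FALSE]
  dates <- seq(min(rows$date), max(rows$date), by = "day")
  v <- rep(NA_real_, length(dates))
  v[match(rows$date, dates)] <- rows$value
  mask <- is.na(v)
  if (any(mask) && interpolate) {
    filled <- stats::approx(seq_along(v)[!mask], v[!mask],
                            xout = seq_along(v), rule = 1)$y
    v <- filled
    keep <- !is.na(v)
    v <- v[keep]; dates <- dates[keep]; mask <- mask[keep]
  }
  names(v) <- as.character(dates)
  attr(v, "interpolated") <- which(mask)
  v
}

#' Read / write a feature panel as long-format CSV
#'
#' The on-disk schema is `date,unit,feature,value` with ISO-8601 dates.
#' Values are written with full precision so that a write/read round trip
#' is lossless.
#'
#' @param path CSV file path.
#' @return `read_panel` returns a [feature_panel()].
#' @export
read_panel <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("character", "character",
                                         "character", "character")),
    error = function(e) stop("cannot read panel CSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("date", "unit", "feature", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), " (header line 1)")
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable date in '", path, "' at line ",
         which(is.na(d))[1L] + 1L)
  v <- suppressWarnings(as.numeric(df$value))
  bad <- is.na(v) & !(df$value %in% c("NA", ""))
  if (any(bad))
    stop("non-numeric value in '", path, "' at line ", which(bad)[1L] + 1L)
  feature_panel(data.frame(date = d, unit = df$unit, feature = df$feature,
                           value = v))
}

#' @rdname read_panel
#' @param panel a `feature_panel`.
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  out$value <- sprintf("%.17g", out$value)
  out$value[out$value == "nan"] <- "NA"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Directed causal ground truth for a synthetic panel
#'
#' @param edges data.frame with columns `from`, `to`, `delay` (one row per
#'   directed edge), or NULL for an empty graph.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(edges = NULL) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        delay = integer())
  }
  stopifnot(all(c("from", "to", "delay") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$delay <- as.integer(edges$delay)
  if (any(edges$from == edges$to)) stop("ground truth may not contain self-loops")
  if (any(edges$delay < 0)) stop("edge delays must be nonnegative")
  structure(list(edges = edges), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  if (!nrow(x$edges)) {
    cat("<ground_truth> no causal edges\n")
  } else {
    cat("<ground_truth>", nrow(x$edges), "directed edge(s):\n")
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s (delay %d)\n", x$edges$from[i], x$edges$to[i],
                  x$edges$delay[i]))
  }
  invisible(x)
}

#' @rdname ground_truth
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(edges = truth$edges), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
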