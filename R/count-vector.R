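#' Per-unit event counts
#'
#' A `count_vector` holds the number of events observed in each spatial unit
#' (hexagonal tile or road segment) over a fixed observation window. It is
#' the input to the mixture model and to the count-based Gini.
#'
#' @param counts non-negative integer vector, one entry per unit.
#' @param unit_ids optional identifiers (hex axial coordinates or segment
#'   index); defaults to `seq_along(counts)`.
#' @param window observation-window length in years (metadata only; rates
#'   fitted from these counts are per unit per window).
#' @return an object of class `count_vector`: a list with elements
#'   `unit_ids`, `counts`, `n_units`, `window`.
#' @examples
#' cv <- count_vector(c(0, 0, 1, 3))
#' cv$n_units
#' @export
count_vector <- function(counts, unit_ids = NULL, window = 1) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    stop("`counts` must be non-empty")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("`counts` must be finite and non-missing")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("`counts` must be non-negative integers")
  if (is.null(unit_ids)) unit_ids <- seq_along(counts)
  if (length(unit_ids) != length(counts))
    stop("`unit_ids` and `counts` must have the same length")
  structure(
    list(unit_ids = unit_ids, counts = as.integer(counts),
         n_units = length(counts), window = window),
    class = "count_vector"
  )
}

#' @export
print.count_vector <- function(x, ...) {
  cat(sprintf("<count_vector> %d units, %d events, window %s year(s)\n",
              x$n_units, sum(x$counts), format(x$window)))
  invisible(x)
}

#' @export
length.count_vector <- function(x) x$n_units

# Accept either a count_vector or a bare numeric vector of counts.
as_counts <- function(x) {
  if (inherits(x, "count_vector")) return(x$counts)
  cv <- count_vector(x)
  cv$counts
}

#' Write a count vector to CSV
#'
#' @param cv a [count_vector()].
#' @param path output file path; columns `unit_id,count`.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(cv, path) {
  stopifnot(inherits(cv, "count_vector"))
  utils::write.csv(
    data.frame(unit_id = as.character(cv$unit_ids), count = cv$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count vector from CSV
#'
#' Expects columns `unit_id,count` (as written by [write_counts_csv()]), or a
#' single `count` column.
#'
#' @param path input CSV path.
#' @param window observation-window metadata to attach.
#' @return a [count_vector()].
#' @export
read_counts_csv <- function(path, window = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"count" %in% names(df))
    stop("counts CSV must have a `count` column")
  ids <- if ("unit_id" %in% names(df)) df$unit_id else NULL
  count_vector(df$count, unit_ids = ids, window = window)
}
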