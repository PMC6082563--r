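#' Count events along fixed-length road segments
#'
#' Divides a road of known length into non-overlapping segments (default
#' 500 m), measured from the road origin, and counts events per segment.
#' Segments are half-open `[a, b)` with 0-based start positions; the final
#' segment is closed at the road end so the partition is exhaustive.
#'
#' @param positions event positions as kilometre-posts from the road origin.
#' @param road_length road length in kilometres.
#' @param segment_length segment length in metres (default 500).
#' @param strict if `TRUE`, a position outside `[0, road_length]` is an
#'   error; otherwise such events are dropped with a warning.
#' @param window observation-window metadata for the resulting counts.
#' @return a [count_vector()] with `ceiling(road_length * 1000 /
#'   segment_length)` entries, `unit_ids` the 1-based segment indices, and
#'   attribute `n_dropped`.
#' @examples
#' segment_road(c(0.1, 0.4, 0.6), road_length = 1)$counts  # 2, 1
#' @export
segment_road <- function(positions, road_length, segment_length = 500,
                         strict = FALSE, window = 1) {
  if (!is.numeric(road_length) || road_length <= 0)
    stop("`road_length` must be a positive number of kilometres")
  if (!is.numeric(segment_length) || segment_length <= 0)
    stop("`segment_length` must be a positive number of metres")
  positions <- as.numeric(positions)
  if (anyNA(positions)) stop("positions must be non-missing")
  n_segments <- ceiling(road_length * 1000 / segment_length)

  inside <- positions >= 0 & positions <= road_length
  n_drop <- sum(!inside)
  if (n_drop > 0) {
    if (strict)
      stop(n_drop, " position(s) outside [0, ", road_length,
           "] km (strict mode)")
    warning(n_drop, " position(s) outside the road were dropped")
    positions <- positions[inside]
  }
  idx <- floor(positions * 1000 / segment_length) + 1
  idx[idx > n_segments] <- n_segments   # road end falls in the last segment
  counts <- tabulate(idx, nbins = n_segments)
  cv <- count_vector(counts, unit_ids = seq_len(n_segments), window = window)
  attr(cv, "n_dropped") <- n_drop
  cv
}
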