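#' Uniform (CSR) point pattern in a rectangle
#'
#' @param n number of points (>= 0).
#' @param bbox rectangular window `c(xmin, ymin, xmax, ymax)`.
#' @param seed optional integer seed.
#' @return data.frame with `x`, `y` (0 rows when `n = 0`).
#' @export
gen_uniform_points <- function(n, bbox, seed = NULL) {
  bbox <- check_bbox(bbox)
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  data.frame(x = stats::runif(n, bbox[1], bbox[3]),
             y = stats::runif(n, bbox[2], bbox[4]))
}

#' Built-in synthetic scenarios
#'
#' Returns the generating truth for one of the named regimes the package's
#' tests and examples are built on:
#'
#' * `"london_table4"` — zero-inflated, heavy-tailed urban counts: a
#'   12-group mixture (64.2% of tiles at rate 0 up to 0.4% at rate 10.95
#'   per decade) over 29,600 hexagonal tiles, 10-year window.
#' * `"puebla_uniform"` — near-uniform motorway counts: a single rate
#'   0.1978 per 500-m segment per 2-year window over 242 segments (121 km).
#' * `"pachuca_3group"` — a 3-group motorway regime: weights
#'   (17%, 74%, 8.2%) (printed values; renormalised from their 99.2% sum)
#'   at rates (0, 1.36, 3.4) over 125 segments (62.5 km), 2-year window.
#' * `"csr_null"` — no rate structure: uniform points in a
#'   2,000 x 2,000 m window, binned on a 40-m hex grid.
#'
#' @param name scenario name.
#' @return a list with `name`, `truth` (a [mixture()], or `NULL` for
#'   `"csr_null"`), `n_units`, `window_years`, and a `domain` description
#'   (`type` "linear" or "hex" plus its geometry).
#' @export
scenario <- function(name = c("london_table4", "puebla_uniform",
                              "pachuca_3group", "csr_null")) {
  name <- match.arg(name)
  switch(name,
    london_table4 = {
      q <- c(64.2, 22.7, 2.1, 1.9, 1.7, 1.5, 1.3, 1.2, 1.0, 1.0, 1.0, 0.4)
      lam <- c(0, 0.488, 0.823, 1.159, 1.517, 1.906, 2.337, 2.839, 3.466,
               4.359, 5.860, 10.950)
      list(name = name,
           truth = mixture(q / sum(q), lam, window = 10),
           n_units = 29600, window_years = 10,
           domain = list(type = "hex", side = 40))
    },
    puebla_uniform = list(
      name = name,
      truth = mixture(1, 0.1978, window = 2),
      n_units = 242, window_years = 2,
      domain = list(type = "linear", road_length = 121,
                    segment_length = 500)),
    pachuca_3group = {
      q <- c(0.17, 0.74, 0.082)   # printed weights sum to 0.992
      list(name = name,
           truth = mixture(q / sum(q), c(0, 1.36, 3.4), window = 2),
           n_units = 125, window_years = 2,
           domain = list(type = "linear", road_length = 62.5,
                         segment_length = 500))
    },
    csr_null = list(
      name = name, truth = NULL, n_units = NA_integer_, window_years = 1,
      domain = list(type = "hex", side = 40,
                    bbox = c(0, 0, 2000, 2000), n_points = 500))
  )
}

#' Generate a synthetic dataset from a scenario
#'
#' Simulates per-unit counts from the scenario's truth (or a CSR point
#' pattern for `"csr_null"`). For hexagonal domains each unit's events can
#' additionally be scattered uniformly within their tile, yielding a point
#' pattern consistent with the counts.
#'
#' @param spec a [scenario()] (or a list with the same fields).
#' @param seed optional integer seed.
#' @param n_units override the scenario's unit count.
#' @param points for hex domains, also return scattered event coordinates.
#' @return a list with `counts` (a [count_vector()]), `points` (data.frame
#'   or `NULL`), `truth`, and `seed`.
#' @export
gen_scenario <- function(spec, seed = NULL, n_units = NULL, points = FALSE) {
  if (is.character(spec)) spec <- scenario(spec)
  if (!is.null(seed)) set.seed(seed)

  if (identical(spec$name, "csr_null") || is.null(spec$truth)) {
    bbox <- spec$domain$bbox
    pts <- gen_uniform_points(spec$domain$n_points, bbox)
    grid <- build_hex_grid(bbox, side = spec$domain$side)
    cv <- assign_points_to_hexes(pts, grid)
    return(list(counts = cv, points = pts, truth = NULL, seed = seed))
  }

  n <- if (is.null(n_units)) spec$n_units else n_units
  cv <- simulate_counts(spec$truth, n)
  pts <- NULL
  if (points && identical(spec$domain$type, "hex")) {
    side <- spec$domain$side
    grid_dim <- ceiling(sqrt(n))
    bbox <- c(0, 0, grid_dim * 1.5 * side + side,
              grid_dim * sqrt(3) * side + side)
    grid <- build_hex_grid(bbox, side = side)
    tiles <- grid$tiles[seq_len(n), ]
    idx <- rep(seq_len(n), cv$counts)
    pts <- scatter_in_hex(tiles$cx[idx], tiles$cy[idx], side)
  }
  list(counts = cv, points = pts, truth = spec$truth, seed = seed)
}

# Uniform draws inside flat-top hexagons centred at (cx, cy): rejection
# sampling from the bounding box (acceptance ~ 0.65).
scatter_in_hex <- function(cx, cy, side) {
  n <- length(cx)
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  half_h <- sqrt(3) / 2 * side
  while (length(todo) > 0) {
    dx <- stats::runif(length(todo), -side, side)
    dy <- stats::runif(length(todo), -half_h, half_h)
    # inside the flat-top hexagon: |dy| <= sqrt(3) * (side - |dx|) and
    # |dy| <= half_h (the latter already holds by construction)
    ok <- abs(dy) <= sqrt(3) * (side - abs(dx))
    x[todo[ok]] <- cx[todo[ok]] + dx[ok]
    y[todo[ok]] <- cy[todo[ok]] + dy[ok]
    todo <- todo[!ok]
  }
  data.frame(x = x, y = y)
}
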