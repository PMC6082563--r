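#' Hexagonal tessellation of a rectangular region
#'
#' Builds a grid of non-overlapping regular hexagons covering a bounding
#' box. Tiles are indexed by axial coordinates `(q, r)`; the default
#' orientation is flat-top, and the grid origin (the centre of tile (0,0))
#' defaults to the lower-left corner of the box. Coordinates are assumed to
#' be planar, in metres: project geographic data before tessellating.
#'
#' A flat-top hexagon of side `s` has area `(3 sqrt(3) / 2) s^2`, extends
#' `s` left/right of its centre and `s sqrt(3) / 2` up/down. Tiles are
#' retained when this extent overlaps the box, so the retained tiles cover
#' the box completely (a few extreme-corner tiles may be retained whose
#' hexagon only touches the box's bounding neighbourhood).
#'
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)` in metres; must be
#'   non-degenerate.
#' @param side hexagon edge length in metres (default 40).
#' @param origin centre of tile (0,0); defaults to `c(xmin, ymin)`.
#' @return an object of class `hex_grid`: list with `origin`, `side`,
#'   `orientation`, `bbox`, `tile_area`, and `tiles` (data.frame with axial
#'   `q`, `r`, centre `cx`, `cy`, and `unit_id = "q:r"`).
#' @examples
#' g <- build_hex_grid(c(0, 0, 1000, 1000), side = 40)
#' g$tile_area  # (3 * sqrt(3) / 2) * 40^2
#' @export
build_hex_grid <- function(bbox, side = 40, origin = NULL) {
  bbox <- check_bbox(bbox)
  if (!is.numeric(side) || length(side) != 1 || !is.finite(side) || side <= 0)
    stop("`side` must be a positive number")
  if (is.null(origin)) origin <- c(bbox[1], bbox[2])
  stopifnot(is.numeric(origin), length(origin) == 2)

  s <- side
  # axial index ranges whose hexagon extent can overlap the bbox
  q_rng <- floor((bbox[1] - origin[1] - s) / (1.5 * s)):
           ceiling((bbox[3] - origin[1] + s) / (1.5 * s))
  tiles <- do.call(rbind, lapply(q_rng, function(qi) {
    cx <- origin[1] + 1.5 * s * qi
    if (cx + s < bbox[1] || cx - s > bbox[3]) return(NULL)
    half_h <- sqrt(3) / 2 * s
    r_lo <- floor((bbox[2] - half_h - origin[2]) / (sqrt(3) * s) - qi / 2)
    r_hi <- ceiling((bbox[4] + half_h - origin[2]) / (sqrt(3) * s) - qi / 2)
    ri <- r_lo:r_hi
    cy <- origin[2] + sqrt(3) * s * (ri + qi / 2)
    ok <- (cy + half_h >= bbox[2]) & (cy - half_h <= bbox[4])
    if (!any(ok)) return(NULL)
    data.frame(q = qi, r = ri[ok], cx = cx, cy = cy[ok])
  }))
  tiles$unit_id <- paste0(tiles$q, ":", tiles$r)
  structure(
    list(origin = origin, side = s, orientation = "flat-top", bbox = bbox,
         tile_area = 3 * sqrt(3) / 2 * s^2, tiles = tiles),
    class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf(
    "<hex_grid> %d flat-top hexagons, side %g m (tile area %.1f m^2)\n  bbox [%g, %g] x [%g, %g]\n",
    nrow(x$tiles), x$side, x$tile_area,
    x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

check_bbox <- function(bbox) {
  if (!is.numeric(bbox) || length(bbox) != 4 || anyNA(bbox))
    stop("`bbox` must be numeric c(xmin, ymin, xmax, ymax)")
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop("`bbox` is degenerate: xmax > xmin and ymax > ymin required")
  as.numeric(bbox)
}

# Point -> axial hex index by cube rounding (exact, O(1) per point).
# Boundary ties resolve deterministically through the rounding rule.
point_to_axial <- function(x, y, origin, side) {
  px <- (x - origin[1]) / side
  py <- (y - origin[2]) / side
  qf <- 2 / 3 * px
  rf <- -1 / 3 * px + sqrt(3) / 3 * py
  cube_round(qf, rf)
}

cube_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  data.frame(q = q, r = r)
}

#' Count point events per hexagonal tile
#'
#' Assigns each event to the unique hexagon containing it (cube rounding of
#' fractional axial coordinates, which on a hex grid is the nearest tile
#' centre) and counts events per tile over the whole grid.
#'
#' @param events data.frame with numeric `x`, `y` columns in metres (as
#'   returned by [read_point_events()]).
#' @param grid a [build_hex_grid()] grid.
#' @param strict if `TRUE`, an event outside the grid's bbox is an error;
#'   otherwise such events are dropped with a warning reporting how many.
#' @return a [count_vector()] with one entry per grid tile, `unit_ids` the
#'   tiles' `"q:r"` labels, and attribute `n_dropped`.
#' @export
assign_points_to_hexes <- function(events, grid, strict = FALSE) {
  stopifnot(inherits(grid, "hex_grid"))
  ev <- check_events(events)
  inside <- ev$x >= grid$bbox[1] & ev$x <= grid$bbox[3] &
            ev$y >= grid$bbox[2] & ev$y <= grid$bbox[4]
  n_drop <- sum(!inside)
  if (n_drop > 0) {
    if (strict)
      stop(n_drop, " event(s) outside the grid bbox (strict mode)")
    warning(n_drop, " event(s) outside the grid bbox were dropped")
    ev <- ev[inside, , drop = FALSE]
  }
  counts <- integer(nrow(grid$tiles))
  if (nrow(ev) > 0) {
    ax <- point_to_axial(ev$x, ev$y, grid$origin, grid$side)
    idx <- match(paste0(ax$q, ":", ax$r), grid$tiles$unit_id)
    if (anyNA(idx))
      stop("internal error: in-bbox event mapped to a tile outside the grid")
    tab <- tabulate(idx, nbins = nrow(grid$tiles))
    counts <- as.integer(tab)
  }
  cv <- count_vector(counts, unit_ids = grid$tiles$unit_id)
  attr(cv, "n_dropped") <- n_drop
  cv
}

check_events <- function(events) {
  if (!is.data.frame(events) || !all(c("x", "y") %in% names(events)))
    stop("`events` must be a data.frame with `x` and `y` columns")
  if (nrow(events) > 0 &&
      (anyNA(events$x) || anyNA(events$y) ||
       any(!is.finite(events$x)) || any(!is.finite(events$y))))
    stop("event coordinates must be finite")
  events
}

#' Vertices of a grid's hexagons
#'
#' @param grid a [build_hex_grid()] grid.
#' @return a list of 6x2 matrices, one closed polygon ring per tile (first
#'   vertex not repeated), in tile order.
#' @export
hex_polygons <- function(grid) {
  stopifnot(inherits(grid, "hex_grid"))
  ang <- (0:5) * pi / 3   # flat-top: vertices at 0, 60, ..., 300 degrees
  vx <- grid$side * cos(ang)
  vy <- grid$side * sin(ang)
  lapply(seq_len(nrow(grid$tiles)), function(i)
    cbind(grid$tiles$cx[i] + vx, grid$tiles$cy[i] + vy))
}

#' Export hexagon counts as GeoJSON
#'
#' Writes each tile as a Polygon feature with `unit_id` and `count`
#' properties, in the grid's planar coordinates.
#'
#' @param grid a [build_hex_grid()] grid.
#' @param cv the matching [count_vector()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hex_geojson <- function(grid, cv, path) {
  stopifnot(inherits(cv, "count_vector"),
            cv$n_units == nrow(grid$tiles))
  polys <- hex_polygons(grid)
  features <- lapply(seq_along(polys), function(i) {
    ring <- rbind(polys[[i]], polys[[i]][1, ])
    list(type = "Feature",
         properties = list(unit_id = grid$tiles$unit_id[i],
                           count = cv$counts[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(j) ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
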