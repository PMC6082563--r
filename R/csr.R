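#' Nearest-neighbour test of complete spatial randomness
#'
#' Apparent hot spots arise even in uniformly random point patterns, so an
#' observed concentration is only meaningful once complete spatial
#' randomness (CSR) is rejected. This test compares the observed mean
#' nearest-neighbour distance with its CSR expectation via the Clark-Evans
#' ratio `R = mean NN distance / (0.5 sqrt(area / n))`: `R < 1` indicates
#' clustering, `R > 1` regularity.
#'
#' Two null computations are available and both are reported when
#' `n_sims > 0`: a normal approximation (Clark-Evans z test, no edge
#' correction) and a Monte Carlo envelope that simulates `n_sims` CSR
#' patterns of the same size in the rectangular window and ranks the
#' observed mean distance among them. The Monte Carlo p-value is exactly
#' calibrated by exchangeability and is the default `p_value`.
#'
#' @param events data.frame with numeric `x`, `y` (>= 2 rows).
#' @param region_area area of the observation region; defaults to the area
#'   of `bbox`.
#' @param bbox rectangular window `c(xmin, ymin, xmax, ymax)` used for the
#'   Monte Carlo simulations; defaults to the events' bounding box.
#' @param n_sims Monte Carlo replicates (0 disables the envelope).
#' @param seed optional integer seed for the simulations.
#' @param alternative `"clustered"` (one-sided, small distances; the
#'   alternative of interest for hot-spot analysis) or `"two.sided"`.
#' @return an object of class `csr_test`: list with `n`, `R` (Clark-Evans
#'   ratio), `mean_nn`, `expected_nn`, `z`, `p_normal`, `p_mc` (or `NA`),
#'   `p_value`, `null` (which computation `p_value` used), `n_sims`,
#'   `alternative`.
#' @export
nearest_neighbour_csr_test <- function(events, region_area = NULL,
                                       bbox = NULL, n_sims = 99,
                                       seed = NULL,
                                       alternative = c("clustered",
                                                       "two.sided")) {
  alternative <- match.arg(alternative)
  ev <- check_events(events)
  n <- nrow(ev)
  if (n < 2) stop("at least 2 events are required")
  if (is.null(bbox))
    bbox <- c(min(ev$x), min(ev$y), max(ev$x), max(ev$y))
  if (is.null(region_area))
    region_area <- (bbox[3] - bbox[1]) * (bbox[4] - bbox[2])
  if (!is.numeric(region_area) || region_area <= 0)
    stop("`region_area` must be positive")

  d_obs <- mean_nn_distance(ev$x, ev$y)
  expected <- 0.5 * sqrt(region_area / n)
  r_ratio <- d_obs / expected
  se <- 0.26136 * sqrt(region_area) / n
  z <- (d_obs - expected) / se
  p_normal <- if (alternative == "clustered") stats::pnorm(z)
              else 2 * stats::pnorm(-abs(z))

  p_mc <- NA_real_
  if (n_sims > 0) {
    if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
      stop("degenerate window: cannot run Monte Carlo simulations")
    if (!is.null(seed)) set.seed(seed)
    d_sim <- vapply(seq_len(n_sims), function(s) {
      xs <- stats::runif(n, bbox[1], bbox[3])
      ys <- stats::runif(n, bbox[2], bbox[4])
      mean_nn_distance(xs, ys)
    }, numeric(1))
    lo <- (1 + sum(d_sim <= d_obs)) / (n_sims + 1)
    hi <- (1 + sum(d_sim >= d_obs)) / (n_sims + 1)
    p_mc <- if (alternative == "clustered") lo else min(1, 2 * min(lo, hi))
  }

  structure(
    list(n = n, R = r_ratio, mean_nn = d_obs, expected_nn = expected,
         z = z, p_normal = p_normal, p_mc = p_mc,
         p_value = if (n_sims > 0) p_mc else p_normal,
         null = if (n_sims > 0) "monte-carlo envelope"
                else "normal approximation (Clark-Evans)",
         n_sims = n_sims, alternative = alternative),
    class = "csr_test")
}

#' @export
print.csr_test <- function(x, ...) {
  cat(sprintf(
    "<csr_test> n = %d points\n  Clark-Evans R = %.4f (mean NN %.4f vs CSR %.4f)\n  p = %.4f [%s, alternative: %s]\n",
    x$n, x$R, x$mean_nn, x$expected_nn, x$p_value, x$null, x$alternative))
  invisible(x)
}

# Mean nearest-neighbour distance; O(n^2) pairwise distances, adequate for
# the pattern sizes this test is meant for (hundreds to a few thousand).
mean_nn_distance <- function(x, y) {
  dm <- as.matrix(stats::dist(cbind(x, y)))
  diag(dm) <- Inf
  n <- length(x)
  idx <- max.col(-dm, ties.method = "first")
  mean(dm[cbind(seq_len(n), idx)])
}
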