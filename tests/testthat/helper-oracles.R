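# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no outer(), no sorting tricks) so they can certify them.

# Gini of a rate distribution by explicit double loop
recc_oracle <- function(q, lambda) {
  k <- length(q)
  num <- 0
  for (i in seq_len(k))
    for (j in seq_len(k))
      num <- num + q[i] * q[j] * abs(lambda[i] - lambda[j])
  den <- 0
  for (i in seq_len(k)) den <- den + q[i] * lambda[i]
  num / (2 * den)
}

# Gini of raw counts by explicit double loop
gini_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      s <- s + abs(x[i] - x[j])
  s / (2 * n * sum(x))
}

# Mean nearest-neighbour distance by explicit loops
nn_oracle <- function(x, y) {
  n <- length(x)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  mean(nn)
}

# Nearest hex-centre assignment (on a hexagonal lattice the nearest centre
# is the containing tile)
nearest_centre_oracle <- function(px, py, centres_x, centres_y) {
  vapply(seq_along(px), function(i)
    which.min((centres_x - px[i])^2 + (centres_y - py[i])^2), integer(1))
}

# Random valid mixture for property tests
random_mixture <- function(k = NULL) {
  if (is.null(k)) k <- sample(1:8, 1)
  q <- stats::runif(k, 0.05, 1)
  lam <- sort(stats::runif(k, 0, 20))
  while (any(diff(lam) < 1e-6)) lam <- sort(stats::runif(k, 0, 20))
  mixture(q / sum(q), lam)
}

# Table of urban severe-accident rate groups used as a heavy-tailed,
# zero-inflated generating truth in tests (12 groups; weights in %, rates
# per decade)
table4_mixture <- function() scenario("london_table4")$truth
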