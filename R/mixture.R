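#' Finite Poisson mixture distribution
#'
#' The rate model for per-unit counts: a fraction `q[j]` of units share the
#' Poisson rate `lambda[j]` (events per unit per observation window). Rates
#' must be strictly increasing; weights are positive and sum to one. A rate
#' of exactly zero is allowed and handled exactly (a structural-zero group).
#'
#' @param q group weights (fractions, summing to 1 within 1e-9; they are
#'   renormalised to machine precision).
#' @param lambda group rates, strictly increasing, all >= 0.
#' @param window observation-window length in years (metadata).
#' @return an object of class `mixture`: list with `k`, `q`, `lambda`,
#'   `window`.
#' @examples
#' m <- mixture(q = c(0.5, 0.5), lambda = c(0, 2))
#' recc(m)
#' @export
mixture <- function(q, lambda, window = 1) {
  q <- as.numeric(q); lambda <- as.numeric(lambda)
  if (length(q) != length(lambda) || length(q) == 0L)
    stop("`q` and `lambda` must be non-empty vectors of equal length")
  if (anyNA(q) || anyNA(lambda) || any(!is.finite(q)) || any(!is.finite(lambda)))
    stop("`q` and `lambda` must be finite")
  if (any(q <= 0))
    stop("all weights must be strictly positive")
  if (abs(sum(q) - 1) > 1e-9)
    stop("weights must sum to 1 (within 1e-9); got ", format(sum(q)))
  if (any(lambda < 0))
    stop("rates must be non-negative")
  if (is.unsorted(lambda, strictly = TRUE))
    stop("rates must be strictly increasing")
  structure(
    list(k = length(q), q = q / sum(q), lambda = lambda, window = window),
    class = "mixture"
  )
}

#' @export
print.mixture <- function(x, digits = 4, ...) {
  cat(sprintf("<mixture> k = %d group(s), window %s year(s)\n",
              x$k, format(x$window)))
  print(data.frame(group = seq_len(x$k),
                   size_pct = round(100 * x$q, 1),
                   rate = round(x$lambda, digits)),
        row.names = FALSE)
  invisible(x)
}

# Sort (q, lambda) by rate and merge exact duplicates; used internally when
# assembling mixtures from estimation output.
make_mixture <- function(q, lambda, window = 1) {
  keep <- q > 0
  q <- q[keep]; lambda <- lambda[keep]
  o <- order(lambda)
  q <- q[o]; lambda <- lambda[o]
  # merge numerically identical support points so rates are strictly increasing
  grp <- cumsum(c(TRUE, diff(lambda) > .Machine$double.eps * 4))
  qm <- as.numeric(tapply(q, grp, sum))
  lm <- as.numeric(tapply(q * lambda, grp, sum)) / qm
  mixture(qm / sum(qm), lm, window = window)
}

#' Poisson probability mass function
#'
#' Stable evaluation of `exp(-lambda) lambda^h / h!`, computed in log space.
#' The degenerate rate `lambda = 0` is handled exactly: all mass at zero.
#'
#' @param h non-negative integer count (vectorised).
#' @param lam non-negative rate (vectorised).
#' @param log return the log-probability.
#' @return probability (or log-probability) of observing `h` events.
#' @examples
#' poisson_pmf(0, 1)            # exp(-1) = 0.368
#' 1 - poisson_pmf(0, 1) - poisson_pmf(1, 1)  # P(H > 1) = 0.264
#' @export
poisson_pmf <- function(h, lam, log = FALSE) {
  if (anyNA(h) || anyNA(lam)) stop("`h` and `lam` must be non-missing")
  if (any(h < 0) || any(h != floor(h)))
    stop("`h` must be a non-negative integer")
  if (any(lam < 0)) stop("`lam` must be non-negative")
  stats::dpois(h, lam, log = log)
}

# Aggregate counts into (value, multiplicity); the mixture likelihood only
# depends on counts through this table, which makes fits O(#unique values).
count_table <- function(counts) {
  tab <- table(counts)
  list(v = as.integer(names(tab)), m = as.integer(tab), n = length(counts))
}

# Component density matrix: rows = unique count values, cols = support points.
component_matrix <- function(v, lambda) {
  nu <- length(v); k <- length(lambda)
  matrix(stats::dpois(rep.int(v, k), rep(lambda, each = nu)), nu, k)
}

#' Log-likelihood of counts under a mixture
#'
#' `sum_i log sum_j q_j Pois(H_i; lambda_j)`.
#'
#' @param counts a [count_vector()] or bare numeric vector of counts.
#' @param mix a [mixture()].
#' @return the log-likelihood; `-Inf` if some count has zero density under
#'   every component (e.g. a positive count with all rates zero).
#' @export
loglik_mixture <- function(counts, mix) {
  stopifnot(inherits(mix, "mixture"))
  x <- as_counts(counts)
  ct <- count_table(x)
  P <- component_matrix(ct$v, mix$lambda)
  f <- as.numeric(P %*% mix$q)
  if (any(f == 0)) return(-Inf)
  sum(ct$m * log(f))
}

#' NPMLE gradient (directional derivative) function
#'
#' `d(lam) = N^-1 sum_i Pois(H_i; lam) / f_mix(H_i)`. The general mixture
#' maximum-likelihood theorem characterises the non-parametric MLE by
#' `sup_lam d(lam) <= 1`, with equality at the support points.
#'
#' @param lam candidate rate(s) at which to evaluate the derivative.
#' @param counts a [count_vector()] or numeric counts.
#' @param mix the current [mixture()] iterate.
#' @return `d(lam)`, vectorised over `lam`.
#' @export
gradient_function <- function(lam, counts, mix) {
  stopifnot(inherits(mix, "mixture"))
  if (any(lam < 0)) stop("`lam` must be non-negative")
  x <- as_counts(counts)
  ct <- count_table(x)
  P <- component_matrix(ct$v, mix$lambda)
  f <- as.numeric(P %*% mix$q)
  if (any(f == 0))
    stop("mixture assigns zero density to an observed count")
  w <- ct$m / f / ct$n
  as.numeric(crossprod(component_matrix(ct$v, lam), w))
}

#' Simulate counts from a mixture
#'
#' Each unit is independently assigned to a group with probabilities `q`,
#' then draws a Poisson count at the group's rate.
#'
#' @param mix a [mixture()].
#' @param n_units number of units to simulate.
#' @param seed optional integer seed for reproducibility (uses the global
#'   generator if `NULL`).
#' @return a [count_vector()] with the mixture's window attached.
#' @export
simulate_counts <- function(mix, n_units, seed = NULL) {
  stopifnot(inherits(mix, "mixture"), n_units >= 1)
  if (!is.null(seed)) set.seed(seed)
  grp <- sample.int(mix$k, n_units, replace = TRUE, prob = mix$q)
  count_vector(stats::rpois(n_units, mix$lambda[grp]), window = mix$window)
}
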