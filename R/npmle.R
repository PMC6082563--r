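#' Non-parametric maximum likelihood fit of a Poisson mixture
#'
#' Estimates the mixing distribution of per-unit Poisson rates by NPMLE:
#' a vertex exchange method (VEM) optimises weights over a dense grid of
#' candidate rates on `[0, max(count)]`, EM then refines weights and rates
#' jointly, near-duplicate support points are collapsed, and the support is
#' augmented (and re-refined) until the gradient optimality condition
#' `sup_lam d(lam) <= 1 + tol` holds.
#'
#' The number of groups is not chosen a priori: it is the number of support
#' points the NPMLE retains, which is how the optimal group count is
#' obtained from the data.
#'
#' @param counts a [count_vector()] or numeric vector of per-unit counts.
#' @param grid_size number of equally spaced VEM candidate rates on
#'   `[0, max(count)]` (default 50; the EM refinement makes the result
#'   insensitive to this choice).
#' @param tol gradient optimality tolerance: convergence requires the
#'   directional derivative to stay below `1 + tol` (default 1e-6; the VEM
#'   stage always uses 1e-7 on its grid).
#' @param max_iter VEM iteration cap (default 5000).
#' @param collapse_delta support points closer than this are merged after
#'   EM, weights summed and rates weight-averaged. Default `NULL` uses
#'   `0.05 * (1 + lambda)` locally, so the merge radius scales with rate.
#' @param em_tol EM stops when the log-likelihood improves by less than this
#'   (default 1e-8; tightened tenfold each augmentation round).
#' @param max_rounds cap on EM/collapse/augmentation rounds (default 40).
#' @return an object of class `npmle_fit`: list with `mixture` (a
#'   [mixture()]), `loglik`, `n_iter_vem`, `n_iter_em`, `max_gradient`
#'   (final supremum of the directional derivative over a fine rate grid),
#'   and `converged`.
#' @examples
#' set.seed(1)
#' cv <- simulate_counts(mixture(c(.5, .5), c(0, 2)), 500)
#' fit <- fit_npmle(cv)
#' fit$mixture
#' @export
fit_npmle <- function(counts, grid_size = 50, tol = 1e-6, max_iter = 5000,
                      collapse_delta = NULL, em_tol = 1e-8,
                      max_rounds = 40) {
  window <- if (inherits(counts, "count_vector")) counts$window else 1
  x <- as_counts(counts)
  if (grid_size < 2) stop("`grid_size` must be at least 2")
  ct <- count_table(x)

  # degenerate data: all counts equal -> point mass at that value
  if (length(ct$v) == 1L) {
    mix <- mixture(1, ct$v, window = window)
    ll <- if (ct$v == 0) 0 else loglik_mixture(x, mix)
    return(structure(
      list(mixture = mix, loglik = ll, n_iter_vem = 0L, n_iter_em = 0L,
           max_gradient = 1, converged = TRUE),
      class = "npmle_fit"))
  }

  grid <- seq(0, max(ct$v), length.out = grid_size)
  P <- component_matrix(ct$v, grid)
  w <- rep(1 / grid_size, grid_size)

  vem <- vem_weights(P, ct$m, w, tol = min(tol, 1e-7), max_iter = max_iter)
  w <- vem$w

  keep <- w > 1e-8
  q <- w[keep] / sum(w[keep])
  lam <- grid[keep]
  # pre-collapse the (often diffuse) VEM weights so EM starts from a small
  # support; the augmentation rounds restore any structure this loses
  col0 <- collapse_support(q, lam, collapse_delta)
  q <- col0$q; lam <- col0$lambda

  # EM refinement + collapse + support augmentation until the gradient
  # condition holds on a fine grid (or the augmentation loop stalls). Each
  # round alternates EM and collapsing until the support is stable, checks
  # the directional derivative, and (on failure) adds the most violating
  # rate as a new support point and tightens the EM tolerance.
  n_em_total <- 0L
  max_grad <- Inf
  fine <- sort(unique(c(seq(0, max(ct$v) + 1, length.out = 512), grid)))
  best <- NULL
  for (round in seq_len(max_rounds)) {
    em_tol_r <- max(em_tol * 0.1^(round - 1), 1e-13)
    repeat {
      em <- em_refine(ct, q, lam, em_tol = em_tol_r, max_iter = 5000)
      q <- em$q; lam <- em$lambda; n_em_total <- n_em_total + em$n_iter
      col <- collapse_support(q, lam, collapse_delta)
      if (!col$merged) break
      q <- col$q; lam <- col$lambda
    }
    mix_now <- make_mixture(q, lam, window = window)
    d <- gradient_function(c(fine, mix_now$lambda), x, mix_now)
    max_grad <- max(d)
    ll_now <- loglik_mixture(x, mix_now)
    if (is.null(best) || ll_now > best$loglik ||
        (ll_now == best$loglik && max_grad < best$max_grad))
      best <- list(mixture = mix_now, loglik = ll_now, max_grad = max_grad)
    if (max_grad <= 1 + tol) break
    lam_new <- c(fine, mix_now$lambda)[which.max(d)]
    if (min(abs(lam_new - mix_now$lambda)) > 1e-8) {
      q <- c(mix_now$q * (1 - 1e-3), 1e-3)
      lam <- c(mix_now$lambda, lam_new)
    }
    # otherwise: the violation sits at an existing support point, meaning
    # the EM has not converged tightly enough; the next round's tighter
    # tolerance handles it
  }

  mix <- best$mixture
  max_grad <- best$max_grad

  # the single-Poisson MLE is in the feasible set and has a closed form;
  # never return anything it dominates
  mix1 <- mixture(1, mean(x), window = window)
  ll1 <- loglik_mixture(x, mix1)
  if (ll1 >= best$loglik) {
    d1 <- gradient_function(c(fine, mean(x)), x, mix1)
    if (max(d1) <= max(max_grad, 1 + tol)) {
      mix <- mix1
      max_grad <- max(d1)
      best$loglik <- ll1
    }
  }

  structure(
    list(mixture = mix,
         loglik = loglik_mixture(x, mix),
         n_iter_vem = vem$n_iter,
         n_iter_em = n_em_total,
         max_gradient = max_grad,
         converged = max_grad <= 1 + tol),
    class = "npmle_fit")
}

#' @export
print.npmle_fit <- function(x, ...) {
  cat(sprintf(
    "<npmle_fit> k = %d, loglik = %.4f, max gradient = %.8f (%s)\n",
    x$mixture$k, x$loglik, x$max_gradient,
    if (x$converged) "converged" else "NOT converged"))
  print(x$mixture)
  invisible(x)
}

# Vertex exchange method on a fixed grid: move mass from the support point
# with the smallest directional derivative to the grid point with the
# largest, with a line-searched step. Monotone in likelihood.
vem_weights <- function(P, m, w, tol, max_iter) {
  n <- sum(m)
  it <- 0L
  repeat {
    it <- it + 1L
    f <- as.numeric(P %*% w)
    d <- as.numeric(crossprod(P, m / f)) / n
    j_add <- which.max(d)
    sup <- w > 0
    j_rem <- which(sup)[which.min(d[sup])]
    if (d[j_add] <= 1 + tol || it > max_iter) break
    # f(t) = f + t * w_rem * (P[,add] - P[,rem]); maximise the loglik in t
    delta <- w[j_rem] * (P[, j_add] - P[, j_rem])
    obj <- function(t) sum(m * log(pmax(f + t * delta, 1e-300)))
    t_opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-10)$maximum
    if (obj(t_opt) <= obj(0)) t_opt <- 0
    step <- t_opt * w[j_rem]
    w[j_add] <- w[j_add] + step
    w[j_rem] <- w[j_rem] - step
    if (step == 0 && d[j_add] > 1 + tol) break  # line search stalled
  }
  list(w = w, n_iter = it)
}

# EM for a Poisson mixture with free weights and rates, on aggregated
# counts. Zero rates are exact fixed points when their posterior mass sits
# entirely on zero counts. Log-likelihood is non-decreasing by construction;
# an assertion guards against numerical regression. Support points that
# drift within a hair of each other create flat directions that stall EM,
# so numerical duplicates are merged every 200 iterations (log-likelihood
# neutral at that radius).
em_refine <- function(ct, q, lam, em_tol, max_iter) {
  ll_old <- -Inf
  it <- 0L
  nu <- length(ct$v)
  repeat {
    it <- it + 1L
    k <- length(lam)
    P <- component_matrix(ct$v, lam)
    num <- P * rep(q, each = nu)
    f <- .rowSums(num, nu, k)
    if (any(f == 0)) stop("EM: zero density at an observed count")
    wz <- num * (ct$m / f)               # multiplicity-weighted responsibilities
    nj <- .colSums(wz, nu, k)
    keep <- nj > 1e-12
    q <- nj[keep] / ct$n
    lam <- (.colSums(wz * ct$v, nu, k)[keep]) / nj[keep]
    if (it %% 200L == 0L && length(lam) > 1L) {
      col <- collapse_support(q, lam, collapse_delta = 1e-3)
      if (col$merged) {
        q <- col$q; lam <- col$lambda
        ll_old <- -Inf   # the merge may move loglik by O(radius^2)
      }
    }
    ll <- sum(ct$m * log(f))
    # monotone up to accumulated rounding noise (relative to |loglik|)
    if (ll < ll_old - (1e-9 + 1e-9 * abs(ll)))
      stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
    if (ll - ll_old < em_tol || it >= max_iter) break
    ll_old <- ll
  }
  list(q = q / sum(q), lambda = lam, n_iter = it, loglik = ll)
}

# Merge support points closer than the collapse radius (default
# 0.05 * (1 + lambda_lower)); weights summed, rates weight-averaged.
collapse_support <- function(q, lam, collapse_delta = NULL) {
  o <- order(lam)
  q <- q[o]; lam <- lam[o]
  merged <- FALSE
  repeat {
    if (length(lam) == 1L) break
    gaps <- diff(lam)
    radius <- if (is.null(collapse_delta)) 0.05 * (1 + lam[-length(lam)])
              else rep(collapse_delta, length(gaps))
    j <- which(gaps < radius)
    if (length(j) == 0L) break
    j <- j[1]
    qq <- q[j] + q[j + 1]
    ll <- (q[j] * lam[j] + q[j + 1] * lam[j + 1]) / qq
    q <- c(q[seq_len(j - 1)], qq, q[-seq_len(j + 1)])
    lam <- c(lam[seq_len(j - 1)], ll, lam[-seq_len(j + 1)])
    merged <- TRUE
  }
  list(q = q, lambda = lam, merged = merged)
}

#' Fit a Poisson mixture with a fixed number of components
#'
#' Plain EM at a user-chosen `k`, used as the null model of the bootstrap
#' likelihood-ratio test. Rates are initialised at spread quantiles of the
#' counts.
#'
#' @param counts a [count_vector()] or numeric counts.
#' @param k number of components.
#' @param em_tol,max_iter EM stopping rule.
#' @return list with `mixture`, `loglik`, `n_iter`.
#' @export
fit_mixture_k <- function(counts, k, em_tol = 1e-8, max_iter = 2000) {
  window <- if (inherits(counts, "count_vector")) counts$window else 1
  x <- as_counts(counts)
  stopifnot(k >= 1)
  ct <- count_table(x)
  if (k == 1 || length(ct$v) == 1L) {
    mix <- mixture(1, mean(x), window = window)
    return(list(mixture = mix, loglik = loglik_mixture(x, mix), n_iter = 0L))
  }
  lam0 <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k))
  lam0 <- lam0 + seq(0, 1e-3, length.out = k)   # break ties
  em <- em_refine(ct, rep(1 / k, k), lam0, em_tol = em_tol,
                  max_iter = max_iter)
  mix <- make_mixture(em$q, em$lambda, window = window)
  list(mixture = mix, loglik = loglik_mixture(x, mix), n_iter = em$n_iter)
}

#' Parametric bootstrap likelihood-ratio test of a k-component fit
#'
#' Tests whether a `k_null`-component Poisson mixture is an acceptable
#' description of the counts, against the unconstrained NPMLE. The observed
#' statistic is `2 (loglik_NPMLE - loglik_null)`; its null distribution is
#' approximated by refitting both models on `n_boot` datasets simulated from
#' the null fit, and `p = (1 + #[T* >= T_obs]) / (n_boot + 1)`.
#'
#' @param counts a [count_vector()] or numeric counts.
#' @param k_null components under the null (>= 1).
#' @param n_boot bootstrap replicates (>= 19, for p-value resolution).
#' @param seed optional integer seed.
#' @return an object of class `gof_report`: list with `statistic`,
#'   `p_value`, `k_null`, `k_alt` (NPMLE support size), `n_boot`.
#' @export
bootstrap_lrt <- function(counts, k_null = 1, n_boot = 99, seed = NULL) {
  if (n_boot < 19) stop("`n_boot` must be at least 19")
  if (k_null < 1) stop("`k_null` must be at least 1")
  x <- as_counts(counts)
  if (!is.null(seed)) set.seed(seed)
  null_fit <- fit_mixture_k(x, k_null)
  alt_fit <- fit_npmle(x)
  t_obs <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  n <- length(x)
  t_star <- vapply(seq_len(n_boot), function(b) {
    xb <- simulate_counts(null_fit$mixture, n)$counts
    nb <- fit_mixture_k(xb, k_null)
    ab <- fit_npmle(xb)
    max(0, 2 * (ab$loglik - nb$loglik))
  }, numeric(1))
  structure(
    list(statistic = t_obs,
         p_value = (1 + sum(t_star >= t_obs)) / (n_boot + 1),
         k_null = k_null, k_alt = alt_fit$mixture$k, n_boot = n_boot,
         boot_stats = t_star),
    class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf(
    "<gof_report> bootstrap LRT: k_null = %d vs NPMLE (k = %d)\n  statistic = %.4f, p = %.4f (%d replicates)\n",
    x$k_null, x$k_alt, x$statistic, x$p_value, x$n_boot))
  invisible(x)
}
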