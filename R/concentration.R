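#' Rare Event Concentration Coefficient
#'
#' The RECC is the Gini coefficient of the fitted distribution of per-unit
#' event rates:
#' \deqn{RECC = \frac{\sum_i \sum_j q_i q_j |\lambda_i - \lambda_j|}
#'                  {2 \sum_i q_i \lambda_i}.}
#' Zero means homogeneous rates; values near one mean the events concentrate
#' in a small share of units. Unlike a Gini computed on raw counts, it is
#' not inflated by the abundance of zero counts in rare-event data.
#'
#' @param mix a [mixture()].
#' @return a value in `[0, 1)`. An all-zero-rate mixture is perfectly
#'   homogeneous; its RECC is defined as 0, with a warning.
#' @examples
#' recc(mixture(c(0.5, 0.5), c(0, 2)))  # 0.5
#' @export
recc <- function(mix) {
  stopifnot(inherits(mix, "mixture"))
  mean_rate <- sum(mix$q * mix$lambda)
  if (mean_rate == 0) {
    warning("all rates are zero; RECC defined as 0 (perfect homogeneity)")
    return(0)
  }
  num <- sum(outer(mix$q, mix$q) * abs(outer(mix$lambda, mix$lambda, "-")))
  num / (2 * mean_rate)
}

#' Lorenz curve of a rate distribution
#'
#' With groups ordered by increasing rate, vertex `m` is
#' `(sum_{j<=m} q_j, sum_{j<=m} q_j lambda_j / mean rate)`: the cumulative
#' share of units against the cumulative share of the total rate they carry.
#' The curve is piecewise linear between vertices; the RECC equals twice the
#' area between the curve and the diagonal.
#'
#' @param mix a [mixture()].
#' @return an object of class `lorenz_curve`: a data.frame with columns
#'   `u` (cumulative unit share) and `v` (cumulative rate share), beginning
#'   at (0,0) and ending at (1,1).
#' @export
lorenz <- function(mix) {
  stopifnot(inherits(mix, "mixture"))
  mean_rate <- sum(mix$q * mix$lambda)
  if (mean_rate == 0) {
    warning("all rates are zero; Lorenz curve degenerates to the diagonal")
    df <- data.frame(u = c(0, 1), v = c(0, 1))
  } else {
    df <- data.frame(u = c(0, cumsum(mix$q)),
                     v = c(0, cumsum(mix$q * mix$lambda) / mean_rate))
    df$u[nrow(df)] <- 1; df$v[nrow(df)] <- 1   # exact endpoints
  }
  class(df) <- c("lorenz_curve", "data.frame")
  df
}

#' Area-based Gini of a Lorenz curve
#'
#' Twice the area between the diagonal and the curve, computed exactly by
#' trapezoids on the vertex set (the curve is piecewise linear, so no
#' quadrature is involved). Equals [recc()] of the generating mixture up to
#' rounding error.
#'
#' @param lc a [lorenz()] curve.
#' @return value in `[0, 1)`.
#' @export
lorenz_gini <- function(lc) {
  stopifnot(inherits(lc, "lorenz_curve"))
  u <- lc$u; v <- lc$v
  area_under <- sum(diff(u) * (v[-length(v)] + v[-1]) / 2)
  2 * (0.5 - area_under)
}

#' Gini coefficient of raw counts
#'
#' The standard Gini `sum_ij |H_i - H_j| / (2 N sum H)` applied directly to
#' the observed counts. For rare events this is dominated by the share of
#' zero-count units and overstates concentration; it is provided for
#' comparison with the RECC, not as the headline metric.
#'
#' @param counts a [count_vector()] or numeric counts.
#' @return value in `[0, 1]`; all-zero counts give 0 with a warning.
#' @export
naive_gini <- function(counts) {
  x <- as_counts(counts)
  n <- length(x)
  tot <- sum(x)
  if (tot == 0) {
    warning("all counts are zero; Gini defined as 0")
    return(0)
  }
  xs <- sort(x)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  sum_abs <- 2 * sum((2 * seq_len(n) - n - 1) * xs)
  sum_abs / (2 * n * tot)
}

#' Minimum achievable share of zero-count units
#'
#' With `n_events` events spread over `n_units` units, at least
#' `(n_units - n_events) / n_units` of the units must have a zero count
#' (attained when every event occupies a distinct unit). This floor drives
#' the count-based Gini of rare events regardless of how the events are
#' actually distributed.
#'
#' @param n_units number of spatial units (>= 1).
#' @param n_events number of events (>= 0).
#' @return the floor, a fraction in `[0, 1]`.
#' @examples
#' zero_floor(242, 49)  # 0.7975...
#' @export
zero_floor <- function(n_units, n_events) {
  stopifnot(n_units >= 1, n_events >= 0)
  max(0, (n_units - n_events) / n_units)
}

#' Exposure-normalised accident risk and lethality
#'
#' Converts per-road totals into flow-normalised rates: `risk` is accidents
#' per million vehicle-km per year, `lethality` is fatalities per million
#' vehicle-km per year. These make roads of different length and traffic
#' volume comparable.
#'
#' @param table data.frame with columns `road`, `length` (km), `flow`
#'   (million vehicle-km per year), `accidents`, `fatalities`.
#' @return the input with `risk` and `lethality` columns appended, class
#'   `exposure_risk`.
#' @export
exposure_risk <- function(table) {
  req <- c("road", "length", "flow", "accidents", "fatalities")
  if (!all(req %in% names(table)))
    stop("exposure table needs columns: ", paste(req, collapse = ", "))
  if (any(table$flow <= 0)) stop("all flows must be positive")
  if (any(table$length < 0) || any(table$accidents < 0) ||
      any(table$fatalities < 0))
    stop("lengths and counts must be non-negative")
  table$risk <- table$accidents / table$flow
  table$lethality <- table$fatalities / table$flow
  class(table) <- c("exposure_risk", "data.frame")
  table
}

#' Pairwise risk or lethality ratio between two roads
#'
#' @param er an [exposure_risk()] table.
#' @param a,b road names (matched against the `road` column).
#' @param what `"risk"` or `"lethality"`.
#' @return the ratio `rate_a / rate_b` (full precision; the conventional
#'   rendering rounds to one decimal).
#' @export
risk_ratio <- function(er, a, b, what = c("risk", "lethality")) {
  stopifnot(inherits(er, "exposure_risk"))
  what <- match.arg(what)
  ia <- match(a, er$road); ib <- match(b, er$road)
  if (is.na(ia) || is.na(ib))
    stop("road not found in exposure table")
  er[[what]][ia] / er[[what]][ib]
}

#' Full concentration report for a count vector
#'
#' Fits the NPMLE mixture, then bundles the RECC, the naive count Gini, the
#' mean rate, the Lorenz curve and (optionally) a Monte Carlo confidence
#' interval for the RECC.
#'
#' @param counts a [count_vector()] or numeric counts.
#' @param ci compute a [recc_confidence_interval()]?
#' @param reps,level,seed forwarded to the confidence interval.
#' @param ... forwarded to [fit_npmle()].
#' @return an object of class `concentration_report`: list with `recc`,
#'   `naive_gini`, `mean_rate`, `lorenz`, `mixture`, `fit`, `ci`.
#' @export
concentration_report <- function(counts, ci = FALSE, reps = 199,
                                 level = 0.95, seed = NULL, ...) {
  cv <- if (inherits(counts, "count_vector")) counts else count_vector(counts)
  fit <- fit_npmle(cv, ...)
  mix <- fit$mixture
  interval <- NULL
  if (ci)
    interval <- recc_confidence_interval(mix, cv$n_units, reps = reps,
                                         level = level, seed = seed)
  structure(
    list(recc = recc(mix),
         naive_gini = naive_gini(cv),
         mean_rate = sum(mix$q * mix$lambda),
         lorenz = lorenz(mix),
         mixture = mix,
         fit = fit,
         ci = interval),
    class = "concentration_report")
}

#' @export
print.concentration_report <- function(x, ...) {
  cat(sprintf("<concentration_report>\n  RECC       = %.4f\n", x$recc))
  if (!is.null(x$ci))
    cat(sprintf("    %.0f%% CI  = [%.4f, %.4f]\n",
                100 * x$ci$level, x$ci$lo, x$ci$hi))
  cat(sprintf("  naive Gini = %.4f\n  mean rate  = %.4f per unit per window\n",
              x$naive_gini, x$mean_rate))
  cat(sprintf("  mixture: %d group(s)\n", x$mixture$k))
  invisible(x)
}
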