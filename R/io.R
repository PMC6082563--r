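#' Read point events from CSV
#'
#' Expects RFC-4180 CSV with mandatory numeric `x`, `y` columns (planar
#' metres) and optional `severity` (labels `fatal` / `serious` / `slight`,
#' case-insensitive) and `date` columns. Rows whose coordinates fail
#' numeric parsing are dropped with a warning (or are an error in strict
#' mode).
#'
#' @param path CSV path.
#' @param severity_filter optional character vector of severity labels to
#'   retain (case-insensitive). Unknown labels in the data pass through
#'   untouched but are excluded by any filter.
#' @param strict error on malformed rows instead of dropping them.
#' @return data.frame of events with attribute `n_dropped` (malformed rows).
#' @export
read_point_events <- function(path, severity_filter = NULL, strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("x", "y"), names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- is.na(x) | is.na(y) | !is.finite(x) | !is.finite(y)
  if (any(bad)) {
    if (strict) stop(sum(bad), " row(s) with malformed coordinates")
    warning(sum(bad), " row(s) with malformed coordinates were skipped")
  }
  df$x <- x; df$y <- y
  df <- df[!bad, , drop = FALSE]
  if (!is.null(severity_filter)) {
    if (!"severity" %in% names(df))
      stop("severity filter requested but no `severity` column present")
    keep <- tolower(df$severity) %in% tolower(severity_filter)
    df <- df[keep, , drop = FALSE]
  }
  attr(df, "n_dropped") <- sum(bad)
  df
}

#' Read linear (kilometre-post) events from CSV
#'
#' Expects a CSV with a mandatory numeric `km` column: each row is one
#' event at that distance from the road origin.
#'
#' @param path CSV path.
#' @param strict error on malformed or negative positions instead of
#'   dropping them.
#' @return numeric vector of positions with attribute `n_dropped`.
#' @export
read_linear_events <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"km" %in% names(df))
    stop("missing mandatory column: km (found: ",
         paste(names(df), collapse = ", "), ")")
  km <- suppressWarnings(as.numeric(df$km))
  bad <- is.na(km) | !is.finite(km) | km < 0
  if (nrow(df) == 0) warning("empty input file")
  if (any(bad)) {
    if (strict) stop(sum(bad), " malformed or negative position(s)")
    warning(sum(bad), " malformed or negative position(s) were skipped")
  }
  out <- km[!bad]
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Read a road exposure table from CSV
#'
#' Columns: `road`, `length` (km), `flow` (million vehicle-km per year),
#' `accidents`, `fatalities`.
#'
#' @param path CSV path.
#' @return data.frame suitable for [exposure_risk()].
#' @export
read_exposure_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("road", "length", "flow", "accidents", "fatalities")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Serialise a mixture to JSON
#'
#' Writes `{k, q, lambda, window_years}`; [read_mixture_json()] restores an
#' identical [mixture()].
#'
#' @param mix a [mixture()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mixture_json <- function(mix, path) {
  stopifnot(inherits(mix, "mixture"))
  jsonlite::write_json(
    list(k = mix$k, q = mix$q, lambda = mix$lambda,
         window_years = mix$window),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_json
#' @export
read_mixture_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mixture(obj$q, obj$lambda, window = as.numeric(obj$window_years))
}

#' Write an analysis object to disk
#'
#' JSON for machine consumption, or an aligned text table (group / size % /
#' rate) for mixtures in human-readable form.
#'
#' @param x a [mixture()], `npmle_fit`, `concentration_report`, `recc_ci`
#'   or `csr_test` object.
#' @param path output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(render_text(x), path)
    return(invisible(path))
  }
  jsonlite::write_json(as_report_list(x), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

as_report_list <- function(x) {
  if (inherits(x, "mixture"))
    return(list(type = "mixture", k = x$k, q = x$q, lambda = x$lambda,
                window_years = x$window))
  if (inherits(x, "npmle_fit"))
    return(list(type = "npmle_fit", mixture = as_report_list(x$mixture),
                loglik = x$loglik, n_iter_vem = x$n_iter_vem,
                n_iter_em = x$n_iter_em, max_gradient = x$max_gradient,
                converged = x$converged))
  if (inherits(x, "concentration_report"))
    return(list(type = "concentration_report", recc = x$recc,
                naive_gini = x$naive_gini, mean_rate = x$mean_rate,
                lorenz = list(u = x$lorenz$u, v = x$lorenz$v),
                mixture = as_report_list(x$mixture),
                ci = if (is.null(x$ci)) NULL else as_report_list(x$ci)))
  if (inherits(x, "recc_ci"))
    return(list(type = "recc_ci", observed = x$observed, lo = x$lo,
                hi = x$hi, level = x$level, reps = x$reps,
                effective_reps = x$effective_reps, seed = x$seed,
                replicate_values = x$replicate_values))
  if (inherits(x, "csr_test"))
    return(list(type = "csr_test", n = x$n, R = x$R, mean_nn = x$mean_nn,
                expected_nn = x$expected_nn, z = x$z,
                p_normal = x$p_normal, p_mc = x$p_mc, p_value = x$p_value,
                null = x$null, n_sims = x$n_sims,
                alternative = x$alternative))
  stop("don't know how to serialise objects of class ",
       paste(class(x), collapse = "/"))
}

render_text <- function(x) {
  mix <- if (inherits(x, "mixture")) x
         else if (inherits(x, "npmle_fit")) x$mixture
         else if (inherits(x, "concentration_report")) x$mixture
         else stop("text rendering is available for mixture-like objects")
  header <- sprintf("%-6s %-8s %s", "group", "size %", "rate")
  rows <- sprintf("%-6d %-8s %s", seq_len(mix$k),
                  formatC(100 * mix$q, format = "f", digits = 1),
                  formatC(mix$lambda, format = "f", digits = 3))
  c(header, rows)
}

#' Write a Lorenz curve as CSV
#'
#' Columns `u` (cumulative unit share) and `v` (cumulative rate share);
#' first row (0,0), last row (1,1).
#'
#' @param lc a [lorenz()] curve.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lorenz_csv <- function(lc, path) {
  stopifnot(inherits(lc, "lorenz_curve"))
  utils::write.csv(as.data.frame(unclass(lc))[, c("u", "v")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
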