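# Regression of predictor scores against binding measurements.
#
# Fraction bound F relates to the dissociation constant by
# Kd = [ligand](1 - F)/F.  Modelling occupancy as a linear function of the
# PBM-mapping score x, F = a*x + b, gives the nonlinear model
# Kd = z(1 - (a*x + b))/(a*x + b) with the ligand concentration z treated
# as a free scale parameter.

#' Linear fit of score versus fraction bound
#'
#' Ordinary least squares of fraction bound on score.  Named probes can be
#' excluded from the fit (non-binders are plotted on the x-axis but not
#' used for the r-squared) and are carried in the result.
#'
#' @param points data.frame with columns `score`, `fraction_bound` and
#'   optionally `name`.
#' @param exclude Character vector of probe names to exclude from fitting.
#' @return A `linear_fit`: `a` (slope), `b` (intercept), `r_squared`, `n`,
#'   `excluded` (data.frame), `fit` (the lm object).
#' @export
fit_score_vs_fraction_bound <- function(points, exclude = character()) {
  stopifnot(all(c("score", "fraction_bound") %in% names(points)))
  if (is.null(points$name)) points$name <- paste0("p", seq_len(nrow(points)))
  fb <- points$fraction_bound
  if (any(!is.na(fb) & (fb < 0 | fb > 1)))
    stop("fraction_bound outside [0, 1]")
  keep <- !(points$name %in% exclude) & !is.na(fb) & !is.na(points$score)
  used <- points[keep, , drop = FALSE]
  if (nrow(used) < 3L) stop("need >= 3 non-excluded points, got ", nrow(used))
  if (stats::sd(used$score) == 0) stop("degenerate fit: zero score variance")
  fit <- stats::lm(fraction_bound ~ score, data = used)
  structure(list(a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 # suppressWarnings: summary.lm warns on an exactly perfect fit
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = nrow(used),
                 excluded = points[!keep, , drop = FALSE],
                 fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: F = %.4f * score + %.4f,  r^2 = %.4f  (n = %d",
              x$a, x$b, x$r_squared, x$n))
  if (nrow(x$excluded)) cat(",", nrow(x$excluded), "excluded")
  cat(")\n")
  invisible(x)
}

#' Predicted Kd under the occupancy model
#'
#' @param score Predictor scores.
#' @param a,b Linear score-to-occupancy parameters.
#' @param z Ligand-concentration scale.
#' @return `z * (1 - (a*score + b)) / (a*score + b)`.
#' @export
kd_model <- function(score, a, b, z) {
  occ <- a * score + b
  z * (1 - occ) / occ
}

#' Nonlinear fit of score versus Kd
#'
#' Least-squares fit of `Kd = z(1 - (a x + b))/(a x + b)` on the Kd scale
#' using Levenberg-Marquardt with multi-start initialisation: `z` starts on
#' a log-spaced grid bracketing the observed Kd range, and for each `z`
#' the implied occupancies `z/(z + Kd)` seed `a` and `b` by linear
#' regression.  The best converged start wins.
#'
#' @param points data.frame with columns `score` and `kd` (kd > 0).
#' @param init Optional named list/vector with elements a, b, z prepended
#'   to the start list.
#' @param n_starts Number of z grid points (default 16).
#' @return A `kd_fit`: `a`, `b`, `z`, `r_squared` (Kd scale),
#'   `r_squared_occupancy`, `residuals`, `converged`, `boundary`
#'   (TRUE when the fitted occupancy a*x+b leaves (0, 1] over the data
#'   range), `fit` (the nls object).
#' @export
fit_kd <- function(points, init = NULL, n_starts = 16L) {
  stopifnot(all(c("score", "kd") %in% names(points)))
  points <- points[!is.na(points$score) & !is.na(points$kd), , drop = FALSE]
  if (nrow(points) < 4L) stop("need >= 4 points for the Kd fit")
  if (any(points$kd <= 0)) stop("kd values must be positive")
  x <- points$score; kd <- points$kd

  starts <- list()
  if (!is.null(init)) starts[[1]] <- as.list(init)[c("a", "b", "z")]
  zgrid <- exp(seq(log(min(kd) / 3), log(max(kd) * 3), length.out = n_starts))
  for (z0 in zgrid) {
    occ <- z0 / (z0 + kd)
    cf <- tryCatch(stats::coef(stats::lm(occ ~ x)), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    starts[[length(starts) + 1L]] <- list(a = unname(cf[2]), b = unname(cf[1]),
                                          z = z0)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(kd ~ z * (1 - (a * x + b)) / (a * x + b),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Kd fit failed to converge from any start")
  cf <- stats::coef(best$fit)
  occ_range <- range(cf["a"] * x + cf["b"])
  boundary <- occ_range[1] <= 0 || occ_range[2] > 1
  if (boundary)
    warning("boundary solution: fitted occupancy a*x+b leaves (0, 1] ",
            "over the data range")
  res <- stats::residuals(best$fit)
  r2 <- 1 - sum(res^2) / sum((kd - mean(kd))^2)
  occ_obs <- cf["z"] / (cf["z"] + kd)
  occ_fit <- cf["a"] * x + cf["b"]
  r2occ <- 1 - sum((occ_obs - occ_fit)^2) / sum((occ_obs - mean(occ_obs))^2)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), z = unname(cf["z"]),
                 r_squared = r2, r_squared_occupancy = unname(r2occ),
                 residuals = as.numeric(res),
                 converged = isTRUE(best$fit$convInfo$isConv),
                 boundary = boundary, fit = best$fit),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Kd fit: Kd = z(1-(ax+b))/(ax+b) with a = %.4g, b = %.4g, z = %.4g\n",
              x$a, x$b, x$z))
  cat(sprintf("  r^2 (Kd scale) = %.4f; converged: %s%s\n", x$r_squared,
              x$converged, if (x$boundary) "; BOUNDARY solution" else ""))
  invisible(x)
}

#' Window-size sweep against fraction bound
#'
#' Scores every probe with the moving-average scanner at each window size,
#' fits fraction bound on the score, and identifies the window with the
#' highest r-squared.  Fit failures for individual windows are recorded
#' and the sweep continues.
#'
#' @param probes data.frame with columns name, sequence, fraction_bound.
#' @param table An [escore_table].
#' @param windows Integer vector of window sizes (default
#'   `c(1, 3, 5, 6, 7, 8)`).
#' @param exclude Probe names excluded from fitting (non-binders).
#' @return A `window_sweep`: `results` data.frame (window, a, b,
#'   r_squared, n, error), `best_window`, `fits` (list of `linear_fit`).
#' @export
window_size_sweep <- function(probes, table, windows = c(1L, 3L, 5L, 6L, 7L, 8L),
                              exclude = character()) {
  stopifnot(inherits(table, "escore_table"))
  arr <- build_dense_array(table)
  fits <- list()
  rows <- lapply(windows, function(W) {
    sc <- vapply(probes$sequence, function(s)
      score_probe(s, arr, scan_config(window = W))$pbm_mapping_score,
      numeric(1), USE.NAMES = FALSE)
    pts <- data.frame(name = probes$name, score = sc,
                      fraction_bound = probes$fraction_bound)
    f <- tryCatch(fit_score_vs_fraction_bound(pts, exclude = exclude),
                  error = function(e) e)
    if (inherits(f, "error"))
      return(data.frame(window = W, a = NA, b = NA, r_squared = NA,
                        n = NA, error = conditionMessage(f)))
    fits[[as.character(W)]] <<- f
    data.frame(window = W, a = f$a, b = f$b, r_squared = f$r_squared,
               n = f$n, error = NA_character_)
  })
  results <- do.call(rbind, rows)
  best <- results$window[which.max(results$r_squared)]
  structure(list(results = results, best_window = best, fits = fits),
            class = "window_sweep")
}

#' @export
print.window_sweep <- function(x, ...) {
  cat("window-size sweep (moving average of W overlapping octamers):\n")
  print(x$results[, c("window", "a", "b", "r_squared", "n")], row.names = FALSE)
  cat("best window:", x$best_window, "\n")
  invisible(x)
}

#' Compare scoring methods by fit to fraction bound
#'
#' @param probes data.frame with columns name, sequence, fraction_bound.
#' @param scorers Named list of functions `function(sequence) -> numeric`.
#' @param exclude Probe names excluded from fitting.
#' @return data.frame (scorer, a, b, r_squared, n, rank, error), ranked by
#'   r-squared; scorer failures are recorded, not fatal.
#' @export
compare_methods <- function(probes, scorers, exclude = character()) {
  if (length(scorers) < 2L) stop("need >= 2 scorers to compare")
  if (is.null(names(scorers)) || any(names(scorers) == ""))
    stop("scorers must be a named list")
  rows <- lapply(names(scorers), function(nm) {
    out <- tryCatch({
      sc <- vapply(probes$sequence, scorers[[nm]], numeric(1),
                   USE.NAMES = FALSE)
      f <- fit_score_vs_fraction_bound(
        data.frame(name = probes$name, score = sc,
                   fraction_bound = probes$fraction_bound),
        exclude = exclude)
      data.frame(scorer = nm, a = f$a, b = f$b, r_squared = f$r_squared,
                 n = f$n, error = NA_character_)
    }, error = function(e)
      data.frame(scorer = nm, a = NA, b = NA, r_squared = NA, n = NA,
                 error = conditionMessage(e)))
    out
  })
  df <- do.call(rbind, rows)
  df$rank <- rank(-df$r_squared, ties.method = "min", na.last = "keep")
  df[order(df$rank), ]
}
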