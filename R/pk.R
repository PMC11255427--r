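# Noncompartmental pharmacokinetic analysis: Cmax/Tmax from the raw
# points, terminal elimination rate by log-linear ordinary least
# squares, t1/2 = ln 2 / lambda_z, and AUC by the linear trapezoid.

#' Select terminal points for the elimination fit
#'
#' @param profile a [pk_profile()].
#' @param rule `"last_k"` (the final `k` points, default `k = 3`) or
#'   `"best_adj_r2"` (scan suffixes of at least 3 points strictly after
#'   Tmax and return the one maximizing the adjusted R^2 of the
#'   log-linear fit; ties break toward more points).
#' @param k number of points for `"last_k"` (>= 2).
#' @return Integer indices into the profile.
#' @export
select_terminal_points <- function(profile, rule = c("last_k", "best_adj_r2"),
                                   k = 3) {
  stopifnot(inherits(profile, "pk_profile"))
  rule <- match.arg(rule)
  n <- length(profile$times_min)
  if (rule == "last_k") {
    if (k < 2) stop("select_terminal_points: k must be >= 2")
    if (n < k) stop("select_terminal_points: profile has fewer than k points")
    return((n - k + 1L):n)
  }
  tmax_i <- which.max(profile$conc_ng_per_ml)
  cand <- (tmax_i + 1L):n
  if (tmax_i >= n || length(cand) < 3L)
    stop("select_terminal_points: need >= 3 points after Tmax for best_adj_r2")
  best <- NULL; best_r2 <- -Inf
  for (s in cand[seq_len(length(cand) - 2L)]) {
    idx <- s:n
    if (any(profile$conc_ng_per_ml[idx] <= 0)) next
    fit <- stats::lm(log(profile$conc_ng_per_ml[idx]) ~
                       profile$times_min[idx])
    # suppress the "essentially perfect fit" note on exact data
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    # >= : ties (and near-ties within 1e-12) break toward longer suffixes,
    # scanned from the longest first
    if (r2 > best_r2 + 1e-12) {
      best_r2 <- r2; best <- idx
    }
  }
  if (is.null(best))
    stop("select_terminal_points: no valid terminal subset")
  best
}

#' Noncompartmental PK analysis
#'
#' @param profile a [pk_profile()] with at least 3 points.
#' @param terminal_rule passed to [select_terminal_points()].
#' @param k terminal-point count for the `"last_k"` rule.
#' @return Object of class `nca_result`: `cmax`, `tmax`, `lambda_z`
#'   (1/min), `t_half` (min, `= ln(2)/lambda_z`), `auc_last`
#'   (linear trapezoid over all points, conc x min), and
#'   `terminal_points_used` (times of the fitted points).
#' @export
nca <- function(profile, terminal_rule = c("last_k", "best_adj_r2"), k = 3) {
  stopifnot(inherits(profile, "pk_profile"))
  terminal_rule <- match.arg(terminal_rule)
  t <- profile$times_min
  conc <- profile$conc_ng_per_ml
  if (length(t) < 3L) stop("nca: need at least 3 points")
  idx <- select_terminal_points(profile, terminal_rule, k = k)
  if (any(conc[idx] <= 0))
    stop("nca: non-positive concentrations in terminal fit")
  fit <- stats::lm(log(conc[idx]) ~ t[idx])
  lambda_z <- -unname(stats::coef(fit)[2])
  if (lambda_z <= 0)
    stop("nca: no elimination phase (non-negative terminal slope)")
  i_max <- which.max(conc)
  structure(list(
    cmax = conc[i_max],
    tmax = t[i_max],
    lambda_z = lambda_z,
    t_half = log(2) / lambda_z,
    auc_last = sum(diff(t) * (conc[-1] + conc[-length(conc)]) / 2),
    terminal_points_used = t[idx]),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(paste0("<nca_result> Cmax %.4g at Tmax %g min | lambda_z ",
                     "%.5g /min | t1/2 %.4g min | AUC(0-last) %.5g\n"),
              x$cmax, x$tmax, x$lambda_z, x$t_half, x$auc_last))
  cat("  terminal points at t =",
      paste(x$terminal_points_used, collapse = ", "), "min\n")
  invisible(x)
}
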