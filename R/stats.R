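#' Paired t test on baseline/follow-up values
#'
#' Classical paired t on the per-eye differences `d = followup - baseline`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-sided p. Degenerate
#' differences follow the limiting conventions: all differences exactly zero
#' gives `t = 0, p = 1`; zero variance with a nonzero mean gives an infinite
#' statistic and `p = 0`.
#'
#' @param baseline,followup numeric vectors of equal length `n >= 2`.
#' @return a list of class `astig_test` with `statistic`, `df`, `p.value`,
#'   `n`, `estimate` (mean difference) and `method`.
#' @examples
#' paired_t(c(0, 0, 0), c(0.1, 0.2, 0.3))
#' @export
paired_t <- function(baseline, followup) {
  if (length(baseline) != length(followup)) {
    stop("paired_t(): baseline and followup must have equal length")
  }
  n <- length(baseline)
  if (n < 2) stop("paired_t(): need n >= 2 pairs")
  d <- followup - baseline
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    tstat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    tstat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  }
  structure(list(statistic = tstat, df = n - 1, p.value = p, n = n,
                 estimate = m, method = "paired t test"),
            class = "astig_test")
}

#' @export
print.astig_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$F)) {
    cat(sprintf("  T2 = %.4g, F = %.4g, df = (%g, %g), p = %.4g, n = %d\n",
                x$statistic, x$F, x$df[1], x$df[2], x$p.value, x$n))
  } else {
    cat(sprintf("  t = %.4g, df = %g, p = %.4g, n = %d\n",
                x$statistic, x$df, x$p.value, x$n))
  }
  invisible(x)
}

#' One-sample Hotelling T-squared on paired differences
#'
#' The bivariate analogue of the paired t test for a two-timepoint
#' within-eye design: with `d_i` the per-eye difference vectors (e.g.
#' `(delta Rx, delta Ry)`), `T2 = n * dbar' S^-1 dbar` where `S` is the
#' sample covariance of the differences, and
#' `F = (n - p) / (p (n - 1)) * T2` follows an F(p, n - p) distribution
#' under the null of zero mean change. This is the standard reduction of a
#' repeated-measures MANOVA with two timepoints.
#'
#' A one-column input is accepted and reproduces the squared paired t
#' statistic exactly.
#'
#' @param d a numeric matrix (or data frame) with one row per pair and one
#'   column per component; `n >= p + 1` rows.
#' @return a list of class `astig_test` with `statistic` (T2), `F`, `df`
#'   (length 2), `p.value`, `n` and `estimate` (mean difference vector).
#' @examples
#' hotelling_paired(cbind(c(0.1, 0.2, 0, 0.1), c(0, 0.1, -0.1, 0.2)))
#' @export
hotelling_paired <- function(d) {
  d <- as.matrix(d)
  storage.mode(d) <- "double"
  n <- nrow(d)
  p <- ncol(d)
  if (n < p + 1 || n < 3 && p >= 2) {
    stop("hotelling_paired(): need at least p + 1 (and >= 3 for p = 2) pairs")
  }
  dbar <- colMeans(d)
  S <- stats::cov(d)
  if (all(dbar == 0) && all(S == 0)) {
    t2 <- 0
  } else {
    Sinv <- tryCatch(solve(S), error = function(e) {
      stop("hotelling_paired(): singular difference covariance")
    })
    t2 <- drop(n * t(dbar) %*% Sinv %*% dbar)
  }
  Fstat <- (n - p) / (p * (n - 1)) * t2
  pval <- stats::pf(Fstat, p, n - p, lower.tail = FALSE)
  structure(list(statistic = t2, F = Fstat, df = c(p, n - p),
                 p.value = pval, n = n, estimate = dbar,
                 method = "paired Hotelling T-squared"),
            class = "astig_test")
}

#' Monte-Carlo power of the paired bivariate test
#'
#' Simulates cohorts of paired difference vectors from a bivariate normal
#' with the given mean effect and covariance, applies [hotelling_paired()]
#' to each, and reports the rejection fraction at level `alpha` together
#' with a binomial (Wald) confidence interval. Simulation is used because a
#' closed form requires the difference covariance, which real studies often
#' do not report; [power_hotelling_exact()] provides the noncentral-F
#' cross-check when a covariance is assumed.
#'
#' @param effect length-2 numeric, the mean difference vector in diopters
#'   (default `c(0.20, 0.20)`, a conventional clinically meaningful change).
#' @param n pairs per simulated cohort.
#' @param sigma 2x2 symmetric positive-definite covariance of the paired
#'   differences.
#' @param alpha significance level.
#' @param reps number of simulated cohorts (>= 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param conf level of the Monte-Carlo confidence interval on the power.
#' @return a list of class `power_estimate` with `power`, `ci`, `reps`,
#'   `n`, `effect`, `alpha`.
#' @export
power_hotelling_sim <- function(effect = c(0.20, 0.20), n = 60, sigma,
                                alpha = 0.05, reps = 1000, seed = NULL,
                                conf = 0.95) {
  effect <- as.numeric(effect)
  if (length(effect) != 2) stop("effect must have length 2")
  sigma <- as.matrix(sigma)
  check_cov2(sigma)
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  R <- chol(sigma)
  hits <- 0L
  for (r in seq_len(reps)) {
    z <- matrix(stats::rnorm(2 * n), n, 2)
    d <- sweep(z %*% R, 2, effect, "+")
    if (hotelling_paired(d)$p.value < alpha) hits <- hits + 1L
  }
  pw <- hits / reps
  se <- sqrt(pw * (1 - pw) / reps)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(power = pw,
                 ci = c(max(0, pw - zq * se), min(1, pw + zq * se)),
                 se = se, reps = reps, n = n, effect = effect,
                 alpha = alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Simulated power: %.3f (MC CI %.3f-%.3f), n = %d, %d reps\n",
              x$power, x$ci[1], x$ci[2], x$n, x$reps))
  invisible(x)
}

check_cov2 <- function(sigma) {
  if (!all(dim(sigma) == c(2, 2))) stop("sigma must be 2x2")
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("sigma must be positive-definite")
  invisible(sigma)
}

#' Closed-form power of the paired Hotelling test
#'
#' Under a bivariate normal difference model the T-squared statistic follows
#' a scaled noncentral F with noncentrality `n * effect' Sigma^-1 effect`;
#' power is the tail mass of that distribution beyond the critical value.
#' Serves as the analytic cross-check of [power_hotelling_sim()].
#'
#' @inheritParams power_hotelling_sim
#' @return a single power value in \[0, 1\].
#' @export
power_hotelling_exact <- function(effect = c(0.20, 0.20), n = 60, sigma,
                                  alpha = 0.05) {
  effect <- as.numeric(effect)
  sigma <- as.matrix(sigma)
  check_cov2(sigma)
  p <- 2
  ncp <- drop(n * t(effect) %*% solve(sigma) %*% effect)
  fcrit <- stats::qf(1 - alpha, p, n - p)
  stats::pf(fcrit, p, n - p, ncp = ncp, lower.tail = FALSE)
}

#' Bivariate normal confidence ellipse in the double-angle plane
#'
#' Fits an ellipse to a point cloud from its sample mean and covariance.
#' In `"dataset"` mode the squared Mahalanobis radius is the chi-square(2)
#' quantile at `level`, so the ellipse is the region expected to contain
#' that fraction of individual observations; in `"centroid"` mode the
#' quantile is divided by `n`, giving the confidence region for the mean
#' (centroid). Semi-axes and orientation come from the eigendecomposition
#' of the covariance.
#'
#' @param points numeric matrix (or data frame) with columns `(u, v)` and
#'   `n >= 3` rows.
#' @param level coverage probability in (0, 1).
#' @param mode `"dataset"` or `"centroid"`.
#' @return a list of class `ellipse_result` with `center`, `semi_axes`
#'   (major, minor), `angle_deg` (major-axis orientation, degrees
#'   counterclockwise from +u), `level`, `mode`, `n`.
#' @export
confidence_ellipse <- function(points, level = 0.95,
                               mode = c("dataset", "centroid")) {
  mode <- match.arg(mode)
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2) stop("confidence_ellipse(): points must have 2 columns")
  n <- nrow(pts)
  if (n < 3) stop("confidence_ellipse(): need at least 3 points")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) <= max(eg$values) * 1e-10 || max(eg$values) == 0) {
    stop("confidence_ellipse(): degenerate (collinear) point set")
  }
  r2 <- stats::qchisq(level, df = 2)
  if (mode == "centroid") r2 <- r2 / n
  structure(list(center = ctr, semi_axes = sqrt(eg$values * r2),
                 angle_deg = rad2deg(atan2(eg$vectors[2, 1], eg$vectors[1, 1])) %% 180,
                 level = level, mode = mode, n = n),
            class = "ellipse_result")
}

# parametric boundary of an ellipse_result, for plotting
ellipse_path <- function(e, k = 180) {
  t <- seq(0, 2 * pi, length.out = k)
  a <- deg2rad(e$angle_deg)
  x <- e$semi_axes[1] * cos(t)
  y <- e$semi_axes[2] * sin(t)
  cbind(u = e$center[1] + x * cos(a) - y * sin(a),
        v = e$center[2] + x * sin(a) + y * cos(a))
}
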