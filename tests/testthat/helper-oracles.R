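# Independent oracles used across the suite. These deliberately avoid the
# package's double-angle code paths.

# Dioptric power-matrix representation of a pure-cylinder astigmatism:
# the traceless symmetric 2x2 matrix whose +C/2 eigenvector lies along the
# steep meridian. Astigmatisms combine by matrix addition/subtraction.
oracle_power_matrix <- function(magnitude, meridian) {
  t2 <- 2 * meridian * pi / 180
  (magnitude / 2) * matrix(c(cos(t2), sin(t2), sin(t2), -cos(t2)), 2, 2)
}

# recover (magnitude, meridian) from a traceless symmetric matrix via
# eigendecomposition (no atan2-halving involved)
oracle_matrix_to_astig <- function(M) {
  eg <- eigen(M, symmetric = TRUE)
  mag <- eg$values[1] - eg$values[2]
  if (mag < 1e-12) return(c(magnitude = 0, meridian = 0))
  v <- eg$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  c(magnitude = mag, meridian = ang %% 180)
}

oracle_combine <- function(m1, t1, m2, t2, sign = 1) {
  oracle_matrix_to_astig(oracle_power_matrix(m1, t1) +
                           sign * oracle_power_matrix(m2, t2))
}

# brute-force one-sample Hotelling T^2 by explicit matrix algebra
oracle_hotelling <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d); p <- ncol(d)
  dbar <- matrix(colMeans(d), ncol = 1)
  S <- matrix(0, p, p)
  for (i in seq_len(n)) {
    e <- matrix(d[i, ], ncol = 1) - dbar
    S <- S + e %*% t(e)
  }
  S <- S / (n - 1)
  t2 <- n * drop(t(dbar) %*% solve(S) %*% dbar)
  f <- (n - p) / (p * (n - 1)) * t2
  list(t2 = t2, f = f)
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (fixed margins) no more probable
# than the observed one
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  pr <- stats::dhyper(lo:hi, c1, N - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

random_astig <- function(n, max_mag = 5) {
  astigvec::astig(stats::runif(n, 0, max_mag), stats::runif(n, 0, 180))
}

# tiny deterministic cohort for io/pipeline contract tests
tiny_cohort <- function(n_per_group = 4) {
  cfg <- astigvec::default_paper_config()
  for (g in names(cfg$groups)) cfg$groups[[g]]$n <- n_per_group
  astigvec::simulate_cohort(cfg, seed = 99)
}
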