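test_that("paired t matches the worked example and stats::t.test", {
  res <- paired_t(c(0, 0, 0), c(0.1, 0.2, 0.3))
  expect_equal(round(res$statistic, 3), 3.464)
  expect_equal(res$df, 2)
  expect_equal(round(res$p.value, 4), 0.0742)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:50, 1)
    b <- rnorm(n); f <- rnorm(n, 0.2)
    want <- stats::t.test(f, b, paired = TRUE)
    got <- paired_t(b, f)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
})

test_that("paired t degenerate conventions and errors", {
  x <- c(1, 3, -2)   # integer-valued so x + 2 - x is exactly constant
  expect_equal(paired_t(x, x)[c("statistic", "p.value")],
               list(statistic = 0, p.value = 1))
  zv <- paired_t(x, x + 2)     # zero-variance, nonzero mean
  expect_equal(zv$p.value, 0)
  expect_true(is.infinite(zv$statistic))
  expect_error(paired_t(1, 2), "n >= 2")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("paired t is invariant under common affine shifts, consistent power", {
  set.seed(32)
  b <- rnorm(30); f <- b + rnorm(30, 0.1, 0.2)
  r1 <- paired_t(b, f)
  r2 <- paired_t(b + 5, f + 5)
  expect_equal(r1$p.value, r2$p.value)
  # p -> 0 as n grows for a constant shift plus noise
  p_for_n <- function(n) {
    set.seed(33)
    b <- rnorm(n)
    paired_t(b, b + 0.5 + rnorm(n, 0, 0.5))$p.value
  }
  expect_lt(p_for_n(2000), p_for_n(20))
  expect_lt(p_for_n(2000), 1e-10)
})

test_that("Hotelling matches the worked 4-pair example and the oracle", {
  d <- rbind(c(0.1, 0.0), c(0.2, 0.1), c(0.0, -0.1), c(0.1, 0.2))
  want <- oracle_hotelling(d)
  got <- hotelling_paired(d)
  expect_equal(got$statistic, want$t2, tolerance = 1e-12)
  expect_equal(got$F, want$f, tolerance = 1e-12)
  expect_equal(round(got$statistic, 2), 7.00)
  expect_equal(round(got$F, 3), 2.333)
  # F(2,2) tail has the closed form 1/(1+F)
  expect_equal(got$p.value, 1 / (1 + got$F), tolerance = 1e-12)
  expect_equal(round(got$p.value, 3), 0.300)

  set.seed(34)
  for (i in 1:10) {
    n <- sample(4:60, 1)
    d <- cbind(rnorm(n, 0.1), rnorm(n, -0.05))
    want <- oracle_hotelling(d)
    got <- hotelling_paired(d)
    expect_equal(got$statistic, want$t2, tolerance = 1e-10)
    expect_equal(got$p.value,
                 stats::pf(want$f, 2, n - 2, lower.tail = FALSE))
  }
})

test_that("Hotelling degenerate cases, errors, t^2 consistency, rotation", {
  expect_error(hotelling_paired(matrix(rnorm(4), 2, 2)), "pairs")
  coll <- cbind(1:10, 2 * (1:10))   # singular covariance
  expect_error(hotelling_paired(coll), "singular")
  z <- matrix(0, 5, 2)
  zz <- hotelling_paired(z)
  expect_equal(zz$statistic, 0)
  expect_equal(zz$p.value, 1)

  set.seed(35)
  d1 <- rnorm(20, 0.1)
  ht <- hotelling_paired(matrix(d1, ncol = 1))
  tt <- paired_t(rep(0, 20), d1)
  expect_equal(ht$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(ht$p.value, tt$p.value, tolerance = 1e-10)

  d <- cbind(rnorm(25, 0.15), rnorm(25, 0.05))
  base <- hotelling_paired(d)
  for (delta in c(10, 45, 90)) {
    a <- delta * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    rot <- hotelling_paired(d %*% R)
    expect_equal(rot$statistic, base$statistic, tolerance = 1e-9)
    expect_equal(rot$p.value, base$p.value, tolerance = 1e-9)
  }
})

test_that("simulated power: null size, overwhelming effect, exact cross-check", {
  sigma <- diag(0.15^2, 2)
  null_pw <- power_hotelling_sim(c(0, 0), n = 20, sigma = sigma,
                                 reps = 2000, seed = 41)
  expect_lt(abs(null_pw$power - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  big <- power_hotelling_sim(c(1, 1), n = 60, sigma = diag(0.01, 2),
                             reps = 200, seed = 42)
  expect_equal(big$power, 1)
  # simulation agrees with the noncentral-F closed form
  pw <- power_hotelling_sim(c(0.2, 0.2), n = 30, sigma = sigma,
                            reps = 2000, seed = 43)
  exact <- power_hotelling_exact(c(0.2, 0.2), n = 30, sigma = sigma)
  expect_lt(abs(pw$power - exact), 4 * pw$se + 1e-6)
  expect_error(power_hotelling_sim(c(0, 0), sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(power_hotelling_sim(c(0, 0), sigma = diag(2) + 0.1), NA)
})

test_that("confidence ellipse geometry and coverage", {
  # known covariance limit: identity cov, dataset mode, level .95
  set.seed(44)
  n <- 50000
  pts <- cbind(rnorm(n), rnorm(n))
  e <- confidence_ellipse(pts, 0.95, "dataset")
  expect_equal(unname(e$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.02)
  ec <- confidence_ellipse(pts, 0.95, "centroid")
  expect_equal(unname(ec$semi_axes), unname(e$semi_axes) / sqrt(n),
               tolerance = 0.02)
  # empirical dataset coverage near nominal
  maha <- rowSums(pts^2)  # identity-cov Mahalanobis, population
  expect_equal(mean(maha <= qchisq(0.95, 2)), 0.95, tolerance = 0.01)

  expect_error(confidence_ellipse(cbind(1:10, 2 * (1:10))), "collinear")
  expect_error(confidence_ellipse(pts[1:2, ]), "at least 3")
  expect_error(confidence_ellipse(pts, level = 1.2), "level")

  # orientation follows the major axis of an anisotropic cloud
  set.seed(45)
  a <- rnorm(2000, 0, 3); b <- rnorm(2000, 0, 0.3)
  th <- 30 * pi / 180
  rot <- cbind(a * cos(th) - b * sin(th), a * sin(th) + b * cos(th))
  e2 <- confidence_ellipse(rot, 0.95)
  expect_lt(min(abs(e2$angle_deg - 30), abs(e2$angle_deg - 210)), 3)
  expect_gt(e2$semi_axes[1], e2$semi_axes[2])
})
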