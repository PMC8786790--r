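test_that("astig construction normalizes and enforces invariants", {
  a <- astig(c(1, 2, 0), c(185, -10, 37))
  expect_equal(a$meridian, c(5, 170, 0))  # mod 180 and canonical zero
  expect_error(astig(-1, 90), "magnitude")
  expect_error(astig(NA, 90), "non-missing")
})

test_that("double-angle map matches the worked examples and round-trips", {
  expect_equal(to_double_angle(astig(1, 90)), data.frame(u = -1, v = 0))
  expect_equal(to_double_angle(astig(0, 0)), data.frame(u = 0, v = 0))
  da <- to_double_angle(astig(1.5, 110))
  expect_equal(round(unlist(da), 3), c(u = -1.149, v = -0.964))

  expect_equal(from_double_angle(-1, 0), astig(1, 90))
  expect_equal(from_double_angle(0, 0), astig(0, 0))
  b <- from_double_angle(1, 1)
  expect_equal(b$magnitude, sqrt(2), tolerance = 1e-12)
  expect_equal(b$meridian, 22.5)

  set.seed(11)
  a <- random_astig(500)
  rt <- from_double_angle(to_double_angle(a)$u, to_double_angle(a)$v)
  expect_equal(rt$magnitude, a$magnitude, tolerance = 1e-9)
  expect_equal(rt$meridian, a$meridian, tolerance = 1e-7)
  expect_true(all(abs(sqrt(rowSums(to_double_angle(a)^2)) - a$magnitude)
                  < 1e-9))
})

test_that("Naeser polar values follow the WTR/ATR sign rule", {
  expect_equal(naeser_polar(astig(1, 90)), data.frame(rx = 1, ry = 0))
  expect_equal(naeser_polar(astig(1, 0)), data.frame(rx = -1, ry = 0))
  np <- naeser_polar(astig(1.5, 110))
  expect_equal(round(unlist(np), 3), c(rx = 1.149, ry = 0.964))
  # oblique sign convention: steep at 135 gives positive Ry
  expect_gt(naeser_polar(astig(1, 135))$ry, 0)

  set.seed(12)
  a <- random_astig(300)
  np <- naeser_polar(a)
  da <- to_double_angle(a)
  expect_equal(np$rx, -da$u)
  expect_equal(np$ry, -da$v)
  expect_equal(np$rx^2 + np$ry^2, a$magnitude^2, tolerance = 1e-9)
  rt <- from_naeser_polar(np$rx, np$ry)
  expect_equal(rt$magnitude, a$magnitude, tolerance = 1e-9)
})

test_that("combine matches the power-matrix oracle on 1000 random pairs", {
  expect_equal(astig_combine(astig(1, 90), astig(1, 90), -1), astig(0, 0))
  # opposed double-angle vectors cancel to numerical precision
  opp <- astig_combine(astig(1, 90), astig(1, 180), 1)
  expect_lt(opp$magnitude, 1e-12)
  expect_equal(astig_combine(astig(2, 90), astig(1, 180), -1), astig(3, 90))

  set.seed(13)
  a <- random_astig(1000); b <- random_astig(1000)
  sgn <- sample(c(-1, 1), 1000, replace = TRUE)
  for (i in seq_len(1000)) {
    got <- astig_combine(a[i, ], b[i, ], sgn[i])
    want <- oracle_combine(a$magnitude[i], a$meridian[i],
                           b$magnitude[i], b$meridian[i], sgn[i])
    expect_equal(got$magnitude, unname(want["magnitude"]), tolerance = 1e-9)
    if (want["magnitude"] > 1e-9) {
      expect_lt(meridian_difference(got$meridian, want["meridian"]), 1e-6)
    }
  }
})

test_that("combine is commutative for addition and rotation-equivariant", {
  set.seed(14)
  a <- random_astig(50); b <- random_astig(50)
  s1 <- astig_combine(a, b, 1); s2 <- astig_combine(b, a, 1)
  expect_equal(s1, s2)
  for (delta in c(10, 45, 90)) {
    ar <- astig(a$magnitude, a$meridian + delta)
    br <- astig(b$magnitude, b$meridian + delta)
    sr <- astig_combine(ar, br, 1)
    expect_equal(sr$magnitude, s1$magnitude, tolerance = 1e-9)
    nz <- s1$magnitude > 1e-9
    expect_true(all(meridian_difference(sr$meridian[nz],
                                        (s1$meridian + delta)[nz]) < 1e-6))
  }
})

test_that("meridian_difference wraps at 180", {
  expect_equal(meridian_difference(178, 2), 4)
  expect_equal(meridian_difference(45, 135), 90)
  expect_equal(meridian_difference(90, 90), 0)
  set.seed(15)
  t1 <- runif(100, -360, 360); t2 <- runif(100, -360, 360)
  d <- meridian_difference(t1, t2)
  expect_true(all(d >= 0 & d <= 90))
  expect_equal(meridian_difference(t1 + 180, t2), d)  # axial aliasing
})

test_that("classification bands, boundaries and aliasing", {
  expect_equal(as.character(astig_classify(astig(1, c(90, 15, 45, 170)))),
               c("WTR", "ATR", "OBLIQUE", "ATR"))
  # boundary policy: default assigns 30/60/120/150 to the non-oblique class
  expect_equal(as.character(astig_classify(astig(1, c(30, 60, 120, 150)))),
               c("ATR", "WTR", "WTR", "ATR"))
  expect_equal(as.character(astig_classify(astig(1, c(30, 60, 120, 150)),
                                           boundary = "oblique")),
               rep("OBLIQUE", 4))
  expect_error(astig_classify(astig(0, 0)), "unclassifiable")
  set.seed(16)
  th <- runif(200, 0.01, 179.99)
  expect_equal(astig_classify(astig(1, th)),
               astig_classify(astig(1, th + 180)))
})

test_that("centroid is the double-angle mean and obeys the triangle bound", {
  expect_equal(astig_centroid(astig(1, 90))$centroid, astig(1, 90))
  ce <- astig_centroid(astig(c(1, 1), c(90, 0)))
  expect_equal(ce$centroid$magnitude, 0)
  expect_equal(ce$mean_absolute_magnitude, 1)
  ce2 <- astig_centroid(astig(c(2, 1), c(90, 90)))
  expect_equal(ce2$centroid, astig(1.5, 90))
  expect_error(astig_centroid(astig(numeric(0), numeric(0))), "empty")
  set.seed(17)
  for (i in 1:20) {
    ce <- astig_centroid(random_astig(sample(2:40, 1)))
    expect_lte(ce$centroid$magnitude, ce$mean_absolute_magnitude + 1e-12)
  }
})
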