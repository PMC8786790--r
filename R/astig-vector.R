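#' Astigmatism vectors (magnitude and steep meridian)
#'
#' An `astig` object holds one or more astigmatisms, each a non-negative
#' cylinder magnitude (diopters) together with the steep meridian (degrees,
#' normalized into \[0, 180)). It is the unit of all double-angle vector
#' arithmetic: astigmatisms add and subtract linearly once mapped to
#' Cartesian coordinates at twice the meridian angle.
#'
#' A zero-magnitude astigmatism is stored canonically as 0 D at meridian 0,
#' so that equality and round-trips are well defined.
#'
#' @param magnitude numeric vector of cylinder magnitudes in diopters
#'   (must be >= 0).
#' @param meridian numeric vector of steep meridians in degrees; any real
#'   value is accepted and reduced mod 180.
#' @return an object of class `astig` (a data frame with columns
#'   `magnitude` and `meridian`).
#' @examples
#' astig(1.5, 110)
#' astig(c(1, 2), c(90, 185))  # 185 is normalized to 5
#' @export
astig <- function(magnitude, meridian) {
  n <- max(length(magnitude), length(meridian))
  magnitude <- rep_len(as.numeric(magnitude), n)
  meridian <- rep_len(as.numeric(meridian), n)
  if (anyNA(magnitude) || anyNA(meridian)) {
    stop("astig(): magnitude and meridian must be non-missing numerics")
  }
  if (any(magnitude < 0)) {
    stop("astig(): magnitude must be >= 0 (got ",
         min(magnitude), ")")
  }
  meridian <- meridian %% 180
  meridian[meridian == 180] <- 0  # fp: tiny negatives can mod to exactly 180
  meridian[magnitude == 0] <- 0   # canonical zero
  structure(data.frame(magnitude = magnitude, meridian = meridian),
            class = c("astig", "data.frame"))
}

#' @export
print.astig <- function(x, ...) {
  cat(sprintf("<astig: %d vector%s>\n", nrow(x), if (nrow(x) == 1) "" else "s"))
  print(data.frame(magnitude_D = x$magnitude, meridian_deg = x$meridian), ...)
  invisible(x)
}

#' @export
format.astig <- function(x, ...) {
  sprintf("%.2f D @ %g°", x$magnitude, x$meridian)
}

is_astig <- function(x) inherits(x, "astig")

check_astig <- function(x, arg = deparse(substitute(x))) {
  if (!is_astig(x)) stop(arg, " must be an 'astig' object (see astig())")
  x
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Double-angle (Cartesian) components of an astigmatism
#'
#' Maps each astigmatism to the point `(u, v) = (C cos 2theta, C sin 2theta)`
#' of the double-angle plane, the coordinate system of double-angle plots in
#' which astigmatic vector addition and subtraction are ordinary Cartesian
#' operations.
#'
#' @param a an [astig] object.
#' @return a data frame with numeric columns `u` and `v` (diopters).
#' @examples
#' to_double_angle(astig(1, 90))   # u = -1, v = 0
#' @export
to_double_angle <- function(a) {
  check_astig(a)
  t2 <- deg2rad(2 * a$meridian)
  data.frame(u = a$magnitude * cos(t2), v = a$magnitude * sin(t2))
}

#' Reassemble an astigmatism from double-angle components
#'
#' Inverse of [to_double_angle()]: magnitude is the Euclidean norm and the
#' meridian is half the polar angle, normalized into \[0, 180). Components
#' that are both zero give the canonical zero vector (0 D at 0 degrees).
#'
#' @param u,v numeric vectors of double-angle components in diopters.
#' @return an [astig] object.
#' @export
from_double_angle <- function(u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  mag <- sqrt(u^2 + v^2)
  mer <- ifelse(mag == 0, 0, rad2deg(atan2(v, u)) / 2)
  astig(mag, mer)
}

#' Naeser polar values Rx and Ry
#'
#' Decomposes each astigmatism into the vertical/horizontal component Rx and
#' the oblique component Ry of the Naeser--Hjortdal X-Y coordinate analysis:
#' `Rx = C cos(2(theta - 90))`, `Ry = C sin(2(theta - 90))`. A positive Rx
#' indicates with-the-rule astigmatism (steep meridian near 90 degrees), a
#' negative Rx against-the-rule. The pair equals the negated double-angle
#' components. The oblique sign follows the same formula, so Ry > 0 for a
#' steep meridian of 135 degrees.
#'
#' @param a an [astig] object.
#' @return a data frame with numeric columns `rx` and `ry` (diopters).
#' @examples
#' naeser_polar(astig(1, 90))  # rx = +1 (WTR)
#' naeser_polar(astig(1, 0))   # rx = -1 (ATR)
#' @export
naeser_polar <- function(a) {
  da <- to_double_angle(a)
  data.frame(rx = -da$u, ry = -da$v)
}

#' Rebuild an astigmatism from Naeser polar values
#'
#' @param rx,ry numeric vectors of polar values in diopters.
#' @return an [astig] object.
#' @export
from_naeser_polar <- function(rx, ry) {
  from_double_angle(-rx, -ry)
}

#' Add or subtract astigmatisms in double-angle space
#'
#' Vector combination of two astigmatisms: components are added (or
#' subtracted) in the double-angle plane and the result mapped back to
#' magnitude/meridian form. Subtraction with `sign = -1` is the operation
#' behind ocular residual astigmatism (refractive minus corneal).
#'
#' @param a,b [astig] objects (recycled to a common length).
#' @param sign `+1` to add, `-1` to subtract `b` from `a`.
#' @return an [astig] object.
#' @examples
#' astig_combine(astig(2, 90), astig(1, 180), -1)  # 3 D @ 90
#' @export
astig_combine <- function(a, b, sign = 1) {
  check_astig(a); check_astig(b)
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  da <- to_double_angle(a)
  db <- to_double_angle(b)
  from_double_angle(da$u + sign * db$u, da$v + sign * db$v)
}

#' Acute angle between two meridians
#'
#' Meridians are axial (period 180 degrees), so the distance between two of
#' them is at most 90 degrees and wraps around at 0/180.
#'
#' @param t1,t2 numeric vectors of meridians in degrees (any real values;
#'   reduced mod 180).
#' @return numeric vector of separations in \[0, 90\] degrees.
#' @examples
#' meridian_difference(178, 2)  # 4
#' @export
meridian_difference <- function(t1, t2) {
  d <- abs((t1 %% 180) - (t2 %% 180))
  pmin(d, 180 - d)
}

#' Classify astigmatism as WTR, ATR, or oblique
#'
#' Classification by the steep meridian alone: with-the-rule (WTR) when it
#' lies between 60 and 120 degrees, against-the-rule (ATR) between 0 and 30
#' or between 150 and 180 degrees, and oblique in between. The boundary
#' meridians 30, 60, 120 and 150 are assigned to the non-oblique class by
#' default (`boundary = "nonoblique"`); set `boundary = "oblique"` to assign
#' them to the oblique class instead.
#'
#' @param a an [astig] object; every magnitude must be > 0 (zero astigmatism
#'   has no meridian and is unclassifiable).
#' @param boundary tie policy for the boundary meridians.
#' @return a factor with levels `WTR`, `ATR`, `OBLIQUE`.
#' @examples
#' astig_classify(astig(1, c(90, 15, 45)))
#' @export
astig_classify <- function(a, boundary = c("nonoblique", "oblique")) {
  check_astig(a)
  boundary <- match.arg(boundary)
  if (any(a$magnitude == 0)) {
    stop("astig_classify(): zero-magnitude astigmatism is unclassifiable")
  }
  th <- a$meridian
  if (boundary == "nonoblique") {
    wtr <- th >= 60 & th <= 120
    atr <- th <= 30 | th >= 150
  } else {
    wtr <- th > 60 & th < 120
    atr <- th < 30 | th > 150
  }
  lab <- ifelse(wtr, "WTR", ifelse(atr, "ATR", "OBLIQUE"))
  factor(lab, levels = c("WTR", "ATR", "OBLIQUE"))
}

#' Centroid of a set of astigmatisms
#'
#' The centroid is the vector mean in double-angle space: the mean of the
#' `(u, v)` components mapped back to magnitude/meridian. Because scatter
#' cancels vectorially, the centroid magnitude never exceeds the arithmetic
#' mean of the absolute magnitudes.
#'
#' @param a an [astig] object with at least one vector.
#' @return a list of class `astig_centroid` with elements `centroid` (an
#'   [astig] of length 1), `mean_absolute_magnitude` (diopters) and `n`.
#' @examples
#' astig_centroid(astig(c(1, 1), c(90, 0)))  # centroid 0 D
#' @export
astig_centroid <- function(a) {
  check_astig(a)
  if (nrow(a) == 0) stop("astig_centroid(): empty input")
  da <- to_double_angle(a)
  structure(list(
    centroid = from_double_angle(mean(da$u), mean(da$v)),
    mean_absolute_magnitude = mean(a$magnitude),
    n = nrow(a)
  ), class = "astig_centroid")
}

#' @export
print.astig_centroid <- function(x, ...) {
  cat(sprintf("Centroid: %s (mean |C| = %.2f D, n = %d)\n",
              format(x$centroid), x$mean_absolute_magnitude, x$n))
  invisible(x)
}
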