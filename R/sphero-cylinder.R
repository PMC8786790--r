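#' Sphero-cylinder refractions
#'
#' A `spherocyl` object holds one or more refractions in sphere/cylinder/axis
#' notation at a named optical plane (spectacle or corneal). The axis is
#' normalized into \[0, 180); a plano cylinder is canonicalized to axis 0.
#' The cylinder sign is kept as given -- use [as_minus_cyl()] to force the
#' package's canonical minus-cylinder form.
#'
#' @param sphere,cylinder numeric vectors in diopters (cylinder signed).
#' @param axis numeric vector of cylinder axes in degrees (reduced mod 180).
#' @param plane `"spectacle"` or `"corneal"` -- the plane at which the powers
#'   are expressed.
#' @return an object of class `spherocyl` (a data frame with columns
#'   `sphere`, `cylinder`, `axis` and a `plane` attribute).
#' @examples
#' spherocyl(-1, -2, 180)
#' @export
spherocyl <- function(sphere, cylinder, axis, plane = c("spectacle", "corneal")) {
  plane <- match.arg(plane)
  n <- max(length(sphere), length(cylinder), length(axis))
  sphere <- rep_len(as.numeric(sphere), n)
  cylinder <- rep_len(as.numeric(cylinder), n)
  axis <- rep_len(as.numeric(axis), n)
  if (anyNA(sphere) || anyNA(cylinder) || anyNA(axis)) {
    stop("spherocyl(): sphere, cylinder and axis must be non-missing")
  }
  axis <- axis %% 180
  axis[cylinder == 0] <- 0
  structure(data.frame(sphere = sphere, cylinder = cylinder, axis = axis),
            class = c("spherocyl", "data.frame"),
            plane = plane)
}

#' @export
print.spherocyl <- function(x, ...) {
  cat(sprintf("<spherocyl at %s plane: %d refraction%s>\n",
              attr(x, "plane"), nrow(x), if (nrow(x) == 1) "" else "s"))
  print(sprintf("%+.2f %+.2f x %g", x$sphere, x$cylinder, x$axis))
  invisible(x)
}

is_spherocyl <- function(x) inherits(x, "spherocyl")

check_spherocyl <- function(x, arg = deparse(substitute(x))) {
  if (!is_spherocyl(x)) stop(arg, " must be a 'spherocyl' object")
  x
}

#' @rdname spherocyl
#' @param x a `spherocyl` object.
#' @export
sc_plane <- function(x) attr(check_spherocyl(x), "plane")

#' Transpose sphero-cylinder notation
#'
#' The standard cross-cylinder transposition: `sphere' = sphere + cylinder`,
#' `cylinder' = -cylinder`, `axis' = axis + 90 (mod 180)`. The two principal
#' meridian powers are unchanged; the operation is an involution.
#'
#' @param sc a [spherocyl] object.
#' @return a [spherocyl] at the same plane.
#' @examples
#' transpose_notation(spherocyl(-1, -2, 180))  # -3.00 +2.00 x 90
#' @export
transpose_notation <- function(sc) {
  check_spherocyl(sc)
  spherocyl(sc$sphere + sc$cylinder, -sc$cylinder, sc$axis + 90,
            plane = sc_plane(sc))
}

#' Canonical minus-cylinder form
#'
#' Transposes any plus-cylinder entries so every cylinder is <= 0.
#'
#' @param sc a [spherocyl] object.
#' @return a [spherocyl] with all cylinders <= 0.
#' @export
as_minus_cyl <- function(sc) {
  check_spherocyl(sc)
  pos <- sc$cylinder > 0
  if (!any(pos)) return(sc)
  tr <- transpose_notation(sc)
  out <- sc
  out$sphere[pos] <- tr$sphere[pos]
  out$cylinder[pos] <- tr$cylinder[pos]
  out$axis[pos] <- tr$axis[pos]
  out$axis[out$cylinder == 0] <- 0
  out
}

# principal meridian powers: F1 along the cylinder axis meridian carries
# sphere alone; F2 = sphere + cylinder acts 90 degrees away
principal_powers <- function(sc) {
  cbind(f1 = sc$sphere, f2 = sc$sphere + sc$cylinder)
}

#' Vertex-distance conversion between spectacle and corneal planes
#'
#' Each principal meridian power `F` is converted by the thin-lens
#' effectivity relation `F' = F / (1 - d F)` when moving from the spectacle
#' to the corneal plane and by its inverse `F' = F / (1 + d F)` when moving
#' back, with `d` the vertex distance in meters. The sphere/cylinder/axis
#' form is reassembled from the two converted powers; the axis never
#' changes. The two directions are exact inverses of one another.
#'
#' @param sc a [spherocyl] object.
#' @param d vertex distance in meters (>= 0); conventional default 0.012.
#' @param direction `"to_corneal"` or `"to_spectacle"`.
#' @return a [spherocyl] at the target plane, in the same cylinder-sign
#'   convention as the input.
#' @examples
#' vertex_convert(spherocyl(-5, -2, 180), 0.012, "to_corneal")
#' @export
vertex_convert <- function(sc, d = 0.012,
                           direction = c("to_corneal", "to_spectacle")) {
  check_spherocyl(sc)
  direction <- match.arg(direction)
  if (length(d) != 1 || is.na(d) || d < 0) {
    stop("vertex_convert(): vertex distance d must be a single number >= 0")
  }
  pp <- principal_powers(sc)
  denom <- if (direction == "to_corneal") 1 - d * pp else 1 + d * pp
  if (any(abs(denom) < 1e-12)) {
    stop("vertex_convert(): singular conversion (1 - d*F = 0 for a ",
         "principal power)")
  }
  conv <- pp / denom
  # effectivity is monotone in F, so each converted power keeps its meridian
  # and the cylinder sign convention of every entry is preserved
  spherocyl(conv[, "f1"], conv[, "f2"] - conv[, "f1"], sc$axis,
            plane = if (direction == "to_corneal") "corneal" else "spectacle")
}

#' Manifest refractive spherical equivalent
#'
#' `MRSE = sphere + cylinder / 2`; invariant under notation transposition.
#'
#' @param sc a [spherocyl] object.
#' @return numeric vector of spherical equivalents in diopters.
#' @export
mrse <- function(sc) {
  check_spherocyl(sc)
  sc$sphere + sc$cylinder / 2
}

#' Convert decimal visual acuity to logMAR
#'
#' `logMAR = -log10(decimal acuity)`.
#'
#' @param va numeric vector of decimal acuities, all > 0.
#' @return numeric vector on the logMAR scale.
#' @examples
#' decimal_to_logmar(c(1, 0.5, 0.1))
#' @export
decimal_to_logmar <- function(va) {
  va <- as.numeric(va)
  if (anyNA(va) || any(va <= 0)) {
    stop("decimal_to_logmar(): decimal acuity must be > 0")
  }
  -log10(va)
}

#' Astigmatism vector of the eye implied by a refraction
#'
#' In minus-cylinder notation the cylinder axis is the flat meridian of the
#' eye's astigmatic error, so the steep meridian lies 90 degrees away. The
#' refraction is first forced to minus-cylinder form; the result has
#' magnitude `|cylinder|` and meridian `(axis + 90) mod 180`. This places
#' refractive astigmatism on the same double-angle axes as keratometric
#' astigmatism (a WTR eye, steep near 90, needs a minus cylinder at axis
#' 180).
#'
#' @param sc a [spherocyl] object.
#' @return an [astig] object.
#' @examples
#' refractive_astig(spherocyl(-1, -1, 180))  # 1 D @ 90 (WTR)
#' @export
refractive_astig <- function(sc) {
  m <- as_minus_cyl(sc)
  astig(abs(m$cylinder), ifelse(m$cylinder == 0, 0, (m$axis + 90) %% 180))
}

#' Analysis configuration
#'
#' Bundles the knobs shared across the pipeline: the vertex distance used
#' for spectacle-to-corneal plane conversion (the source study does not
#' state one; 12 mm is the conventional refraction-lane default), the
#' significance level, the classification boundary policy, and the
#' autorefractor reliability-index threshold (measurements below 8 are
#' excluded).
#'
#' @param vertex_distance vertex distance in meters (>= 0).
#' @param alpha two-sided significance level in (0, 1).
#' @param boundary classification tie policy, see [astig_classify()].
#' @param reliability_threshold minimum reliability index kept, in 5..9.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(vertex_distance = 0.012, alpha = 0.05,
                            boundary = c("nonoblique", "oblique"),
                            reliability_threshold = 8) {
  boundary <- match.arg(boundary)
  if (vertex_distance < 0) stop("vertex_distance must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!reliability_threshold %in% 5:9) {
    stop("reliability_threshold must be an integer in 5..9")
  }
  structure(list(vertex_distance = vertex_distance, alpha = alpha,
                 boundary = boundary,
                 reliability_threshold = reliability_threshold),
            class = "analysis_config")
}
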