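#' Double-angle plot of astigmatism vectors
#'
#' Draws the field's standard double-angle plot: each astigmatism is placed
#' at radius `C` (diopters) and polar angle `2 theta` measured
#' counterclockwise from +x, while the angular tick labels show the
#' single-angle meridian, so WTR vectors cluster on the left (label 90) and
#' ATR on the right (label 0/180). Baseline vectors are green squares,
#' follow-up vectors red circles; centroids are drawn as filled markers and
#' 95% dataset/centroid confidence ellipses can be overlaid. Rendering is
#' deterministic for identical inputs.
#'
#' @param baseline,followup [astig] objects (both non-empty).
#' @param file output path ending in `.svg`, `.png` or `.pdf`; `NULL` draws
#'   on the current device.
#' @param ellipses draw confidence ellipses (needs >= 3 points per set).
#' @param level coverage level for the ellipses.
#' @param main plot title.
#' @param rings radii of the magnitude rings; default adapts to the data.
#' @return the file path (or `NULL`), invisibly.
#' @export
render_double_angle_plot <- function(baseline, followup, file = NULL,
                                     ellipses = TRUE, level = 0.95,
                                     main = "Double-angle plot",
                                     rings = NULL) {
  check_astig(baseline); check_astig(followup)
  if (nrow(baseline) == 0 || nrow(followup) == 0) {
    stop("render_double_angle_plot(): both timepoint sets must be non-empty")
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           svg = grDevices::svg(file, width = 7, height = 7),
           png = grDevices::png(file, width = 700, height = 700),
           pdf = grDevices::pdf(file, width = 7, height = 7),
           stop("unsupported plot format: .", ext))
    on.exit(grDevices::dev.off())
  }
  ub <- to_double_angle(baseline); uf <- to_double_angle(followup)
  rmax <- max(baseline$magnitude, followup$magnitude, 0.5)
  if (is.null(rings)) rings <- pretty(c(0, rmax * 1.05))[-1]
  lim <- max(rings)
  op <- graphics::par(mar = c(2, 2, 3, 2), pty = "s")
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-lim, lim) * 1.15, ylim = c(-lim, lim) * 1.15,
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 241)
  for (r in rings) {
    graphics::lines(r * cos(th), r * sin(th), col = "grey80")
    graphics::text(r * cos(pi / 8), r * sin(pi / 8), sprintf("%g D", r),
                   col = "grey50", cex = 0.7)
  }
  for (ang in seq(0, 150, by = 30)) {       # single-angle meridian labels
    a2 <- deg2rad(2 * ang)
    graphics::lines(c(0, lim * cos(a2)), c(0, lim * sin(a2)), col = "grey90")
    graphics::text(1.1 * lim * cos(a2), 1.1 * lim * sin(a2),
                   sprintf("%d°", ang), cex = 0.8)
  }
  graphics::points(ub$u, ub$v, pch = 0, col = "darkgreen")
  graphics::points(uf$u, uf$v, pch = 1, col = "red")
  cb <- astig_centroid(baseline); cf <- astig_centroid(followup)
  cub <- to_double_angle(cb$centroid); cuf <- to_double_angle(cf$centroid)
  graphics::points(cub$u, cub$v, pch = 15, col = "darkgreen", cex = 1.4)
  graphics::points(cuf$u, cuf$v, pch = 16, col = "red", cex = 1.4)
  if (ellipses && nrow(ub) >= 3 && nrow(uf) >= 3) {
    for (set in list(list(d = ub, col = "darkgreen"),
                     list(d = uf, col = "red"))) {
      for (mode in c("dataset", "centroid")) {
        e <- tryCatch(confidence_ellipse(set$d, level, mode),
                      error = function(err) NULL)
        if (!is.null(e)) {
          graphics::lines(ellipse_path(e), col = set$col,
                          lty = if (mode == "dataset") 3 else 1)
        }
      }
    }
  }
  graphics::legend("topleft", bty = "n", cex = 0.75,
                   pch = c(0, 15, 1, 16),
                   col = c("darkgreen", "darkgreen", "red", "red"),
                   legend = c(
                     sprintf("baseline (n=%d)", cb$n),
                     sprintf("baseline centroid %s", format(cb$centroid)),
                     sprintf("follow-up (n=%d)", cf$n),
                     sprintf("follow-up centroid %s", format(cf$centroid))))
  invisible(file)
}

#' Double-angle plots for every group and measure of a cohort
#'
#' Convenience wrapper producing one [render_double_angle_plot()] per
#' group x measure into a directory.
#'
#' @param x a cohort data frame.
#' @param dir output directory (created if needed).
#' @param format `"svg"`, `"png"` or `"pdf"`.
#' @param cfg an [analysis_config()].
#' @return character vector of files written, invisibly.
#' @export
plot_cohort <- function(x, dir, format = c("svg", "png", "pdf"),
                        cfg = analysis_config()) {
  format <- match.arg(format)
  x <- validate_cohort(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- eye_measures(x, cfg)
  files <- character()
  for (g in sort(unique(m$group))) {
    for (meas in measure_names) {
      sel <- function(tp) {
        mm <- m[m$group == g & m$timepoint == tp, ]
        from_naeser_polar(mm[[paste0(meas, "_rx")]],
                          mm[[paste0(meas, "_ry")]])
      }
      f <- file.path(dir, sprintf("%s_%s.%s", tolower(g), meas, format))
      render_double_angle_plot(sel("baseline"), sel("followup"), file = f,
                               level = 1 - cfg$alpha,
                               main = sprintf("%s — %s astigmatism", g, meas))
      files <- c(files, f)
    }
  }
  invisible(files)
}
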