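#' Cohort tables
#'
#' The pipeline's row type is one eye at one timepoint. A cohort is a data
#' frame with one row per eye per timepoint and the columns
#'
#' * `id` — eye identifier (character or integer)
#' * `group` — preoperative astigmatism group, `"ATR"` or `"WTR"`
#' * `age` — years at baseline
#' * `sex` — `"M"` or `"F"`
#' * `eye` — `"L"` or `"R"`
#' * `timepoint` — `"baseline"` or `"followup"`
#' * `sphere_D`, `cylinder_D`, `axis_deg` — manifest refraction at the
#'   spectacle plane (minus-cylinder canonical; plus-cylinder rows are
#'   transposed on ingestion)
#' * `corneal_cyl_D`, `corneal_steep_meridian_deg` — anterior keratometric
#'   astigmatism (magnitude and steep meridian)
#' * `ucva_decimal`, `cdva_decimal` — uncorrected / corrected decimal acuity
#' * `reliability_index` — autorefractor reliability index, 5..9
#' * `years_since_baseline` — 0 at baseline, the follow-up interval otherwise
#'
#' @name cohort-table
NULL

cohort_columns <- c("id", "group", "age", "sex", "eye", "timepoint",
                    "sphere_D", "cylinder_D", "axis_deg", "corneal_cyl_D",
                    "corneal_steep_meridian_deg", "ucva_decimal",
                    "cdva_decimal", "reliability_index",
                    "years_since_baseline")

#' Validate and canonicalize a cohort table
#'
#' Checks the schema described in [cohort-table], normalizes axes and
#' meridians into \[0, 180) (with a warning naming the rows changed),
#' transposes plus-cylinder refractions to the canonical minus-cylinder
#' form, and verifies that every eye has exactly one baseline and one
#' follow-up row.
#'
#' @param x a data frame.
#' @param require_both require both timepoints per eye (default `TRUE`).
#' @return the canonicalized cohort data frame.
#' @export
validate_cohort <- function(x, require_both = TRUE) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(cohort_columns, names(x))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[cohort_columns]
  x$group <- as.character(x$group)
  x$timepoint <- as.character(x$timepoint)
  if (!all(x$group %in% c("ATR", "WTR"))) {
    stop("group must be 'ATR' or 'WTR'")
  }
  if (!all(x$timepoint %in% c("baseline", "followup"))) {
    stop("timepoint must be 'baseline' or 'followup'")
  }
  num_cols <- c("age", "sphere_D", "cylinder_D", "axis_deg", "corneal_cyl_D",
                "corneal_steep_meridian_deg", "ucva_decimal", "cdva_decimal",
                "reliability_index", "years_since_baseline")
  for (cc in num_cols) {
    x[[cc]] <- as.numeric(x[[cc]])
    if (anyNA(x[[cc]])) {
      stop("non-numeric or missing values in column '", cc, "' (rows ",
           paste(utils::head(which(is.na(x[[cc]])), 5), collapse = ", "), ")")
    }
  }
  if (any(x$corneal_cyl_D < 0)) stop("corneal_cyl_D must be >= 0")
  if (any(x$ucva_decimal <= 0) || any(x$cdva_decimal <= 0)) {
    stop("decimal acuities must be > 0")
  }
  if (!all(x$reliability_index %in% 5:9)) {
    stop("reliability_index must be an integer in 5..9")
  }
  for (cc in c("axis_deg", "corneal_steep_meridian_deg")) {
    out_of_range <- which(x[[cc]] < 0 | x[[cc]] >= 180)
    if (length(out_of_range)) {
      warning("column '", cc, "': ", length(out_of_range),
              " value(s) normalized mod 180 (rows ",
              paste(utils::head(out_of_range, 5), collapse = ", "), ")")
      x[[cc]] <- x[[cc]] %% 180
    }
  }
  dup <- duplicated(x[c("id", "timepoint")])
  if (any(dup)) {
    stop("duplicate (id, timepoint) rows: ",
         paste(utils::head(unique(x$id[dup]), 5), collapse = ", "))
  }
  # canonical minus-cylinder refraction
  sc <- as_minus_cyl(spherocyl(x$sphere_D, x$cylinder_D, x$axis_deg))
  x$sphere_D <- sc$sphere; x$cylinder_D <- sc$cylinder; x$axis_deg <- sc$axis
  if (require_both) {
    tab <- table(x$id, factor(x$timepoint,
                              levels = c("baseline", "followup")))
    bad <- rownames(tab)[tab[, "baseline"] != 1 | tab[, "followup"] != 1]
    if (length(bad)) {
      stop("eye record(s) without exactly one baseline and one followup: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  x
}

#' Keep only high-reliability measurements
#'
#' Retains rows whose autorefractor reliability index meets the threshold
#' (the source device reports 5..9; only 8 and 9 count as high reliability).
#' Exclusions are reported one per row via `message()` and the kept order is
#' preserved. Idempotent.
#'
#' @param x a cohort data frame with a `reliability_index` column.
#' @param threshold minimum index kept, in 5..9.
#' @return the filtered data frame, with an attribute `n_excluded`.
#' @export
reliability_filter <- function(x, threshold = 8) {
  if (!threshold %in% 5:9) stop("threshold must be in 5..9")
  drop <- which(x$reliability_index < threshold)
  for (i in drop) {
    message(sprintf("excluded: id=%s timepoint=%s reason=reliability_index %d < %d",
                    x$id[i], x$timepoint[i], x$reliability_index[i], threshold))
  }
  out <- if (length(drop)) x[-drop, , drop = FALSE] else x
  attr(out, "n_excluded") <- length(drop)
  out
}

#' Repeatability of two keratometry readings
#'
#' Two corneal-astigmatism measurements of the same eye are considered
#' repeatable when the cylinder magnitudes agree within 0.5 D and the steep
#' meridians within 15 degrees (axial distance, wrapping at 0/180).
#'
#' @param k1,k2 [astig] objects of equal length.
#' @param max_cyl_diff magnitude tolerance in diopters.
#' @param max_axis_diff meridian tolerance in degrees.
#' @return logical vector.
#' @export
repeatability_check <- function(k1, k2, max_cyl_diff = 0.5,
                                max_axis_diff = 15) {
  check_astig(k1); check_astig(k2)
  abs(k1$magnitude - k2$magnitude) <= max_cyl_diff &
    meridian_difference(k1$meridian, k2$meridian) <= max_axis_diff
}

#' Ocular residual astigmatism
#'
#' ORA is the vector difference between the manifest refractive astigmatism
#' and the anterior corneal astigmatism, computed at the corneal plane: the
#' spectacle-plane refraction is vertex-converted to the corneal plane, its
#' astigmatism vector extracted, and the corneal vector subtracted in
#' double-angle space. After toric-IOL implantation it mainly reflects the
#' IOL's correcting cylinder plus IOL tilt/decentration and the posterior
#' cornea.
#'
#' @param refraction a [spherocyl] at the spectacle plane.
#' @param corneal an [astig] of anterior corneal astigmatism.
#' @param cfg an [analysis_config()]; supplies the vertex distance.
#' @return an [astig] at the corneal plane.
#' @export
compute_ora <- function(refraction, corneal, cfg = analysis_config()) {
  check_spherocyl(refraction)
  check_astig(corneal)
  rc <- vertex_convert(refraction, cfg$vertex_distance, "to_corneal")
  astig_combine(refractive_astig(rc), corneal, -1)
}

#' Per-eye derived measures
#'
#' One row per eye per timepoint with the three Naeser polar-value pairs the
#' longitudinal analysis is built on — manifest refractive astigmatism at
#' the spectacle plane (as presented in summary tables), anterior corneal
#' astigmatism, and ocular residual astigmatism at the corneal plane —
#' plus MRSE and logMAR acuities.
#'
#' @param x a cohort data frame (see [cohort-table]).
#' @param cfg an [analysis_config()].
#' @return a data frame with columns `id`, `group`, `timepoint`,
#'   `refractive_rx/ry`, `corneal_rx/ry`, `ora_rx/ry`, `mrse`,
#'   `ucva_logmar`, `cdva_logmar`.
#' @export
eye_measures <- function(x, cfg = analysis_config()) {
  sc <- spherocyl(x$sphere_D, x$cylinder_D, x$axis_deg)
  corneal <- astig(x$corneal_cyl_D, x$corneal_steep_meridian_deg)
  refr <- refractive_astig(sc)             # spectacle plane, as presented
  ora <- compute_ora(sc, corneal, cfg)     # corneal plane
  cbind(x[c("id", "group", "timepoint")],
        stats::setNames(naeser_polar(refr), c("refractive_rx", "refractive_ry")),
        stats::setNames(naeser_polar(corneal), c("corneal_rx", "corneal_ry")),
        stats::setNames(naeser_polar(ora), c("ora_rx", "ora_ry")),
        mrse = mrse(sc),
        ucva_logmar = decimal_to_logmar(x$ucva_decimal),
        cdva_logmar = decimal_to_logmar(x$cdva_decimal))
}

measure_names <- c("refractive", "corneal", "ora")

#' Longitudinal cohort summary
#'
#' The study's analysis chain for a two-timepoint toric-IOL cohort. For each
#' group (ATR / WTR) and measure (manifest refractive astigmatism at the
#' spectacle plane, anterior corneal astigmatism, ocular residual
#' astigmatism at the corneal plane) it reports, per Naeser component (Rx,
#' Ry): baseline and follow-up mean, SD and range, and the paired t p-value
#' for the change; per measure, the paired bivariate Hotelling T-squared on
#' `(delta Rx, delta Ry)`; logMAR visual-acuity comparisons; double-angle
#' centroids with dataset and centroid 95% confidence ellipses per
#' timepoint; and the baseline-characteristics comparison between groups.
#'
#' @param x a cohort data frame (see [cohort-table]); validated first.
#' @param cfg an [analysis_config()].
#' @return a list of class `cohort_result` with elements `components`,
#'   `bivariate`, `va`, `centroids`, `ellipses`, `baseline_characteristics`,
#'   `n`, `config`.
#' @export
summarize_cohort <- function(x, cfg = analysis_config()) {
  x <- validate_cohort(x)
  m <- eye_measures(x, cfg)
  groups <- sort(unique(m$group))
  comp_rows <- list(); biv_rows <- list(); va_rows <- list()
  cent_rows <- list(); ellipses <- list()
  for (g in groups) {
    mb <- m[m$group == g & m$timepoint == "baseline", ]
    mf <- m[m$group == g & m$timepoint == "followup", ]
    mb <- mb[order(mb$id), ]; mf <- mf[order(mf$id), ]
    if (nrow(mb) < 2) stop("group ", g, " has fewer than 2 eyes")
    stopifnot(identical(mb$id, mf$id))
    for (meas in measure_names) {
      d <- list()
      for (compn in c("rx", "ry")) {
        col <- paste(meas, compn, sep = "_")
        b <- mb[[col]]; f <- mf[[col]]
        tt <- paired_t(b, f)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          group = g, measure = meas, component = toupper(compn),
          baseline_mean = mean(b), baseline_sd = stats::sd(b),
          baseline_min = min(b), baseline_max = max(b),
          followup_mean = mean(f), followup_sd = stats::sd(f),
          followup_min = min(f), followup_max = max(f),
          mean_change = tt$estimate, t = tt$statistic, p = tt$p.value,
          n = tt$n)
        d[[compn]] <- f - b
      }
      ht <- hotelling_paired(cbind(rx = d$rx, ry = d$ry))
      biv_rows[[length(biv_rows) + 1L]] <- data.frame(
        group = g, measure = meas, T2 = ht$statistic, F = ht$F,
        df1 = ht$df[1], df2 = ht$df[2], p = ht$p.value, n = ht$n)
      for (tp in c("baseline", "followup")) {
        mm <- if (tp == "baseline") mb else mf
        # polar values back to magnitude/meridian for the centroid
        vec <- from_naeser_polar(mm[[paste0(meas, "_rx")]],
                                 mm[[paste0(meas, "_ry")]])
        ce <- astig_centroid(vec)
        cent_rows[[length(cent_rows) + 1L]] <- data.frame(
          group = g, measure = meas, timepoint = tp,
          centroid_magnitude = ce$centroid$magnitude,
          centroid_meridian = ce$centroid$meridian,
          mean_absolute_magnitude = ce$mean_absolute_magnitude, n = ce$n)
        uv <- to_double_angle(vec)
        key <- paste(g, meas, tp, sep = ".")
        ellipses[[key]] <- list(
          dataset = confidence_ellipse(uv, 1 - cfg$alpha, "dataset"),
          centroid = confidence_ellipse(uv, 1 - cfg$alpha, "centroid"))
      }
    }
    for (va in c("ucva_logmar", "cdva_logmar")) {
      tt <- paired_t(mb[[va]], mf[[va]])
      va_rows[[length(va_rows) + 1L]] <- data.frame(
        group = g, measure = sub("_logmar", "", va),
        baseline_mean = mean(mb[[va]]), baseline_sd = stats::sd(mb[[va]]),
        followup_mean = mean(mf[[va]]), followup_sd = stats::sd(mf[[va]]),
        t = tt$statistic, p = tt$p.value, n = tt$n)
    }
  }
  structure(list(
    components = do.call(rbind, comp_rows),
    bivariate = do.call(rbind, biv_rows),
    va = do.call(rbind, va_rows),
    centroids = do.call(rbind, cent_rows),
    ellipses = ellipses,
    baseline_characteristics =
      if (length(groups) == 2) compare_baseline_characteristics(x) else NULL,
    n = stats::setNames(as.integer(table(m$group[m$timepoint == "baseline"])),
                        groups),
    config = cfg
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, digits = 3, ...) {
  cat("Cohort analysis (", paste(sprintf("%s n=%d", names(x$n), x$n),
                                 collapse = ", "), ")\n", sep = "")
  cat("\nPer-component paired comparisons:\n")
  print(format(x$components, digits = digits), row.names = FALSE)
  cat("\nBivariate (Hotelling T2) comparisons:\n")
  print(format(x$bivariate, digits = digits), row.names = FALSE)
  cat("\nVisual acuity (logMAR):\n")
  print(format(x$va, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Baseline characteristics comparison between groups
#'
#' Continuous characteristics (age, baseline MRSE, baseline corneal
#' astigmatism magnitude, baseline corrected logMAR acuity, follow-up
#' interval) are compared between the two groups with an unpaired t test —
#' Welch's unequal-variance form by default, with a pooled-variance option.
#' The 2x2 categorical characteristics (sex, eye side) are tested with both
#' the Pearson chi-square (no continuity correction) and Fisher's exact
#' test, since either may be "applicable".
#'
#' @param x a cohort data frame containing both groups.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return a data frame with one row per characteristic: group summaries
#'   and p-values (`p_t` for continuous rows, `p_chisq`/`p_fisher` for
#'   categorical rows).
#' @export
compare_baseline_characteristics <- function(x, var_equal = FALSE) {
  x <- validate_cohort(x, require_both = FALSE)
  base <- x[x$timepoint == "baseline", ]
  groups <- sort(unique(base$group))
  if (length(groups) != 2) stop("need exactly two groups (ATR, WTR)")
  g1 <- base[base$group == groups[1], ]
  g2 <- base[base$group == groups[2], ]
  if (nrow(g1) == 0 || nrow(g2) == 0) stop("empty group")
  sc1 <- spherocyl(g1$sphere_D, g1$cylinder_D, g1$axis_deg)
  sc2 <- spherocyl(g2$sphere_D, g2$cylinder_D, g2$axis_deg)
  cont <- list(
    age = list(g1$age, g2$age),
    mrse = list(mrse(sc1), mrse(sc2)),
    corneal_astig_magnitude = list(g1$corneal_cyl_D, g2$corneal_cyl_D),
    cdva_logmar = list(decimal_to_logmar(g1$cdva_decimal),
                       decimal_to_logmar(g2$cdva_decimal)),
    followup_years = {
      f1 <- x[x$group == groups[1] & x$timepoint == "followup", ]
      f2 <- x[x$group == groups[2] & x$timepoint == "followup", ]
      list(f1$years_since_baseline, f2$years_since_baseline)
    })
  rows <- lapply(names(cont), function(nm) {
    a <- cont[[nm]][[1]]; b <- cont[[nm]][[2]]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(characteristic = nm, type = "continuous",
               group1 = groups[1], summary1 = sprintf("%.2f ± %.2f", mean(a), stats::sd(a)),
               group2 = groups[2], summary2 = sprintf("%.2f ± %.2f", mean(b), stats::sd(b)),
               p_t = tt$p.value, p_chisq = NA_real_, p_fisher = NA_real_)
  })
  cats <- list(sex = c("M", "F"), eye = c("L", "R"))
  for (nm in names(cats)) {
    lev <- cats[[nm]]
    tab <- rbind(table(factor(g1[[nm]], levels = lev)),
                 table(factor(g2[[nm]], levels = lev)))
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    fis <- stats::fisher.test(tab)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = nm, type = "categorical",
      group1 = groups[1],
      summary1 = paste(tab[1, ], lev, collapse = "/"),
      group2 = groups[2],
      summary2 = paste(tab[2, ], lev, collapse = "/"),
      p_t = NA_real_, p_chisq = chi$p.value, p_fisher = fis$p.value)
  }
  do.call(rbind, rows)
}
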