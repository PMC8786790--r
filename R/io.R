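#' Write a cohort table to CSV
#'
#' The canonical interchange format: one row per eye per timepoint with the
#' [cohort-table] columns, preceded by a `#`-prefixed metadata header that
#' declares the cylinder sign convention.
#'
#' @param x a cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  x <- validate_cohort(x, require_both = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# astigvec cohort v1; cylinder_sign=minus; angles_deg=[0,180)",
             con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Reads a file written by [write_cohort_csv()] (or any CSV with the
#' [cohort-table] columns; `#` lines are ignored), then validates and
#' canonicalizes it: missing columns are a named error, duplicate
#' `(id, timepoint)` rows are an error, out-of-range axes are normalized
#' mod 180 with a warning, and plus-cylinder refractions are transposed.
#'
#' @param path CSV file path.
#' @param require_both require both timepoints per eye.
#' @return a cohort data frame.
#' @export
read_cohort_csv <- function(path, require_both = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_cohort(x, require_both = require_both)
}

#' Read per-eye data from a supplementary spreadsheet
#'
#' Reads an XLSX sheet of per-eye longitudinal records and maps its columns
#' onto the [cohort-table] schema via an explicit column-mapping, because
#' the layout of such supplementary files is not standardized. The mapping
#' pairs each required canonical column with the sheet's column name;
#' anything unmapped and required is an error that lists the sheet's actual
#' columns as candidates. After renaming, the same validation as
#' [read_cohort_csv()] applies.
#'
#' @param path XLSX file path.
#' @param mapping named character vector or list: names are canonical
#'   [cohort-table] columns, values are sheet column names. May also be a
#'   path to a plain-text `key = value` file (see [read_mapping_config()]).
#' @param sheet sheet index or name passed to [readxl::read_excel()].
#' @param require_both require both timepoints per eye.
#' @return a cohort data frame.
#' @export
read_supplementary_xlsx <- function(path, mapping, sheet = 1,
                                    require_both = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    mapping <- read_mapping_config(mapping)
  }
  mapping <- unlist(mapping)
  raw <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  absent <- mapping[!mapping %in% names(raw)]
  if (length(absent)) {
    stop("mapped sheet column(s) not found: ",
         paste(sprintf("%s -> '%s'", names(absent), absent), collapse = ", "),
         "; sheet has columns: ", paste(names(raw), collapse = ", "))
  }
  unmapped <- setdiff(cohort_columns, names(mapping))
  if (length(unmapped)) {
    stop("mapping is missing required field(s): ",
         paste(unmapped, collapse = ", "),
         "; candidate sheet columns: ", paste(names(raw), collapse = ", "))
  }
  out <- raw[unname(mapping[cohort_columns])]
  names(out) <- cohort_columns
  validate_cohort(out, require_both = require_both)
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments are ignored. Used for the XLSX column mapping.
#'
#' @param path file path.
#' @return a named character vector.
#' @export
read_mapping_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- lengths(m) != 3
  if (any(bad)) stop("unparseable config line(s): ",
                     paste(lines[bad], collapse = "; "))
  stats::setNames(trimws(vapply(m, `[`, "", 3)),
                  trimws(vapply(m, `[`, "", 2)))
}

#' Serialize a cohort_result to JSON
#'
#' @param res a `cohort_result` from [summarize_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(res, path) {
  out <- list(
    n = as.list(res$n),
    components = res$components,
    bivariate = res$bivariate,
    va = res$va,
    centroids = res$centroids,
    baseline_characteristics = res$baseline_characteristics,
    config = unclass(res$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
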