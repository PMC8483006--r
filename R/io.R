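# Table schemas, validation and delimiter-separated I/O.
#
# Three tables travel through the pipeline:
#   ranges:      species, family, genus, lat_min, lat_max
#   assemblages: site, latitude, species, count   (long format)
#   predictors:  bin_lower, bin_upper, sst, sst_range, salinity,
#                salinity_range, prim_prod, shelf_area
# All are written as tab-separated UTF-8 text with a header row; missing
# values are empty fields.

predictor_names <- function() {
  c("sst", "sst_range", "salinity", "salinity_range", "prim_prod",
    "shelf_area")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate a species range table
#'
#' Checks the `species`/`family`/`genus`/`lat_min`/`lat_max` schema: unique
#' species identifiers, finite latitudes with `lat_min <= lat_max`, and
#' lineage consistency (each genus belongs to exactly one family).
#'
#' @param ranges A data frame of species ranges.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_ranges <- function(ranges) {
  require_columns(ranges, c("species", "family", "genus", "lat_min", "lat_max"),
                  "ranges")
  ranges <- tibble::as_tibble(ranges)
  if (anyDuplicated(ranges$species)) {
    dup <- ranges$species[duplicated(ranges$species)][1]
    stop(sprintf("duplicated species identifier: %s", dup), call. = FALSE)
  }
  bad <- !is.finite(ranges$lat_min) | !is.finite(ranges$lat_max) |
    ranges$lat_min > ranges$lat_max
  if (any(bad)) {
    stop(sprintf("malformed range for species %s: need finite lat_min <= lat_max.",
                 paste(ranges$species[bad][seq_len(min(3, sum(bad)))],
                       collapse = ", ")), call. = FALSE)
  }
  fam_per_genus <- tapply(ranges$family, ranges$genus,
                          function(f) length(unique(f)))
  if (any(fam_per_genus > 1L)) {
    stop(sprintf("genus %s is assigned to more than one family.",
                 names(fam_per_genus)[fam_per_genus > 1L][1]), call. = FALSE)
  }
  ranges
}

#' Validate a local assemblage table
#'
#' @param assemblages Long-format data frame with `site`, `latitude`,
#'   `species`, `count`.
#' @return The validated table as a tibble.
#' @export
validate_assemblages <- function(assemblages) {
  require_columns(assemblages, c("site", "latitude", "species", "count"),
                  "assemblages")
  assemblages <- tibble::as_tibble(assemblages)
  if (any(!is.finite(assemblages$latitude))) {
    stop("assemblage latitudes must be finite.", call. = FALSE)
  }
  if (any(assemblages$count < 0 | assemblages$count != round(assemblages$count))) {
    stop("assemblage counts must be non-negative integers.", call. = FALSE)
  }
  totals <- tapply(assemblages$count, assemblages$site, sum)
  if (any(totals <= 0)) {
    stop(sprintf("site %s has no positive counts.",
                 names(totals)[totals <= 0][1]), call. = FALSE)
  }
  assemblages
}

#' Validate a per-bin predictor table
#'
#' @param predictors Data frame with `bin_lower`, `bin_upper` and the six
#'   predictor columns (`sst`, `sst_range`, `salinity`, `salinity_range`,
#'   `prim_prod`, `shelf_area`).
#' @return The validated table as a tibble.
#' @export
validate_predictors <- function(predictors) {
  require_columns(predictors, c("bin_lower", "bin_upper", predictor_names()),
                  "predictors")
  predictors <- tibble::as_tibble(predictors)
  if (any(predictors$bin_lower >= predictors$bin_upper)) {
    stop("predictor bins must have bin_lower < bin_upper.", call. = FALSE)
  }
  if (is.unsorted(predictors$bin_lower, strictly = TRUE)) {
    stop("predictor bins must be sorted and non-overlapping.", call. = FALSE)
  }
  predictors
}

#' Validate survey tables without running the pipeline
#'
#' Schema-checks whichever of the three tables are supplied; this is the
#' `validate` entry point of the pipeline and accepts every table
#' [simulate_survey()] emits.
#'
#' @param ranges,assemblages,predictors Data frames or `NULL`.
#' @return `TRUE` invisibly if all supplied tables validate; otherwise an
#'   error naming the offending table and record.
#' @export
validate_tables <- function(ranges = NULL, assemblages = NULL,
                            predictors = NULL) {
  if (is.null(ranges) && is.null(assemblages) && is.null(predictors)) {
    stop("supply at least one table to validate.", call. = FALSE)
  }
  if (!is.null(ranges)) validate_ranges(ranges)
  if (!is.null(assemblages)) validate_assemblages(assemblages)
  if (!is.null(predictors)) validate_predictors(predictors)
  invisible(TRUE)
}

#' Read and write survey tables
#'
#' Tab-separated UTF-8 text with a header row; missing values are empty
#' fields. `write_survey_tables()` writes `ranges.tsv`, `assemblages.tsv`
#' and `predictors.tsv` into `dir`.
#'
#' @param path,dir File or directory paths.
#' @param survey An `ldg_survey` from [simulate_survey()], or a list with
#'   elements `ranges`, `assemblages`, `predictors`.
#' @return Readers return validated tibbles; the writer returns the paths
#'   invisibly.
#' @name survey_io
NULL

read_tsv_base <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      na.strings = "", fileEncoding = "UTF-8"))
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname survey_io
#' @export
read_ranges <- function(path) validate_ranges(read_tsv_base(path))

#' @rdname survey_io
#' @export
read_assemblages <- function(path) validate_assemblages(read_tsv_base(path))

#' @rdname survey_io
#' @export
read_predictors <- function(path) validate_predictors(read_tsv_base(path))

#' @rdname survey_io
#' @export
write_survey_tables <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("ranges.tsv", "assemblages.tsv", "predictors.tsv"))
  write_tsv_base(survey$ranges, paths[1])
  write_tsv_base(survey$assemblages, paths[2])
  write_tsv_base(survey$predictors, paths[3])
  invisible(paths)
}
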