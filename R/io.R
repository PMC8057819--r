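#' @title Reading and writing tidy community tables
#' @description Tidy-CSV interchange for abundance tables, biomass tables,
#'   prediction tables and interaction calls, plus JSON run manifests.
#' @name nutridom-io
NULL

ABUNDANCE_COLS <- c("sample_id", "inoculum", "replicate", "environment",
                    "taxon", "taxon_level", "rel_abundance")
BIOMASS_COLS <- c("sample_id", "biomass")

#' Normalize a carbon-source pair label
#'
#' Pair environments are written `CS1+CS2`; the two carbon sources are put in
#' lexicographic order so that `ribose+glucose` and `glucose+ribose` name the
#' same environment. Single-nutrient labels pass through unchanged.
#'
#' @param x character vector of environment labels.
#' @return character vector with normalized pair labels.
#' @export
#' @examples
#' normalize_pair(c("ribose+glucose", "glucose"))
normalize_pair <- function(x) {
  vapply(x, function(lab) {
    parts <- strsplit(lab, "+", fixed = TRUE)[[1]]
    paste(sort(parts), collapse = "+")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a pair label from two carbon sources
#'
#' @param cs1,cs2 carbon-source labels.
#' @return the normalized `CS1+CS2` label.
#' @export
pair_label <- function(cs1, cs2) normalize_pair(paste(cs1, cs2, sep = "+"))

#' Split a pair label into its two carbon sources
#'
#' @param pair a `CS1+CS2` environment label.
#' @return character vector of length 2.
#' @export
split_pair <- function(pair) {
  parts <- strsplit(pair, "+", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("not a two-carbon-source pair label: '", pair, "'", call. = FALSE)
  parts
}

#' Validate an abundance table
#'
#' Checks the tidy schema (`sample_id, inoculum, replicate, environment,
#' taxon, taxon_level, rel_abundance`), that relative abundances are
#' non-negative and sum to 1 within `tol` in every sample, and that each
#' (inoculum, replicate, environment) triple maps to a single sample.
#'
#' @param x data.frame to validate.
#' @param tol tolerance on per-sample abundance sums.
#' @return `x` invisibly, with pair environments normalized.
#' @export
validate_abundance_table <- function(x, tol = 1e-6) {
  missing <- setdiff(ABUNDANCE_COLS, names(x))
  if (length(missing))
    stop("abundance table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(x$rel_abundance < 0))
    stop("negative rel_abundance values present", call. = FALSE)
  bad_level <- setdiff(unique(x$taxon_level), c("family", "genus", "species"))
  if (length(bad_level))
    stop("unknown taxon_level: ", paste(bad_level, collapse = ", "),
         call. = FALSE)
  x$environment <- normalize_pair(as.character(x$environment))
  key <- paste(x$inoculum, x$replicate, x$environment, sep = "\r")
  n_ids <- tapply(x$sample_id, key, function(s) length(unique(s)))
  if (any(n_ids > 1)) {
    dup <- names(n_ids)[n_ids > 1][1]
    stop("multiple sample_ids for one (inoculum, replicate, environment) ",
         "triple: ", gsub("\r", " / ", dup), call. = FALSE)
  }
  sums <- tapply(x$rel_abundance, x$sample_id, sum)
  off <- abs(sums - 1) > tol
  if (any(off))
    stop("relative abundances do not sum to 1 in sample(s): ",
         paste(names(sums)[off], collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Validate a biomass table
#'
#' @param x data.frame with columns `sample_id`, `biomass`.
#' @return `x` invisibly.
#' @export
validate_biomass_table <- function(x) {
  missing <- setdiff(BIOMASS_COLS, names(x))
  if (length(missing))
    stop("biomass table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$sample_id))
    stop("duplicated sample_id in biomass table", call. = FALSE)
  if (any(!is.finite(x$biomass)) || any(x$biomass < 0))
    stop("biomass must be finite and non-negative", call. = FALSE)
  invisible(x)
}

#' Read an abundance table from CSV
#'
#' Reads the tidy schema, normalizes pair environment labels
#' lexicographically and validates all table invariants.
#'
#' @param path path to a CSV file.
#' @param tol tolerance on per-sample abundance sums.
#' @return a validated abundance data.frame.
#' @export
read_abundance_csv <- function(path, tol = 1e-6) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$environment <- normalize_pair(as.character(x$environment))
  validate_abundance_table(x, tol = tol)
  x
}

#' Read a biomass table from CSV
#'
#' @param path path to a CSV file with columns `sample_id`, `biomass`.
#' @return a validated biomass data.frame.
#' @export
read_biomass_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_biomass_table(x)
  x
}

#' Write a tidy results table with a JSON manifest
#'
#' Writes `x` as CSV and, alongside it, a `<file>.manifest.json` recording the
#' package version, a hash of the configuration, the seed and the record
#' count, so that every output can be traced back to its run.
#'
#' @param x data.frame of results (predictions or interaction calls).
#' @param path output CSV path.
#' @param config optional named list of run configuration to record.
#' @param seed optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = NULL, seed = NULL) {
  utils::write.csv(x, path, row.names = FALSE)
  manifest <- list(
    package = "nutridom",
    version = as.character(utils::packageVersion("nutridom")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_records = nrow(x),
    seed = seed,
    config = config
  )
  manifest$config_hash <- if (!is.null(config))
    sum(utf8ToInt(paste(deparse(config), collapse = ""))) else NULL
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
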