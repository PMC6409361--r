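#' Write a cohort to delimited text files
#'
#' Writes three files under `dir`: `<prefix>_subjects.csv` (UTF-8, header
#' row, empty cell = missing), `<prefix>_pet.csv` (long-format PET records)
#' and `<prefix>_meta.json` (analyte modality lists, clinical threshold,
#' follow-up horizon). The round trip through [load_cohort()] is lossless,
#' including the missingness pattern. Generator ground truth is not
#' serialized.
#'
#' @param cohort a `csf_cohort`.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return the paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_subjects.csv", "_pet.csv", "_meta.json")))
  utils::write.csv(cohort$subjects, paths[1], row.names = FALSE, na = "")
  utils::write.csv(cohort$pet, paths[2], row.names = FALSE, na = "")
  jsonlite::write_json(list(protein_names = cohort$protein_names,
                            metabolite_names = cohort$metabolite_names,
                            clinical_threshold = cohort$clinical_threshold,
                            followup_months = cohort$followup_months),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a cohort from delimited text files
#'
#' Reads the files written by [write_cohort()]. Empty cells are parsed as
#' missing values, never as zero. Schema violations are reported with the
#' offending column names.
#'
#' @param dir directory containing the cohort files.
#' @param prefix file-name prefix used when writing.
#' @return a `csf_cohort`.
#' @export
load_cohort <- function(dir, prefix = "cohort") {
  paths <- file.path(dir, paste0(prefix, c("_subjects.csv", "_pet.csv", "_meta.json")))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0)
    stop("cohort file(s) not found: ", paste(missing_files, collapse = ", "))
  subjects <- utils::read.csv(paths[1], stringsAsFactors = FALSE,
                              na.strings = "", check.names = FALSE)
  pet <- utils::read.csv(paths[2], stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(subject_id = "character"))
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  csf_cohort(subjects, pet,
             protein_names = as.character(meta$protein_names),
             metabolite_names = as.character(meta$metabolite_names),
             clinical_threshold = meta$clinical_threshold,
             followup_months = meta$followup_months)
}
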