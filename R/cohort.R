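#' Load a cohort metadata table
#'
#' Reads a tab-separated cohort table with one row per lesion (multi-lesion
#' patients span several rows; patient-level fields may be left blank on
#' continuation rows). The packaged fixture
#' `system.file("extdata", "cohort_table1.tsv", package = "langmap")`
#' transcribes the 35-patient presurgical tumor cohort this package's
#' defaults are modeled on.
#'
#' @param path Path to a TSV with columns `patient_id`, `age_years`,
#'   `handedness`, `laterality_index`, `tumor_location`, `tumor_size_ml`,
#'   `tumor_pathology`.
#' @return An object of class `cohort_table`: `patients` (one row per
#'   patient with id, age bin, handedness, laterality index, pathology,
#'   lesion hemisphere, lesion count and total lesion volume in mL) and
#'   `lesions` (one row per lesion).
#' @examples
#' tab <- load_cohort_table(system.file("extdata", "cohort_table1.tsv",
#'                                      package = "langmap"))
#' nrow(tab$patients)
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) stopf("cohort table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stopf("parse error: %s has no data rows", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("patient_id", "age_years", "handedness", "laterality_index",
            "tumor_location", "tumor_size_ml", "tumor_pathology")
  if (!all(need %in% header))
    stopf("parse error: missing column(s) %s",
          paste(setdiff(need, header), collapse = ", "))
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(f) <- length(header)
    f[is.na(f)] <- ""
    names(f) <- header
    if (!nzchar(trimws(f["patient_id"])))
      stopf("parse error at line %d: empty patient id", i)
    vol <- suppressWarnings(as.numeric(f["tumor_size_ml"]))
    if (is.na(vol) || vol <= 0)
      stopf("parse error at line %d: lesion volume '%s' is not a positive number",
            i, f["tumor_size_ml"])
    f
  })
  lesions <- data.frame(
    patient_id = vapply(rows, `[[`, "", "patient_id"),
    location = vapply(rows, `[[`, "", "tumor_location"),
    volume_ml = as.numeric(vapply(rows, `[[`, "", "tumor_size_ml")),
    stringsAsFactors = FALSE)

  ids <- unique(lesions$patient_id)
  first <- function(id, col) {
    vals <- vapply(rows, `[[`, "", col)[lesions$patient_id == id]
    vals <- vals[nzchar(vals)]
    if (length(vals)) vals[1] else NA_character_
  }
  hemi <- function(loc) {
    if (grepl("^Left", loc)) "left"
    else if (grepl("^Right", loc)) "right"
    else if (grepl("^Bilateral", loc)) "bilateral"
    else NA_character_
  }
  patients <- data.frame(
    patient_id = ids,
    age_years = vapply(ids, first, "", col = "age_years"),
    handedness = vapply(ids, first, "", col = "handedness"),
    laterality_index = as.numeric(vapply(ids, first, "", col = "laterality_index")),
    pathology = vapply(ids, first, "", col = "tumor_pathology"),
    hemisphere = vapply(ids, function(id)
      hemi(lesions$location[lesions$patient_id == id][1]), ""),
    n_lesions = vapply(ids, function(id)
      sum(lesions$patient_id == id), 0L),
    total_volume_ml = vapply(ids, function(id)
      sum(lesions$volume_ml[lesions$patient_id == id]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  patients$handedness[patients$handedness == "NA"] <- NA_character_

  structure(list(patients = patients, lesions = lesions),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d patients, %d lesions, mean total lesion volume %.1f mL\n",
              nrow(x$patients), nrow(x$lesions), mean(x$patients$total_volume_ml)))
  invisible(x)
}
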