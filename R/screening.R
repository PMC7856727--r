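#' Screen a patient cohort against a PIM criteria set
#'
#' Applies the criteria to patient medication and condition records.
#' Each substance-level medication code is matched hierarchically against
#' every active statement's curated ATC code ([match_atc()]): statements
#' independent of diagnosis flag on a medication match alone; condition-
#' specific statements flag only when the patient also carries the
#' statement's condition. Printed-but-erroneous codes never drive matches.
#'
#' When one medication is matched by several statements of the same category
#' and condition whose codes nest (a class-level rule plus a more specific
#' member rule), the most specific statement keeps `is_primary = TRUE` and
#' the class-level match is retained as a secondary flag. Distinct
#' statements with equally specific codes (e.g. the same drug listed under
#' two indications) each yield a primary flag.
#'
#' Patients younger than `age_threshold` (default 65, the population the
#' criteria were developed for) are screened like everyone else but marked
#' `in_population = FALSE` in the per-patient table.
#'
#' @param medications Long-form tibble: `patient_id`, `age_years`,
#'   `atc_code` (one row per prescribed medication, substance level).
#' @param conditions Optional tibble: `patient_id`, `condition_id`. Unknown
#'   condition tokens trigger a warning and are ignored.
#' @param criteria A `criteria_set`.
#' @param include_questionable Also flag statements with status
#'   `QUESTIONABLE` (default `FALSE`: only the final included list fires).
#' @param age_threshold Age defining the target population.
#' @return A `screening_report`: [tidy()] returns the flag table,
#'   [glance()] the cohort summary including prevalence (the fraction of
#'   patients with at least one flag).
#' @export
#' @examples
#' meds <- tibble::tibble(patient_id = "p1", age_years = 78,
#'                        atc_code = "N05BA01")
#' conds <- tibble::tibble(patient_id = "p1",
#'                         condition_id = "dementia_cognitive_impairment")
#' rep <- screen_cohort(meds, conds, hk_pim_criteria())
#' generics::tidy(rep)
screen_cohort <- function(medications, conditions = NULL, criteria,
                          include_questionable = FALSE, age_threshold = 65) {
  stopifnot(inherits(criteria, "criteria_set"))
  medications <- as_tibble(medications)
  if (!all(c("patient_id", "age_years", "atc_code") %in% names(medications))) {
    stop_validation("medications must have columns patient_id, age_years, atc_code")
  }
  if (nrow(medications) == 0L) {
    stop_validation("empty cohort: no patient records")
  }
  ages <- distinct(medications, .data$patient_id, .data$age_years)
  dup <- ages$patient_id[duplicated(ages$patient_id)]
  if (length(dup) > 0L) {
    stop_validation(sprintf("patient_id with conflicting records: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  if (is.null(conditions)) {
    conditions <- tibble(patient_id = character(), condition_id = character())
  }
  conditions <- distinct(as_tibble(conditions))

  vocab <- unique(criteria$condition_id[nzchar(criteria$condition_id)])
  unknown <- setdiff(unique(conditions$condition_id), vocab)
  if (length(unknown) > 0L) {
    warn(sprintf("ignoring unknown condition token(s): %s",
                 paste(unknown, collapse = ", ")))
    conditions <- filter(conditions, .data$condition_id %in% vocab)
  }

  statuses <- "INCLUDED"
  if (include_questionable) statuses <- c(statuses, "QUESTIONABLE")
  stm <- filter(as_tibble(criteria), .data$status %in% statuses)
  stm <- select(stm, "statement_id", "category",
                statement_code = "atc_code_curated",
                condition_req = "condition_id")

  meds <- distinct(medications, .data$patient_id, .data$atc_code)
  cross <- tidyr::crossing(meds, stm)
  cross$match_level <- match_atc(cross$atc_code, cross$statement_code)
  hits <- filter(cross, !is.na(.data$match_level))
  cond_hits <- filter(hits, .data$category == "CONDITION_SPECIFIC")
  cond_hits <- semi_join(
    cond_hits, conditions,
    by = c(patient_id = "patient_id", condition_req = "condition_id")
  )
  ind_hits <- filter(hits, .data$category == "INDEPENDENT")
  flags <- bind_rows(ind_hits, cond_hits)
  flags <- tibble(
    patient_id = flags$patient_id,
    statement_id = flags$statement_id,
    matched_medication = flags$atc_code,
    match_level = flags$match_level,
    matched_condition = if_else(flags$category == "CONDITION_SPECIFIC",
                                flags$condition_req, NA_character_),
    category = flags$category,
    statement_code = flags$statement_code
  )
  flags <- distinct(flags)
  flags <- mark_primary_flags(flags)
  flags <- arrange(select(flags, -"statement_code"),
                   .data$patient_id, .data$statement_id,
                   .data$matched_medication)

  patients <- mutate(
    ages,
    n_flags = vapply(ages$patient_id,
                     function(p) sum(flags$patient_id == p), integer(1)),
    any_pim = .data$n_flags > 0L,
    in_population = .data$age_years >= age_threshold
  )
  structure(
    list(
      flags = flags,
      patients = patients,
      statement_hits = count(flags, .data$statement_id, .data$category,
                             name = "n_hits"),
      prevalence = mean(patients$any_pim),
      n_patients = nrow(patients),
      include_questionable = include_questionable,
      age_threshold = age_threshold
    ),
    class = "screening_report"
  )
}

empty_flag_table <- function() {
  tibble(patient_id = character(), statement_id = character(),
         matched_medication = character(), match_level = character(),
         matched_condition = character(), category = character(),
         is_primary = logical())
}

# within one (patient, medication, category, condition) family, a class-level
# match nested under a more specific match is demoted to a secondary flag
mark_primary_flags <- function(flags) {
  if (nrow(flags) == 0L) {
    flags$is_primary <- logical(0)
    return(flags)
  }
  key <- paste(flags$patient_id, flags$matched_medication, flags$category,
               coalesce(flags$matched_condition, ""), sep = "\r")
  flags$is_primary <- TRUE
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    codes <- flags$statement_code[idx]
    for (j in seq_along(idx)) {
      nested <- nchar(codes) > nchar(codes[j]) &
        substr(codes, 1L, nchar(codes[j])) == codes[j]
      if (any(nested)) flags$is_primary[idx[j]] <- FALSE
    }
  }
  flags
}

#' Screen a single patient
#'
#' Convenience wrapper around [screen_cohort()] for one patient record.
#'
#' @param atc_codes Character vector of substance-level medication codes.
#' @param condition_ids Character vector of condition tokens.
#' @param criteria A `criteria_set`.
#' @param age_years Patient age.
#' @param ... Passed on to [screen_cohort()].
#' @return The flag tibble for this patient (possibly zero rows).
#' @export
#' @examples
#' screen_patient("N05BA01", "dementia_cognitive_impairment",
#'                hk_pim_criteria())
screen_patient <- function(atc_codes, condition_ids = character(),
                           criteria, age_years = 65, ...) {
  if (length(atc_codes) == 0L) {
    return(empty_flag_table())
  }
  meds <- tibble(patient_id = "patient", age_years = age_years,
                 atc_code = atc_codes)
  conds <- tibble(patient_id = rep("patient", length(condition_ids)),
                  condition_id = condition_ids)
  screen_cohort(meds, conds, criteria, ...)$flags
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report: %d patients, %d flags>\n",
              x$n_patients, nrow(x$flags)))
  cat(sprintf("  any-PIM prevalence: %.1f%%\n", 100 * x$prevalence))
  invisible(x)
}

#' Read patient medication and condition records
#'
#' @param medications_path CSV with columns `patient_id`, `age_years`,
#'   `atc_code` (one row per prescribed medication).
#' @param conditions_path Optional CSV with columns `patient_id`,
#'   `condition_id`.
#' @return A list with elements `medications` and `conditions`.
#' @export
read_patient_records <- function(medications_path, conditions_path = NULL) {
  check_file_exists(medications_path, "medications file")
  meds <- readr::read_csv(medications_path,
                          col_types = readr::cols(
                            patient_id = readr::col_character(),
                            age_years = readr::col_double(),
                            atc_code = readr::col_character()
                          ))
  conds <- NULL
  if (!is.null(conditions_path)) {
    check_file_exists(conditions_path, "conditions file")
    conds <- readr::read_csv(conditions_path, col_types = "cc")
  }
  list(medications = meds, conditions = conds)
}

#' Write a screening report
#'
#' JSON output carries the full report (flags, per-patient table, summary);
#' TSV output is the flag table with stable column order.
#'
#' @param report A `screening_report`.
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @param meta Optional named list merged into the JSON header.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path, format = c("json", "tsv"),
                                   meta = list()) {
  format <- match.arg(format)
  stopifnot(inherits(report, "screening_report"))
  if (format == "tsv") {
    readr::write_tsv(report$flags, path)
  } else {
    doc <- c(meta, list(
      n_patients = report$n_patients,
      prevalence = report$prevalence,
      include_questionable = report$include_questionable,
      age_threshold = report$age_threshold,
      flags = report$flags,
      patients = report$patients
    ))
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
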