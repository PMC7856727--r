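criteria_columns <- c(
  "statement_id", "category", "class_name", "medication_name",
  "atc_code_printed", "atc_code_curated", "condition_id",
  "median", "iqr_low", "iqr_high", "status", "origin", "decided_round",
  "concerns", "alternatives"
)

errata_columns <- c(
  "statement_id", "field_name", "printed_value", "curated_value", "rationale"
)

empty_errata <- function() {
  tibble(statement_id = character(), field_name = character(),
         printed_value = character(), curated_value = character(),
         rationale = character())
}

chr_blank <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

#' Construct a criteria set
#'
#' A criteria set is a tibble of PIM statements (one row per statement) plus
#' an errata table recording curated corrections to values as printed in the
#' source tables. Most users will start from [hk_pim_criteria()] or
#' [load_criteria()] rather than calling this directly.
#'
#' @param statements A data frame with the criteria columns (see
#'   [load_criteria()] for the schema).
#' @param errata Optional errata data frame (`statement_id`, `field_name`,
#'   `printed_value`, `curated_value`, `rationale`).
#' @param name Label for the set.
#' @param check If `TRUE` (default), abort on any error-severity validation
#'   finding.
#' @return A `criteria_set`: a tibble subclass carrying `name` and `errata`
#'   attributes.
#' @export
new_criteria_set <- function(statements, errata = NULL, name = "criteria",
                             check = TRUE) {
  statements <- as_tibble(statements)
  missing <- setdiff(criteria_columns, names(statements))
  if (length(missing) > 0L) {
    stop_validation(sprintf("criteria table lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  statements <- select(statements, all_of(criteria_columns))
  statements <- mutate(
    statements,
    across(c("statement_id", "category", "class_name", "medication_name",
             "atc_code_printed", "atc_code_curated", "condition_id",
             "status", "origin", "concerns"), chr_blank),
    median = as.numeric(.data$median),
    iqr_low = as.numeric(.data$iqr_low),
    iqr_high = as.numeric(.data$iqr_high),
    decided_round = as.integer(.data$decided_round),
    alternatives = as_alternatives(.data$alternatives)
  )
  errata <- if (is.null(errata)) empty_errata() else as_tibble(errata)
  if (!setequal(names(errata), errata_columns)) {
    stop_validation(sprintf("errata table must have columns: %s",
                            paste(errata_columns, collapse = ", ")))
  }
  cs <- structure(statements,
                  class = c("criteria_set", class(tibble())),
                  name = name, errata = select(errata, all_of(errata_columns)))
  if (check) {
    report <- validate_criteria(cs)
    errs <- report[report$severity == "ERROR", ]
    if (nrow(errs) > 0L) {
      stop_validation(paste0(
        "invalid criteria set:\n",
        paste(sprintf("  [%s/%s] %s", errs$statement_id, errs$field,
                      errs$message), collapse = "\n")
      ))
    }
  }
  cs
}

as_alternatives <- function(x) {
  if (is.list(x)) {
    return(purrr::map(x, function(v) as.character(v[nzchar(v)])))
  }
  purrr::map(chr_blank(x), function(v) {
    if (!nzchar(v)) character(0) else strsplit(v, "|", fixed = TRUE)[[1]]
  })
}

#' Errata attached to a criteria set
#'
#' @param criteria A `criteria_set`.
#' @return The errata tibble.
#' @export
criteria_errata <- function(criteria) {
  attr(criteria, "errata") %||% empty_errata()
}

#' @export
print.criteria_set <- function(x, ...) {
  cat(sprintf("<criteria_set \"%s\": %d statements, %d errata>\n",
              attr(x, "name") %||% "criteria", nrow(x),
              nrow(criteria_errata(x))))
  NextMethod()
}

#' Load a criteria set from disk
#'
#' Reads a criteria file in the documented CSV or JSON layout and returns a
#' validated [new_criteria_set()]. The CSV schema has one row per statement
#' with columns `statement_id`, `category` (`INDEPENDENT` or
#' `CONDITION_SPECIFIC`), `class_name`, `medication_name`,
#' `atc_code_printed`, `atc_code_curated`, `condition_id`, `median`,
#' `iqr_low`, `iqr_high`, `status` (`INCLUDED`/`QUESTIONABLE`/`EXCLUDED`),
#' `origin` (`PRELIMINARY`/`PANEL_SUGGESTED`), `decided_round`, `concerns`
#' and pipe-separated `alternatives`. Errata live in a sibling file
#' `<name>_errata.csv` (CSV) or an `errata` element (JSON).
#'
#' Structural problems - a malformed curated ATC code, a median or quartile
#' outside \[1, 5\], `Q1 > Q3`, or a category/condition mismatch - abort with
#' a message naming the statement and field. Consensus-rule inconsistencies
#' are reported as warnings by [validate_criteria()], not load errors.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`.
#' @param errata For CSV input, an optional explicit errata file path;
#'   `NA` suppresses errata loading. Defaults to the sibling file when it
#'   exists.
#' @param name Label for the set; defaults to the file name.
#' @return A `criteria_set`.
#' @export
#' @examples
#' cs <- hk_pim_criteria()
#' dplyr::count(cs, category, status)
load_criteria <- function(path, format = c("csv", "json"), errata = NULL,
                          name = NULL) {
  format <- match.arg(format)
  check_file_exists(path, "criteria file")
  name <- name %||% basename(path)
  if (format == "csv") {
    statements <- readr::read_csv(
      path,
      col_types = readr::cols(
        median = readr::col_double(),
        iqr_low = readr::col_double(),
        iqr_high = readr::col_double(),
        decided_round = readr::col_integer(),
        .default = readr::col_character()
      )
    )
    if (is.null(errata)) {
      sibling <- paste0(sub("\\.csv$", "", path), "_errata.csv")
      errata_tbl <- if (file.exists(sibling)) read_errata(sibling) else NULL
    } else if (length(errata) == 1L && is.na(errata)) {
      errata_tbl <- NULL
    } else {
      errata_tbl <- read_errata(errata)
    }
  } else {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    statements <- as_tibble(doc$statements)
    if (nrow(statements) > 0L && is.list(statements$alternatives)) {
      statements$alternatives <- purrr::map(statements$alternatives,
                                            as.character)
    }
    errata_tbl <- if (!is.null(doc$errata) && length(doc$errata) > 0L) {
      as_tibble(doc$errata)
    } else {
      NULL
    }
    name <- doc$name %||% name
  }
  new_criteria_set(statements, errata = errata_tbl, name = name)
}

read_errata <- function(path) {
  check_file_exists(path, "errata file")
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Write a criteria set to disk
#'
#' Inverse of [load_criteria()]: a written set reloads field-for-field.
#' For CSV output the errata (if any) go to the sibling file
#' `<path without .csv>_errata.csv`; JSON output is a single document.
#'
#' @param criteria A `criteria_set`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(criteria, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(criteria, "criteria_set"))
  errata <- criteria_errata(criteria)
  flat <- as_tibble(criteria)
  flat$alternatives <- purrr::map_chr(flat$alternatives, paste, collapse = "|")
  if (format == "csv") {
    readr::write_csv(flat, path, na = "")
    if (nrow(errata) > 0L) {
      readr::write_csv(errata, paste0(sub("\\.csv$", "", path), "_errata.csv"),
                       na = "")
    }
  } else {
    doc <- list(
      name = attr(criteria, "name") %||% "criteria",
      statements = mutate(as_tibble(criteria),
                          alternatives = purrr::map(.data$alternatives,
                                                    as.character)),
      errata = errata
    )
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Validate a criteria set
#'
#' Checks every statement invariant (id uniqueness, enum values, quartile
#' ordering and ranges, ATC grammar, category/condition coherence) and the
#' coherence between each statement's printed consensus summary and its
#' status. A statement whose status is `INCLUDED` but whose printed
#' (median, IQR) fails the consensus rule is a `WARNING`; in `strict` mode
#' such warnings escalate to `ERROR` unless the statement carries a
#' `status` erratum documenting the inconsistency.
#'
#' @param criteria A `criteria_set`.
#' @param config A [delphi_config()] supplying the consensus thresholds.
#' @param strict Escalate uncovered warnings to errors.
#' @return A tibble of findings (`statement_id`, `field`, `severity`,
#'   `message`); zero rows when the set is clean.
#' @export
#' @examples
#' validate_criteria(hk_pim_criteria())
validate_criteria <- function(criteria, config = delphi_config(),
                              strict = FALSE) {
  st <- as_tibble(criteria)
  errata <- criteria_errata(criteria)
  finding <- function(id, field, severity, message) {
    tibble(statement_id = id, field = field, severity = severity,
           message = message)
  }
  out <- list()
  dup <- st$statement_id[duplicated(st$statement_id)]
  if (length(dup) > 0L) {
    out <- c(out, list(finding(unique(dup), "statement_id", "ERROR",
                               "duplicate statement_id")))
  }
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    id <- row$statement_id
    if (!nzchar(id)) {
      out <- c(out, list(finding("<blank>", "statement_id", "ERROR",
                                 sprintf("row %d has no statement_id", i))))
      next
    }
    if (!row$category %in% pim_categories) {
      out <- c(out, list(finding(id, "category", "ERROR",
                                 sprintf("unknown category '%s'", row$category))))
    }
    if (!row$status %in% pim_statuses) {
      out <- c(out, list(finding(id, "status", "ERROR",
                                 sprintf("unknown status '%s'", row$status))))
    }
    if (!row$origin %in% pim_origins) {
      out <- c(out, list(finding(id, "origin", "ERROR",
                                 sprintf("unknown origin '%s'", row$origin))))
    }
    if (!isTRUE(row$decided_round %in% c(1L, 2L))) {
      out <- c(out, list(finding(id, "decided_round", "ERROR",
                                 "decided_round must be 1 or 2")))
    }
    qs <- c(row$iqr_low, row$median, row$iqr_high)
    if (anyNA(qs) || any(qs < 1 | qs > 5)) {
      out <- c(out, list(finding(id, "median", "ERROR",
                                 "median and quartiles must lie in [1, 5]")))
    } else if (row$iqr_low > row$iqr_high) {
      out <- c(out, list(finding(id, "iqr_low", "ERROR", "Q1 > Q3")))
    } else if (row$median < row$iqr_low || row$median > row$iqr_high) {
      out <- c(out, list(finding(id, "median", "ERROR",
                                 "median outside [Q1, Q3]")))
    }
    if (row$category == "CONDITION_SPECIFIC" && !nzchar(row$condition_id)) {
      out <- c(out, list(finding(id, "condition_id", "ERROR",
                                 "condition-specific statement lacks a condition")))
    }
    if (row$category == "INDEPENDENT" && nzchar(row$condition_id)) {
      out <- c(out, list(finding(id, "condition_id", "ERROR",
                                 "independent statement carries a condition")))
    }
    if (!atc_valid(row$atc_code_curated)) {
      out <- c(out, list(finding(id, "atc_code_curated", "ERROR",
                                 sprintf("malformed ATC code '%s'",
                                         row$atc_code_curated))))
    }
    # printed codes may be blank (not printed) or wrong only under an erratum
    if (nzchar(row$atc_code_printed) && !atc_valid(row$atc_code_printed)) {
      covered <- any(errata$statement_id == id &
                       errata$field_name == "atc_code")
      if (!covered) {
        out <- c(out, list(finding(id, "atc_code_printed", "ERROR",
                                   sprintf("malformed ATC code '%s'",
                                           row$atc_code_printed))))
      }
    }
  }
  # consensus/status coherence for structurally sound rows
  sound <- st$median >= 1 & st$median <= 5 &
    st$iqr_low <= st$iqr_high &
    !is.na(st$median) & !is.na(st$iqr_low) & !is.na(st$iqr_high) &
    st$status %in% pim_statuses
  for (i in which(sound)) {
    row <- st[i, ]
    cls <- classify_statement(row$median,
                              snap_quarter(row$iqr_high - row$iqr_low), config)
    if (cls != row$status) {
      covered <- any(errata$statement_id == row$statement_id &
                       errata$field_name == "status")
      severity <- if (strict && !covered) "ERROR" else "WARNING"
      out <- c(out, list(finding(
        row$statement_id, "status", severity,
        sprintf("status %s but consensus rule gives %s (median %.2f, IQR width %.2f)%s",
                row$status, cls, row$median,
                snap_quarter(row$iqr_high - row$iqr_low),
                if (covered) "; covered by erratum" else "")
      )))
    }
  }
  orphan <- setdiff(errata$statement_id, st$statement_id)
  if (length(orphan) > 0L) {
    out <- c(out, list(finding(orphan, "errata", "ERROR",
                               "erratum references unknown statement_id")))
  }
  if (length(out) == 0L) {
    return(tibble(statement_id = character(), field = character(),
                  severity = character(), message = character()))
  }
  bind_rows(out)
}

#' The packaged Hong Kong-specific PIM criteria
#'
#' Returns the packaged 172-row transcription of the published Hong
#' Kong-specific PIM list: the 77 final statements independent of diagnosis,
#' the 87 final condition-specific statements, and the 8 questionable
#' candidates the panel did not reach consensus on (which appear with status
#' `QUESTIONABLE` and are not part of the 164-statement final list). Two
#' panel-suggested analgesic statements appear both among the questionables
#' and - as printed - in the final independent-of-diagnosis table; the
#' contradiction is surfaced by [validate_criteria()] and documented in the
#' errata, which also record five drug-name/ATC-code mismatches in the
#' printed new-PIM rows.
#'
#' Matching in [screen_cohort()] always uses `atc_code_curated`;
#' `atc_code_printed` preserves the codes as printed for auditability.
#'
#' @return A `criteria_set` with 172 statements.
#' @export
#' @examples
#' cs <- hk_pim_criteria()
#' sum(cs$status == "INCLUDED")
hk_pim_criteria <- function() {
  if (is.null(the$hk_criteria)) {
    path <- system.file("extdata", "hk_pim_criteria.csv", package = "hkpim",
                        mustWork = TRUE)
    the$hk_criteria <- load_criteria(path, name = "hk_pim_criteria")
  }
  the$hk_criteria
}

#' Controlled vocabulary of medical conditions
#'
#' Condition identifiers are lower-snake-case tokens derived from the
#' disease/syndrome labels of the condition-specific criteria table; no
#' ICD coding is attempted.
#'
#' @return A tibble with columns `condition_id` and `label`.
#' @export
hk_conditions <- function() {
  path <- system.file("extdata", "hk_pim_conditions.csv", package = "hkpim",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "cc")
}
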