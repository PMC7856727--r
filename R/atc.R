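#' ATC code grammar and hierarchy
#'
#' The WHO Anatomical Therapeutic Chemical (ATC) classification assigns drug
#' codes at five hierarchical levels, distinguished purely by code length:
#' 1 character (anatomical main group), 3 (therapeutic subgroup),
#' 4 (pharmacological subgroup), 5 (chemical subgroup) and 7 (substance).
#' `atc_valid()` checks a code against this grammar; `atc_level()` returns
#' the level (1 to 5) and errors on invalid codes.
#'
#' @param code Character vector of candidate ATC codes.
#' @return `atc_valid()`: a logical vector. `atc_level()`: an integer vector
#'   with values in `1:5`.
#' @export
#' @examples
#' atc_valid(c("N05BA01", "N05BA", "N05B", "N05", "N", "N05BA012"))
#' atc_level(c("N", "N05", "N05B", "N05BA", "N05BA01"))
atc_valid <- function(code) {
  code <- as.character(code)
  !is.na(code) &
    grepl("^[A-Z0-9]+$", code) &
    nchar(code) %in% c(1L, 3L, 4L, 5L, 7L)
}

#' @rdname atc_valid
#' @export
atc_level <- function(code) {
  ok <- atc_valid(code)
  if (!all(ok)) {
    stop_validation(sprintf(
      "invalid ATC code(s): %s",
      paste(unique(code[!ok]), collapse = ", ")
    ))
  }
  match(nchar(code), c(1L, 3L, 4L, 5L, 7L))
}

#' Hierarchical ATC matching
#'
#' Matches a substance-level (7-character) patient medication code against a
#' criteria statement code at any ATC level. A statement written at substance
#' level matches only the identical code (`"EXACT"`); a statement written at
#' class level matches every substance whose code it prefixes
#' (`"CLASS_PREFIX"`). Sibling substances never match.
#'
#' @param patient_code Substance-level (7-character) ATC code(s).
#' @param statement_code Statement ATC code(s) at any level. Recycled against
#'   `patient_code` in the usual vectorised way.
#' @return A character vector: `"EXACT"`, `"CLASS_PREFIX"`, or `NA` for no
#'   match.
#' @export
#' @examples
#' match_atc("C02CA01", "C02CA01")  # EXACT
#' match_atc("C02AB01", "C02AB")    # CLASS_PREFIX
#' match_atc("N05BA02", "N05BA01")  # NA (sibling substance)
match_atc <- function(patient_code, statement_code) {
  if (!all(atc_valid(patient_code)) || !all(nchar(patient_code) == 7L)) {
    stop_validation("patient medication codes must be valid substance-level (7-character) ATC codes")
  }
  if (!all(atc_valid(statement_code))) {
    stop_validation(sprintf(
      "invalid statement ATC code(s): %s",
      paste(unique(statement_code[!atc_valid(statement_code)]), collapse = ", ")
    ))
  }
  n <- max(length(patient_code), length(statement_code))
  p <- rep_len(patient_code, n)
  s <- rep_len(statement_code, n)
  out <- rep(NA_character_, n)
  out[p == s] <- "EXACT"
  prefix <- nchar(s) < 7L & substr(p, 1L, nchar(s)) == s
  out[is.na(out) & prefix] <- "CLASS_PREFIX"
  out
}
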