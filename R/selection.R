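#' Select PIM candidates from a reference-criteria incidence table
#'
#' Applies the preliminary-list selection rule: a medication or medication
#' class is a PIM candidate when it appears on at least two of the nine
#' reference lists, and - when it appears on exactly two - one of the two is
#' the Beers list. Three or more lists suffice without the Beers condition.
#'
#' @param incidence A tibble with columns `entity`, `atc_code`, one logical
#'   column per reference list (see [reference_list_names()]), and
#'   `conditions` (pipe-separated condition tokens, may be empty).
#' @param min_lists Membership threshold; the published rule is the default
#'   2. An entity is selected when it appears on more than `min_lists` lists,
#'   or on exactly `min_lists` lists one of which is `Beers2015`. Raising the
#'   threshold can only shrink the selected set.
#' @return The selected rows, in input order, with an `n_lists` count column
#'   appended.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   entity = c("diazepam", "naproxen", "digoxin"),
#'   atc_code = c("N05BA01", "M01AE02", "C01AA05"),
#'   McLeod = FALSE, Rancourt = FALSE, Lindblad = FALSE, Laroche = FALSE,
#'   WinitWatjana = FALSE, NORGEP = FALSE,
#'   PRISCUS = c(TRUE, TRUE, FALSE),
#'   STOPPv2 = c(TRUE, TRUE, FALSE),
#'   Beers2015 = c(TRUE, FALSE, TRUE),
#'   conditions = ""
#' )
#' select_candidates(tab)$entity
select_candidates <- function(incidence, min_lists = 2) {
  incidence <- as_tibble(incidence)
  lists <- reference_list_names()
  known <- c("entity", "atc_code", "conditions", lists)
  unknown <- setdiff(names(incidence), known)
  if (length(unknown) > 0L) {
    stop_validation(sprintf("unknown reference list identifier(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(c("entity", lists), names(incidence))
  if (length(missing) > 0L) {
    stop_validation(sprintf("incidence table lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  m <- as.matrix(incidence[, lists])
  mode(m) <- "logical"
  if (anyNA(m)) stop_validation("membership flags must be TRUE/FALSE")
  n_lists <- rowSums(m)
  keep <- n_lists > min_lists |
    (n_lists == min_lists & m[, "Beers2015"])
  mutate(incidence[keep, , drop = FALSE], n_lists = n_lists[keep])
}

#' Drug formulary objects
#'
#' A formulary is the set of ATC codes available for prescribing, plus a map
#' from class-level codes to their member substance codes (used to expand
#' class-level PIM candidates into individual medications).
#'
#' @param codes Character vector of available ATC codes.
#' @param class_members Optional tibble with columns `class_code`,
#'   `member_code`; every member must carry its class code as a prefix.
#' @return A `formulary` object.
#' @export
new_formulary <- function(codes, class_members = NULL) {
  codes <- unique(as.character(codes))
  if (!all(atc_valid(codes))) {
    stop_validation(sprintf("malformed formulary ATC code(s): %s",
                            paste(codes[!atc_valid(codes)], collapse = ", ")))
  }
  if (is.null(class_members)) {
    class_members <- tibble(class_code = character(), member_code = character())
  }
  class_members <- as_tibble(class_members)
  stopifnot(all(c("class_code", "member_code") %in% names(class_members)))
  bad <- substr(class_members$member_code, 1L,
                nchar(class_members$class_code)) != class_members$class_code
  if (any(bad)) {
    stop_validation("every formulary class member must have its class code as a prefix")
  }
  structure(list(codes = codes, class_members = class_members),
            class = "formulary")
}

#' @export
print.formulary <- function(x, ...) {
  cat(sprintf("<formulary: %d codes, %d class-member links>\n",
              length(x$codes), nrow(x$class_members)))
  invisible(x)
}

#' @rdname new_formulary
#' @param path CSV with columns `atc_code` and `member_of`; rows with a
#'   non-empty `member_of` define the class-member map.
#' @export
read_formulary <- function(path) {
  check_file_exists(path, "formulary file")
  raw <- readr::read_csv(path, col_types = "cc")
  raw$member_of <- chr_blank(raw$member_of)
  members <- filter(raw, nzchar(.data$member_of))
  new_formulary(
    codes = raw$atc_code,
    class_members = tibble(class_code = members$member_of,
                           member_code = members$atc_code)
  )
}

#' A small synthetic demonstration formulary
#'
#' A stand-in for a real hospital drug formulary, constructed for examples
#' and tests: it covers a subset of the packaged criteria's ATC universe with
#' a class-member map. It is synthetic and carries no information about any
#' actual formulary's contents.
#'
#' @return A `formulary`.
#' @export
synthetic_formulary <- function() {
  read_formulary(system.file("extdata", "formulary_synthetic.csv",
                             package = "hkpim", mustWork = TRUE))
}

#' Filter selected candidates by formulary availability
#'
#' Retains exactly the candidates whose ATC code - or, for class-level
#' codes, at least one class member - is available on the formulary.
#' The result is always a subset of the input and the operation is
#' idempotent.
#'
#' @param selected Tibble of candidates with an `atc_code` column.
#' @param formulary A [new_formulary()] object.
#' @return The retained rows, in input order.
#' @export
filter_by_formulary <- function(selected, formulary) {
  stopifnot(inherits(formulary, "formulary"))
  selected <- as_tibble(selected)
  code <- chr_blank(selected$atc_code)
  if (any(!nzchar(code))) {
    stop_validation(sprintf("candidate(s) without an ATC code: %s",
                            paste(selected$entity[!nzchar(code)],
                                  collapse = ", ")))
  }
  member_hit <- vapply(code, function(cc) {
    members <- formulary$class_members$member_code[
      formulary$class_members$class_code == cc]
    any(members %in% formulary$codes)
  }, logical(1))
  selected[code %in% formulary$codes | member_hit, , drop = FALSE]
}

#' Expand a class-level code into its formulary member medications
#'
#' Class-level PIM candidates are expanded into the individual medications
#' the formulary lists under that class. A substance-level (7-character)
#' code is returned unchanged.
#'
#' @param code A single ATC code.
#' @param formulary A [new_formulary()] object.
#' @return Character vector of substance-level member codes.
#' @export
#' @examples
#' f <- new_formulary(c("N05BA01", "N05BA06"),
#'                    tibble::tibble(class_code = "N05BA",
#'                                   member_code = c("N05BA01", "N05BA06")))
#' expand_class_members("N05BA", f)
#' expand_class_members("N05BA01", f)
expand_class_members <- function(code, formulary) {
  stopifnot(inherits(formulary, "formulary"), length(code) == 1L)
  if (!atc_valid(code)) {
    stop_validation(sprintf("malformed ATC code '%s'", code))
  }
  if (nchar(code) == 7L) {
    return(code)
  }
  if (!code %in% formulary$class_members$class_code) {
    stop_validation(sprintf("class code %s absent from the formulary class-member map", code))
  }
  members <- formulary$class_members$member_code[
    formulary$class_members$class_code == code]
  members <- unique(members)
  if (length(members) == 0L) {
    warn(sprintf("class %s has no member medications on the formulary", code))
  }
  members
}

#' Read a reference-criteria incidence table
#'
#' @param path CSV with columns `entity`, `atc_code`, one TRUE/FALSE column
#'   per reference list, and pipe-separated `conditions`.
#' @return A tibble suitable for [select_candidates()].
#' @export
read_incidence <- function(path) {
  check_file_exists(path, "incidence file")
  raw <- readr::read_csv(path, show_col_types = FALSE)
  lists <- intersect(reference_list_names(), names(raw))
  raw <- mutate(raw, across(all_of(lists), as.logical))
  if ("conditions" %in% names(raw)) {
    raw$conditions <- chr_blank(raw$conditions)
  }
  raw
}
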