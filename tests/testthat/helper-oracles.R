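# Independent reference implementations used as oracles. These deliberately
# share no code with the package: quartiles via direct sorted-index
# arithmetic, screening via a naive triple loop.

oracle_quartiles <- function(x, method = "linear_interpolation") {
  x <- sort(x)
  n <- length(x)
  if (method == "linear_interpolation") {
    q <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      hi <- ceiling(h)
      x[lo] + (h - lo) * (x[hi] - x[lo])
    }
    return(c(q(0.25), q(0.5), q(0.75)))
  }
  if (method == "nearest_rank") {
    return(x[pmax(1, ceiling(c(0.25, 0.5, 0.75) * n))])
  }
  if (method == "tukey_hinges") {
    med <- function(v) {
      m <- length(v)
      if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
    }
    half <- floor((n + 1) / 2)
    return(c(med(x[1:half]), med(x), med(x[(n + 1 - half):n])))
  }
  stop("unknown method")
}

# all multisets of {1..5} of a given size, as a list of integer vectors
all_likert_multisets <- function(n) {
  out <- list()
  for (c1 in 0:n) for (c2 in 0:(n - c1)) for (c3 in 0:(n - c1 - c2)) {
    for (c4 in 0:(n - c1 - c2 - c3)) {
      c5 <- n - c1 - c2 - c3 - c4
      out[[length(out) + 1L]] <- rep(1:5, times = c(c1, c2, c3, c4, c5))
    }
  }
  out
}

# brute-force screening: nested loops over patients x medications x
# statements with a naive prefix test, per-patient condition check
brute_force_screen <- function(medications, conditions, criteria,
                               include_questionable = FALSE) {
  st <- as.data.frame(criteria)
  statuses <- if (include_questionable) c("INCLUDED", "QUESTIONABLE") else "INCLUDED"
  st <- st[st$status %in% statuses, ]
  rows <- list()
  for (pid in unique(medications$patient_id)) {
    meds <- unique(medications$atc_code[medications$patient_id == pid])
    conds <- conditions$condition_id[conditions$patient_id == pid]
    for (med in meds) {
      for (i in seq_len(nrow(st))) {
        code <- st$atc_code_curated[i]
        hit <- if (med == code) {
          "EXACT"
        } else if (nchar(code) < 7 && substr(med, 1, nchar(code)) == code) {
          "CLASS_PREFIX"
        } else {
          NA_character_
        }
        if (is.na(hit)) next
        if (st$category[i] == "CONDITION_SPECIFIC" &&
            !(st$condition_id[i] %in% conds)) next
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid,
          statement_id = st$statement_id[i],
          matched_medication = med,
          match_level = hit,
          matched_condition = if (st$category[i] == "CONDITION_SPECIFIC")
            st$condition_id[i] else NA_character_,
          category = st$category[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(patient_id = character(), statement_id = character(),
                      matched_medication = character(),
                      match_level = character(),
                      matched_condition = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$patient_id, out$statement_id, out$matched_medication), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

sort_flags <- function(flags) {
  flags <- as.data.frame(flags)[, c("patient_id", "statement_id",
                                    "matched_medication", "match_level",
                                    "matched_condition", "category")]
  out <- flags[order(flags$patient_id, flags$statement_id,
                     flags$matched_medication), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# minimal self-consistent criteria set for targeted tests
make_test_criteria <- function(rows, errata = NULL, name = "test") {
  defaults <- tibble::tibble(
    statement_id = NA_character_, category = "INDEPENDENT",
    class_name = "Test class", medication_name = "testdrug",
    atc_code_printed = "", atc_code_curated = "N05BA01", condition_id = "",
    median = 4, iqr_low = 3.5, iqr_high = 4.5, status = "INCLUDED",
    origin = "PRELIMINARY", decided_round = 1L, concerns = "",
    alternatives = ""
  )
  filled <- lapply(rows, function(r) {
    out <- defaults
    for (k in names(r)) out[[k]] <- r[[k]]
    out
  })
  new_criteria_set(dplyr::bind_rows(filled), errata = errata, name = name)
}
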