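#' Consensus thresholds and quantile rule for the Delphi engine
#'
#' Configuration for the two-round modified Delphi consensus procedure.
#' A statement is *included* when its rating median is at least
#' `include_median_min` (default 3.5) and the interquartile-range width
#' `Q3 - Q1` is at most `iqr_max` (default 1.5); it is *excluded* when the
#' median falls below `exclude_median_max` (default 3.0); everything else is
#' *questionable*. Exclusion takes precedence when both the low-median and
#' wide-IQR conditions hold.
#'
#' The quantile rule matters with seven or eight raters. The default,
#' `"linear_interpolation"` (the empirical-CDF interpolation used by most
#' spreadsheets and by [stats::quantile()] type 7), reproduces quarter-step
#' quartiles such as 2.75 or 4.25 with eight raters and half-step quartiles
#' with seven. `"nearest_rank"` (type 1) and `"tukey_hinges"`
#' ([stats::fivenum()]) are provided for sensitivity analysis.
#'
#' @param include_median_min Minimum median for inclusion (on the 1-5 Likert
#'   scale).
#' @param exclude_median_max Exclusive upper median bound for exclusion.
#' @param iqr_max Maximum IQR width `Q3 - Q1` compatible with consensus.
#' @param quantile_method One of `"linear_interpolation"`, `"nearest_rank"`,
#'   `"tukey_hinges"`.
#' @return An object of class `delphi_config`.
#' @export
#' @examples
#' delphi_config()
#' delphi_config(quantile_method = "tukey_hinges")
delphi_config <- function(include_median_min = 3.5,
                          exclude_median_max = 3.0,
                          iqr_max = 1.5,
                          quantile_method = c("linear_interpolation",
                                              "nearest_rank",
                                              "tukey_hinges")) {
  quantile_method <- match.arg(quantile_method)
  if (!(exclude_median_max >= 1 && exclude_median_max <= include_median_min &&
        include_median_min <= 5)) {
    stop_validation("need 1 <= exclude_median_max <= include_median_min <= 5")
  }
  if (iqr_max < 0) stop_validation("iqr_max must be non-negative")
  structure(
    list(include_median_min = include_median_min,
         exclude_median_max = exclude_median_max,
         iqr_max = iqr_max,
         quantile_method = quantile_method),
    class = "delphi_config"
  )
}

#' @export
print.delphi_config <- function(x, ...) {
  cat("<delphi_config>\n")
  cat(sprintf("  include: median >= %.2f and IQR width <= %.2f\n",
              x$include_median_min, x$iqr_max))
  cat(sprintf("  exclude: median < %.2f\n", x$exclude_median_max))
  cat(sprintf("  quantile method: %s\n", x$quantile_method))
  invisible(x)
}

check_ratings <- function(ratings) {
  if (length(ratings) == 0L) {
    stop_validation("rating vector is empty")
  }
  if (!is.numeric(ratings) || anyNA(ratings) ||
      any(ratings != as.integer(ratings)) || any(ratings < 1 | ratings > 5)) {
    stop_validation("ratings must be integers between 1 and 5")
  }
  as.integer(ratings)
}

# All three rules land on multiples of 1/4 for integer Likert input; snapping
# removes binary floating-point dust so threshold comparisons are exact.
snap_quarter <- function(x) round(x * 4) / 4

likert_quartiles <- function(ratings, quantile_method = "linear_interpolation") {
  q <- switch(
    quantile_method,
    linear_interpolation = quantile(ratings, c(0.25, 0.5, 0.75),
                                    type = 7, names = FALSE),
    nearest_rank = quantile(ratings, c(0.25, 0.5, 0.75),
                            type = 1, names = FALSE),
    tukey_hinges = fivenum(ratings)[2:4],
    stop_validation(sprintf("unknown quantile method: %s", quantile_method))
  )
  snap_quarter(q)
}

#' Classify a statement from its rating median and IQR width
#'
#' Applies the consensus thresholds to a (median, IQR width) summary. The
#' classification is total over medians in \[1, 5\] and widths in \[0, 4\]:
#' every summary maps to exactly one of `"INCLUDED"`, `"EXCLUDED"`,
#' `"QUESTIONABLE"`.
#'
#' @param median Rating median(s) in \[1, 5\].
#' @param iqr_width IQR width(s) `Q3 - Q1` in \[0, 4\].
#' @param config A [delphi_config()].
#' @return Character vector of classifications.
#' @export
#' @examples
#' classify_statement(3.0, 1.0)  # QUESTIONABLE: median in [3, 3.5)
#' classify_statement(2.0, 1.0)  # EXCLUDED
#' classify_statement(4.0, 2.0)  # QUESTIONABLE: IQR width > 1.5
classify_statement <- function(median, iqr_width, config = delphi_config()) {
  if (anyNA(median) || anyNA(iqr_width) ||
      any(median < 1 | median > 5) || any(iqr_width < 0 | iqr_width > 4)) {
    stop_validation("median must lie in [1, 5] and iqr_width in [0, 4]")
  }
  out <- rep("QUESTIONABLE", max(length(median), length(iqr_width)))
  m <- rep_len(median, length(out))
  w <- rep_len(iqr_width, length(out))
  out[m < config$exclude_median_max] <- "EXCLUDED"
  out[m >= config$exclude_median_max &
        m >= config$include_median_min & w <= config$iqr_max] <- "INCLUDED"
  out
}

#' Median/IQR consensus summary for one rating vector
#'
#' Computes median, first and third quartiles, IQR width, and the resulting
#' classification for a single statement's expert ratings.
#'
#' @param ratings Integer Likert ratings in 1-5, one per responding expert.
#' @param config A [delphi_config()].
#' @return A one-row tibble with columns `n_ratings`, `median`, `q1`, `q3`,
#'   `iqr_width`, `classification`.
#' @export
#' @examples
#' compute_consensus(c(4, 4, 5, 5, 5, 5, 5, 5))
#' compute_consensus(c(1, 2, 3, 4, 4, 5, 5))
compute_consensus <- function(ratings, config = delphi_config()) {
  ratings <- check_ratings(ratings)
  q <- likert_quartiles(ratings, config$quantile_method)
  tibble(
    n_ratings = length(ratings),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    iqr_width = snap_quarter(q[3] - q[1]),
    classification = classify_statement(q[2], snap_quarter(q[3] - q[1]), config)
  )
}

#' Run one round of the modified Delphi process
#'
#' Computes a consensus summary for every candidate statement and partitions
#' the candidates into included, excluded and questionable sets. Missing
#' ratings (e.g. after a panelist drops out) are simply omitted from a
#' statement's rating vector, never imputed.
#'
#' @param candidates Character vector of statement ids to evaluate.
#' @param ratings Long-form ratings: a data frame with columns
#'   `statement_id`, `expert_id`, `rating` (integer 1-5; `NA` rows are
#'   dropped). See [read_ratings()] for the wide CSV layout.
#' @param round_no Round number (1 or 2), recorded in the result.
#' @param config A [delphi_config()].
#' @return A `delphi_round` object. [tidy()] returns the per-statement
#'   consensus table; [glance()] the partition sizes.
#' @export
#' @examples
#' ratings <- tibble::tibble(
#'   statement_id = rep(c("A", "B", "C"), each = 8),
#'   expert_id = rep(paste0("E", 1:8), times = 3),
#'   rating = rep(c(5L, 1L, 3L), each = 8)
#' )
#' rr <- run_round(c("A", "B", "C"), ratings)
#' generics::glance(rr)
run_round <- function(candidates, ratings, round_no = 1,
                      config = delphi_config()) {
  if (!all(c("statement_id", "expert_id", "rating") %in% names(ratings))) {
    stop_validation("ratings must have columns statement_id, expert_id, rating")
  }
  if (!round_no %in% c(1, 2)) {
    stop_validation("round_no must be 1 or 2")
  }
  candidates <- as.character(candidates)
  ratings <- filter(ratings, !is.na(.data$rating))
  missing <- setdiff(candidates, unique(ratings$statement_id))
  if (length(missing) > 0L) {
    stop_validation(sprintf(
      "candidate(s) without ratings: %s", paste(missing, collapse = ", ")
    ))
  }
  results <- purrr::map_dfr(candidates, function(id) {
    rv <- ratings$rating[ratings$statement_id == id]
    mutate(compute_consensus(rv, config), statement_id = id, .before = 1L)
  })
  if (nrow(results) == 0L) {
    results <- tibble(statement_id = character(), n_ratings = integer(),
                      median = numeric(), q1 = numeric(), q3 = numeric(),
                      iqr_width = numeric(), classification = character())
  }
  structure(
    list(round_no = as.integer(round_no), results = results, config = config),
    class = "delphi_round"
  )
}

round_ids <- function(x, classification) {
  x$results$statement_id[x$results$classification == classification]
}

#' @export
print.delphi_round <- function(x, ...) {
  cat(sprintf("<delphi_round %d: %d candidates>\n", x$round_no,
              nrow(x$results)))
  tab <- table(factor(x$results$classification, levels = pim_statuses))
  cat(sprintf("  included %d, questionable %d, excluded %d\n",
              tab[["INCLUDED"]], tab[["QUESTIONABLE"]], tab[["EXCLUDED"]]))
  invisible(x)
}

#' Assemble the final PIM list from two Delphi rounds
#'
#' The final included set is the union of the statements included in round 1
#' and in round 2. Statements still questionable after round 2, and all
#' excluded statements, carry non-included status. Round-2 candidates must be
#' disjoint from the round-1 included set (they are the round-1 questionables
#' plus panel-suggested additions).
#'
#' @param round1,round2 `delphi_round` objects from [run_round()].
#' @param statements Optional metadata joined onto the result; a data frame
#'   with `statement_id` and (typically) `category`.
#' @return A `pim_final_list` object: [tidy()] gives one row per statement
#'   with `status` and `decided_round`; [glance()] gives headline counts.
#' @export
assemble_final_list <- function(round1, round2, statements = NULL) {
  stopifnot(inherits(round1, "delphi_round"), inherits(round2, "delphi_round"))
  overlap <- intersect(round_ids(round1, "INCLUDED"),
                       round2$results$statement_id)
  if (length(overlap) > 0L) {
    stop_validation(sprintf(
      "round-2 candidates overlap the round-1 included set: %s",
      paste(head(overlap, 5L), collapse = ", ")
    ))
  }
  carried <- round2$results$statement_id
  r1 <- filter(round1$results, !.data$statement_id %in% carried)
  out <- bind_rows(
    tibble(statement_id = r1$statement_id,
           status = r1$classification,
           decided_round = 1L),
    tibble(statement_id = round2$results$statement_id,
           status = round2$results$classification,
           decided_round = 2L)
  )
  if (!is.null(statements)) {
    out <- left_join(out, as_tibble(statements), by = "statement_id")
  }
  structure(list(statements = out), class = "pim_final_list")
}

#' @export
print.pim_final_list <- function(x, ...) {
  st <- x$statements
  inc <- st[st$status == "INCLUDED", ]
  cat(sprintf("<pim_final_list: %d statements included of %d candidates>\n",
              nrow(inc), nrow(st)))
  if ("category" %in% names(st)) {
    cat(sprintf("  independent %d, condition-specific %d\n",
                sum(inc$category == "INDEPENDENT", na.rm = TRUE),
                sum(inc$category == "CONDITION_SPECIFIC", na.rm = TRUE)))
  }
  invisible(x)
}

#' Read and write expert rating matrices
#'
#' The on-disk layout is wide: one row per statement, one column per expert,
#' with the first column named `statement_id` and blank cells marking missing
#' ratings. In memory ratings are long tibbles with columns `statement_id`,
#' `expert_id`, `rating`.
#'
#' @param path CSV file path.
#' @param ratings A long-form ratings tibble.
#' @return `read_ratings()` returns a long tibble; `write_ratings()` its
#'   input, invisibly.
#' @export
read_ratings <- function(path) {
  check_file_exists(path, "ratings file")
  wide <- readr::read_csv(path, show_col_types = FALSE)
  if (names(wide)[1] != "statement_id") {
    stop_validation("first column of a ratings file must be statement_id")
  }
  long <- tidyr::pivot_longer(wide, -"statement_id",
                              names_to = "expert_id", values_to = "rating")
  long <- filter(long, !is.na(.data$rating))
  bad <- long$rating != as.integer(long$rating) |
    long$rating < 1 | long$rating > 5
  if (any(bad)) {
    stop_validation(sprintf(
      "non-integer or out-of-range rating for statement %s (expert %s)",
      long$statement_id[bad][1], long$expert_id[bad][1]
    ))
  }
  mutate(long, rating = as.integer(.data$rating))
}

#' @rdname read_ratings
#' @export
write_ratings <- function(ratings, path) {
  wide <- tidyr::pivot_wider(ratings, id_cols = "statement_id",
                             names_from = "expert_id",
                             values_from = "rating")
  readr::write_csv(wide, path, na = "")
  invisible(ratings)
}
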