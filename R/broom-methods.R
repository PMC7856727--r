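#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for Delphi round results
#'
#' `tidy()` returns the per-statement consensus table; `glance()` a one-row
#' summary of the partition.
#'
#' @param x A `delphi_round`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy delphi_round
#' @export
tidy.delphi_round <- function(x, ...) {
  mutate(x$results, round_no = x$round_no)
}

#' @rdname tidy.delphi_round
#' @method glance delphi_round
#' @export
glance.delphi_round <- function(x, ...) {
  tab <- table(factor(x$results$classification, levels = pim_statuses))
  tibble(
    round_no = x$round_no,
    n_candidates = nrow(x$results),
    n_included = unname(tab[["INCLUDED"]]),
    n_excluded = unname(tab[["EXCLUDED"]]),
    n_questionable = unname(tab[["QUESTIONABLE"]]),
    quantile_method = x$config$quantile_method
  )
}

#' Tidiers for assembled final PIM lists
#'
#' @param x A `pim_final_list`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pim_final_list
#' @export
tidy.pim_final_list <- function(x, ...) {
  x$statements
}

#' @rdname tidy.pim_final_list
#' @method glance pim_final_list
#' @export
glance.pim_final_list <- function(x, ...) {
  st <- x$statements
  inc <- st[st$status == "INCLUDED", ]
  out <- tibble(
    n_candidates = nrow(st),
    n_included = nrow(inc),
    n_questionable = sum(st$status == "QUESTIONABLE"),
    n_excluded = sum(st$status == "EXCLUDED")
  )
  if ("category" %in% names(st)) {
    out$n_independent <- sum(inc$category == "INDEPENDENT", na.rm = TRUE)
    out$n_condition_specific <- sum(inc$category == "CONDITION_SPECIFIC",
                                    na.rm = TRUE)
  }
  out
}

#' Tidiers for screening reports
#'
#' `tidy()` returns the flag table (one row per patient-statement-medication
#' match); `glance()` the cohort summary with the any-PIM prevalence.
#'
#' @param x A `screening_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy screening_report
#' @export
tidy.screening_report <- function(x, ...) {
  x$flags
}

#' @rdname tidy.screening_report
#' @method glance screening_report
#' @export
glance.screening_report <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    n_flagged = sum(x$patients$any_pim),
    n_flags = nrow(x$flags),
    prevalence = x$prevalence,
    n_out_of_population = sum(!x$patients$in_population),
    include_questionable = x$include_questionable
  )
}

#' Summary counts for a criteria set
#'
#' @param x A `criteria_set`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @method glance criteria_set
#' @export
glance.criteria_set <- function(x, ...) {
  st <- as_tibble(x)
  inc <- st[st$status == "INCLUDED", ]
  tibble(
    n_statements = nrow(st),
    n_included = nrow(inc),
    n_independent_included = sum(inc$category == "INDEPENDENT"),
    n_condition_specific_included = sum(inc$category == "CONDITION_SPECIFIC"),
    n_questionable = sum(st$status == "QUESTIONABLE"),
    n_excluded = sum(st$status == "EXCLUDED"),
    n_errata = nrow(criteria_errata(x))
  )
}

#' Plot a Delphi round as a median/IQR consensus map
#'
#' Each statement is drawn at its rating median and IQR width, coloured by
#' classification, with the inclusion and exclusion thresholds overlaid.
#'
#' @param object A `delphi_round`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot delphi_round
#' @export
autoplot.delphi_round <- function(object, ...) {
  cfg <- object$config
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$median, y = .data$iqr_width,
                               colour = .data$classification)) +
    ggplot2::geom_jitter(width = 0.04, height = 0.04, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(cfg$exclude_median_max,
                                       cfg$include_median_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = cfg$iqr_max, linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("Delphi round %d consensus map", object$round_no),
      x = "rating median", y = "IQR width (Q3 - Q1)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the most frequently triggered statements of a screening report
#'
#' @param object A `screening_report`.
#' @param n_statements Number of top statements to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screening_report
#' @export
autoplot.screening_report <- function(object, n_statements = 15, ...) {
  top <- head(arrange(object$statement_hits, dplyr::desc(.data$n_hits)),
              n_statements)
  ggplot2::ggplot(top,
                  ggplot2::aes(x = stats::reorder(.data$statement_id,
                                                  .data$n_hits),
                               y = .data$n_hits, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "patients flagged", fill = NULL,
                  title = "Most frequently triggered PIM statements") +
    ggplot2::theme_minimal()
}
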