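## Generators: every stage of the pipeline is testable without external data.
## All generators are pure functions of their arguments and a seed.

# Enumerate all multisets of {1..5} of size n as count vectors (c1..c5).
# There are choose(n + 4, 4) of them: 715 at n = 9, so exhaustive search is
# cheap and, unlike random search, complete and deterministic.
likert_multisets <- function(n) {
  key <- paste0("ms", n)
  if (!is.null(the[[key]])) return(the[[key]])
  grid <- expand.grid(c1 = 0:n, c2 = 0:n, c3 = 0:n, c4 = 0:n)
  grid <- grid[rowSums(grid) <= n, , drop = FALSE]
  grid$c5 <- n - rowSums(grid)
  m <- as.matrix(grid)
  rownames(m) <- NULL
  the[[key]] <- m
  m
}

counts_to_vector <- function(counts) {
  rep(1:5, times = counts)
}

# consensus summaries for every multiset of size n under one quantile method
consensus_table <- function(n, quantile_method) {
  key <- paste("ct", n, quantile_method, sep = "_")
  if (!is.null(the[[key]])) return(the[[key]])
  m <- likert_multisets(n)
  qs <- t(apply(m, 1L, function(counts) {
    likert_quartiles(counts_to_vector(counts), quantile_method)
  }))
  the[[key]] <- list(counts = m, q1 = qs[, 1], med = qs[, 2], q3 = qs[, 3])
  the[[key]]
}

#' Generate a rating vector with a prescribed consensus summary
#'
#' Searches all integer Likert multisets of the requested panel size for
#' those whose (Q1, median, Q3) under the chosen quantile rule equal the
#' target exactly, and returns one of them; the seed picks deterministically
#' among multiple solutions. This is the inverse of [compute_consensus()]
#' and is how synthetic expert panels reproducing published summary rows are
#' built.
#'
#' @param target_median,target_q1,target_q3 The summary to hit, each in
#'   \[1, 5\].
#' @param n_experts Panel size (number of responding experts).
#' @param quantile_method As in [delphi_config()].
#' @param seed Integer; breaks ties among solutions.
#' @return An integer rating vector of length `n_experts`, sorted
#'   ascending. Errors with class `hkpim_unreachable_target` when no
#'   integer multiset attains the target under the chosen rule.
#' @export
#' @examples
#' gen_ratings(4, 2.5, 4.5, n_experts = 7)
#' compute_consensus(gen_ratings(4, 2.5, 4.5, n_experts = 7))
gen_ratings <- function(target_median, target_q1, target_q3, n_experts,
                        quantile_method = "linear_interpolation", seed = 1) {
  if (!(n_experts >= 1)) stop_validation("n_experts must be >= 1")
  tgt <- c(target_q1, target_median, target_q3)
  if (anyNA(tgt) || any(tgt < 1 | tgt > 5) ||
      !(target_q1 <= target_median && target_median <= target_q3)) {
    stop_validation("need 1 <= q1 <= median <= q3 <= 5")
  }
  tab <- consensus_table(n_experts, quantile_method)
  hit <- abs(tab$q1 - target_q1) < 1e-9 &
    abs(tab$med - target_median) < 1e-9 &
    abs(tab$q3 - target_q3) < 1e-9
  idx <- which(hit)
  if (length(idx) == 0L) {
    abort(
      sprintf(
        "no integer rating multiset of size %d attains median %.2f, Q1 %.2f, Q3 %.2f under %s",
        n_experts, target_median, target_q1, target_q3, quantile_method
      ),
      class = "hkpim_unreachable_target"
    )
  }
  pick <- idx[(as.integer(seed) %% length(idx)) + 1L]
  counts_to_vector(tab$counts[pick, ])
}

#' Generate a rating matrix hitting per-statement consensus targets
#'
#' Builds one rating vector per target with [gen_ratings()] and assembles
#' them into a long-form rating matrix; [run_round()] on the result
#' reproduces each target's classification by construction.
#'
#' @param targets Tibble with columns `statement_id`, `median`, `q1`, `q3`,
#'   `n_experts`.
#' @param quantile_method As in [delphi_config()].
#' @param seed Integer seed.
#' @return A long ratings tibble (`statement_id`, `expert_id`, `rating`).
#' @export
gen_panel <- function(targets, quantile_method = "linear_interpolation",
                      seed = 1) {
  targets <- as_tibble(targets)
  if (nrow(targets) == 0L) {
    return(tibble(statement_id = character(), expert_id = character(),
                  rating = integer()))
  }
  stopifnot(all(c("statement_id", "median", "q1", "q3", "n_experts") %in%
                  names(targets)))
  purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    rv <- gen_ratings(t$median, t$q1, t$q3, t$n_experts,
                      quantile_method = quantile_method, seed = seed + i)
    tibble(statement_id = t$statement_id,
           expert_id = paste0("E", seq_len(t$n_experts)),
           rating = rv)
  })
}

pad_to_substance <- function(code) {
  # deterministic grammatical completion of a class code to 7 characters
  vapply(code, function(cc) {
    if (nchar(cc) >= 7L) cc else paste0(cc, substr("AA01AA0", 1L, 7L - nchar(cc)))
  }, character(1), USE.NAMES = FALSE)
}

# naive reference matcher used by the cohort generator so that planted
# ground truth is derived independently of screen_cohort()
naive_match_flags <- function(patient_id, med_codes, cond_ids, stm) {
  out <- list()
  for (med in med_codes) {
    for (i in seq_len(nrow(stm))) {
      code <- stm$atc_code_curated[i]
      lvl <- if (med == code) {
        "EXACT"
      } else if (nchar(code) < 7L &&
                 substr(med, 1L, nchar(code)) == code) {
        "CLASS_PREFIX"
      } else {
        NA_character_
      }
      if (is.na(lvl)) next
      if (stm$category[i] == "CONDITION_SPECIFIC" &&
          !stm$condition_id[i] %in% cond_ids) {
        next
      }
      out <- c(out, list(tibble(
        patient_id = patient_id,
        statement_id = stm$statement_id[i],
        matched_medication = med,
        match_level = lvl,
        matched_condition = if (stm$category[i] == "CONDITION_SPECIFIC")
          stm$condition_id[i] else NA_character_,
        category = stm$category[i]
      )))
    }
  }
  if (length(out) == 0L) {
    return(tibble(patient_id = character(), statement_id = character(),
                  matched_medication = character(), match_level = character(),
                  matched_condition = character(), category = character()))
  }
  distinct(bind_rows(out))
}

#' Generate a synthetic patient cohort with known ground-truth flags
#'
#' Plants a flaggable medication (and condition, for condition-specific
#' statements) in exactly `round(n_patients * pim_rate)` patients; all other
#' medications are drawn from a pool of codes verified not to match any
#' active statement, so the any-PIM prevalence of the cohort is exact by
#' construction. The returned `truth` table lists every flag the cohort
#' should raise, derived with a naive reference matcher independent of
#' [screen_cohort()].
#'
#' @param criteria A `criteria_set` with at least one included statement.
#' @param n_patients Cohort size.
#' @param pim_rate Fraction of patients planted with at least one flaggable
#'   medication.
#' @param seed Integer seed; fully determines the cohort.
#' @param meds_per_patient Mean number of medications per patient (at least
#'   one is always prescribed).
#' @param condition_prob Probability that a patient carries each of up to
#'   two extra (randomly chosen) conditions.
#' @param include_questionable Plant against questionable statements too.
#' @return A list: `medications`, `conditions`, `truth` (the planted flag
#'   set) and `planted` (which patients were planted, with what).
#' @export
#' @examples
#' cohort <- gen_patients(hk_pim_criteria(), n_patients = 20, pim_rate = 0.4,
#'                        seed = 7)
#' generics::glance(screen_cohort(cohort$medications, cohort$conditions,
#'                                hk_pim_criteria()))
gen_patients <- function(criteria, n_patients = 100, pim_rate = 0.4, seed = 1,
                         meds_per_patient = 3, condition_prob = 0.3,
                         include_questionable = FALSE) {
  stopifnot(inherits(criteria, "criteria_set"))
  if (pim_rate < 0 || pim_rate > 1) stop_validation("pim_rate must be in [0, 1]")
  statuses <- "INCLUDED"
  if (include_questionable) statuses <- c(statuses, "QUESTIONABLE")
  stm <- filter(as_tibble(criteria), .data$status %in% statuses,
                atc_valid(.data$atc_code_curated))
  if (nrow(stm) == 0L && pim_rate > 0) {
    stop_validation("criteria set has no flaggable statements")
  }
  withr::local_seed(seed)

  vocab <- unique(stm$condition_id[nzchar(stm$condition_id)])
  # codes guaranteed not to match any active statement, for filler meds
  matches_nothing <- function(code) {
    !any(code == stm$atc_code_curated |
           (nchar(stm$atc_code_curated) < 7L &
              substr(code, 1L, nchar(stm$atc_code_curated)) ==
                stm$atc_code_curated))
  }
  candidate_safe <- c(
    "V03AB01", "V06DC01", "B05XA02", "D01AE15", "A11CC05", "S01ED51",
    "L04AA06", "P01BA02", "B03BA01", "A12AA04", "V07AB00", "D02AC00"
  )
  safe_pool <- candidate_safe[vapply(candidate_safe, matches_nothing,
                                     logical(1))]
  if (length(safe_pool) == 0L && n_patients > round(n_patients * pim_rate)) {
    stop_validation("no non-matching filler codes available for this criteria set")
  }

  n_flagged <- round(n_patients * pim_rate)
  ids <- sprintf("P%04d", seq_len(n_patients))
  flagged <- sample(ids, n_flagged)

  meds <- list()
  conds <- list()
  planted <- list()
  for (pid in ids) {
    n_meds <- max(1L, rpois(1L, meds_per_patient))
    my_meds <- sample(safe_pool, min(n_meds, length(safe_pool)),
                      replace = FALSE)
    my_conds <- character(0)
    if (length(vocab) > 0L) {
      n_extra <- sum(runif(2L) < condition_prob)
      if (n_extra > 0L) {
        my_conds <- sample(vocab, min(n_extra, length(vocab)))
      }
    }
    if (pid %in% flagged) {
      s <- stm[sample.int(nrow(stm), 1L), ]
      planted_med <- pad_to_substance(s$atc_code_curated)
      my_meds <- unique(c(my_meds, planted_med))
      if (s$category == "CONDITION_SPECIFIC") {
        my_conds <- unique(c(my_conds, s$condition_id))
      }
      planted <- c(planted, list(tibble(
        patient_id = pid, statement_id = s$statement_id,
        planted_medication = planted_med,
        planted_condition = if (s$category == "CONDITION_SPECIFIC")
          s$condition_id else NA_character_
      )))
    }
    age <- sample(65:95, 1L)
    meds <- c(meds, list(tibble(patient_id = pid, age_years = age,
                                atc_code = my_meds)))
    if (length(my_conds) > 0L) {
      conds <- c(conds, list(tibble(patient_id = pid,
                                    condition_id = my_conds)))
    }
  }
  medications <- bind_rows(meds)
  conditions <- if (length(conds) > 0L) bind_rows(conds) else
    tibble(patient_id = character(), condition_id = character())

  truth <- purrr::map_dfr(ids, function(pid) {
    naive_match_flags(pid,
                      medications$atc_code[medications$patient_id == pid],
                      conditions$condition_id[conditions$patient_id == pid],
                      stm)
  })
  list(
    medications = medications,
    conditions = conditions,
    truth = truth,
    planted = if (length(planted) > 0L) bind_rows(planted) else
      tibble(patient_id = character(), statement_id = character(),
             planted_medication = character(), planted_condition = character())
  )
}

#' Generate a reference-criteria incidence table with known selections
#'
#' Draws random reference-list memberships for `n_entities` synthetic
#' medications and computes the expected candidate set by applying the
#' selection rule (at least two lists; exactly two requires the Beers list)
#' literally inside the generator, so [select_candidates()] can be checked
#' against it.
#'
#' @param n_entities Number of entities.
#' @param seed Integer seed.
#' @param p_member Marginal probability of membership on each list.
#' @return A list: `incidence` (a table for [select_candidates()]) and
#'   `expected` (entity names that must be selected).
#' @export
gen_reference_matrix <- function(n_entities, seed = 1, p_member = 0.25) {
  stopifnot(n_entities >= 1)
  withr::local_seed(seed)
  lists <- reference_list_names()
  m <- matrix(runif(n_entities * length(lists)) < p_member,
              nrow = n_entities, dimnames = list(NULL, lists))
  none <- rowSums(m) == 0L
  if (any(none)) {
    m[cbind(which(none), sample.int(length(lists), sum(none), replace = TRUE))] <- TRUE
  }
  entity <- sprintf("ENT%03d", seq_len(n_entities))
  atc <- paste0(sample(LETTERS, n_entities, replace = TRUE),
                sprintf("%02d", sample.int(99, n_entities, replace = TRUE)),
                sample(LETTERS, n_entities, replace = TRUE),
                sample(LETTERS, n_entities, replace = TRUE),
                sprintf("%02d", sample.int(99, n_entities, replace = TRUE)))
  n_mem <- rowSums(m)
  expected <- entity[n_mem >= 3L | (n_mem == 2L & m[, "Beers2015"])]
  incidence <- bind_cols(
    tibble(entity = entity, atc_code = atc),
    as_tibble(m),
    tibble(conditions = "")
  )
  list(incidence = incidence, expected = expected)
}

## ---------------------------------------------------------------------------
## Whole-study simulation

r1_shapes_included <- function(k) {
  shapes <- list(c(4, 4, 4), c(4, 3.75, 4.25), c(4, 3.5, 4), c(5, 4, 5),
                 c(3.5, 3, 4), c(4, 3, 4))
  do.call(rbind, shapes[rep_len(seq_along(shapes), k)])
}

r1_shapes_questionable <- function(k) {
  # roughly one in four questionables fails on IQR width, the rest on median
  shapes <- list(c(3, 3, 4), c(3, 2.5, 3.5), c(3, 3, 4), c(4, 2.5, 4.25))
  do.call(rbind, shapes[rep_len(seq_along(shapes), k)])
}

r2_shapes_included <- function(k) {
  shapes <- list(c(4, 4, 4), c(4, 3.5, 4), c(4, 4, 4.5), c(4, 3, 4))
  do.call(rbind, shapes[rep_len(seq_along(shapes), k)])
}

# the eight published questionable summaries (rated by seven experts)
table3_targets <- function() {
  tibble(
    median = c(3, 4, 3, 3, 3, 3, 3, 3),
    q1 = c(2.5, 2.5, 2, 2.5, 3, 3, 3, 3),
    q3 = c(3.5, 4.5, 3.5, 4, 4, 4, 4, 4)
  )
}

shape_targets <- function(ids, shapes, n_experts) {
  tibble(statement_id = ids, median = shapes[, 1], q1 = shapes[, 2],
         q3 = shapes[, 3], n_experts = n_experts)
}

#' Simulate the full two-round Delphi study
#'
#' Reconstructs the published study's arithmetic end to end on synthetic
#' rating panels. A preliminary list of 168 candidates (78 independent of
#' diagnosis, 90 condition-specific) is rated by eight experts in round 1;
#' the rating vectors are generated to land 117 candidates in the included
#' class, 8 excluded and 43 questionable. Round 2 is rated by seven experts
#' (one panelist drops out) over 55 candidates: the 43 questionables carried
#' forward, 3 additional indications of listed medications, and 9 newly
#' suggested candidates; its targets land 47 in the included class, with the
#' 8 remaining questionable candidates given the published questionable
#' summaries. The final list assembles to 164 statements (77 independent,
#' 87 condition-specific).
#'
#' The class of every candidate is set by construction through
#' [gen_panel()] targets, but every reported count is measured by actually
#' running [run_round()] and [assemble_final_list()] on the generated
#' ratings.
#'
#' @param seed Integer seed (tie-breaking among rating vectors).
#' @param config A [delphi_config()].
#' @return A list: `preliminary` (candidate metadata), `round1`, `round2`
#'   (`delphi_round` objects), `final` (`pim_final_list`), and `counts`, a
#'   named list of measured headline numbers.
#' @export
#' @examples
#' sim <- simulate_delphi_study(seed = 1)
#' sim$counts$final_total
simulate_delphi_study <- function(seed = 1, config = delphi_config()) {
  # candidate composition of the preliminary list and per-class round-1
  # outcome counts (independent: 52 included / 6 excluded / 20 questionable;
  # condition-specific: 65 / 2 / 23)
  ind_ids <- sprintf("SIM_IND%03d", 1:78)
  csp_ids <- sprintf("SIM_CSP%03d", 1:90)
  preliminary <- tibble(
    statement_id = c(ind_ids, csp_ids),
    category = rep(c("INDEPENDENT", "CONDITION_SPECIFIC"), c(78L, 90L))
  )

  r1_targets <- bind_rows(
    shape_targets(ind_ids[1:52], r1_shapes_included(52), 8L),
    shape_targets(ind_ids[53:58], matrix(rep(c(2, 2, 2), 6), ncol = 3,
                                         byrow = TRUE), 8L),
    shape_targets(ind_ids[59:78], r1_shapes_questionable(20), 8L),
    shape_targets(csp_ids[1:65], r1_shapes_included(65), 8L),
    shape_targets(csp_ids[66:67], matrix(rep(c(2, 1.75, 2.25), 2), ncol = 3,
                                         byrow = TRUE), 8L),
    shape_targets(csp_ids[68:90], r1_shapes_questionable(23), 8L)
  )
  ratings1 <- gen_panel(r1_targets, config$quantile_method, seed)
  round1 <- run_round(preliminary$statement_id, ratings1, round_no = 1,
                      config = config)

  carried <- round_ids(round1, "QUESTIONABLE")
  carried_ind <- intersect(carried, ind_ids)
  carried_csp <- intersect(carried, csp_ids)
  new_indication_ids <- sprintf("SIM_IND%03d", 79:81)   # e.g. alpha-blocker dual indications
  new_ind_ids <- sprintf("SIM_IND%03d", 82:88)          # 7 new independent candidates
  new_csp_ids <- sprintf("SIM_CSP%03d", 91:92)          # 2 new condition-specific candidates
  additions <- tibble(
    statement_id = c(new_indication_ids, new_ind_ids, new_csp_ids),
    category = rep(c("INDEPENDENT", "CONDITION_SPECIFIC"), c(10L, 2L))
  )

  # of the carried questionables, three independent and three
  # condition-specific stay questionable; among the nine new candidates the
  # two analgesic suggestions stay questionable
  t3 <- table3_targets()
  q_ind <- head(carried_ind, 3L)
  q_csp <- head(carried_csp, 3L)
  inc_ind <- setdiff(carried_ind, q_ind)
  inc_csp <- setdiff(carried_csp, q_csp)
  q_new <- head(new_ind_ids, 2L)
  inc_new_ind <- setdiff(new_ind_ids, q_new)

  r2_targets <- bind_rows(
    shape_targets(inc_ind, r2_shapes_included(length(inc_ind)), 7L),
    shape_targets(inc_csp, r2_shapes_included(length(inc_csp)), 7L),
    shape_targets(new_indication_ids, r2_shapes_included(3L), 7L),
    shape_targets(inc_new_ind, r2_shapes_included(length(inc_new_ind)), 7L),
    shape_targets(new_csp_ids, r2_shapes_included(2L), 7L),
    shape_targets(c(q_ind, q_csp, q_new),
                  as.matrix(t3[c(1, 3, 4, 5, 6, 7, 2, 8), ]), 7L)
  )
  ratings2 <- gen_panel(r2_targets, config$quantile_method, seed + 1000L)
  round2 <- run_round(r2_targets$statement_id, ratings2, round_no = 2,
                      config = config)

  meta <- bind_rows(preliminary, additions)
  final <- assemble_final_list(round1, round2, statements = meta)
  st <- final$statements
  included <- st[st$status == "INCLUDED", ]
  g1 <- table(factor(round1$results$classification, levels = pim_statuses))
  g2 <- table(factor(round2$results$classification, levels = pim_statuses))

  counts <- list(
    preliminary_total = nrow(preliminary),
    preliminary_independent = sum(preliminary$category == "INDEPENDENT"),
    preliminary_condition_specific =
      sum(preliminary$category == "CONDITION_SPECIFIC"),
    round1_included = unname(g1[["INCLUDED"]]),
    round1_excluded = unname(g1[["EXCLUDED"]]),
    round1_questionable = unname(g1[["QUESTIONABLE"]]),
    round1_included_pct = 100 * g1[["INCLUDED"]] / nrow(preliminary),
    round2_candidates = nrow(round2$results),
    round2_included = unname(g2[["INCLUDED"]]),
    round2_included_pct = 100 * g2[["INCLUDED"]] / nrow(round2$results),
    round2_questionable = unname(g2[["QUESTIONABLE"]]),
    round2_questionable_pct = 100 * g2[["QUESTIONABLE"]] / nrow(round2$results),
    final_total = nrow(included),
    final_independent = sum(included$category == "INDEPENDENT"),
    final_condition_specific =
      sum(included$category == "CONDITION_SPECIFIC")
  )
  list(preliminary = preliminary, round1 = round1, round2 = round2,
       final = final, ratings = list(round1 = ratings1, round2 = ratings2),
       counts = counts)
}
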