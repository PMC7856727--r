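test_that("classification is total, mutually exclusive and respects boundaries", {
  grid <- expand.grid(median = seq(1, 5, by = 0.25),
                      width = seq(0, 4, by = 0.25))
  cls <- classify_statement(grid$median, grid$width)
  expect_true(all(cls %in% c("INCLUDED", "EXCLUDED", "QUESTIONABLE")))
  # exclusion wins whenever the median is below 3, regardless of the width
  expect_true(all(cls[grid$median < 3] == "EXCLUDED"))
  # median exactly 3.0 is questionable, not excluded
  expect_equal(unique(cls[grid$median == 3]), "QUESTIONABLE")
  # width exactly 1.5 still satisfies inclusion
  expect_equal(classify_statement(3.5, 1.5), "INCLUDED")
  expect_equal(classify_statement(3.5, 1.75), "QUESTIONABLE")
  expect_true(all(cls[grid$median >= 3.5 & grid$width <= 1.5] == "INCLUDED"))
  expect_error(classify_statement(5.5, 1), class = "hkpim_validation_error")
  expect_error(classify_statement(4, -0.5), class = "hkpim_validation_error")
})

test_that("published boundary summaries classify as reported", {
  expect_equal(classify_statement(3.0, 1.0), "QUESTIONABLE")
  expect_equal(classify_statement(2.0, 1.0), "EXCLUDED")
  expect_equal(classify_statement(4.0, 2.0), "QUESTIONABLE")
})

test_that("constant rating vectors classify by their value alone", {
  for (n in c(1, 3, 7, 8, 9)) {
    for (v in 1:5) {
      cc <- compute_consensus(rep(v, n))
      expect_equal(cc$median, v)
      expect_equal(cc$iqr_width, 0)
      expected <- if (v >= 4) "INCLUDED" else if (v <= 2) "EXCLUDED" else "QUESTIONABLE"
      expect_equal(cc$classification, expected)
    }
  }
})

test_that("consensus summaries match a direct sorted-index oracle exhaustively (n <= 9)", {
  for (n in 1:9) {
    sets <- all_likert_multisets(n)
    for (method in c("linear_interpolation", "nearest_rank", "tukey_hinges")) {
      cfg <- delphi_config(quantile_method = method)
      for (x in sets) {
        got <- compute_consensus(x, cfg)
        ref <- oracle_quartiles(x, method)
        expect_equal(c(got$q1, got$median, got$q3), ref,
                     info = sprintf("n=%d method=%s x=%s", n, method,
                                    paste(x, collapse = ",")))
      }
    }
  }
})

test_that("specific panels reproduce printed summary rows", {
  cc <- compute_consensus(c(4, 4, 5, 5, 5, 5, 5, 5))
  expect_equal(c(cc$median, cc$q1, cc$q3), c(5, 4.75, 5))
  expect_equal(cc$classification, "INCLUDED")
  cc <- compute_consensus(c(1, 2, 3, 4, 4, 5, 5))
  expect_equal(c(cc$median, cc$q1, cc$q3, cc$iqr_width), c(4, 2.5, 4.5, 2))
  expect_equal(cc$classification, "QUESTIONABLE")
})

test_that("adding a top rating never decreases the median", {
  set.seed(42)
  for (i in 1:200) {
    x <- sample(1:5, sample(1:9, 1), replace = TRUE)
    before <- compute_consensus(x)$median
    after <- compute_consensus(c(x, 5L))$median
    expect_gte(after, before)
  }
})

test_that("rating vectors are validated", {
  expect_error(compute_consensus(integer(0)), class = "hkpim_validation_error")
  expect_error(compute_consensus(c(1, 6)), class = "hkpim_validation_error")
  expect_error(compute_consensus(c(2.5, 3)), class = "hkpim_validation_error")
})

test_that("run_round partitions candidates and validates its inputs", {
  ratings <- tibble::tibble(
    statement_id = rep(c("A", "B", "C"), each = 8),
    expert_id = rep(paste0("E", 1:8), times = 3),
    rating = rep(c(5L, 1L, 3L), each = 8)
  )
  rr <- run_round(c("A", "B", "C"), ratings)
  g <- generics::glance(rr)
  expect_equal(c(g$n_included, g$n_excluded, g$n_questionable), c(1, 1, 1))
  expect_equal(tidy(rr)$classification, c("INCLUDED", "EXCLUDED", "QUESTIONABLE"))
  # empty candidate list gives an empty partition
  expect_equal(nrow(run_round(character(0), ratings)$results), 0)
  expect_error(run_round(c("A", "Z"), ratings),
               class = "hkpim_validation_error")
  # missing cells are omitted, not imputed: one NA leaves 7 ratings
  ratings$rating[1] <- NA
  expect_equal(tidy(run_round("A", ratings))$n_ratings, 7)
})

test_that("final-list assembly unions the rounds and conserves statements", {
  sim <- simulate_delphi_study(seed = 3)
  st <- tidy(sim$final)
  all_candidates <- union(sim$round1$results$statement_id,
                          sim$round2$results$statement_id)
  # every candidate ends in exactly one bucket
  expect_setequal(st$statement_id, all_candidates)
  expect_equal(anyDuplicated(st$statement_id), 0)
  expect_equal(sum(st$status == "INCLUDED"),
               generics::glance(sim$round1)$n_included +
                 generics::glance(sim$round2)$n_included)
})

test_that("assembly rejects round-2 candidates already included in round 1", {
  ratings <- tibble::tibble(
    statement_id = rep("A", 8), expert_id = paste0("E", 1:8),
    rating = rep(5L, 8)
  )
  r1 <- run_round("A", ratings, round_no = 1)
  r2 <- run_round("A", ratings[1:7, ], round_no = 2)
  expect_error(assemble_final_list(r1, r2), class = "hkpim_validation_error")
})

test_that("an empty round 2 leaves the round-1 included set as the final list", {
  ratings <- tibble::tibble(
    statement_id = rep(c("A", "B"), each = 8),
    expert_id = rep(paste0("E", 1:8), times = 2),
    rating = rep(c(5L, 4L), each = 8)
  )
  r1 <- run_round(c("A", "B"), ratings, round_no = 1)
  r2 <- run_round(character(0), ratings, round_no = 2)
  final <- assemble_final_list(r1, r2)
  expect_setequal(tidy(final)$statement_id[tidy(final)$status == "INCLUDED"],
                  c("A", "B"))
})

test_that("ratings round-trip through the wide CSV layout", {
  targets <- tibble::tibble(statement_id = c("S1", "S2"),
                            median = c(4, 3), q1 = c(3.5, 3), q3 = c(4, 4),
                            n_experts = 7L)
  long <- gen_panel(targets, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(long, path)
  back <- read_ratings(path)
  expect_equal(dplyr::arrange(back, statement_id, expert_id),
               dplyr::arrange(long, statement_id, expert_id))
})
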