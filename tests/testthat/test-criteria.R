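test_that("the packaged criteria set carries the published counts", {
  cs <- hk_pim_criteria()
  g <- generics::glance(cs)
  expect_equal(g$n_included, 164)
  expect_equal(g$n_independent_included, 77)
  expect_equal(g$n_condition_specific_included, 87)
  expect_equal(g$n_questionable, 8)
  expect_equal(anyDuplicated(cs$statement_id), 0)
  # the two operational categories are coherent with condition tokens
  expect_true(all(nzchar(cs$condition_id[cs$category == "CONDITION_SPECIFIC"])))
  expect_true(all(!nzchar(cs$condition_id[cs$category == "INDEPENDENT"])))
})

test_that("curated codes always parse; printed codes fail only under an erratum", {
  cs <- hk_pim_criteria()
  expect_true(all(atc_valid(cs$atc_code_curated)))
  printed <- cs$atc_code_printed
  bad <- nzchar(printed) & !atc_valid(printed)
  expect_true(all(cs$statement_id[bad] %in%
                    criteria_errata(cs)$statement_id))
  # curated differs from printed exactly on the erratum rows
  err_ids <- unique(criteria_errata(cs)$statement_id[
    criteria_errata(cs)$field_name == "atc_code"])
  differs <- nzchar(printed) & printed != cs$atc_code_curated
  expect_setequal(cs$statement_id[differs], err_ids)
})

test_that("every questionable condition token is in the packaged vocabulary", {
  cs <- hk_pim_criteria()
  vocab <- hk_conditions()
  expect_true(all(cs$condition_id[nzchar(cs$condition_id)] %in%
                    vocab$condition_id))
})

test_that("validation flags exactly the two contradictory analgesic rows", {
  cs <- hk_pim_criteria()
  report <- validate_criteria(cs)
  expect_equal(nrow(report), 2)
  expect_setequal(report$statement_id, c("IND073", "IND074"))
  expect_true(all(report$severity == "WARNING"))
  # strict mode: the errata cover both findings, so they stay warnings
  strict <- validate_criteria(cs, strict = TRUE)
  expect_true(all(strict$severity == "WARNING"))
})

test_that("without errata the contradictions escalate to errors in strict mode", {
  path <- system.file("extdata", "hk_pim_criteria.csv", package = "hkpim")
  bare <- load_criteria(path, errata = NA)
  expect_equal(nrow(criteria_errata(bare)), 0)
  report <- validate_criteria(bare, strict = TRUE)
  expect_setequal(report$statement_id[report$severity == "ERROR"],
                  c("IND073", "IND074"))
})

test_that("structurally invalid rows are rejected at load with named fields", {
  expect_error(
    make_test_criteria(list(list(statement_id = "X1", iqr_low = 4.5,
                                 iqr_high = 2.5))),
    "Q1 > Q3"
  )
  expect_error(
    make_test_criteria(list(list(statement_id = "X1",
                                 atc_code_curated = "N05BA0"))),
    "malformed ATC"
  )
  expect_error(
    make_test_criteria(list(list(statement_id = "X1", median = 5.5,
                                 iqr_high = 5.5))),
    "\\[1, 5\\]"
  )
  expect_error(
    make_test_criteria(list(list(statement_id = "X1",
                                 category = "CONDITION_SPECIFIC"))),
    "lacks a condition"
  )
  expect_error(
    make_test_criteria(list(list(statement_id = "X1", condition_id = "falls"))),
    "carries a condition"
  )
  expect_error(
    make_test_criteria(list(
      list(statement_id = "X1"), list(statement_id = "X1")
    )),
    "duplicate"
  )
})

test_that("a clean single-statement set validates to an empty report", {
  cs <- make_test_criteria(list(list(statement_id = "X1", median = 4,
                                     iqr_low = 3.5, iqr_high = 4.5)))
  expect_equal(nrow(validate_criteria(cs)), 0)
})

test_that("criteria round-trip identically through CSV and JSON", {
  cs <- hk_pim_criteria()
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_criteria(cs, path, format = fmt)
    back <- load_criteria(path, format = fmt, name = attr(cs, "name"))
    expect_equal(as.data.frame(back), as.data.frame(cs))
    expect_equal(criteria_errata(back), criteria_errata(cs))
  }
})

test_that("unicode names and alternatives survive the round-trip", {
  cs <- make_test_criteria(list(list(
    statement_id = "X1", class_name = "苯二氮卓类",
    medication_name = "diazépam", alternatives = "melatonin|CBT-i"
  )))
  path <- withr::local_tempfile(fileext = ".csv")
  write_criteria(cs, path)
  back <- load_criteria(path)
  expect_equal(back$class_name, "苯二氮卓类")
  expect_equal(back$alternatives[[1]], c("melatonin", "CBT-i"))
})

test_that("an empty statements file loads to an empty, writable set", {
  empty <- new_criteria_set(hk_pim_criteria()[0, ])
  g <- generics::glance(empty)
  expect_equal(g$n_statements, 0)
  expect_equal(g$n_included, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_criteria(empty, path)
  back <- load_criteria(path)
  expect_equal(nrow(back), 0)
})

test_that("errata must reference existing statements", {
  expect_error(
    make_test_criteria(
      list(list(statement_id = "X1")),
      errata = tibble::tibble(statement_id = "NOPE", field_name = "status",
                              printed_value = "a", curated_value = "b",
                              rationale = "")
    ),
    "unknown statement_id"
  )
})
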