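test_that("a benzodiazepine prescription with dementia raises both category flags", {
  flags <- screen_patient("N05BA01", "dementia_cognitive_impairment",
                          hk_pim_criteria())
  expect_equal(nrow(flags), 2)
  expect_setequal(flags$statement_id, c("IND049", "CSP022"))
  expect_equal(flags$match_level[flags$statement_id == "IND049"], "EXACT")
  expect_equal(flags$match_level[flags$statement_id == "CSP022"],
               "CLASS_PREFIX")
  expect_equal(flags$matched_condition[flags$statement_id == "CSP022"],
               "dementia_cognitive_impairment")
})

test_that("patients with no medications or only unlisted codes get no flags", {
  expect_equal(nrow(screen_patient(character(0), criteria = hk_pim_criteria())),
               0)
  # confirmed by brute-force scan: no statement code prefixes A02BC01
  cs <- hk_pim_criteria()
  codes <- cs$atc_code_curated[cs$status == "INCLUDED"]
  expect_false(any(codes == "A02BC01" |
                     (nchar(codes) < 7 &
                        substr("A02BC01", 1, nchar(codes)) == codes)))
  expect_equal(nrow(screen_patient("A02BC01", criteria = cs)), 0)
})

test_that("cohort prevalence is the fraction of patients with any flag", {
  meds <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    age_years = c(70, 80, 66),
    atc_code = c("N05BA01", "M01AE01", "V03AB01")
  )
  rep <- screen_cohort(meds, criteria = hk_pim_criteria())
  expect_equal(rep$prevalence, 2 / 3)
  g <- generics::glance(rep)
  expect_equal(g$n_flagged, 2)
  # determinism: screening twice gives identical reports
  rep2 <- screen_cohort(meds, criteria = hk_pim_criteria())
  expect_equal(tidy(rep2), tidy(rep))
  expect_equal(generics::glance(rep2), generics::glance(rep))
})

test_that("nested class and substance rules keep the most specific flag primary", {
  cs <- make_test_criteria(list(
    list(statement_id = "CLS", medication_name = "",
         atc_code_curated = "N05BA"),
    list(statement_id = "SUB", atc_code_curated = "N05BA01")
  ))
  flags <- screen_patient("N05BA01", criteria = cs)
  expect_equal(nrow(flags), 2)
  expect_true(flags$is_primary[flags$statement_id == "SUB"])
  expect_false(flags$is_primary[flags$statement_id == "CLS"])
  # equally specific duplicate listings each stay primary
  cs2 <- make_test_criteria(list(
    list(statement_id = "A", atc_code_curated = "G04CA03"),
    list(statement_id = "B", atc_code_curated = "G04CA03")
  ))
  flags2 <- screen_patient("G04CA03", criteria = cs2)
  expect_equal(sum(flags2$is_primary), 2)
})

test_that("questionable statements flag only on request, monotonically", {
  cs <- hk_pim_criteria()
  # dipyridamole is only on the questionable list
  strict <- screen_patient("B01AC07", criteria = cs)
  loose <- screen_patient("B01AC07", criteria = cs,
                          include_questionable = TRUE)
  expect_equal(nrow(strict), 0)
  expect_gt(nrow(loose), 0)
  expect_true(all(interaction(strict$statement_id, strict$matched_medication)
                  %in% interaction(loose$statement_id, loose$matched_medication)))
})

test_that("screening ignores non-included rows when include_questionable is off", {
  cohort <- gen_patients(hk_pim_criteria(), n_patients = 30, pim_rate = 0.5,
                         seed = 21)
  full <- screen_cohort(cohort$medications, cohort$conditions,
                        hk_pim_criteria())
  only_included <- new_criteria_set(
    dplyr::filter(tibble::as_tibble(hk_pim_criteria()), status == "INCLUDED"),
    name = "included-only"
  )
  restricted <- screen_cohort(cohort$medications, cohort$conditions,
                              only_included)
  expect_equal(tidy(full), tidy(restricted))
})

test_that("adding medications or conditions never removes existing flags", {
  cs <- hk_pim_criteria()
  withr::with_seed(99, {
    for (i in 1:20) {
      meds <- sample(c("N05BA01", "M01AE02", "N06AA09", "V03AB01", "C01AA05"),
                     sample(1:3, 1))
      conds <- sample(c("falls", "dementia_cognitive_impairment", "glaucoma"),
                      sample(0:2, 1))
      before <- screen_patient(meds, conds, cs)
      after_med <- screen_patient(c(meds, "N05CF01"), conds, cs)
      after_cond <- screen_patient(meds, c(conds, "delirium"), cs)
      key <- function(f) paste(f$statement_id, f$matched_medication,
                               f$matched_condition)
      expect_true(all(key(before) %in% key(after_med)))
      expect_true(all(key(before) %in% key(after_cond)))
    }
  })
})

test_that("screening agrees with a brute-force triple-loop matcher on random cohorts", {
  cs <- hk_pim_criteria()
  for (seed in 1:10) {
    cohort <- gen_patients(cs, n_patients = 8, pim_rate = 0.5, seed = seed,
                           meds_per_patient = 2)
    got <- screen_cohort(cohort$medications, cohort$conditions, cs)
    expect_equal(sort_flags(tidy(got)),
                 brute_force_screen(cohort$medications, cohort$conditions, cs),
                 info = paste("seed", seed))
  }
})

test_that("under-age patients are screened but marked out of population", {
  meds <- tibble::tibble(patient_id = c("young", "old"),
                         age_years = c(60, 70), atc_code = "N05BA01")
  rep <- screen_cohort(meds, criteria = hk_pim_criteria())
  expect_equal(sum(rep$patients$in_population), 1)
  expect_true(all(rep$patients$any_pim))
})

test_that("conflicting patient records and unknown conditions are handled", {
  meds <- tibble::tibble(patient_id = c("p1", "p1"), age_years = c(70, 71),
                         atc_code = c("N05BA01", "M01AE01"))
  expect_error(screen_cohort(meds, criteria = hk_pim_criteria()),
               class = "hkpim_validation_error")
  meds_ok <- tibble::tibble(patient_id = "p1", age_years = 70,
                            atc_code = "N05BA01")
  conds <- tibble::tibble(patient_id = "p1", condition_id = "not_a_condition")
  expect_warning(screen_cohort(meds_ok, conds, hk_pim_criteria()),
                 "unknown condition")
})
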