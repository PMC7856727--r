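# hkpim

Tools for building, validating and applying an explicit **potentially
inappropriate medication (PIM)** assessment list for older adults (aged 65+),
modelled on the Hong Kong-specific PIM criteria. The package is aimed at
pharmacoepidemiologists and medication-safety researchers who want to

* apply the 164-statement, ATC-coded criteria set to patient medication and
  condition records and estimate cohort PIM prevalence,
* reproduce (or re-run with different thresholds) the two-round modified
  Delphi consensus procedure that produced the list, and
* rebuild a preliminary candidate list from a reference-criteria incidence
  table filtered by formulary availability.

## The model

Each candidate statement is rated by an expert panel on a 5-point Likert
scale (1 = strongly disagree that use is inappropriate, 5 = strongly agree).
With per-statement rating median *M* and interquartile range width
*W = Q3 − Q1*, the consensus classification is

```
EXCLUDED      if  M < 3.0
INCLUDED      if  M ≥ 3.5  and  W ≤ 1.5
QUESTIONABLE  otherwise      (3.0 ≤ M < 3.5, or W > 1.5)
```

Questionable statements from round 1 are re-rated in round 2 together with
panel-suggested additions; statements still questionable after round 2 are
dropped. Quartiles are computed by linear interpolation of the empirical CDF
(`stats::quantile` type 7) by default — the only rule that reproduces all of
the published quarter-step summaries — with nearest-rank and Tukey-hinge
alternatives for sensitivity analysis.

Screening matches each patient's substance-level (7-character) ATC codes
hierarchically against each statement's curated code: exact at substance
level, prefix at class level. Statements tied to a diagnosis additionally
require the patient to carry that condition token.

## Worked example

```r
library(hkpim)

criteria <- hk_pim_criteria()
generics::glance(criteria)
#> # A tibble: 1 × 7
#>   n_statements n_included n_independent_included n_condition_specific_included
#> 1          172        164                     77                            87
```

The packaged set holds the 164 final statements (77 independent of diagnosis,
87 condition-specific) plus the 8 questionable candidates the panel did not
reach consensus on. Screening one patient on diazepam and naproxen who has
documented cognitive impairment and chronic kidney disease:

```r
screen_patient(c("N05BA01", "M01AE02"),
               c("dementia_cognitive_impairment", "chronic_kidney_disease"),
               criteria)
#> # A tibble: 4 × 7
#>   patient_id statement_id matched_medication match_level  matched_condition
#> 1 patient    CSP022       N05BA01            CLASS_PREFIX dementia_cognitive_im…
#> 2 patient    CSP061       M01AE02            CLASS_PREFIX chronic_kidney_disease
#> 3 patient    IND029       M01AE02            EXACT        <NA>
#> 4 patient    IND049       N05BA01            EXACT        <NA>
```

Diazepam fires the substance-level independent statement (IND049, exact
match) and the class-level benzodiazepines-in-dementia statement (CSP022,
prefix match); naproxen fires its independent NSAID statement and the
NSAIDs-in-chronic-kidney-disease statement. Cohort-level prevalence on a
synthetic cohort with a planted 40% PIM rate:

```r
cohort <- gen_patients(criteria, n_patients = 100, pim_rate = 0.4, seed = 7)
report <- screen_cohort(cohort$medications, cohort$conditions, criteria)
report
#> <screening_report: 100 patients, 47 flags>
#>   any-PIM prevalence: 40.0%
```

A command-line front end covering validation, Delphi rounds, assembly,
candidate selection, screening and simulation is installed at
`system.file("cli", "hkpim.R", package = "hkpim")`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hkpim.R",package="hkpim"))')" validate
```

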