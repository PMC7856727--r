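---
title: "Methods: consensus model, criteria fixture, and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus model, criteria fixture, and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkpim)
```

## Background

Explicit (criterion-based) tools for detecting potentially inappropriate
medication (PIM) use in older adults encode prescribing-quality rules as
lists of drugs, drug classes and drug–disease pairs that should generally be
avoided in people aged 65 or over. `hkpim` implements such a tool end to
end for the Hong Kong-specific PIM list: the candidate-selection rule that
built the preliminary list from nine published reference criteria, the
two-round modified Delphi procedure that validated it, the final criteria
set as a machine-readable artifact, and a patient-level screening engine.

## The consensus model

Experts rate the inappropriateness of each candidate statement on a 1–5
Likert scale. Per statement, the rating vector is summarised by its median
$M$ and interquartile range width $W = Q_3 - Q_1$ and classified as

* **excluded** when $M < 3.0$,
* **included** when $M \ge 3.5$ and $W \le 1.5$,
* **questionable** otherwise, i.e. $3.0 \le M < 3.5$ or $W > 1.5$.

Three reading decisions are built in. "IQR ≤ 1.5" is read as the *width*
$Q_3 - Q_1$; that is the only reading under which exactly one of the eight
published questionable candidates fails on the IQR (dosulepin, with bounds
2.50–4.50, width 2.0) while the other seven fail on the median. Exclusion
takes precedence when both the low-median and wide-IQR conditions hold,
because the exclusion rule is stated unconditionally. Finally, the
boundaries are closed exactly as written: a median of 3.0 is questionable,
not excluded, and a width of exactly 1.5 still satisfies inclusion. These
thresholds are parameters of `delphi_config()` and can be varied.

### Quantile rule

With panels of seven or eight raters, the choice of quantile definition is
not cosmetic. The default is linear interpolation of the empirical CDF
(`stats::quantile` type 7): with eight raters its quartiles take
quarter-step values ($Q_1 = 0.25\,x_{(2)} + 0.75\,x_{(3)}$,
$Q_3 = 0.75\,x_{(6)} + 0.25\,x_{(7)}$, median $= (x_{(4)}+x_{(5)})/2$), and
with seven raters half-step values. This is the only standard rule that
reproduces *every* quartile printed in the published tables (2.75, 3.75,
4.25, 4.75 with eight raters; 2.50, 3.50, 4.50 with seven). Nearest-rank
(type 1) and Tukey hinges (`fivenum()`) are selectable for sensitivity
analysis.

All three rules map integer ratings to multiples of 1/4, so consensus
values are snapped to the nearest quarter before threshold comparisons;
this makes the 0.25-step arithmetic exact in binary floating point
(quarters are dyadic) and keeps boundary comparisons deterministic.

### Panel sizes per round

Eight experts rated round 1; one panelist dropped out, leaving seven in
round 2. Missing ratings are omitted from a statement's rating vector,
never imputed. The round in which each published row was decided is not
printed, so the fixture's `decided_round` field is partly inferred: a row
whose printed $Q_3$ is 4.50 cannot arise from eight integer ratings under
type-7 interpolation ($0.75\,x_{(6)} + 0.25\,x_{(7)} = 4.5$ has no integer
solution with ratings ≤ 5), so the ten such rows are assigned to round 2;
the hypnotics zopiclone and zolpidem (described as decided in round 2) and
the three alpha-blocker dual-indication rows (added in round 2) are likewise
round 2, as are all panel-suggested rows and the eight questionable
candidates. Everything else defaults to round 1. An exhaustive enumeration
test verifies that every printed (median, $Q_1$, $Q_3$) triple is attainable
by an integer rating multiset of the assigned panel size — which is also a
check on the quantile-rule decision itself.

## The criteria fixture

`hk_pim_criteria()` returns a 172-row transcription of the published
results tables: 77 final statements independent of diagnosis, 87 final
condition-specific statements, and the 8 questionable candidates (excluded
from the final list). Statement ids are deterministic: `IND`/`CSP` prefix
plus zero-padded ordinal in table order, with the questionable rows
appended after the final-list rows of their category.

Several properties of the printed tables require care:

* **Two contradictory rows.** Acetaminophen and methyl salicylate topical
  ointment appear both among the questionable candidates and — with the
  same medians of 3, which fail the inclusion rule — in the final
  independent-of-diagnosis table. The fixture transcribes both appearances
  with statuses as printed; `validate_criteria()` reports the two
  final-list rows as warnings, and errata entries (`field_name = "status"`)
  document the contradiction so that strict-mode validation still passes.
  The headline count of 77 counts the table rows as printed.
* **Shifted ATC codes.** The five panel-suggested rows in the
  independent-of-diagnosis table are printed with ATC codes that belong to
  neighbouring drugs (e.g. acetaminophen with the methadone code, the
  sodium phosphate enema with the bisphosphonates class code). The fixture
  stores the printed codes verbatim in `atc_code_printed`, assigns
  pharmacologically correct codes in `atc_code_curated`, and registers one
  erratum per row; the curated assignments are this package's inference,
  recorded as such in the errata rationale.
* **Codes not printed at all.** The questionable-candidates table and the
  condition-specific table print no ATC codes (the latter's codes live in
  supplementary material that is out of scope). `atc_code_printed` is
  blank for those rows — the grammar is enforced only on non-empty printed
  codes — while `atc_code_curated` is always assigned and always valid.
  Class labels without a single ATC node receive a representative class
  code (NSAIDs → `M01A`, TCAs → `N06AA`, benzodiazepines → `N05BA`,
  alpha-adrenoreceptor antagonists → `C02CA`, anticholinergics → `A03B`).
  This is a deliberate simplification: pharmacological families such as
  "anticholinergics" span several ATC branches, so class-level
  condition-specific rules capture the prototypical branch only. Real
  deployments would substitute a locally curated code list per class; the
  engine itself supports any ATC level.
* **Conditions.** Condition identifiers are lower-snake-case tokens derived
  from the disease/syndrome row labels (`hk_conditions()` maps tokens to
  labels). No ICD mapping is attempted.

## Screening semantics

Matching uses `atc_code_curated` only; printed-but-erroneous codes never
drive matches. A substance-level patient code matches a statement exactly
(same 7-character code) or by class prefix (statement code of length 1, 3,
4 or 5 that prefixes it). Condition-specific statements additionally
require the patient to carry the statement's condition token; the two
categories are independent axes, so one medication can legitimately raise
both an independent and a condition-specific flag.

When a class-level rule and a more specific nested rule of the same
category and condition both match one medication, the most specific
statement keeps `is_primary = TRUE` and the class match is retained as a
secondary flag — one actionable flag per drug per rule family, with the
audit trail preserved. Distinct statements with equally specific codes
(the same drug listed under two indications) each stay primary. Patients
younger than the configurable age threshold (default 65) are screened but
marked out of population. Prevalence is the fraction of patients with at
least one flag.

## Synthetic data

No patient data or expert rating matrices are distributed, so generators
make every stage testable with known ground truth:

* `gen_ratings()` inverts the consensus summary: it enumerates all integer
  multisets of the requested panel size (at most $\binom{n+4}{4} = 715$ at
  $n = 9$), keeps those whose quartiles equal the target exactly, and uses
  the seed to pick among solutions. Enumeration rather than random search
  makes the generator deterministic and its "unreachable target" errors a
  proof, not a timeout. Note that targets need not pin every rating: with
  all three quartiles at 5 and eight raters, the minimum rating is
  unconstrained, so even a unanimous-looking summary has several
  solutions.
* `gen_panel()` assembles per-statement vectors into a rating matrix whose
  round result reproduces each target's classification by construction.
* `gen_patients()` plants a flaggable medication (plus condition where
  needed) in exactly `round(n_patients * pim_rate)` patients and fills the
  rest of every record with codes verified not to match any active
  statement, so cohort prevalence is exact by construction. Ground truth
  is derived by a naive matcher internal to the generator, independent of
  the screening engine; the test suite adds a third, brute-force
  triple-loop implementation as an oracle.
* `gen_reference_matrix()` draws random reference-list memberships and
  computes the expected selection by restating the rule literally, so the
  selection engine can be checked against it.
* `simulate_delphi_study()` reconstructs the full published flow on
  synthetic panels: 168 preliminary candidates (78 independent, 90
  condition-specific) rated by eight experts, generated to land 117
  included / 8 excluded / 43 questionable in round 1; then 55 round-2
  candidates (the 43 carried questionables, 3 added indications, 9 new
  suggestions) rated by seven experts, landing 47 included and 8
  questionable — the latter given the eight published questionable
  summaries. The per-category split (52 + 17 + 3 + 5 = 77 independent,
  65 + 20 + 2 = 87 condition-specific) is the unique arithmetic consistent
  with the published totals. Class membership is set by construction, but
  every reported count is measured by running the rounds and the assembly.

What the generators do *not* emulate: realistic co-prescription and
comorbidity correlation structure, age- or sex-dependent prescribing,
free-text expert comments, and rating distributions beyond their quartile
summaries. Passing tests therefore demonstrate the correctness of the
engines, not the clinical performance of the criteria on real data.

## Problem sizes and runtime

The test suite runs exhaustive oracle comparisons for all integer rating
multisets up to nine raters (about 2,000 multisets per quantile rule),
verifies reachability of all 172 printed summaries, and compares the
screening engine against the brute-force matcher on 100 small random
cohorts (five patients each) plus ten larger ones; the whole suite
completes in well under two minutes on one CPU. The acceptance script uses
a 100-patient cohort with a planted 40% PIM rate and one full study
simulation per run.

## Known limitations

* Class-level curated codes approximate multi-branch pharmacological
  families (see above); statements whose family has no ATC node can
  under-match.
* Dose, duration and route qualifiers are free-text concerns, not
  structured rule conditions, mirroring the source material; drug–drug
  interactions and therapeutic duplication are out of scope by design.
* The condition vocabulary is the fixture's own; mapping from ICD or local
  coding systems is the caller's responsibility.
* `decided_round` is inferred for most final-list rows and should be
  treated as low-confidence metadata rather than historical record.
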