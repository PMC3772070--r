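---
title: "Smoking-status ascertainment from clinical free text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoking-status ascertainment from clinical free text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoketext)
```

## Scope and design stance

`smoketext` ascertains tobacco-smoking status (current / past / never) for
patients in a mental-health case register from two sources: a sparse
structured smoking-status field and the free text of assessments, progress
notes and correspondence. The package covers the full chain — text
annotation, source merging, patient-level resolution, cohort construction,
and the contingency-table epidemiology computed on the result — plus an
evaluation harness and a synthetic register generator, so every step is
testable without patient data.

The extraction engine is deliberately *not* a learned model. It is a
shallow, rule-based keyword matcher, because in this setting interpretable,
auditable rules with a controllable precision/recall trade-off are the point:
the engine is tuned to maximise annotation-level precision and to accept low
recall, on the argument that smoking is mentioned repeatedly across a
patient's record, so a mention missed in one document is usually recovered
from another, while a false positive poisons the patient-level status
directly.

## The rule engine

### Sentence scope and offsets

Text is segmented into sentences at `.`/`!`/`?` followed by whitespace, and
at newlines (clinical notes are line-structured). A short abbreviation list
(`e.g.`, `Dr.`, single initials, ...) prevents spurious splits. All cue
reasoning is *sentence-bounded*: no cue can scope a mention in another
sentence. Annotation offsets are 0-based and half-open into the original,
unnormalised text, so `substr(text, start + 1, end)` always recovers the
matched slice; matching itself is case-insensitive.

### Candidates and the non-tobacco exclusion

`tobacco_terms` splits conceptually into smoking **verbs**
(smoke/smokes/smoked/smoking), which take an object, and explicit tobacco
**products** (cigarette, tobacco, nicotine, cig, roll-up). The exclusion
logic exploits this:

* a verb whose nearest following object within `max_tokens` is a
  non-tobacco substance (cannabis, marijuana, cocaine, ...) is suppressed —
  "Smokes cannabis daily." yields nothing;
* a verb whose nearest object is a tobacco product defers to the product,
  which anchors the mention — "Smokes cigarettes and cannabis." yields one
  candidate, on *cigarettes*;
* a product immediately preceded by a non-tobacco modifier ("cannabis
  cigarettes") is suppressed.

### Classification and abstention

Cues are matched within the candidate's sentence and within `max_tokens`
word tokens (default 5) of the candidate, on either side. Categories:
negation (`never`, `denies`, `non-`, `no history of`, ...), past (`ex-`,
`former`, `quit`, `gave up`, ...), current (`currently`, `per day`,
`heavy`, `daily`, ...), third-party experiencers (`mother`, `family`, ...)
and uncertainty (`unclear`, `unknown`, `?`). The decision rule, in order:

1. any third-party or uncertainty cue in scope → **abstain**;
2. cues from more than one of {negation, past, current} in scope →
   **abstain** (conflict);
3. exactly one category in scope → that status;
4. no cue, candidate is the finite present-tense form *smokes* → current
   (an unmodified present-tense assertion, as in "She smokes.");
5. otherwise → **abstain** (bare mentions such as "Smoker." carry no
   resolvable temporality).

Abstention is a normal outcome, not an error. Setting
`smoking_ruleset(abstain = FALSE)` instead defaults every unresolved or
conflicted candidate to *current*; this exists for evaluation experiments
quantifying the precision cost of recall, not for production use.

Two design points deserve flagging. First, no canonical keyword inventory
exists for this kind of annotator, so the shipped lexicons are a documented
reconstruction and every list is configurable (`smoking_ruleset()` arguments
or a JSON rules file). Second, annotation is at *mention* level rather than
sentence level; mention level composes naturally with span-based evaluation
and with the patient-level date logic, and a sentence-level view is
recoverable by grouping.

### The extra cue lists

The standard field set for such rule sets (tobacco terms, non-tobacco
terms, negation, past, current cues, scope) cannot express "Smoking status
unclear" or "family smokes" — sentences a precision-first engine must not
annotate. We therefore carry two additional configurable lists,
`third_party_terms` and `uncertainty_cues`, treated as abstention triggers.
This mirrors the experiencer/certainty dimensions of standard clinical
context algorithms (NegEx/ConText) in minimal form.

## Patient-level resolution

Text annotations are carried to their *document's* date (not their character
position); structured entries carry their own date. Records dated before the
patient's referral are discarded and the earliest surviving record wins —
the first-record-after-referral rule. Patients with no surviving record are
the "missing smoking information" stratum analysed separately.

Tie-breaks are declared package decisions (the source convention for
same-date conflicts is not something the data can decide):

* same date, structured vs text → **structured wins** (a deliberate,
  clinician-entered field is stronger evidence); configurable via
  `tie_break = "text"`;
* same date within a source → precedence **current > past > never**
  (affirmative mentions are the higher-precision signal).

"At least twelve months of care" is computed in whole *calendar months*
between referral and care end (a 15 Jan → 14 Jan interval is 11 months),
not as 365 days, matching how such criteria are phrased clinically. Open
care episodes (missing end date) satisfy any duration bound. Cohort
filters: referral inside the window, age strictly greater than 15 at
referral. Patients with unknown marital status or deprivation stay in the
cohort and drop out of individual analyses (complete-case per factor).

## Statistical conventions

* **Heterogeneity**: Pearson chi-squared, no continuity correction,
  `(r−1)(c−1)` df (delegated to `stats::chisq.test`).
* **Trend**: Cochran–Armitage 1-df chi-squared,
  \(X^2 = [\sum_i s_i(r_i - n_i\bar p)]^2 / \{\bar p(1-\bar p)[\sum_i n_i
  s_i^2 - (\sum_i n_i s_i)^2/N]\}\), scores defaulting to consecutive
  integers from the least-exposed category; the statistic is invariant to
  affine score changes (asserted property-style against
  `stats::prop.trend.test` as an independent oracle). At least three
  ordered categories are required — a 2×2 "trend" is an odds ratio, not a
  trend.
* **Odds ratios**: cross-product with the Woolf interval
  \(\exp(\ln OR \pm z\sqrt{1/a+1/b+1/c+1/d})\), `z = 1.96` at 95%. No
  continuity correction by default; a zero cell is an error that points to
  the explicit `continuity = TRUE` (Haldane–Anscombe +0.5) option.
* **Logistic regression**: IRLS via `stats::glm`, convergence tolerance
  `1e-8`, at most 50 iterations. Grouped-binomial and row-expanded
  individual data give identical fits (tested). Separation or
  non-convergence withholds all estimates rather than reporting garbage;
  the separation heuristic is |coefficient| > 15 or SE > 100 on the logit
  scale. Deprivation enters regression as one ordinal term scored 0/1/2
  ("per tertile increase"); age is dichotomised at 65 for regression while
  cross-tabs retain seven bands.
* **Reporting**: percentages to one decimal, ORs and CI bounds to two
  decimals, p-values to two decimals with a `<0.001` floor.

The published summary counts shipped in `register_counts()` (a 5,588-patient
referral cohort, its 1,555-patient 12-month-care subset, and the 995 of
those with a resolved status) act as fixed reference inputs: the package's
statistics reproduce the cohort's printed derived quantities (odds ratios
such as 0.22 for age 65+, the 1.26 per-tertile deprivation OR, coverage
rising from 11.6% to 64.0% when text supplements the structured field) from
those counts alone, which is exactly what the acceptance tests assert.

## The synthetic register: a stated world

The generator's defaults are fixed once, as a description of the world the
pipeline assumes, and are not tuned against test outcomes:

* demographic marginals equal to the 1,555-patient reference cohort's
  (age-band, sex, marital, deprivation and diagnosis frequencies);
* current smoking from a logistic model whose coefficients are the
  reference cohort's mutually adjusted odds ratios (0.23 for age 65+, 0.62
  female, 0.53 cohabiting, 1.26 per deprivation tertile, 0.77 bipolar,
  ...), intercept 0.85 logits for the baseline stratum; non-current
  patients split 35/65 past/never;
* missingness (a patient having *no* smoking record anywhere) from its own
  logistic model reproducing the reference missingness pattern: higher in
  women, mid-life ages and bipolar disorder, higher in the least-deprived
  tertile, lower over 65;
* documentation: `1 + Poisson(3)` documents per patient, uniformly dated
  over the care episode; a 50% chance per document that smoking is
  mentioned; structured-field completion 11.6% (the reference structured
  coverage), dated referral + 0–30 days;
* phrasing mix: 25% of smoking mentions use out-of-lexicon phrasings
  (street/brand vocabulary the engine cannot know), 15% of in-lexicon
  current mentions are bare and cueless (the engine abstains), and 30% of
  documents carry a distractor sentence (cannabis, third-party, smoked
  food, uncertainty). These rates were chosen a priori to produce the
  precision-first regime the engine is designed for — near-perfect
  precision with recall visibly below it — without claiming to reproduce
  any particular published operating point.

Every generated smoking phrase carries exactly one gold annotation with
exact offsets; distractors carry none. Fixed seed ⇒ byte-identical output.

What the generator does **not** emulate: real note length, vocabulary drift,
misspellings, copy-paste duplication, multiple care episodes, or smoking
histories that change over time (each patient has one true status). A green
evaluation on synthetic gold therefore establishes that the engine
implements its own rules faithfully and that the pipeline's plumbing is
lossless — not that any particular precision/recall would be achieved on
real clinical text.

## Numerical and degenerate-input choices

* Degenerate contingency inputs error early: zero marginals (Pearson),
  fewer than 3 ordered categories (trend), zero cells (OR without
  continuity), empty cohorts (percentages undefined).
* A factor with no missingness anywhere is reported as 0% everywhere with a
  degenerate test (statistic 0, p = 1) rather than an error.
* Malformed dates in patient tables drop the row with a warning; dates are
  ISO-8601 throughout.
* Evaluation matching is greedy leftmost-longest over candidate pairs with
  a symmetric sort key (document, earliest span start, overlap length), so
  it is deterministic, order-invariant, and swapping predicted/gold swaps
  false positives with false negatives. Span agreement defaults to *any
  overlap* plus status agreement; an `exact` mode is provided because the
  appropriate criterion is genuinely unsettled — a span/status pair that
  overlaps with the wrong status counts as both a false positive and a
  false negative.
* The parameter-recovery property (generating coefficients inside their
  Wald 95% intervals) is asserted as *pooled* coverage across slope terms
  over 100 replicates at n = 5,000: per-coefficient thresholds at 100
  replicates have a double-digit false-alarm rate even at nominal coverage,
  while pooled coverage tests the same claim stably.

## Limitations

* Recall is sacrificed by design; the engine is unsuited to settings where
  each document must be classified in isolation.
* No quantity/pack-year extraction, no cessation-advice detection, no
  smoking-history trajectories, and no de-identification — all out of
  scope.
* The lexicons are a reconstruction; any deployment on real notes should
  re-derive them against a local gold standard using the shipped
  evaluation loop (`score_annotations` + `error_report`).
* Asymptotic tests only (no exact/Fisher variants), matching the intended
  cohort-scale use.
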