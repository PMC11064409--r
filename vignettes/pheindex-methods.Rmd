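---
title: "PheIndex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PheIndex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pheindex)
```

## The problem

Children with rare genetic disorders are hard to find in structured
electronic medical records: most individual disorders have no specific ICD
code, codes are often logged while a diagnosis is merely being ruled out, and
the decisive evidence frequently sits in free text. PheIndex sidesteps
per-disease case definitions and instead scores *overall illness burden* in
the first three years of life: children with genetic disease tend to show
multi-system involvement, heavy healthcare utilization, pronounced supportive
care, and intensive diagnostic work-up, whatever the underlying disorder.

This package implements the full computable phenotype: the thirteen criteria,
the severity score and binary classification, the cohort descriptives used to
characterize a birth cohort, the diagnostic-validation computations, and a
synthetic EMR generator so every part is testable without access to protected
clinical data.

## The thirteen criteria

Each criterion is evaluated per child on events dated within the observation
window (age ≤ 1095 days; later events are dropped with a log line). Five
criteria are *major* (score 3), eight are *minor* (feeding and respiratory
support score 2, the rest score 1). Four criteria have term-specific
thresholds; term status is pre-term below 259 days (37 completed weeks) of
gestation, the standard clinical cutoff.

| criterion | tier/score | rule |
|---|---|---|
| `nicu_stay` | major/3 | full-term only: merged ICU episode starting ≤ 7 days after birth, lasting ≥ 4 days |
| `hospitalizations` | major/3 | inpatient episodes ≥ 48 h admitted after 245 days postmenstrual age; met on one ≥ 14-day stay, or ≥ 2 (full-term) / ≥ 3 (pre-term) stays |
| `multiple_specialists` | minor/1 | ≥ 3 (full-term) / ≥ 4 (pre-term) distinct included specialty *types*; Pediatric Infectious Disease never counts |
| `er_visits` | minor/1 | ≥ 5 (full-term) / ≥ 7 (pre-term) emergency encounters |
| `feeding_support` | minor/2 | feeding-support ICD code, or a non-cancelled procedure whose name matches "nasogastric", or "gastrostomy"+"feed", or "gastrostomy"+"tube" |
| `respiratory_support` | minor/2 | tracheostomy/ventilation (incl. CPAP) from procedure names or ICD codes, clear of every surgery day `s` (`d ≤ s−1` or `d ≥ s+5`) |
| `imaging` | minor/1 | CT or MRI order with completed/preliminary/final status |
| `genetic_tests` | minor/1 | any genetic diagnostic test order, regardless of result |
| `metabolic_tests` | minor/1 | any metabolic test order, regardless of result |
| `death` | major/3 | death-type discharge disposition (expired, funeral home/morgue, organ harvest) or a death date in-window |
| `developmental_delay` | minor/1 | a developmental-pediatrics visit, or ≥ 2 matching ICD records on distinct dates |
| `metabolic_icd` | major/3 | metabolic-disease ICD codes in ≥ 2 distinct encounters |
| `heart_surgery` | major/3 | cardiothoracic-ICU encounter or non-cancelled cardiothoracic procedure |

The **score** is the sum of scores over met criteria. Summing the configured
weights gives a ceiling of 25 for full-term children and 22 for pre-term
children, exposed as `max_score()`: the arithmetic over the criterion table
is authoritative, and any lower nominal range quoted for such scores is not
reproduced. The **classification** is positive when any of
(a) ≥ 2 major, (b) ≥ 1 major and ≥ 1 minor, (c) ≥ 5 minor, or (d) the child
is deceased. The reported `triggering_condition` follows a→d precedence but
never changes the binary outcome; over the full truth table the minimum
positive score is 3 (death alone).

## Interpretation choices

The source rules leave several edges open; the package fixes them as follows
and tests each one.

* **NICU inference.** De-identified extracts rarely flag NICU directly, so a
  NICU stay is inferred from ICU-class encounters beginning within 7 days of
  birth. Contiguous ICU encounters are merged first. The criterion never
  applies to pre-term children, whose NICU stays reflect prematurity.
* **Episode merging.** Overlapping or exactly contiguous inpatient
  encounters are one hospitalization — a same-moment transfer is not a new
  stay. Merging is order-insensitive. Open-ended stays (and stays running
  past the window) are censored at the window end and flagged.
* **Postmenstrual-age filter.** Hospitalizations admitted at ≤ 245 days
  postmenstrual age are excluded outright, even if the stay extends past
  245 days: a very pre-term newborn's birth hospitalization never counts.
* **Perioperative ventilation.** A support event on day `d` qualifies only if
  `d ≤ s − 1` or `d ≥ s + 5` for *every* surgery day `s` (surgical
  procedures and CTICU admissions). "One day before" is read as *at least*
  one day. This is the single non-monotone rule: recording an additional
  surgery can disqualify a previously qualifying event, which the tests
  assert as the documented exception.
* **Counting conventions.** Specialist types, not visits, are counted;
  developmental-delay ICD occurrences are counted on distinct calendar dates
  (guarding against same-day duplicate coding); ER visits are distinct
  emergency encounters with no same-day collapsing; cancelled orders and
  procedures never count.
* **First-met age.** The age at which the condition first became true given
  all data to that day: the day a NICU stay reaches 4 days, the start of the
  threshold-reaching hospitalization/visit, the second qualifying
  developmental-delay date, and so on. Ages are completed days.

Dates are ISO-8601; timestamps are UTC. Date-only encounter records span the
whole day (start 00:00, end 24:00), reflecting extracts without times.

## Vocabulary configuration

Code-based criteria are grounded in user-supplied code sets (two-column CSV:
`code,description`), matched by prefix by default so a configured stem covers
its child codes across ICD-9/10 depth differences; exact matching is
available per set. **The shipped code sets under
`inst/extdata/synthetic_codesets/` are synthetic illustrative placeholders,
not clinically curated lists** — deployments on real data must supply their
own. The specialist taxonomy ships with the twenty included types (the
combined gastroenterology/hepatology entry is split into Pediatric GI and
Pediatric Liver to reach the stated count of twenty) and excludes Pediatric
Infectious Disease, since infections are mostly environmental in etiology.
Keyword rules are OR-of-AND substring clauses, case-insensitive, mirroring
how free-text procedure names are screened.

## The synthetic cohort generator

`generate_cohort()` emulates a newborn cohort observed to age three:

* **Structure.** 12.5% pre-term births (gestational ages 175–258 days vs
  259–294 full-term), a latent disorder in 3% of children, and per-criterion
  intent draws with rate `base × multiplier` for disordered children
  (capped at 1).
* **Rates.** `base_rates` are the non-disordered rates, calibrated so the
  implied population marginals (`implied_marginal_rates()`) land on
  realistic frequencies for this population: about 4.2% multiple ER visits,
  3.4% developmental delay, 3.3% multiple specialists, down to 0.14%
  feeding support and 0.09% recurrent metabolic codes. Criteria without a
  published anchor are interpolated between those; they are package choices,
  not reported values. The NICU and heart-surgery marginals (1.2% full-term,
  0.7%) were additionally chosen so the default co-occurrence target below
  is geometrically attainable (the Jaccard of two criteria is bounded by
  their count ratio).
* **Co-occurrence.** Beyond the coupling induced by the shared latent
  disorder, configured pairs are pushed toward a target Jaccard by
  marginal-preserving swaps inside term-by-disorder strata (an "a-only"
  child gains b while a "b-only" child loses it). The default couples
  prolonged NICU stay and heart surgery at J = 0.44 among full-term
  children, the clinically expected overlap; unreachable targets produce a
  warning with the achieved value.
* **Witness + decoy emission.** Each intended criterion is emitted as a
  minimal event pattern the engine provably detects (e.g. exactly five ER
  visits for a full-term child); each non-intended criterion may receive
  sub-threshold decoys (four ER visits, a 3-day ICU stay, a cancelled order,
  a perioperative ventilation pair, duplicate same-encounter codes). The
  engine-vs-generator contract — exact recovery of every intent at zero
  noise — is what the round-trip tests assert at n = 5000, and it holds
  precisely because witnesses and decoys are audited pairwise not to
  interact across criteria. One deliberate simplification: gastrostomy and
  tracheostomy witness procedures are emitted as non-surgical so they cannot
  perturb the perioperative rule.
* **Documentation noise.** `inject_documentation_noise()` flips each child's
  observed record against the latent truth at configured per-criterion
  rates, by re-emitting the event tables from the flipped intent vector. A
  19% NICU flip rate reproduces the kind of extraction error seen when NICU
  status must be inferred from encounter timing. NICU flips are drawn among
  full-term children only — the rule is structurally false for pre-term
  children — so NICU extraction accuracy is assessed within the full-term
  stratum.

What the generator does **not** emulate: realistic visit-frequency
distributions (witness patterns are minimal), correlated timing across
criteria, demographics and socioeconomic fields, mother-side clinical data,
post-mortem record artifacts, and free-text notes. Passing round-trip tests
therefore demonstrates correctness of the extraction rules against the data
dictionary, not performance on real EMR data, where documentation gaps and
coding variation dominate.

## Validation computations

`confusion()` excludes children with an "unknown" gold label before counting
and reports sensitivity, specificity, PPV, NPV and accuracy both as exact
fractions and integer-rounded percentages; zero-denominator metrics are `NA`
and flagged, never silently zero. `adjusted_ppv()` restates PPV at an assumed
population prevalence via the standard Bayes correction
`sens·p / (sens·p + (1−spec)(1−p))` — a balanced case-control validation
sample otherwise overstates real-world PPV roughly tenfold at a 3%
prevalence. `sample_chart_review()` draws review samples whose scores span
each class's observed range (quantile bins, filled in rotation, remainder
uniform), deterministically under a seed. `per_criterion_accuracy()` compares
met flags against any gold profile table and reports the cross-criterion
mean.

## Numerical and testing notes

Problem sizes in the shipped tests are package choices balancing statistical
resolution against runtime: boundary and truth-table checks are exhaustive
(all 2^13 full-term and 2^12 pre-term met-vectors against an independent
literal classifier), the round-trip contract runs at n = 5000, and rate
recovery at n = 20000 with 3-standard-error bands. Stochastic assertions run
under fixed seeds. The acceptance script (`scripts/acceptance.R`) re-runs the
whole pipeline at n = 20000 from a caller-supplied seed and writes its
headline quantities as JSON.

Known limitations: the shipped code sets are placeholders; the adjusted PPV
is the exact Bayes correction and makes no allowance for alternative
adjustment conventions; and classification performance against the
generator's latent disorder is an internal-consistency measure, not a
clinical validation.
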