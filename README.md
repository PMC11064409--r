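# pheindex

Rule-based digital phenotyping of children aged 0–3 at increased risk for
rare genetic disorders, from structured EMR data.

Finding children with rare genetic disorders through diagnosis codes alone is
unreliable: most individual disorders have no specific ICD code, codes are
logged while conditions are still being ruled out, and decisive findings often
live in free text. PheIndex instead scores *overall illness burden* over the
first three years of life — multi-system disease, heavy healthcare
utilization, pronounced supportive care, and intensive diagnostic work-up are
the common signature of this population, whatever the underlying disorder.

## The algorithm

Thirteen criteria are evaluated per child over encounter, diagnosis,
procedure and lab-order tables (events up to age 1095 days). Five are
**major** (score 3): prolonged NICU stay (full-term newborns only),
prolonged/multiple hospitalizations, in-hospital death, recurrent
metabolic-disease diagnosis codes, and heart surgery. Eight are **minor**:
feeding support and respiratory support outside surgery (score 2 each), plus
multiple specialist types, multiple ER visits, CT/MRI imaging, genetic tests,
metabolic tests, and developmental delay (score 1 each). Four criteria apply
term-specific thresholds (pre-term = gestational age < 37 weeks).

* **PheIndex Score** = Σ score(c) over met criteria c
  (ceiling 25 full-term, 22 pre-term).
* **PheIndex Classification** = positive iff
  (a) ≥ 2 major, (b) ≥ 1 major ∧ ≥ 1 minor, (c) ≥ 5 minor, or
  (d) the child is deceased.

Validation utilities compute the confusion summary against gold labels (with
"unknown" reviews excluded), sensitivity/specificity/PPV/NPV/accuracy, the
prevalence-adjusted PPV `sens·p / (sens·p + (1−spec)(1−p))`, per-criterion
accuracy, and a score-stratified chart-review sampler. Cohort analytics cover
per-criterion frequencies, term-stratified Jaccard co-occurrence matrices
(13 criteria full-term, 12 pre-term), time-to-first-criterion curves, and
count/score distributions. A synthetic EMR generator with latent disorder
status and controllable documentation noise makes the whole pipeline testable
without protected data; see the methods vignette
(`vignettes/pheindex-methods.Rmd`) for model details and design choices.

Code-based criteria are driven by configurable code sets. **The code sets
shipped under `inst/extdata/synthetic_codesets/` are synthetic placeholders**;
supply curated lists for real data.

## Worked example

```r
library(pheindex)

cfg <- generator_config(n_children = 2000, seed = 42)
gen <- generate_cohort(cfg)
gen$cohort
#> <emr_cohort: 2000 children, 5975 encounters, 480 diagnoses, 355 procedures, 817 lab orders; 1095-day window>

profiles <- evaluate_cohort(gen$cohort)   # 13 criteria per child
results  <- classify_cohort(profiles)
#> classified 2000 children: 38 positive (1.90%), 1962 negative

freq <- criterion_frequencies(profiles)
head(freq[order(-freq$n), ], 5)
#>             criterion   n  pct
#>             er_visits 104 5.20
#>   developmental_delay  78 3.90
#>               imaging  67 3.35
#>  multiple_specialists  60 3.00
#>      hospitalizations  43 2.15
```

About 2% of synthetic children classify positive — the small slice of a birth
cohort whose utilization pattern warrants genetic work-up. Feeding a typical
chart-review validation table through the confusion summary:

```r
cm <- confusion_from_counts(tp = 85, fn = 9, fp = 3, tn = 91,
                            n_excluded_unknown = 12)
cm
#> <confusion_summary: n=188 evaluated, 12 unknown excluded>
#>   TP=85 FN=9 FP=3 TN=91
#>   sensitivity 90%, specificity 97%, PPV 97%, NPV 91%, accuracy 94%

100 * adjusted_ppv(cm$sensitivity, cm$specificity, prevalence = 0.03)
#> [1] 46.7
```

The adjusted PPV restates the balanced-sample PPV (97%) at a realistic 3%
population prevalence: roughly half of flagged children would carry a genetic
disorder, which is the operationally meaningful number for screening.

A command-line pipeline is available via the launcher in `inst/cli/`:

```sh
pheindex simulate --n 5000 --seed 7 --out-dir cohort/
pheindex classify --in-dir cohort/ --out-dir out/
pheindex analyze  --in-dir out/ --out-dir analytics/
pheindex validate --in-dir out/ --gold gold.csv --out-dir validation/
```

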