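# icupretest

Predicting whether the **next laboratory blood test in the ICU will be
normal or abnormal**, using two information-based feature families built
from a patient's own testing history:

* **Pretest probability** — the conditional probability that a result is
  normal given the number *M* of immediately preceding consecutive normal
  results of the same test within the admission,

  `p(M) = count(normal at run length M) / count(tested at run length M)`,

  estimated on training admissions and looked up per event (run lengths
  beyond the training maximum clamp to the last estimate).
* **Conditional entropy** — for each baseline feature *Z* (vitals
  interpolated at the draw time, age, first result of the day, sex,
  diagnosis), the binary entropy of the outcome within the training bin
  containing the patient's value,

  `H(Y | Z in bin) = -p log2 p - (1-p) log2 (1-p)`, `p = P(normal | bin)`,

  with Freedman–Diaconis binning (`2*IQR/N^(1/3)`) for continuous
  features and categories as bins otherwise. Low entropy marks values that
  practically decide the outcome.

A predictable result is a candidate for *not* ordering the test — an
intermediate step toward reducing overtesting in intensive care, where
roughly half of routine blood tests have been reported to add little
information. The package is aimed at clinical-informatics researchers who
want to study these features under leakage-safe evaluation.

The package provides, end to end:

* a seeded **synthetic ICU EMR generator** (admissions, six vitals at
  irregular times, per-test timestamped results whose normality follows a
  severity-modulated two-state Markov chain) — protected health data of
  this kind cannot be redistributed, so the whole pipeline is testable on
  cohorts with the same statistical structure;
* **cohort labeling** against packaged sex/age-conditional reference
  ranges for 18 common ICU blood tests, inclusion criteria, run-length /
  day-index annotation;
* **natural-cubic-spline alignment** of vitals to lab-draw times, fitted
  per admission with no access to lab values (no leakage);
* a **probabilistic Takagi–Sugeno fuzzy classifier** (fuzzy c-means rule
  induction, product-t-norm activations, probabilistic consequents,
  wrapper forward feature selection) plus ridge logistic regression,
  random forest and gradient boosting baselines with their published
  hyperparameter grids;
* **admission-grouped 10-fold cross-validation**, a 10-metric panel
  (sensitivity, specificity, accuracy, precision, NPV, F1, AUROC, PR-AUC,
  mean G, index balanced accuracy), two-sided Wilcoxon comparison of
  approaches with Benjamini–Hochberg correction, and rank-averaged feature
  relevance.

## Worked example

Simulate a cohort, label it, inspect the pretest distribution, and compare
feature approach 1 (vitals + demographics + first-of-day value, 10
features) with approach 2 (the same plus pretest probability and entropy
features, 21 features):

```r
library(icupretest)

coh <- generate_cohort(sim_config(n_admissions = 120, test_types = "potassium",
                                  mean_labs_per_admission = 15, seed = 42))
coh <- apply_inclusion_criteria(coh)
coh <- annotate_sequences(coh)
coh
#> <icu_cohort> 120 admissions, 53826 vitals samples, 1797 lab events

head(estimate_pretest_table(coh$labs), 5)
#> # A tibble: 5 × 5
#>   test_type     M n_normal n_total probability
#>   <chr>     <int>    <int>   <int>       <dbl>
#> 1 potassium     0      226     715       0.316
#> 2 potassium     1      186     217       0.857
#> 3 potassium     2      149     175       0.851
#> 4 potassium     3      125     141       0.887
#> 5 potassium     4      103     117       0.880
```

After one abnormal (or at the start of a stay) a result is normal only
31.6% of the time; after a single normal the probability jumps to ~86% —
the run-length persistence that makes repeated testing redundant.

```r
cfg <- experiment_config(
  simulation = sim_config(n_admissions = 120, test_types = "potassium",
                          mean_labs_per_admission = 15, seed = 42),
  classifiers = c("fuzzy", "logistic"), approaches = c("1", "2"),
  k_folds = 5, grids = list(logistic = tibble::tibble(C = 1)), seed = 42)
report <- run_experiment(cfg, cohort = coh)
glance(report)[, c("approach", "auroc", "sensitivity", "specificity", "mean_g", "iba")]
#> # A tibble: 2 × 6
#>   approach auroc sensitivity specificity mean_g    iba
#>   <chr>    <dbl>       <dbl>       <dbl>  <dbl>  <dbl>
#> 1 1        0.670       0.123       0.961  0.237 0.0385
#> 2 2        0.847       0.708       0.881  0.790 0.517
```

The information features raise cross-validated AUROC from 0.67 to 0.85 and
sensitivity (abnormal results caught) from 12% to 71% at a modest
specificity cost — exactly the trade a safety-oriented test-reduction
policy wants, since missed abnormals (false negatives) are the harmful
error. Feature relevance confirms where the signal lives:

```r
head(dplyr::filter(report$feature_ranks, approach == "2"), 3)
#> # A tibble: 3 × 5
#>   approach test_type feature             mean_rank  rank
#>   <chr>    <chr>     <chr>                   <dbl> <int>
#> 1 2        potassium pretest_probability       1       1
#> 2 2        potassium entropy_hr                8.6     2
#> 3 2        potassium entropy_bp                9.4     3
```

`autoplot(report)` draws the per-fold metric distributions,
`plot_percent_change(report)` the approach comparison with significance
stars, and `tidy(report)` returns the fold-level metric table. Fitted fuzzy
rule bases serialize to JSON with `write_rulebase()` for inspection.

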