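# speechtags

Speech is a cheap, non-invasive window on cognition: in Alzheimer's disease
(AD) spontaneous speech stays fluent but becomes information-poor — fewer
content words, more fillers, particles and silences ("empty speech").
`speechtags` is an R implementation of a transcript-classification pipeline
that turns part-of-speech and dependency annotated speech transcripts into
tag-usage features and classifies visits as AD or healthy control (HC) with
gradient-boosted trees, for researchers in computational psychiatry and
clinical NLP who have Universal Dependencies parses of interview or
picture-description speech (or who want to prototype on synthetic cohorts).

## The method

For each assessment (one subject at one visit), after removing punctuation
tokens and stop-words, two feature families are computed per tag type
(universal part-of-speech tags and dependency relations):

* **tag frequencies** — for tag *t*, `count(t) / n_tokens`;
* **tag transitions** — over all N adjacent within-utterance tag pairs
  (T<sub>i1</sub>, T<sub>i2</sub>), the relative frequency
  `count(a → b) / N` of each ordered pair, the empirical view of the
  conditional probability of seeing tag b after tag a.

With the default vocabularies of 17 POS tags and 24 dependency relations the
feature vector has 17 + 17² + 24 + 24² = **906** dimensions.

Visits are labeled by the ADNI-2 score rules — AD: MMSE ≤ 23, CDR ≥ 0.5 and
Logical Memory II at or below an education-adjusted threshold (8 / 4 / 2 for
≥16 / 8–15 / ≤7 years of education); HC: MMSE ≥ 24, CDR = 0, Logical Memory
II at or above 9 / 5 / 3; everything else is excluded. An XGBoost classifier
(max_depth 3, 700 rounds, learning rate 0.1, subsample 0.6, gamma 5) is
evaluated by **subject-grouped repeated random subsampling**: in each of 100
folds, 90% of subjects (with all of their visits) train the model and the
held-out 10% of subjects test it, so no person's data ever sits on both
sides of a split. Per-fold precision, recall, specificity, f1 and rank-based
AUC are averaged across folds, and per-feature gain importances (0 for
features a fold's model never used) are averaged to rank features.

Because no clinical corpus ships with the package, a first-order Markov
generator (`generate_cohort()`) produces synthetic tag-annotated cohorts in
which an effect-size knob δ moves probability mass away from content-word
patterns (noun, verb, noun↔adposition transitions) and toward stagnation
patterns (symbol, particle, interjection→particle) in the AD-like group;
δ = 0 gives an exchangeable null cohort.

## Worked example

```r
library(speechtags)

cohort <- generate_cohort(synthetic_cohort_config(
  n_subjects_per_group = 20, visits_per_subject = 3,
  effect_size = reference_effect_size(), seed = 100))
fm <- build_feature_matrix(cohort$corpus)
fm
#> <feature_matrix> 120 assessments x 906 features (60 AD, 60 HC)

plan <- make_split_plan(unique(fm$subject_id), n_folds = 100,
                        test_fraction = 0.1, seed = 100)
report <- run_validation(fm, plan,
  xgb_hyperparameters(n_estimators = 100, random_seed = 100))
report
#> <validation_report> 100 folds
#>   precision   0.917 (SD = 0.209, 96/100 folds)
#>   recall      0.994 (SD = 0.024, 92/100 folds)
#>   specificity 0.958 (SD = 0.079, 93/100 folds)
#>   f1          0.973 (SD = 0.048, 92/100 folds)
#>   accuracy    0.973 (SD = 0.043, 100/100 folds)
#>   auc         1.000 (SD = 0.004, 85/100 folds)
#>   pooled AUC  0.996
#>   features with nonzero importance in >=1 fold: 6

top_k_features(report)
#>    feature mean_importance sd_importance
#> 1     NOUN    0.5687544002   0.112753431
#> 2 NOUN_ADP    0.2463213572   0.088739516
#> 3     PART    0.1013892710   0.069411007
#> 4     VERB    0.0832997398   0.044891628
#> ...
```

The fold-averaged AUC near 1 says this large-effect synthetic cohort is
essentially separable; the importance ranking recovers exactly the features
whose generating probabilities differ between the groups (noun frequency,
noun→adposition transition, particle and verb frequencies). Folds whose
metric denominator is zero (e.g. a test draw with one class) report that
metric as undefined and are excluded from its average — the `92/100`-style
counts. On a null cohort (`effect_size = 0`) the same pipeline averages an
AUC near 0.5.

A command-line wrapper covers the same flow from a shell
(`inst/exec/speechtags`): `simulate` writes a synthetic cohort as CoNLL-U
files plus a metadata table, `extract` turns a cohort directory into a
feature-matrix TSV, `validate` writes the JSON validation report and the
importance table, and `report` writes box-plot-style per-group distribution
summaries of the top-k features.

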