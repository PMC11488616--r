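---
title: "Tag-transition features for dementia speech classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-transition features for dementia speech classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtags)
```

## The problem and the model

Alzheimer's disease changes spontaneous speech long before it silences it:
discourse stays grammatical and fluent but carries less content. At the
level of grammatical categories this shows up as lower rates of content
words (nouns, verbs) and of the noun-adposition constructions that package
propositional content, and higher rates of "stagnation" material — fillers,
particles, and the symbol-tagged silence marks transcribers insert.
`speechtags` operationalizes this with two feature families computed from a
Universal Dependencies annotation of each assessment's transcript, for both
part-of-speech (POS) tags and dependency relations:

* tag frequency: count of tag $t$ divided by the number of (filtered)
  tokens;
* tag transition: over the $N$ adjacent within-utterance tag pairs
  $(T_{i1}, T_{i2})$, the count of each ordered pair $(a, b)$ divided by
  $N$ — an empirical estimate of $P(X_i = b \mid X_{i-1} = a)$ scaled by
  the marginal of $a$.

Each of the four blocks (POS frequency, POS transition, dependency
frequency, dependency transition) is a probability vector (or all-zero when
the assessment has no countable material), so every feature lies in
$[0, 1]$ and the vector is invariant to transcript length. With $|P|$ POS
tags and $|D|$ dependency tags the dimension is $|P| + |P|^2 + |D| + |D|^2$;
the defaults $|P| = 17$ (the UPOS inventory) and $|D| = 24$ give 906.

Visits are labeled AD / HC / EXCLUDED from MMSE, CDR and education-adjusted
Logical Memory II thresholds (the ADNI-2 rule set). Labels are per visit —
a subject can convert between visits — and repeated visits are never
averaged: each assessment is one row. An XGBoost binary classifier (AD
positive) is evaluated by repeated random subsampling over *subjects*: each
fold holds out 10% of subjects with all their visits, which is the leakage
guard the repeated-visit design requires. Fold metrics are averaged;
per-feature gain importances (0 when a fold's model never split on the
feature) are averaged to rank features.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `pos_vocab`, `dep_vocab` | 17 UPOS tags, 24 UD relations | feature layout; the dependency membership is configuration |
| `stopwords` | empty | surface forms removed before counting |
| `boundary_mode` | `within_utterance` | whether transition pairs may straddle utterance boundaries |
| `n_folds`, `test_fraction` | 100, 0.10 | subsampling iterations and held-out subject share |
| `max_depth`, `n_estimators`, `learning_rate`, `subsample`, `colsample_bytree`, `gamma`, `min_child_weight` | 3, 700, 0.1, 0.6, 1.0, 5, 1 | boosting configuration, fixed (no in-package grid search) |
| `effect_size` (δ) | 0; reference 0.6 | generator group-difference knob |

Design choices made where the convention was genuinely open:

* **Utterance boundaries.** Adjacency is not defined across sentence
  boundaries in any standard way for transcribed speech, so transitions are
  computed within utterances by default; `boundary_mode = "across_all"`
  treats the assessment as one sequence for sensitivity analysis. The
  CoNLL-U sentence (blank-line) convention supplies the utterance index.
* **Filtering order.** Punctuation tokens and stop-words are removed
  *before* both feature types, so transition pairs join filtered
  neighbours that may not have been adjacent in the raw transcript.
  Punctuation removal keys on the `PUNCT` POS category, not character
  class, so symbol-tagged silence marks (`SYM`) survive — they are signal.
* **Out-of-vocabulary tags** are dropped with a message by default and are
  an error under strict mode, so parser/vocabulary drift is visible.
* **Test-set size** is round-half-up of `test_fraction × n_subjects` with a
  floor of 1 (94 subjects at 10% → 9). Folds are drawn independently
  (subsampling, not a partition) and the plan is a pure function of its
  seed; a fold whose test draw contains one class keeps its confusion
  metrics and reports AUC as undefined rather than being redrawn, so the
  plan stays seed-reproducible.
* **Metrics.** Precision TP/(TP+FP), recall TP/(TP+FN), specificity
  TN/(FP+TN), f1 the harmonic mean, AUC by midrank (Mann–Whitney). A
  zero-denominator metric is undefined (`NA`) and excluded from that
  metric's fold average, with the defined-fold count reported. Both the
  fold-averaged and the pooled (all test predictions) AUC are reported,
  since averaging conventions differ across studies.
* **Importance** is gain-based (each model's gain shares, summing to 1),
  averaged over folds with absent features as 0; top-k ties break
  lexicographically so reports are deterministic. Quartile summaries use
  midpoint interpolation; `drop_zeros` excludes zeros from the quartiles of
  sparse features but reports their count.

## What the synthetic generator emulates — and what it does not

The generator is the generative mirror of the features: a first-order
Markov chain over POS tags (initial distribution + row-stochastic
transition matrix), dependency tags drawn conditionally on the POS tag, and
Poisson-shaped utterance counts and lengths. Defaults are chosen to look
like a roughly ten-minute semistructured interview parsed into UD
categories: a noun/verb/adposition/particle-heavy marginal with small
interjection, symbol and punctuation mass; local syntactic boosts
(noun→adposition, adposition→noun/verb, interjection→particle); a mean of
20 utterances of mean length 8 per assessment; and a visit process
1 + Poisson(2.89), matching the study design's mean of 3.89 visits per
subject with at least one visit each. Clinical scores are synthesized
label-first (drawn from the rule-satisfying region for the subject's
group), because the generator's purpose is pipeline testing, not
psychometric realism.

The effect-size knob δ scales noun/verb emission mass by $1 - \delta$ and
symbol/particle mass by $1 + \delta$ in the initial distribution and every
transition row, scales the noun→adposition and adposition→noun entries by
an extra $1 - \delta$ and interjection→particle by an extra $1 + \delta$,
then renormalizes; δ = 0 leaves the groups identical and δ > 1 is an error.
The **reference value δ = 0.6** is the package's documented "large effect"
calibration — chosen once as a setting safely inside the separable regime
for a 20-subjects-per-group cohort, so that the signal-recovery suite tests
recovery, not borderline power. It is not an estimate of any clinical
effect.

First-order generation is deliberate: the features are first-order
transition frequencies, so a first-order generator makes feature
sufficiency testable — if the pipeline cannot separate these cohorts,
the fault is in the pipeline, not the features. By the same token, passing
tests on synthetic cohorts show correctness of the machinery, not clinical
validity: real transcripts have higher-order and long-range structure,
parser errors, topic effects, class imbalance, and score-label noise that
the generator does not emulate, and the true effect sizes of these group
differences in clinical speech are not established quantities.

## Numerical and degenerate-input conventions

Empty assessments featurize to the all-zero vector; frequency blocks are
zero when no token survives filtering, transition blocks when no utterance
has two tokens ($N = 0$). Probability rows in the generator must sum to 1
within $10^{-9}$. Boosting runs single-threaded with a fixed seed, so
identical inputs give bit-identical models, predictions and reports.
Mutual exclusivity of the AD and HC label rules (disjoint MMSE ranges) is
asserted by exhaustive scan over the score grid in the test suite.

## Problem sizes used by the checks

The test suite and acceptance script run the full 100-fold validation on
cohorts of 20 subjects per group with 3 visits each (120 assessments × 906
features) at 100 boosting rounds — the package's standard desk-scale
configuration, which keeps a full run in the tens of seconds while leaving
every code path identical to a full-size analysis. Exchangeability of the
null generator is checked with two-sample Kolmogorov–Smirnov tests across
features on a 510-assessment cohort; the transition featurizer is checked
against a brute-force pair-enumeration oracle on 1,000 random sequences and
the AUC against an all-pairs oracle on 200 random score sets.

## Known limitations

* No parsing: the package consumes CoNLL-U; producing it from audio or raw
  Japanese text (transcription, GiNZA/spaCy) is upstream of this package.
* The dependency vocabulary and stop-word list are configuration; results
  depend on the parser's tag conventions.
* No hyperparameter search, alternative classifiers, calibration, or
  significance testing of metric differences; the boosting configuration is
  fixed.
* Single binary contrast (AD vs HC); no MCI or staging.
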