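---
title: "Predicting drug-drug interactions from docking-score profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interactions from docking-score profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ddidock)
```

## The problem and the model

Many drug-drug interactions (DDIs) arise because two co-administered
molecules bind the same human protein — a metabolizing enzyme or transporter
(pharmacokinetic, PK) or a shared target/off-target (pharmacodynamic, PD).
A chemical-protein interactome (CPI) profile captures this exposure in one
vector: the reverse-docking scores of a molecule against a fixed panel of
ligand-bindable protein structures, in kcal/mol, where more negative means
stronger predicted binding.

`ddidock` turns CPI profiles into a pair classifier. For an unordered drug
pair $(a, b)$ and target $j$ with docking scores $a_j$ and $b_j$, the pair is
represented by two features per target:

$$S_j = a_j + b_j, \qquad AD_j = |a_j - b_j|,$$

giving $2T$ features for a $T$-target panel (1222 for the library-scale
611-structure panel). Both features are symmetric in the two drugs, so the
representation is independent of pair orientation: $S_j$ measures joint
binding strength at target $j$, $AD_j$ how unequal the two affinities are.
Features are interleaved `S:<target>`, `AD:<target>` per target, and the
names travel with every matrix and model so that panel mismatches are caught
rather than silently misaligned.

A logistic regression with an L2 (ridge) penalty models the probability that
a pair interacts:

$$\min_{b, w} \; -\sum_i \left[ y_i \log p_i + (1-y_i)\log(1-p_i) \right]
  + \frac{\lambda}{2}\lVert w \rVert^2,
  \qquad p_i = \frac{1}{1 + e^{-(b + w \cdot x_i)}}.$$

Known interacting pairs are the positives; negatives are drawn uniformly
without replacement from all remaining unordered pairs (self-pairs excluded),
by default in equal number, yielding a balanced training set.

## Estimation and numerical choices

* **Standardization.** Features are z-scored with training-set statistics
  before fitting: the sum features are roughly twice the scale of single
  docking scores, and a scale-free penalty needs comparable columns.
  Constant features get scale 1 (and thus zero weight). The scaler is stored
  inside the model, so a saved model is self-contained at prediction time.
* **Solver.** Full Newton-Raphson on the penalized log-likelihood with step
  halving; the intercept is unpenalized, as is standard. Convergence is
  declared when the gradient max-norm falls below 1e-6 (cap: 10 000
  iterations; typical fits converge in fewer than 15). The solver is
  deterministic and invariant to row order, so fixed inputs reproduce
  identical models bit for bit. The test suite checks the gradient max-norm
  at the optimum directly and cross-checks weights against an independent
  ridge-logistic implementation.
* **Penalty.** $\lambda = 1$ on standardized features is the default and is
  exposed everywhere. It is a deliberately neutral, scale-free choice: at
  training sizes of a few thousand rows it shrinks little but keeps
  separable directions finite.
* **Missing scores.** A failed docking run is a missing cell (`NA`), never a
  sentinel value. Pairs touching any missing score are dropped from design
  matrices and reported, so only pairs with complete CPI annotations are
  trained on.
* **Serialization.** Models and CV reports are versioned JSON with numbers
  written at 17 significant digits, which round-trips IEEE doubles exactly;
  a reloaded model reproduces predictions bit-identically.

## Evaluation protocol

`repeated_cv()` implements repeated stratified 10-fold cross-validation.
Per repeat: a stratified fold assignment (seed = `base_seed + r`), one model
per training fold-union, out-of-fold probabilities pooled over all rows, a
classification threshold chosen where the F-score
$2PR/(P+R)$ is maximal over the unique pooled scores (ties resolved toward
the lowest threshold), and AUROC, AUPR, accuracy, precision, sensitivity,
specificity and $R^2$ computed at that threshold. The report stores every
per-repeat metric set and threshold; means and standard deviations are
recomputable from them.

`holdout_validate()` adds the independent-validation protocol: a stratified
split reserves 50% of the pairs, repeated CV runs on the training half, a
final model is trained on that half, and the hold-out metrics are computed
at the *arithmetic mean* of the CV-selected thresholds — the held-out rows
never influence training or threshold choice.

Decisions where the protocol was genuinely open, and the readings adopted:

* **Threshold selection** is done on pooled out-of-fold scores (not per
  fold): pooling uses all n rows per repeat and gives one threshold per
  repeat, which is what "averaging thresholds across experiments" needs.
* **$R^2$** is the squared Pearson correlation between predicted
  probabilities and the 0/1 labels, isolated in `pseudo_r2()` so a
  McFadden or Nagelkerke variant could be swapped in; zero-variance scores
  return 0 by convention.
* **Stratification** is used even though plain 10-fold would barely differ
  on balanced data — it stabilizes small synthetic fixtures.
* **AUROC** is the Mann-Whitney concordance probability with ties counted
  1/2; **AUPR** is step-wise average precision over unique thresholds, which
  is well defined under tied scores.

## Mechanistic readout

For a predicted interaction, `rank_percentile()` ranks a target within a
drug's score vector: rank 1 is the most negative score, ties share the mean
rank, and the percentile is rank/N over the drug's non-missing targets.
`explain_pair()` flags targets that *both* drugs rank within the top 20% as
candidate mediating proteins. The ranking runs over all panel columns,
including multiple structures of the same protein — a deliberate choice:
agreement across several structures of one protein strengthens, not dilutes,
the signal, and deduplication would require an external structure-to-protein
mapping.

## Structural-redundancy filter

To ask whether performance is driven by near-duplicate chemistry within
pairs, `redundancy_filter()` computes all pairwise Tanimoto coefficients on
binary fingerprints and removes every molecule with similarity above 0.75 to
*any* other — both members of an over-threshold pair are dropped, so the kept
set provably contains no similar pair and the filter is idempotent. (The
alternative greedy reading — keep one of each similar pair — retains more
molecules; the stricter symmetric reading is implemented because it makes
the retained set's property unconditional.) `filter_pairs_by_similarity()`
then removes training pairs touching any dropped drug so the evaluation can
be repeated on the reduced set. Fingerprint type is up to the user; the
package reads a plain hex-encoded format and generates random synthetic
fingerprints for testing.

## The synthetic-data generator

Real CPI training data requires thousands of docking runs against curated
structure panels, so the package ships a generator that emulates the study
conditions end to end:

* `gen_cpi()` draws independent normal scores per cell, mean −7.0 kcal/mol,
  sd 1.5 — the typical range of rigid-docking output, predominantly
  negative. Missing cells are placed uniformly at random at a requested
  rate.
* `gen_planted_world()` samples distinct drug pairs, builds their
  standardized pair features, draws a sparse weight vector (10% of features
  active by default), and assigns labels from the planted logistic model.
  The intercept is solved so the realized positive fraction is within 2% of
  the request (default balanced, mirroring an equal positive/negative
  design), and the weight magnitude is calibrated so the *oracle AUROC* —
  the AUROC of the planted linear score on the generated labels — falls in
  0.85–0.88, the realistic operating band for interaction classifiers of
  this kind. Every generator is a pure function of its arguments including
  the seed.
* `gen_vina_log()` writes parseable docking-result fixtures in both
  supported dialects (stdout affinity table and PDBQT result remarks).

What the generator deliberately does **not** emulate: correlation of docking
scores across structurally similar binding pockets, the network topology of
curated interaction databases (positives are sampled by label, not by drug
connectivity), and chemical-series structure in fingerprints. Passing the
recovery tests therefore demonstrates that the pipeline is correct and
well-calibrated on data satisfying its own assumptions — not that the
headline numbers transfer to any particular real interaction corpus.

## Problem sizes and what the tests show

The test and acceptance runs use planted worlds of 2 000 pairs over a
300-drug x 10-target CPI for the protocol checks (10-fold CV scaled to 5
repeats; 50% hold-out), and 5 000 pairs over 20 targets for parameter
recovery; these sizes give stable estimates (CV AUROC sd below 0.001) while
keeping a full run in seconds. At those sizes the pipeline recovers the
oracle AUROC within 0.03 in both protocols, fitted weights correlate above
0.9 with the planted ones, and all structural dimensionalities match the
library-scale workflow (2515 drugs x 611 targets -> 1222 features; balanced
6328-pair classes -> a 12 656 x 1222 training matrix; one query -> 2515
candidate pairs).

## Known limitations

* Docking scores are treated as given; the package neither docks nor judges
  docking quality, and systematic docking biases propagate into the model.
* Uniform negative sampling assumes unlabeled pairs are true negatives;
  contaminated negatives bias probabilities toward the base rate (visible in
  the synthetic worlds when training on re-sampled rather than planted
  negatives).
* The linear model scores pairs independently; it cannot represent
  higher-order (three-drug) interactions or non-additive target effects
  beyond what $S$ and $AD$ encode.
* The squared-correlation $R^2$ is one of several pseudo-$R^2$ conventions;
  comparisons against externally reported $R^2$ values should verify the
  convention first.
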