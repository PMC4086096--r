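# ddidock

Drug–drug interaction (DDI) prediction from chemical–protein interactome
(CPI) profiles.

Many clinically relevant DDIs are mediated by two drugs binding the same
human protein — a metabolizing enzyme or transporter (pharmacokinetic) or a
shared target/off-target (pharmacodynamic). `ddidock` predicts such
interactions from structure alone: each drug is profiled by its
reverse-docking scores (kcal/mol, more negative = stronger predicted
binding) against a fixed panel of protein structures, and every unordered
drug pair (a, b) is represented symmetrically, per target j, by

    S_j  = a_j + b_j          (joint binding strength)
    AD_j = |a_j − b_j|        (binding asymmetry)

giving 2T features for a T-target panel. An L2-regularized logistic
regression

    min_{b,w}  −Σ_i [ y_i log p_i + (1−y_i) log(1−p_i) ] + (λ/2)‖w‖²,
    p_i = 1 / (1 + exp(−(b + w·x_i)))

is trained on known interacting pairs versus uniformly sampled
non-interacting pairs, and evaluated with repeated stratified 10-fold
cross-validation, maximum-F1 threshold selection, and an independent
hold-out protocol that reuses the CV-averaged threshold. Per-target rank
percentiles ("is this protein in the top 20% of both drugs' score
vectors?") point at the protein that may mediate a predicted interaction.
A Tanimoto-coefficient redundancy filter (> 0.75 to any other molecule)
supports re-evaluation without near-duplicate chemistry. A planted-model
synthetic generator produces CPI matrices, labeled pair sets, docking-result
files and fingerprints, so the whole pipeline is testable without any
docking runs.

The package is aimed at cheminformatics and drug-safety researchers who
already have docking-score matrices (e.g. from AutoDock Vina) and want a
reproducible pair classifier plus its evaluation protocol.

## Worked example

```r
library(ddidock)

# a synthetic world with planted truth: 300 drugs x 10 targets, 2000 pairs,
# labels drawn from a known logistic model calibrated to oracle AUROC 0.85-0.88
world <- gen_planted_world(n_drugs = 300, n_targets = 10,
                           n_pos = 1000, n_neg = 1000, seed = 11)
world
#> <planted_world> 300 drugs x 10 targets, 2000 pairs (998 pos), oracle AUROC 0.857

cv <- repeated_cv(world$x, world$pairs$label, k = 10, repeats = 5,
                  lambda = 1, base_seed = 21)
cv
#> <cv_report> 10-fold CV x 5 repeats (n = 2000, lambda = 1)
#>   auroc        0.854 +/- 0.001
#>   aupr         0.864 +/- 0.001
#>   accuracy     0.776 +/- 0.003
#>   precision    0.764 +/- 0.011
#>   sensitivity  0.799 +/- 0.012
#>   specificity  0.753 +/- 0.019
#>   r2           0.379 +/- 0.001
#>   f1           0.781 +/- 0.001
#>   mean selected threshold: 0.4398
```

The CV AUROC (0.854) recovers the world's oracle AUROC (0.857) to within
0.03 — the out-of-fold estimate is honest — and the selected thresholds are
stored per repeat. Their mean is then used on an independent hold-out half:

```r
hv <- holdout_validate(world$x, world$pairs$label, holdout_fraction = 0.5,
                       k = 10, repeats = 5, lambda = 1, seed = 51)
hv$holdout
#> <metric_set> AUROC 0.861  AUPR 0.874  acc 0.766  prec 0.725  sens 0.856  spec 0.677  R2 0.399 @ thr 0.3402
```

Mechanistic readout for one predicted pair — which proteins do both drugs
bind strongly?

```r
ex <- explain_pair(world$cpi, "D0001", "D0002", top_frac = 0.20)
head(ex, 2)
#>       target_id target_class percentile_a percentile_b shared_top
#> T0008     T0008           PD          0.4          0.4      FALSE
#> T0002     T0002           PK          0.2          0.5      FALSE
```

The same workflow is scriptable from a shell via `inst/cli/ddidock.R`
(subcommands `fixtures`, `build-cpi`, `train`, `predict`, `filter-similar`):

```sh
Rscript inst/cli/ddidock.R fixtures --out-dir ws --n-drugs 40 --n-targets 6 \
    --n-pos 80 --n-neg 80 --seed 5
#> wrote synthetic fixtures to ws (oracle AUROC 0.862)
Rscript inst/cli/ddidock.R train --cpi ws/cpi.tsv --positives ws/pairs.tsv \
    --model-out ws/model.json --report-out ws/cv.json --repeats 2 --k-folds 5 --seed 5
#> trained on 160 pairs (78 pos / 82 neg); CV AUROC 0.850 +/- 0.017
Rscript inst/cli/ddidock.R predict --model ws/model.json --cpi ws/cpi.tsv \
    --query D0001 --out ws/pred.tsv
#> scored 39 candidate pairs for query 'D0001' -> ws/pred.tsv
```

`ws/pred.tsv` lists every query–library pair sorted by descending
interaction probability, with the shared strongly-bound targets annotated
for the top pairs.

## Package layout

- `R/cpi.R` — CPI matrix type, TSV/CSV I/O, Vina result parsing, rank
  percentiles
- `R/pairs.R` — symmetric pair features, negative sampling, design matrices
- `R/model.R` — ridge-logistic trainer (Newton–Raphson), prediction,
  JSON serialization
- `R/metrics.R`, `R/evaluate.R` — AUROC/AUPR/max-F1/pseudo-R², repeated CV,
  hold-out protocol
- `R/similarity.R` — Tanimoto coefficients, redundancy filter, fingerprints
- `R/synthetic.R` — planted-world generator and fixtures
- `R/cli.R`, `inst/cli/ddidock.R` — command-line workflow
- `vignettes/ddi-prediction-methods.Rmd` — model, protocol and design
  rationale
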