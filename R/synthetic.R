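#' Generate a synthetic CPI matrix
#'
#' Draws independent normal docking scores per cell on the kcal/mol scale of
#' rigid-docking output (default mean -7, sd 1.5, so scores are predominantly
#' negative), with optional uniformly placed missing cells. Real docking
#' scores correlate across structurally similar pockets; the independence
#' here is a deliberate simplification that keeps planted-model oracles
#' analytic while exercising the full pipeline.
#'
#' @param n_drugs,n_targets dimensions.
#' @param seed integer seed; generation is a pure function of the arguments.
#' @param score_mean,score_sd normal parameters (kcal/mol).
#' @param missing_rate fraction of cells set missing, in \[0, 1).
#' @param pk_fraction fraction of targets labeled pharmacokinetic (the rest
#'   pharmacodynamic); cosmetic annotation only.
#' @return a [cpi_matrix()] with drugs `D0001...` and targets `T0001...`.
#' @export
gen_cpi <- function(n_drugs, n_targets, seed, score_mean = -7.0, score_sd = 1.5,
                    missing_rate = 0, pk_fraction = 0.4) {
  if (n_drugs < 1L || n_targets < 1L) {
    ddi_stop("dimensions must be positive", "ddidock_validation_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    ddi_stop("missing_rate must be in [0, 1)", "ddidock_validation_error")
  }
  set.seed(seed)
  scores <- matrix(stats::rnorm(n_drugs * n_targets, score_mean, score_sd),
                   nrow = n_drugs,
                   dimnames = list(sprintf("D%04d", seq_len(n_drugs)),
                                   sprintf("T%04d", seq_len(n_targets))))
  if (missing_rate > 0) {
    scores[stats::runif(length(scores)) < missing_rate] <- NA_real_
  }
  n_pk <- round(pk_fraction * n_targets)
  cpi_matrix(scores, target_class = rep(c("PK", "PD"),
                                        c(n_pk, n_targets - n_pk)))
}

#' Generate a planted-model world for end-to-end testing
#'
#' Builds a synthetic CPI matrix, samples candidate drug pairs, standardizes
#' their pair features, draws a sparse true weight vector, and assigns each
#' pair a Bernoulli label from the planted logistic model
#' `P(y=1) = logit^-1(b + w . x)`. The intercept is solved (and the label
#' draw repeated if needed) so that the realized positive fraction lands
#' within 2% of `n_pos / (n_pos + n_neg)`. When `effect_scale` is `NULL` the
#' weight magnitude is calibrated so that the oracle AUROC — the AUROC of the
#' planted linear score against the generated labels — falls inside
#' `auroc_band` (default 0.85-0.88, a realistic operating point for
#' interaction classifiers of this kind). Because labels are generated from a
#' known model, recovery of that model (weights, AUROC) is a testable
#' property of the whole pipeline.
#'
#' @param n_drugs,n_targets CPI dimensions.
#' @param n_pos,n_neg target class counts; `n_pos + n_neg` pairs are sampled.
#' @param sparsity fraction of the 2T true weights that are nonzero.
#' @param effect_scale weight magnitude multiplier; `NULL` (default)
#'   calibrates it to `auroc_band`, 0 gives label noise (oracle AUROC ~ 0.5).
#' @param auroc_band length-2 numeric, the requested oracle AUROC band.
#' @param seed integer seed; the world is a pure function of the arguments.
#' @return object of class `planted_world`: list with `cpi`, `pairs`
#'   (data.frame `drug_a`, `drug_b`, `label`), `x` (the pair feature matrix,
#'   unstandardized), `true_weights` and `true_intercept` (on the
#'   standardized feature scale), `feature_center`/`feature_scale`,
#'   `oracle_scores`, `oracle_auroc`, `effect_scale`, `seed`.
#' @export
gen_planted_world <- function(n_drugs, n_targets, n_pos, n_neg, sparsity = 0.1,
                              effect_scale = NULL, auroc_band = c(0.85, 0.88),
                              seed = 1L) {
  n_pairs <- n_pos + n_neg
  if (n_pairs > n_drugs * (n_drugs - 1) / 2) {
    ddi_stop("n_pos + n_neg exceeds the number of distinct drug pairs",
             "ddidock_capacity_error")
  }
  cpi <- gen_cpi(n_drugs, n_targets, seed = seed)
  set.seed(seed + 1L)
  # sample distinct unordered pairs
  none <- data.frame(drug_a = character(0), drug_b = character(0))
  pairs <- sample_negatives(none, cpi$drugs, n_pairs, seed = seed + 1L)
  pairs <- pairs[, c("drug_a", "drug_b")]
  dm <- assemble_design_matrix(pairs, cpi)
  x <- dm$x
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")

  set.seed(seed + 2L)
  p <- ncol(z)
  n_active <- max(1L, round(sparsity * p))
  w_dir <- numeric(p)
  w_dir[sample.int(p, n_active)] <- stats::rnorm(n_active)
  frac_pos <- n_pos / n_pairs

  draw_labels <- function(scale, label_seed) {
    w <- w_dir * scale
    lin <- drop(z %*% w)
    # intercept solved so the expected positive fraction matches the request
    b <- stats::uniroot(function(b0) mean(stats::plogis(b0 + lin)) - frac_pos,
                        interval = c(-50, 50), tol = 1e-10)$root
    for (try in 1:50) {
      set.seed(label_seed + try)
      y <- as.integer(stats::runif(n_pairs) < stats::plogis(b + lin))
      if (abs(mean(y) - frac_pos) <= 0.02 && length(unique(y)) == 2L) {
        return(list(w = w, b = b, lin = lin, y = y))
      }
    }
    ddi_stop("could not realize the requested positive fraction within 2%",
             "ddidock_config_error")
  }

  if (is.null(effect_scale)) {
    scale <- 1
    step <- 1.4
    res <- NULL
    for (it in 1:60) {
      res <- draw_labels(scale, label_seed = seed + 100L * it)
      auc <- auroc(res$b + res$lin, res$y)
      if (auc >= auroc_band[[1L]] && auc <= auroc_band[[2L]]) break
      scale <- if (auc < auroc_band[[1L]]) scale * step else scale / step
      step <- max(1.02, step^0.85)   # shrink the step to converge on the band
    }
    effect_scale <- scale
  } else if (effect_scale == 0) {
    # no signal: labels are fair-ish coin flips at the requested prevalence
    res <- draw_labels(0, label_seed = seed + 100L)
  } else {
    res <- draw_labels(effect_scale, label_seed = seed + 100L)
  }

  pairs$label <- res$y
  scores <- res$b + res$lin
  structure(
    list(
      cpi = cpi,
      pairs = pairs,
      x = x,
      true_weights = stats::setNames(res$w, colnames(x)),
      true_intercept = res$b,
      feature_center = ctr,
      feature_scale = scl,
      oracle_scores = scores,
      oracle_auroc = auroc(scores, res$y),
      effect_scale = effect_scale,
      seed = seed
    ),
    class = "planted_world"
  )
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("<planted_world> %d drugs x %d targets, %d pairs (%d pos), oracle AUROC %.3f\n",
              length(x$cpi$drugs), length(x$cpi$targets), nrow(x$pairs),
              sum(x$pairs$label), x$oracle_auroc))
  invisible(x)
}

#' Write a synthetic docking-result fixture file
#'
#' Emits either a Vina-style stdout log with a mode/affinity table
#' (`dialect = "log"`) or a PDBQT-style output structure with one
#' `REMARK VINA RESULT:` line per model (`dialect = "pdbqt"`). Both parse
#' back through [parse_vina_result()] with `best_score = min(scores)` and
#' `n_poses = length(scores)`.
#'
#' @param path output file.
#' @param ligand_id,target_id identifiers (recorded in comment lines only).
#' @param scores numeric vector of per-mode affinities (kcal/mol).
#' @param dialect `"log"` or `"pdbqt"`.
#' @return `path`, invisibly.
#' @export
gen_vina_log <- function(path, ligand_id, target_id, scores,
                         dialect = c("log", "pdbqt")) {
  dialect <- match.arg(dialect)
  if (length(scores) == 0L) {
    ddi_stop("need at least one docking score", "ddidock_validation_error")
  }
  lines <- if (dialect == "log") {
    c(sprintf("# synthetic vina log: ligand %s vs target %s", ligand_id, target_id),
      "mode |   affinity | dist from best mode",
      "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
      "-----+------------+----------+----------",
      sprintf("%5d %12.2f %10.3f %10.3f", seq_along(scores), scores,
              c(0, stats::runif(length(scores) - 1L, 1, 5)),
              c(0, stats::runif(length(scores) - 1L, 1, 8))))
  } else {
    unlist(lapply(seq_along(scores), function(i) {
      c(sprintf("MODEL %d", i),
        sprintf("REMARK VINA RESULT: %8.2f %10.3f %10.3f", scores[[i]],
                if (i == 1L) 0 else i - 1, if (i == 1L) 0 else i),
        sprintf("REMARK synthetic pose for %s/%s", ligand_id, target_id),
        "ENDMDL")
    }))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic binary fingerprints
#'
#' Random sparse fingerprints, optionally with `n_clones` drugs whose
#' fingerprints are exact copies of earlier drugs (to exercise the
#' redundancy filter).
#'
#' @param drug_ids character vector of ids.
#' @param n_bits fingerprint length (default 1024).
#' @param density expected fraction of set bits.
#' @param n_clones how many of the last drugs are made identical to the
#'   first drugs.
#' @param seed integer seed.
#' @return a [fingerprint_set()].
#' @export
gen_fingerprints <- function(drug_ids, n_bits = 1024L, density = 0.1,
                             n_clones = 0L, seed = 1L) {
  n <- length(drug_ids)
  if (n_clones >= n) ddi_stop("n_clones must be < number of drugs",
                              "ddidock_validation_error")
  set.seed(seed)
  bits <- matrix(as.integer(stats::runif(n * n_bits) < density), nrow = n,
                 dimnames = list(drug_ids, NULL))
  if (n_clones > 0L) {
    for (i in seq_len(n_clones)) bits[n - n_clones + i, ] <- bits[i, ]
  }
  fingerprint_set(bits)
}
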