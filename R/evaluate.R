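#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals its members round-robin over the
#' k folds, so every fold has a near-identical class balance.
#'
#' @param y 0/1 labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k, one per row.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.numeric(y)
  if (min(table(y)) < k) {
    ddi_stop(sprintf("smallest class has fewer than k = %d members; cannot stratify", k),
             "ddidock_config_error")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

cv_once <- function(x, y, k, lambda, seed) {
  fold <- stratified_folds(y, k, seed)
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- fold == f
    m <- train_logistic(x[!te, , drop = FALSE], y[!te], lambda = lambda)
    oof[te] <- predict_proba(m, x[te, , drop = FALSE])
  }
  oof
}

#' Repeated stratified k-fold cross-validation
#'
#' Protocol per repeat r: a stratified k-fold split (seed `base_seed + r`),
#' a model trained on each k-1 fold union, out-of-fold probabilities pooled
#' over the whole data, the classification threshold selected by
#' [max_f_threshold()] on the pooled scores, and the full [metric_set()]
#' computed at that threshold. The report aggregates mean and standard
#' deviation per metric over repeats and stores every selected threshold
#' (their mean is the cutoff used for independent hold-out validation).
#'
#' @param x feature matrix.
#' @param y 0/1 labels.
#' @param k folds (default 10).
#' @param repeats number of repeats (default 100).
#' @param lambda L2 penalty passed to [train_logistic()].
#' @param base_seed integer; repeat r uses seed `base_seed + r`.
#' @return An object of class `cv_report`: list with `per_repeat` (list of
#'   `metric_set`), `thresholds`, `mean`, `sd`, `config`.
#' @export
repeated_cv <- function(x, y, k = 10L, repeats = 100L, lambda = 1, base_seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  per_repeat <- vector("list", repeats)
  thresholds <- numeric(repeats)
  for (r in seq_len(repeats)) {
    oof <- cv_once(x, y, k, lambda, seed = base_seed + r)
    sel <- max_f_threshold(oof, y)
    thresholds[[r]] <- sel$threshold
    per_repeat[[r]] <- sel$metrics
  }
  metric_names <- c("auroc", "aupr", "accuracy", "precision", "sensitivity",
                    "specificity", "r2", "f1")
  tab <- vapply(per_repeat, function(m) unlist(m[metric_names]),
                numeric(length(metric_names)))
  tab <- matrix(tab, nrow = length(metric_names),
                dimnames = list(metric_names, NULL))
  structure(
    list(
      per_repeat = per_repeat,
      thresholds = thresholds,
      mean = apply(tab, 1L, mean),
      sd = apply(tab, 1L, stats::sd),
      config = list(k = k, repeats = repeats, lambda = lambda,
                    base_seed = base_seed, n = length(y),
                    n_pos = sum(y == 1), n_neg = sum(y == 0))
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV x %d repeats (n = %d, lambda = %g)\n",
              x$config$k, x$config$repeats, x$config$n, x$config$lambda))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  cat(sprintf("  mean selected threshold: %.4f\n", mean(x$thresholds)))
  invisible(x)
}

#' Independent hold-out validation with CV-averaged threshold
#'
#' Protocol: a stratified split reserves `holdout_fraction` of the data as an
#' independent validation set; [repeated_cv()] runs on the training half; a
#' final model is trained on the full training half; the hold-out
#' [metric_set()] is computed at the arithmetic mean of the thresholds
#' selected across the CV repeats. The hold-out rows never touch training,
#' so the resulting metrics are an unbiased estimate of generalization.
#'
#' @inheritParams repeated_cv
#' @param holdout_fraction fraction reserved for validation (default 0.5).
#' @param seed integer seed controlling the split; the internal CV uses
#'   `base_seed = seed`.
#' @return list with `holdout` (a `metric_set`), `cv` (the `cv_report` on the
#'   training half), `model` (the final `ddi_model`), `threshold` (the
#'   averaged cutoff) and `holdout_index` (row indices held out).
#' @export
holdout_validate <- function(x, y, holdout_fraction = 0.5, k = 10L,
                             repeats = 100L, lambda = 1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    ddi_stop("holdout_fraction must be in (0, 1)", "ddidock_config_error")
  }
  set.seed(seed)
  hold <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_h <- round(length(idx) * holdout_fraction)
    hold[sample(idx, n_h)] <- TRUE
  }
  if (length(unique(y[hold])) < 2L || length(unique(y[!hold])) < 2L) {
    ddi_stop("both classes must be present in both halves", "ddidock_config_error")
  }
  cv <- repeated_cv(x[!hold, , drop = FALSE], y[!hold], k = k,
                    repeats = repeats, lambda = lambda, base_seed = seed)
  thr <- mean(cv$thresholds)
  model <- train_logistic(x[!hold, , drop = FALSE], y[!hold], lambda = lambda)
  scores <- predict_proba(model, x[hold, , drop = FALSE])
  list(
    holdout = metric_set(scores, y[hold], thr),
    cv = cv,
    model = model,
    threshold = thr,
    holdout_index = which(hold)
  )
}

#' Write an evaluation report to JSON
#'
#' Serializes a `cv_report` (per-repeat metrics, selected thresholds, mean,
#' sd, configuration) as plain-text JSON.
#'
#' @param report a `cv_report` from [repeated_cv()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  obj <- list(
    format = "ddidock_cv_report",
    config = report$config,
    mean = as.list(report$mean),
    sd = as.list(report$sd),
    thresholds = report$thresholds,
    per_repeat = lapply(report$per_repeat, function(m) unclass(m))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
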