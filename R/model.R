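#' Train an L2-regularized logistic regression DDI classifier
#'
#' Minimizes the penalized negative log-likelihood
#' \deqn{-\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)] + \frac{\lambda}{2}\|w\|^2,
#'       \quad p_i = \mathrm{logit}^{-1}(b + w \cdot x_i)}
#' on z-score standardized features, with the intercept unpenalized.
#' Optimization is full Newton-Raphson with step halving; convergence is
#' declared when the gradient max-norm drops below `tol`. The fit is
#' deterministic: identical inputs give identical weights regardless of row
#' order.
#'
#' Standardization uses the training data's per-feature mean and standard
#' deviation (constant features get scale 1 and end up with zero weight);
#' the scaler is stored in the model so prediction is self-contained.
#'
#' @param x numeric feature matrix with column names (see
#'   [assemble_design_matrix()]).
#' @param y 0/1 labels, both classes present.
#' @param lambda L2 penalty strength (>= 0) on standardized features;
#'   default 1.
#' @param seed unused by the deterministic solver; accepted for interface
#'   uniformity with stochastic trainers.
#' @param tol gradient max-norm convergence tolerance.
#' @param maxit iteration cap.
#' @return An object of class `ddi_model`: list with `weights` (named, on the
#'   standardized scale), `intercept`, `lambda`, `center`, `scale`,
#'   `feature_names`, `converged`, `n_iter`.
#' @export
train_logistic <- function(x, y, lambda = 1, seed = NULL, tol = 1e-6,
                           maxit = 10000L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) < 2L) ddi_stop("need at least 2 rows to train", "ddidock_validation_error")
  if (length(y) != nrow(x)) ddi_stop("label/feature row mismatch", "ddidock_validation_error")
  if (!all(y %in% c(0, 1))) ddi_stop("labels must be 0/1", "ddidock_validation_error")
  if (length(unique(y)) < 2L) {
    ddi_stop("both classes must be present in the labels", "ddidock_degenerate_labels_error")
  }
  if (!all(is.finite(x))) ddi_stop("non-finite feature value", "ddidock_validation_error")
  if (lambda < 0) ddi_stop("lambda must be >= 0", "ddidock_validation_error")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  zz <- cbind(`(Intercept)` = 1, z)
  p1 <- ncol(zz)
  pen <- c(0, rep(lambda, ncol(z)))   # intercept unpenalized

  obj <- function(th) {
    eta <- drop(zz %*% th)
    # numerically stable -loglik: log(1 + exp(eta)) - y*eta
    ll <- sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
    ll + sum(pen * th^2) / 2
  }
  grad <- function(th) {
    p <- stats::plogis(drop(zz %*% th))
    drop(crossprod(zz, p - y)) + pen * th
  }

  th <- numeric(p1)
  f <- obj(th)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(maxit)) {
    n_iter <- it
    g <- grad(th)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    p <- stats::plogis(drop(zz %*% th))
    w <- pmax(p * (1 - p), 1e-10)
    h <- crossprod(zz * w, zz)
    diag(h) <- diag(h) + pen
    step <- drop(solve(h, g))
    # step halving keeps the objective monotone on separable data
    alpha <- 1
    repeat {
      th_new <- th - alpha * step
      f_new <- obj(th_new)
      if (f_new <= f + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    th <- th_new
    f <- f_new
  }
  if (!converged && max(abs(grad(th))) < tol) converged <- TRUE

  structure(
    list(
      version = 1L,
      weights = stats::setNames(th[-1L], colnames(x)),
      intercept = th[[1L]],
      lambda = lambda,
      center = stats::setNames(ctr, colnames(x)),
      scale = stats::setNames(scl, colnames(x)),
      feature_names = colnames(x),
      converged = converged,
      n_iter = n_iter
    ),
    class = "ddi_model"
  )
}

#' @export
print.ddi_model <- function(x, ...) {
  cat(sprintf("<ddi_model> %d features, lambda = %g, intercept = %.4f (%s in %d iter)\n",
              length(x$weights), x$lambda, x$intercept,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Predict interaction probabilities
#'
#' Applies the stored scaler and returns the logistic probability of each
#' feature row being an interacting pair.
#'
#' @param model a `ddi_model` from [train_logistic()].
#' @param x feature matrix whose column names match `model$feature_names`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "ddi_model"))
  x <- as.matrix(x)
  if (is.null(colnames(x)) || !identical(colnames(x), model$feature_names)) {
    ddi_stop("feature columns do not match the model's feature names (panel mismatch)",
             "ddidock_panel_mismatch_error")
  }
  z <- sweep(sweep(x, 2L, model$center, "-"), 2L, model$scale, "/")
  stats::plogis(model$intercept + drop(z %*% model$weights))
}

#' Save / load a trained model
#'
#' Versioned plain-text JSON holding the feature names, scaler, weights,
#' intercept and penalty at full double precision: `load_model(save_model(m))`
#' reproduces predictions bit-identically.
#'
#' @param model a `ddi_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `ddi_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ddi_model"))
  obj <- list(
    format = "ddidock_model",
    version = model$version,
    feature_names = model$feature_names,
    weights = unname(model$weights),
    intercept = model$intercept,
    lambda = model$lambda,
    center = unname(model$center),
    scale = unname(model$scale),
    converged = model$converged,
    n_iter = model$n_iter
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    ddi_stop(sprintf("model file not found: %s", path), "ddidock_io_error")
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    ddi_stop(sprintf("cannot parse model file '%s': %s",
                                     path, conditionMessage(e)),
                             "ddidock_parse_error")
                  })
  if (!identical(obj$format, "ddidock_model")) {
    ddi_stop("not a ddidock model file", "ddidock_parse_error")
  }
  if (!identical(as.integer(obj$version), 1L)) {
    ddi_stop(sprintf("unsupported model file version: %s", obj$version),
             "ddidock_version_error")
  }
  need <- c("feature_names", "weights", "intercept", "lambda", "center", "scale")
  if (!all(need %in% names(obj)) ||
      length(obj$weights) != length(obj$feature_names) ||
      length(obj$center) != length(obj$feature_names) ||
      length(obj$scale) != length(obj$feature_names)) {
    ddi_stop("truncated or inconsistent model file", "ddidock_parse_error")
  }
  structure(
    list(
      version = 1L,
      weights = stats::setNames(as.numeric(obj$weights), obj$feature_names),
      intercept = as.numeric(obj$intercept),
      lambda = as.numeric(obj$lambda),
      center = stats::setNames(as.numeric(obj$center), obj$feature_names),
      scale = stats::setNames(as.numeric(obj$scale), obj$feature_names),
      feature_names = as.character(obj$feature_names),
      converged = isTRUE(obj$converged),
      n_iter = as.integer(obj$n_iter %||% NA_integer_)
    ),
    class = "ddi_model"
  )
}
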