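# Independent brute-force oracles. These deliberately use naive loops and
# first-principles definitions so they share no code path with the package.

# concordance probability by exhaustive pair enumeration, ties count 1/2
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# step-wise average precision via explicit threshold loop
brute_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# exhaustive scan over unique-score thresholds, lowest-threshold tie-break
brute_max_f <- function(scores, labels) {
  best_f <- -1
  best_t <- NA_real_
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (f > best_f) { best_f <- f; best_t <- t }
  }
  list(threshold = best_t, f1 = best_f)
}

# bit-by-bit Tanimoto
brute_tanimoto <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    if (a[i] == 1 || b[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 0 else inter / uni
}

# elementwise loop recomputation of pair features in the interleaved layout
brute_pair_features <- function(row_a, row_b) {
  out <- numeric(2 * length(row_a))
  for (j in seq_along(row_a)) {
    out[2 * j - 1] <- row_a[j] + row_b[j]
    out[2 * j] <- abs(row_a[j] - row_b[j])
  }
  out
}

# small shared fixture: a CPI matrix with hand-set values
tiny_cpi <- function() {
  m <- matrix(c(-9, -7, -5,
                -8, -6, -4), nrow = 2, byrow = TRUE,
              dimnames = list(c("DA", "DB"), c("T1", "T2", "T3")))
  cpi_matrix(m)
}
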