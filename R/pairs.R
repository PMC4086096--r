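#' Canonicalize unordered drug pairs
#'
#' A drug pair is unordered; its canonical form sorts the two ids so that
#' deduplication and label lookup are order-independent. Self-pairs are
#' rejected: the absolute-difference features of a self-pair are identically
#' zero and such rows are degenerate for training.
#'
#' @param drug_a,drug_b character vectors of equal length.
#' @return data.frame with columns `drug_a`, `drug_b` where
#'   `drug_a < drug_b` elementwise.
#' @export
canonical_pairs <- function(drug_a, drug_b) {
  drug_a <- as.character(drug_a)
  drug_b <- as.character(drug_b)
  if (length(drug_a) != length(drug_b)) {
    ddi_stop("`drug_a` and `drug_b` must have equal length", "ddidock_validation_error")
  }
  if (any(drug_a == drug_b)) {
    ddi_stop("self-pairs (drug_a == drug_b) are not allowed", "ddidock_validation_error")
  }
  data.frame(drug_a = pmin(drug_a, drug_b), drug_b = pmax(drug_a, drug_b),
             stringsAsFactors = FALSE)
}

pair_key <- function(pairs) paste(pairs$drug_a, pairs$drug_b, sep = "\r")

#' Feature names for a target panel
#'
#' Features are interleaved per target: `S:<target_id>` (sum of the two
#' drugs' docking scores) then `AD:<target_id>` (absolute difference), giving
#' 2T features for T targets. This order is the machine-readable contract
#' that makes trained models portable across tools.
#'
#' @param targets character vector of target ids.
#' @return character vector of length `2 * length(targets)`.
#' @export
pair_feature_names <- function(targets) {
  as.vector(rbind(paste0("S:", targets), paste0("AD:", targets)))
}

#' Symmetric pair features from two docking-score vectors
#'
#' For each target j the pair is represented by the sum `S_j = a_j + b_j`
#' and the absolute difference `AD_j = |a_j - b_j|` of the two drugs'
#' docking scores — both invariant to the order of the drugs in the pair.
#'
#' @param row_a,row_b numeric score vectors over the same target panel
#'   (same length and, if named, same names), no missing entries.
#' @return named numeric vector of length `2 * length(row_a)`, interleaved
#'   `[S_1, AD_1, S_2, AD_2, ...]`.
#' @export
featurize_pair <- function(row_a, row_b) {
  if (length(row_a) != length(row_b)) {
    ddi_stop("score vectors come from different target panels (length mismatch)",
             "ddidock_panel_mismatch_error")
  }
  if (!is.null(names(row_a)) && !is.null(names(row_b)) &&
      !identical(names(row_a), names(row_b))) {
    ddi_stop("score vectors come from different target panels (target order mismatch)",
             "ddidock_panel_mismatch_error")
  }
  if (anyNA(row_a) || anyNA(row_b)) {
    ddi_stop("missing docking score in pair featurization", "ddidock_missing_data_error")
  }
  s <- row_a + row_b
  ad <- abs(row_a - row_b)
  out <- as.vector(rbind(s, ad))
  names(out) <- pair_feature_names(names(row_a) %||% seq_along(row_a))
  out
}

# linear index (1-based, pairs ordered (1,2),(1,3),...,(1,n),(2,3),...) <-> (i,j)
pair_index_decode <- function(k, n) {
  cum <- c(0, cumsum((n - 1L):1L))
  i <- findInterval(k - 0.5, cum)
  j <- i + (k - cum[i])
  cbind(i = i, j = as.integer(j))
}

pair_index_encode <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  cum <- c(0, cumsum((n - 1L):1L))
  cum[lo] + (hi - lo)
}

#' Sample negative (non-interacting) drug pairs
#'
#' Draws `n` distinct unordered pairs uniformly without replacement from all
#' C(|drugs|, 2) candidate pairs, excluding self-pairs and every pair in the
#' positive set. This mirrors the construction of a balanced training set
#' from known interacting pairs plus randomly generated non-pairs.
#'
#' @param positives data.frame with columns `drug_a`, `drug_b` (the known
#'   interacting pairs; order within a pair irrelevant).
#' @param drugs character vector of candidate drug ids.
#' @param n number of negatives to draw.
#' @param seed integer seed; a fixed seed gives an identical sample.
#' @return data.frame with columns `drug_a`, `drug_b`, `label` (all 0) and
#'   `provenance` (`"sampled_negative"`).
#' @export
sample_negatives <- function(positives, drugs, n, seed) {
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs)) {
    ddi_stop("duplicate drug ids in library", "ddidock_duplicate_id_error")
  }
  nd <- length(drugs)
  m <- nd * (nd - 1) / 2
  excl <- integer(0)
  if (nrow(positives) > 0L) {
    cp <- canonical_pairs(positives$drug_a, positives$drug_b)
    ia <- match(cp$drug_a, drugs)
    ib <- match(cp$drug_b, drugs)
    keep <- !is.na(ia) & !is.na(ib)   # positives outside the library cannot collide
    excl <- unique(pair_index_encode(ia[keep], ib[keep], nd))
  }
  capacity <- m - length(excl)
  if (n > capacity) {
    ddi_stop(sprintf("cannot sample %d negatives: only %d candidate pairs remain",
                     n, capacity), "ddidock_capacity_error")
  }
  set.seed(seed)
  if (m <= 5e6) {
    pool <- if (length(excl) > 0L) seq_len(m)[-excl] else seq_len(m)
    idx <- if (length(pool) == 1L) pool else sample(pool, n)
  } else {
    drawn <- integer(0)
    while (length(drawn) < n) {
      cand <- sample.int(m, min(m, 2L * (n - length(drawn)) + 100L))
      cand <- setdiff(cand, c(excl, drawn))
      drawn <- c(drawn, cand[seq_len(min(n - length(drawn), length(cand)))])
    }
    idx <- drawn
  }
  ij <- pair_index_decode(idx, nd)
  out <- data.frame(drug_a = drugs[ij[, "i"]], drug_b = drugs[ij[, "j"]],
                    stringsAsFactors = FALSE)
  # canonical form: ids sorted lexicographically within a pair
  out <- canonical_pairs(out$drug_a, out$drug_b)
  out$label <- 0L
  out$provenance <- "sampled_negative"
  out
}

#' Build a labeled pair set from positives and negatives
#'
#' @param positives data.frame with `drug_a`, `drug_b`.
#' @param negatives data.frame with `drug_a`, `drug_b` (e.g. from
#'   [sample_negatives()]).
#' @return data.frame with `drug_a`, `drug_b`, `label`, `provenance`;
#'   canonical pairs, no duplicates, no pair with both labels.
#' @export
labeled_pair_set <- function(positives, negatives) {
  pos <- canonical_pairs(positives$drug_a, positives$drug_b)
  neg <- canonical_pairs(negatives$drug_a, negatives$drug_b)
  if (anyDuplicated(pair_key(pos))) {
    ddi_stop("duplicate pairs in positive set", "ddidock_validation_error")
  }
  if (anyDuplicated(pair_key(neg))) {
    ddi_stop("duplicate pairs in negative set", "ddidock_validation_error")
  }
  if (length(intersect(pair_key(pos), pair_key(neg))) > 0L) {
    ddi_stop("a pair appears in both the positive and negative set",
             "ddidock_validation_error")
  }
  pos$label <- 1L; pos$provenance <- "positive_list"
  neg$label <- 0L; neg$provenance <- "sampled_negative"
  rbind(pos, neg)
}

#' Assemble the design matrix for a set of labeled pairs
#'
#' One feature row per pair, in the order given, with 2T columns (see
#' [pair_feature_names()]). Pairs touching any missing docking score are
#' dropped and reported: only pairs with complete CPI annotations enter
#' training.
#'
#' @param pairs data.frame with columns `drug_a`, `drug_b` and optionally
#'   `label`.
#' @param cpi a [cpi_matrix()].
#' @return list with `x` (numeric matrix, rownames `drug_a|drug_b`), `y`
#'   (labels for kept rows, or NULL), `kept` (logical over input rows) and
#'   `pairs` (the kept pair data.frame).
#' @export
assemble_design_matrix <- function(pairs, cpi) {
  stopifnot(inherits(cpi, "cpi_matrix"))
  ia <- match(pairs$drug_a, cpi$drugs)
  ib <- match(pairs$drug_b, cpi$drugs)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- c(pairs$drug_a[is.na(ia)], pairs$drug_b[is.na(ib)])[1L]
    ddi_stop(sprintf("pair references drug '%s' absent from the CPI matrix", bad),
             "ddidock_unknown_id_error")
  }
  a <- cpi$scores[ia, , drop = FALSE]
  b <- cpi$scores[ib, , drop = FALSE]
  kept <- !(rowSums(is.na(a)) > 0L | rowSums(is.na(b)) > 0L)
  a <- a[kept, , drop = FALSE]
  b <- b[kept, , drop = FALSE]
  s <- a + b
  ad <- abs(a - b)
  n_t <- ncol(cpi$scores)
  x <- matrix(0.0, nrow = sum(kept), ncol = 2L * n_t)
  if (n_t > 0L) {
    x[, seq(1L, 2L * n_t, by = 2L)] <- s
    x[, seq(2L, 2L * n_t, by = 2L)] <- ad
  }
  colnames(x) <- pair_feature_names(cpi$targets)
  rownames(x) <- paste(pairs$drug_a[kept], pairs$drug_b[kept], sep = "|")
  list(
    x = x,
    y = if ("label" %in% names(pairs)) as.integer(pairs$label[kept]) else NULL,
    kept = kept,
    pairs = pairs[kept, , drop = FALSE]
  )
}

#' Enumerate query-versus-library candidate pairs
#'
#' Pairs one query drug with every library drug (skipping the query itself if
#' it is in the library), in library order. These are the candidate pairs a
#' trained model scores to screen a new molecule against the drug library.
#'
#' @param query_id drug id of the query molecule.
#' @param library character vector of library drug ids.
#' @return data.frame with columns `drug_a` (query) and `drug_b` (library
#'   drug), one row per retained library drug.
#' @export
enumerate_query_pairs <- function(query_id, library) {
  assert_scalar_string(query_id, "query_id")
  library <- as.character(library)
  if (length(library) == 0L) {
    ddi_stop("library must be non-empty", "ddidock_validation_error")
  }
  keep <- library != query_id
  data.frame(drug_a = query_id, drug_b = library[keep], stringsAsFactors = FALSE)
}

#' Read a drug-pair list file
#'
#' Two tab-separated columns of drug ids, optional third column with a 0/1
#' label; `#` starts a comment line.
#'
#' @param path pair list file.
#' @return data.frame with `drug_a`, `drug_b` and, when present, `label`.
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) {
    ddi_stop(sprintf("pair list not found: %s", path), "ddidock_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    ddi_stop(sprintf("pair list line %d has fewer than two columns",
                     which(nf < 2L)[1L]), "ddidock_parse_error")
  }
  out <- data.frame(
    drug_a = vapply(fields, `[[`, "", 1L),
    drug_b = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  if (all(nf >= 3L)) {
    lab <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
      ddi_stop("pair list labels must be 0 or 1", "ddidock_parse_error")
    }
    out$label <- lab
  }
  out
}

#' Write a drug-pair list file
#'
#' @param pairs data.frame with `drug_a`, `drug_b` and optionally `label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pair_list <- function(pairs, path) {
  cols <- intersect(c("drug_a", "drug_b", "label"), names(pairs))
  utils::write.table(pairs[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
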