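#' Fingerprint set
#'
#' Binary molecular fingerprints for a set of drugs, stored as a 0/1 integer
#' matrix (drugs in rows, bits in columns) with drug ids as rownames. All
#' fingerprints in one set share the same bit length.
#'
#' @param bits 0/1 matrix with unique rownames (drug ids).
#' @return object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(bits) {
  if (!is.matrix(bits)) ddi_stop("`bits` must be a matrix", "ddidock_validation_error")
  if (is.null(rownames(bits)) || anyDuplicated(rownames(bits))) {
    ddi_stop("fingerprints need unique drug-id rownames", "ddidock_validation_error")
  }
  if (!all(bits %in% c(0L, 1L))) {
    ddi_stop("fingerprint bits must be 0/1", "ddidock_validation_error")
  }
  storage.mode(bits) <- "integer"
  structure(list(bits = bits, drug_ids = rownames(bits), n_bits = ncol(bits)),
            class = "fingerprint_set")
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' The standard 2D chemical-similarity measure: the number of bits set in
#' both fingerprints divided by the number set in either. Two all-zero
#' fingerprints have similarity 0 by convention.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return fraction in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    ddi_stop("fingerprints have different bit lengths", "ddidock_validation_error")
  }
  a <- as.logical(a); b <- as.logical(b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  sum(a & b) / uni
}

#' All pairwise Tanimoto coefficients
#'
#' @param fps a [fingerprint_set()].
#' @return symmetric numeric matrix (diagonal 1 for non-empty fingerprints,
#'   0 for all-zero ones).
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  b <- fps$bits
  inter <- tcrossprod(b)
  popcount <- rowSums(b)
  uni <- outer(popcount, popcount, "+") - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  dimnames(tc) <- list(fps$drug_ids, fps$drug_ids)
  tc
}

#' Remove structurally redundant molecules
#'
#' Drops every molecule whose Tanimoto coefficient to ANY other molecule in
#' the set exceeds `cutoff` — both members of an over-threshold pair are
#' removed, so the kept set contains no pair above the cutoff. Used to test
#' whether model performance is driven by near-duplicate structures in the
#' training pairs.
#'
#' @param fps a [fingerprint_set()].
#' @param cutoff similarity cutoff (default 0.75).
#' @return character vector of kept drug ids, in input order.
#' @export
redundancy_filter <- function(fps, cutoff = 0.75) {
  stopifnot(inherits(fps, "fingerprint_set"))
  if (nrow(fps$bits) == 0L) {
    ddi_stop("need at least one fingerprint", "ddidock_validation_error")
  }
  tc <- tanimoto_matrix(fps)
  diag(tc) <- 0
  keep <- apply(tc, 1L, max) <= cutoff
  fps$drug_ids[keep]
}

#' Restrict a pair list to non-redundant drugs
#'
#' Applies [redundancy_filter()] and drops every pair touching a removed
#' drug, yielding a reduced training set for re-evaluation.
#'
#' @param pairs data.frame with `drug_a`, `drug_b` (and optionally `label`).
#' @param fps a [fingerprint_set()] covering the pair drugs.
#' @param cutoff similarity cutoff.
#' @return the filtered pair data.frame.
#' @export
filter_pairs_by_similarity <- function(pairs, fps, cutoff = 0.75) {
  kept <- redundancy_filter(fps, cutoff)
  pairs[pairs$drug_a %in% kept & pairs$drug_b %in% kept, , drop = FALSE]
}

bits_to_hex <- function(bits) {
  n <- length(bits)
  pad <- (4L - n %% 4L) %% 4L
  bits <- c(bits, rep(0L, pad))
  nib <- matrix(bits, nrow = 4L)
  vals <- as.integer(8 * nib[1L, ] + 4 * nib[2L, ] + 2 * nib[3L, ] + nib[4L, ])
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  chars <- strsplit(tolower(hex), "")[[1L]]
  vals <- match(chars, c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                         "a", "b", "c", "d", "e", "f")) - 1L
  if (anyNA(vals)) ddi_stop("invalid hex fingerprint", "ddidock_parse_error")
  bits <- as.integer(rbind(vals %/% 8L %% 2L, vals %/% 4L %% 2L,
                           vals %/% 2L %% 2L, vals %% 2L))
  if (length(bits) < n_bits) {
    ddi_stop("fingerprint shorter than declared bit length", "ddidock_parse_error")
  }
  bits[seq_len(n_bits)]
}

#' Read / write fingerprint files
#'
#' Tab-separated `drug_id <TAB> hex-bitstring` rows preceded by a header
#' line `#bits=<L>` declaring the common bit length.
#'
#' @param path fingerprint file.
#' @return `read_fingerprints` returns a [fingerprint_set()].
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) {
    ddi_stop(sprintf("fingerprint file not found: %s", path), "ddidock_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !grepl("^#bits=[0-9]+$", lines[[1L]])) {
    ddi_stop("fingerprint file must start with a '#bits=<L>' header",
             "ddidock_parse_error")
  }
  n_bits <- as.integer(sub("^#bits=", "", lines[[1L]]))
  body <- lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  bits <- t(vapply(fields, function(f) hex_to_bits(f[[2L]], n_bits),
                   integer(n_bits)))
  rownames(bits) <- ids
  fingerprint_set(bits)
}

#' @rdname read_fingerprints
#' @param fps a [fingerprint_set()].
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(inherits(fps, "fingerprint_set"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#bits=%d", fps$n_bits), con)
  for (i in seq_len(nrow(fps$bits))) {
    writeLines(paste(fps$drug_ids[[i]], bits_to_hex(fps$bits[i, ]), sep = "\t"), con)
  }
  invisible(path)
}
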