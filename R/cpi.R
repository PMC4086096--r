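#' Chemical-protein interactome (CPI) matrix
#'
#' A CPI matrix holds docking scores (kcal/mol, more negative = stronger
#' predicted binding) for a library of drug molecules (rows) against a fixed
#' panel of protein structures (columns). It is the central data object of the
#' package: pair features, model training and per-target rank readouts all
#' operate on it. Missing cells (e.g. failed docking runs) are `NA` and are
#' never silently replaced by a sentinel score.
#'
#' @param scores numeric matrix of docking scores, drugs in rows and targets
#'   in columns, with unique non-empty `rownames` (drug ids) and `colnames`
#'   (target ids). `NA` marks a missing score; non-missing values must be
#'   finite.
#' @param target_class optional character vector, one entry per target, each
#'   `"PK"`, `"PD"` or `"unknown"` (pharmacokinetic vs pharmacodynamic
#'   protein). Recycled to `"unknown"` when absent.
#'
#' @return An object of class `cpi_matrix`: a list with elements `scores`
#'   (the numeric matrix), `drugs`, `targets` and `target_class`.
#' @examples
#' m <- matrix(c(-7.1, -6.2, -8.4, -5.9), nrow = 2,
#'             dimnames = list(c("D1", "D2"), c("1abc", "2xyz")))
#' cpi <- cpi_matrix(m)
#' dim(cpi)
#' @export
cpi_matrix <- function(scores, target_class = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    ddi_stop("`scores` must be a numeric matrix", "ddidock_validation_error")
  }
  drugs <- rownames(scores)
  targets <- colnames(scores)
  if (is.null(drugs) && nrow(scores) > 0L) {
    ddi_stop("`scores` must have rownames (drug ids)", "ddidock_validation_error")
  }
  if (is.null(targets) && ncol(scores) > 0L) {
    ddi_stop("`scores` must have colnames (target ids)", "ddidock_validation_error")
  }
  drugs <- as.character(drugs %||% character(0))
  targets <- as.character(targets %||% character(0))
  if (anyDuplicated(drugs)) {
    ddi_stop(sprintf("duplicate drug id(s): %s",
                     paste(unique(drugs[duplicated(drugs)]), collapse = ", ")),
             "ddidock_duplicate_id_error")
  }
  if (anyDuplicated(targets)) {
    ddi_stop(sprintf("duplicate target id(s): %s",
                     paste(unique(targets[duplicated(targets)]), collapse = ", ")),
             "ddidock_duplicate_id_error")
  }
  if (any(!nzchar(drugs)) || any(!nzchar(targets))) {
    ddi_stop("drug and target ids must be non-empty", "ddidock_validation_error")
  }
  if (any(is.infinite(scores))) {
    ddi_stop("non-missing docking scores must be finite", "ddidock_validation_error")
  }
  if (is.null(target_class)) {
    target_class <- rep("unknown", length(targets))
  }
  target_class <- as.character(target_class)
  if (length(target_class) != length(targets)) {
    ddi_stop("`target_class` must have one entry per target", "ddidock_validation_error")
  }
  if (!all(target_class %in% c("PK", "PD", "unknown"))) {
    ddi_stop("`target_class` entries must be 'PK', 'PD' or 'unknown'",
             "ddidock_validation_error")
  }
  storage.mode(scores) <- "double"
  structure(
    list(scores = scores, drugs = drugs, targets = targets,
         target_class = stats::setNames(target_class, targets)),
    class = "cpi_matrix"
  )
}

#' @export
dim.cpi_matrix <- function(x) dim(x$scores)

#' @export
print.cpi_matrix <- function(x, ...) {
  cat(sprintf("<cpi_matrix> %d drugs x %d targets (%d missing cells)\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  cls <- table(factor(x$target_class, levels = c("PK", "PD", "unknown")))
  cat(sprintf("  targets: %d PK, %d PD, %d unknown\n", cls[["PK"]], cls[["PD"]],
              cls[["unknown"]]))
  invisible(x)
}

#' Read a CPI matrix from a delimited text file
#'
#' Expected layout: a header row of target ids, then one row per drug whose
#' first field is the drug id. Missing scores are empty cells or `NA`.
#'
#' @param path file to read.
#' @param sep field delimiter; `"\t"` (default) or `","`.
#' @param target_class optional named character vector mapping target ids to
#'   `"PK"`/`"PD"`, e.g. from [read_target_panel()].
#' @return A [cpi_matrix()].
#' @seealso [write_cpi()] for the inverse operation.
#' @export
read_cpi <- function(path, sep = "\t", target_class = NULL) {
  if (!file.exists(path)) {
    ddi_stop(sprintf("CPI file not found: %s", path), "ddidock_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    ddi_stop(sprintf("CPI file is empty: %s", path), "ddidock_parse_error")
  }
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  if (length(header) < 1L) {
    ddi_stop("malformed CPI header", "ddidock_parse_error")
  }
  targets <- header[-1L]
  n_t <- length(targets)
  body <- lines[-1L]
  drugs <- character(length(body))
  scores <- matrix(NA_real_, nrow = length(body), ncol = n_t)
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], sep, fixed = TRUE)[[1L]]
    # trailing empty cells are dropped by strsplit; pad them back as missing
    if (length(fields) < n_t + 1L) fields <- c(fields, rep("", n_t + 1L - length(fields)))
    if (length(fields) != n_t + 1L) {
      ddi_stop(sprintf("row %d ('%s') has %d data cells, expected %d",
                       i, fields[[1L]], length(fields) - 1L, n_t),
               "ddidock_parse_error")
    }
    drugs[[i]] <- fields[[1L]]
    cells <- fields[-1L]
    miss <- cells == "" | cells == "NA"
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !miss)
    if (length(bad) > 0L) {
      ddi_stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                       fields[[1L]], targets[[bad[[1L]]]], cells[[bad[[1L]]]]),
               "ddidock_parse_error")
    }
    scores[i, ] <- vals
  }
  rownames(scores) <- drugs
  colnames(scores) <- targets
  tc <- NULL
  if (!is.null(target_class)) {
    tc <- unname(target_class[targets])
    tc[is.na(tc)] <- "unknown"
  }
  cpi_matrix(scores, target_class = tc)
}

#' Write a CPI matrix to a delimited text file
#'
#' Emits the same layout [read_cpi()] accepts; scores are written at full
#' double precision so that a read/write round trip is exact. Missing cells
#' are written as `NA`.
#'
#' @param cpi a [cpi_matrix()].
#' @param path output file.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_cpi <- function(cpi, path, sep = "\t") {
  stopifnot(inherits(cpi, "cpi_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("drug_id", cpi$targets), collapse = sep), con)
  for (i in seq_along(cpi$drugs)) {
    writeLines(paste(c(cpi$drugs[[i]], fmt_num(cpi$scores[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' Read a target panel file
#'
#' A two-column tab-separated file of `target_id` and class (`PK` or `PD`).
#' The row order of the panel fixes the target (column) order of any CPI
#' matrix assembled against it, which in turn fixes feature indices.
#'
#' @param path panel file.
#' @return data.frame with columns `target_id` and `target_class`.
#' @export
read_target_panel <- function(path) {
  if (!file.exists(path)) {
    ddi_stop(sprintf("panel file not found: %s", path), "ddidock_io_error")
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("target_id", "target_class"),
                          colClasses = "character")
  if (anyDuplicated(df$target_id)) {
    ddi_stop("duplicate target id in panel", "ddidock_duplicate_id_error")
  }
  bad <- !df$target_class %in% c("PK", "PD")
  if (any(bad)) {
    ddi_stop(sprintf("invalid target class '%s' for target '%s'",
                     df$target_class[bad][1L], df$target_id[bad][1L]),
             "ddidock_parse_error")
  }
  df
}

#' Parse an AutoDock-Vina docking result file
#'
#' Two artifact dialects are recognized: (a) the Vina stdout log, whose
#' mode/affinity table rows look like `"   1   -7.5   0.000   0.000"`, and
#' (b) PDBQT-style output structures with one `REMARK VINA RESULT: <score> ...`
#' line per docked model. In either case the representative docking score is
#' the minimum (best) affinity over all reported modes.
#'
#' @param path result file.
#' @param ligand_id,target_id identifiers to attach to the result.
#' @return A `docking_result`: list with `ligand_id`, `target_id`,
#'   `best_score` (kcal/mol) and `n_poses`.
#' @export
parse_vina_result <- function(path, ligand_id, target_id) {
  assert_scalar_string(ligand_id, "ligand_id")
  assert_scalar_string(target_id, "target_id")
  if (!file.exists(path)) {
    ddi_stop(sprintf("docking result file not found: %s", path), "ddidock_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  # dialect (b): per-model result remarks
  remark <- grep("^REMARK VINA RESULT:", lines, value = TRUE)
  if (length(remark) > 0L) {
    scores <- suppressWarnings(as.numeric(
      vapply(strsplit(sub("^REMARK VINA RESULT:\\s*", "", remark), "\\s+"),
             `[[`, "", 1L)))
  } else {
    # dialect (a): stdout table rows "mode  affinity  rmsd_lb  rmsd_ub"
    tab <- grep("^\\s*[0-9]+\\s+-?[0-9.]+\\s+[0-9.]+\\s+[0-9.]+\\s*$", lines,
                value = TRUE)
    scores <- suppressWarnings(as.numeric(
      vapply(strsplit(trimws(tab), "\\s+"), function(f) f[[2L]], "")))
  }
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) {
    ddi_stop(sprintf("no affinity values found in '%s'; the docking run may have failed or the wrong file was supplied",
                     path), "ddidock_parse_error")
  }
  structure(
    list(ligand_id = ligand_id, target_id = target_id,
         best_score = min(scores), n_poses = length(scores)),
    class = "docking_result"
  )
}

#' Assemble a CPI matrix from docking results
#'
#' Fills cell (drug, target) with the best (minimum) docking score of the
#' matching result. Cells with no result stay missing. When several results
#' hit the same cell the minimum is kept and a warning is issued.
#'
#' @param results list of `docking_result` objects (see [parse_vina_result()])
#'   or a data.frame with columns `ligand_id`, `target_id`, `best_score`.
#' @param drugs character vector of drug ids defining the row order.
#' @param targets character vector of target ids defining the column order.
#' @param target_class optional per-target class vector, as in [cpi_matrix()].
#' @return A [cpi_matrix()].
#' @export
assemble_cpi <- function(results, drugs, targets, target_class = NULL) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    df <- data.frame(
      ligand_id = vapply(results, `[[`, "", "ligand_id"),
      target_id = vapply(results, `[[`, "", "target_id"),
      best_score = vapply(results, `[[`, 0.0, "best_score"),
      stringsAsFactors = FALSE
    )
  }
  ri <- match(df$ligand_id, drugs)
  ci <- match(df$target_id, targets)
  if (anyNA(ri)) {
    ddi_stop(sprintf("result references undeclared drug '%s'",
                     df$ligand_id[which(is.na(ri))[1L]]),
             "ddidock_unknown_id_error")
  }
  if (anyNA(ci)) {
    ddi_stop(sprintf("result references undeclared target '%s'",
                     df$target_id[which(is.na(ci))[1L]]),
             "ddidock_unknown_id_error")
  }
  cell <- (ci - 1L) * length(drugs) + ri
  if (anyDuplicated(cell)) {
    dup <- unique(cell[duplicated(cell)])
    warning(sprintf("%d cell(s) had multiple docking results; keeping the minimum score",
                    length(dup)), call. = FALSE)
  }
  scores <- matrix(NA_real_, nrow = length(drugs), ncol = length(targets),
                   dimnames = list(drugs, targets))
  # minimum rule for duplicates: process in decreasing score order so the
  # smallest (best) score is written last
  ord <- order(df$best_score, decreasing = TRUE)
  scores[cell[ord]] <- df$best_score[ord]
  cpi_matrix(scores, target_class = target_class)
}

#' Per-target rank percentile within a drug's score vector
#'
#' Ranks one target among all targets a drug has scores for: rank 1 is the
#' most negative (strongest predicted binding) score, ties share the mean
#' rank, and the returned percentile is rank/N over the drug's N non-missing
#' targets. A value of 0.20 or less means the target is in the top 20% of the
#' drug's predicted binding partners — the readout used to propose the
#' protein mediating a predicted interaction.
#'
#' @param cpi a [cpi_matrix()].
#' @param drug_id,target_id the cell to rank.
#' @return A fraction in (0, 1].
#' @export
rank_percentile <- function(cpi, drug_id, target_id) {
  stopifnot(inherits(cpi, "cpi_matrix"))
  ri <- match(drug_id, cpi$drugs)
  ci <- match(target_id, cpi$targets)
  if (is.na(ri)) ddi_stop(sprintf("unknown drug id '%s'", drug_id), "ddidock_unknown_id_error")
  if (is.na(ci)) ddi_stop(sprintf("unknown target id '%s'", target_id), "ddidock_unknown_id_error")
  row <- cpi$scores[ri, ]
  if (is.na(row[[ci]])) {
    ddi_stop(sprintf("drug '%s' has no docking score for target '%s'",
                     drug_id, target_id), "ddidock_missing_data_error")
  }
  ok <- !is.na(row)
  r <- rank(row[ok], ties.method = "average")
  unname(r[[target_id]] / sum(ok))
}

#' Per-target rank percentiles for a drug pair
#'
#' Mechanistic readout for a predicted interaction: for each target, the rank
#' percentile of that target in each drug's score vector (see
#' [rank_percentile()]), and whether both drugs rank it within `top_frac`.
#' Targets both drugs bind strongly are candidate mediators of the
#' interaction.
#'
#' @param cpi a [cpi_matrix()].
#' @param drug_a,drug_b drug ids present in `cpi`.
#' @param top_frac flagging cutoff (default 0.20, i.e. "top 20%").
#' @return data.frame with columns `target_id`, `target_class`,
#'   `percentile_a`, `percentile_b`, `shared_top` (logical), ordered by the
#'   worse of the two percentiles.
#' @export
explain_pair <- function(cpi, drug_a, drug_b, top_frac = 0.20) {
  stopifnot(inherits(cpi, "cpi_matrix"))
  pa <- vapply(cpi$targets, function(t) {
    if (is.na(cpi$scores[drug_a, t])) NA_real_ else rank_percentile(cpi, drug_a, t)
  }, 0.0)
  pb <- vapply(cpi$targets, function(t) {
    if (is.na(cpi$scores[drug_b, t])) NA_real_ else rank_percentile(cpi, drug_b, t)
  }, 0.0)
  out <- data.frame(
    target_id = cpi$targets,
    target_class = unname(cpi$target_class),
    percentile_a = unname(pa),
    percentile_b = unname(pb),
    shared_top = !is.na(pa) & !is.na(pb) & pa <= top_frac & pb <= top_frac,
    stringsAsFactors = FALSE
  )
  out[order(pmax(out$percentile_a, out$percentile_b)), , drop = FALSE]
}
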