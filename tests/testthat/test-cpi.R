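test_that("read_cpi parses a small TSV and validates identifiers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tT1\tT2",
               "D1\t-7.1\t-6.2",
               "D2\t-8.4\t-5.9",
               "D3\t-6.6\tNA"), path)
  cpi <- read_cpi(path)
  expect_identical(dim(cpi), c(3L, 2L))
  expect_identical(cpi$drugs, c("D1", "D2", "D3"))
  expect_identical(cpi$targets, c("T1", "T2"))
  expect_true(is.na(cpi$scores["D3", "T2"]))
  expect_identical(cpi$scores["D2", "T1"], -8.4)

  writeLines(c("drug_id\tT1", "D1\t-7", "D1\t-6"), path)
  expect_error(read_cpi(path), class = "ddidock_duplicate_id_error")

  writeLines(c("drug_id\tT1", "D1\tbogus"), path)
  expect_error(read_cpi(path), regexp = "row 'D1', column 'T1'",
               class = "ddidock_parse_error")
})

test_that("write_cpi/read_cpi round trip is exact, including missing cells", {
  set.seed(42)
  scores <- matrix(rnorm(200, -7, 1.5), nrow = 10,
                   dimnames = list(sprintf("D%02d", 1:10), sprintf("T%02d", 1:20)))
  scores[sample(200, 15)] <- NA
  cpi <- cpi_matrix(scores)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cpi(cpi, path)
  back <- read_cpi(path)
  expect_identical(back$scores, cpi$scores)
  expect_identical(back$drugs, cpi$drugs)
  expect_identical(back$targets, cpi$targets)

  # empty drug list -> header-only file that still round-trips
  empty <- cpi_matrix(matrix(numeric(0), nrow = 0, ncol = 2,
                             dimnames = list(NULL, c("T1", "T2"))))
  write_cpi(empty, path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(dim(read_cpi(path)), c(0L, 2L))
})

test_that("parse_vina_result takes the minimum over modes in both dialects", {
  log <- withr::local_tempfile(fileext = ".log")
  gen_vina_log(log, "L1", "T1", c(-7.5, -7.1, -6.9), dialect = "log")
  r <- parse_vina_result(log, "L1", "T1")
  expect_equal(r$best_score, -7.5)
  expect_identical(r$n_poses, 3L)

  pdbqt <- withr::local_tempfile(fileext = ".pdbqt")
  gen_vina_log(pdbqt, "L1", "T1", c(-8.2, -8.0), dialect = "pdbqt")
  r2 <- parse_vina_result(pdbqt, "L1", "T1")
  expect_equal(r2$best_score, -8.2)
  expect_identical(r2$n_poses, 2L)

  # best_score equals a brute-force scan of every affinity in the file,
  # whatever order the modes are listed in
  shuffled <- withr::local_tempfile(fileext = ".log")
  scores <- round(rnorm(9, -7, 1), 2)
  gen_vina_log(shuffled, "L1", "T1", scores, dialect = "log")
  expect_equal(parse_vina_result(shuffled, "L1", "T1")$best_score, min(scores))
  expect_identical(parse_vina_result(shuffled, "L1", "T1")$n_poses, 9L)

  empty <- withr::local_tempfile(fileext = ".log")
  writeLines(character(0), empty)
  expect_error(parse_vina_result(empty, "L1", "T1"),
               class = "ddidock_parse_error")
})

test_that("assemble_cpi fills cells, flags gaps and keeps minima on duplicates", {
  res <- list(
    list(ligand_id = "D1", target_id = "T1", best_score = -7.0),
    list(ligand_id = "D1", target_id = "T2", best_score = -6.0),
    list(ligand_id = "D2", target_id = "T1", best_score = -8.0)
  )
  cpi <- assemble_cpi(res, c("D1", "D2"), c("T1", "T2"))
  expect_identical(cpi$scores["D1", "T1"], -7.0)
  expect_true(is.na(cpi$scores["D2", "T2"]))

  dup <- c(res, list(list(ligand_id = "D1", target_id = "T1", best_score = -6.4)))
  expect_warning(cpi2 <- assemble_cpi(dup, c("D1", "D2"), c("T1", "T2")),
                 "minimum")
  expect_identical(cpi2$scores["D1", "T1"], -7.0)
  dup2 <- list(list(ligand_id = "D1", target_id = "T1", best_score = -6.0),
               list(ligand_id = "D1", target_id = "T1", best_score = -6.4))
  expect_warning(cpi3 <- assemble_cpi(dup2, "D1", "T1"))
  expect_identical(cpi3$scores["D1", "T1"], -6.4)

  expect_error(assemble_cpi(res, c("D1"), c("T1", "T2")),
               class = "ddidock_unknown_id_error")

  # row extraction reproduces each best_score exactly
  for (r in res) {
    expect_identical(cpi$scores[r$ligand_id, r$target_id], r$best_score)
  }
})

test_that("rank_percentile ranks strongest binding first with mean-rank ties", {
  m <- matrix(c(-9, -7, -5), nrow = 1, dimnames = list("D1", c("T1", "T2", "T3")))
  cpi <- cpi_matrix(m)
  expect_equal(rank_percentile(cpi, "D1", "T1"), 1 / 3)
  expect_equal(rank_percentile(cpi, "D1", "T3"), 1.0)

  # two tied minima over 10 targets share percentile (1+2)/2/10 = 0.15
  row <- c(-9, -9, -8, -7, -6, -5, -4, -3, -2, -1)
  m10 <- matrix(row, nrow = 1,
                dimnames = list("D1", sprintf("T%02d", 1:10)))
  cpi10 <- cpi_matrix(m10)
  expect_equal(rank_percentile(cpi10, "D1", "T01"), 0.15)
  expect_equal(rank_percentile(cpi10, "D1", "T02"), 0.15)

  # missing cells are excluded from N and error when queried
  mna <- matrix(c(-9, NA, -5), nrow = 1, dimnames = list("D1", c("T1", "T2", "T3")))
  cna <- cpi_matrix(mna)
  expect_equal(rank_percentile(cna, "D1", "T3"), 1.0)
  expect_error(rank_percentile(cna, "D1", "T2"),
               class = "ddidock_missing_data_error")
})

test_that("rank_percentile is monotone and enumerates k/N on distinct rows", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    row <- rnorm(n, -7, 2)
    m <- matrix(row, nrow = 1, dimnames = list("D", sprintf("T%03d", seq_len(n))))
    cpi <- cpi_matrix(m)
    pct <- vapply(cpi$targets, function(t) rank_percentile(cpi, "D", t), 0)
    # more negative score -> smaller (or equal) percentile
    ord <- order(row)
    expect_true(all(diff(pct[ord]) >= 0))
    # distinct scores enumerate {1/N, ..., 1}
    expect_equal(sort(unname(pct)), seq_len(n) / n)
  }
})

test_that("explain_pair flags targets both drugs rank in the top fraction", {
  set.seed(11)
  cpi <- gen_cpi(6, 10, seed = 11)
  # make T0001 the strongest target for both drugs
  cpi$scores["D0001", "T0001"] <- -15
  cpi$scores["D0002", "T0001"] <- -15
  ex <- explain_pair(cpi, "D0001", "D0002", top_frac = 0.20)
  expect_true(ex$shared_top[ex$target_id == "T0001"])
  expect_identical(ex$target_id[[1]], "T0001")
  expect_true(all(ex$percentile_a > 0 & ex$percentile_a <= 1))
})
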