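test_that("featurize_pair matches hand arithmetic and is symmetric", {
  f <- featurize_pair(c(T1 = -7.0, T2 = -5.0), c(T1 = -7.0, T2 = -5.0))
  expect_equal(unname(f), c(-14.0, 0.0, -10.0, 0.0))

  f1 <- featurize_pair(c(T1 = -8.0), c(T1 = -6.5))
  expect_equal(unname(f1), c(-14.5, 1.5))
  expect_identical(f1, featurize_pair(c(T1 = -6.5), c(T1 = -8.0)))
  expect_identical(names(f1), c("S:T1", "AD:T1"))

  expect_error(featurize_pair(c(T1 = -7), c(T1 = -7, T2 = -6)),
               class = "ddidock_panel_mismatch_error")
  expect_error(featurize_pair(c(T1 = NA_real_), c(T1 = -6)),
               class = "ddidock_missing_data_error")
})

test_that("featurize_pair agrees with a brute-force loop on random vectors", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    a <- rnorm(n, -7, 2); b <- rnorm(n, -7, 2)
    names(a) <- names(b) <- sprintf("T%03d", seq_len(n))
    f <- featurize_pair(a, b)
    expect_equal(unname(f), brute_pair_features(a, b))
    expect_identical(f, featurize_pair(b, a))
    expect_true(all(f[seq(2, 2 * n, by = 2)] >= 0))
  }
})

test_that("a 611-target panel yields 1222 pair features", {
  targets <- sprintf("T%04d", 1:611)
  expect_length(pair_feature_names(targets), 1222L)
  a <- rnorm(611, -7); names(a) <- targets
  expect_length(featurize_pair(a, rev(a)[targets]), 1222L)
})

test_that("sample_negatives is exclusion-correct, uniform-ish and seeded", {
  pos <- data.frame(drug_a = "A", drug_b = "B")
  forced <- sample_negatives(pos, c("A", "B", "C"), 2, seed = 1)
  expect_setequal(paste(forced$drug_a, forced$drug_b), c("A C", "B C"))

  expect_error(sample_negatives(pos, c("A", "B", "C"), 3, seed = 1),
               class = "ddidock_capacity_error")

  drugs <- sprintf("D%03d", 1:100)
  set.seed(99)
  pos100 <- data.frame(drug_a = sample(drugs, 200, TRUE),
                       drug_b = sample(drugs, 200, TRUE))
  pos100 <- unique(canonical_pairs(pos100$drug_a[pos100$drug_a != pos100$drug_b],
                                   pos100$drug_b[pos100$drug_a != pos100$drug_b]))
  pos_keys <- paste(pos100$drug_a, pos100$drug_b)
  for (seed in 1:50) {
    neg <- sample_negatives(pos100, drugs, 300, seed = seed)
    keys <- paste(neg$drug_a, neg$drug_b)
    expect_length(unique(keys), 300L)
    expect_length(intersect(keys, pos_keys), 0L)
    expect_true(all(neg$drug_a < neg$drug_b))
  }
  expect_identical(sample_negatives(pos100, drugs, 300, seed = 7),
                   sample_negatives(pos100, drugs, 300, seed = 7))
})

test_that("labeled_pair_set rejects duplicates and label conflicts", {
  pos <- data.frame(drug_a = c("A", "C"), drug_b = c("B", "D"))
  neg <- data.frame(drug_a = "A", drug_b = "C")
  ps <- labeled_pair_set(pos, neg)
  expect_identical(ps$label, c(1L, 1L, 0L))
  conflict <- data.frame(drug_a = "B", drug_b = "A")   # == positive (A,B)
  expect_error(labeled_pair_set(pos, conflict), class = "ddidock_validation_error")
  expect_error(labeled_pair_set(rbind(pos, pos), neg),
               class = "ddidock_validation_error")
})

test_that("assemble_design_matrix reproduces brute-force rows and drops incomplete pairs", {
  cpi <- tiny_cpi()
  pairs <- data.frame(drug_a = "DA", drug_b = "DB", label = 1L)
  dm <- assemble_design_matrix(pairs, cpi)
  expect_identical(dim(dm$x), c(1L, 6L))
  expect_equal(unname(dm$x[1, ]),
               brute_pair_features(cpi$scores["DA", ], cpi$scores["DB", ]))
  expect_identical(colnames(dm$x), pair_feature_names(c("T1", "T2", "T3")))

  # random pairs against a larger CPI agree with brute force per row
  big <- gen_cpi(20, 7, seed = 5)
  rp <- sample_negatives(data.frame(drug_a = character(0),
                                    drug_b = character(0)),
                         big$drugs, 10, seed = 6)[, c("drug_a", "drug_b")]
  dmb <- assemble_design_matrix(rp, big)
  for (i in seq_len(nrow(dmb$x))) {
    expect_equal(unname(dmb$x[i, ]),
                 brute_pair_features(big$scores[rp$drug_a[i], ],
                                     big$scores[rp$drug_b[i], ]))
  }

  # a missing score anywhere in either row drops the pair, with a report
  miss <- big
  miss$scores["D0001", "T0003"] <- NA
  rp2 <- data.frame(drug_a = c("D0001", "D0002"), drug_b = c("D0005", "D0006"),
                    label = c(1L, 0L))
  dm2 <- assemble_design_matrix(rp2, miss)
  expect_identical(unname(dm2$kept), c(FALSE, TRUE))
  expect_identical(nrow(dm2$x), 1L)
  expect_identical(dm2$y, 0L)

  expect_error(assemble_design_matrix(
    data.frame(drug_a = "nope", drug_b = "D0001"), big),
    class = "ddidock_unknown_id_error")
})

test_that("enumerate_query_pairs covers the library once, in order", {
  lib <- sprintf("L%04d", 1:2515)
  qp <- enumerate_query_pairs("QUERY", lib)
  expect_identical(nrow(qp), 2515L)
  expect_identical(qp$drug_b, lib)

  qp2 <- enumerate_query_pairs("A", c("A", "B"))
  expect_identical(nrow(qp2), 1L)
  expect_identical(qp2$drug_b, "B")
})

test_that("pair list files round trip with and without labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  pairs <- data.frame(drug_a = c("A", "B"), drug_b = c("B", "C"),
                      label = c(1L, 0L))
  write_pair_list(pairs, path)
  expect_identical(read_pair_list(path), pairs)

  writeLines(c("# comment", "A\tB", "", "C\tD"), path)
  got <- read_pair_list(path)
  expect_identical(got$drug_a, c("A", "C"))
  expect_null(got$label)
})
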