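test_that("expression reader partitions genes and aligns purity", {
  d <- withr::local_tempdir()
  writeLines(c("gene_id\tS1\tS2\tS3\tS4",
               "G1\t1\t2\t3\t4",
               "G2\t0.5\t0.5\t0.5\t1",
               "L1\t2\t2\t1\t1"),
             file.path(d, "expr.tsv"))
  writeLines(c("gene_id\ttype", "G1\tmRNA", "G2\tmRNA", "L1\tlncRNA"),
             file.path(d, "ann.tsv"))
  writeLines(c("sample_id\tpurity", "S1\t0.5", "S2\t0.6", "S3\t0.7", "S4\t0.8"),
             file.path(d, "pur.tsv"))
  b <- read_expression(file.path(d, "expr.tsv"), file.path(d, "ann.tsv"),
                       file.path(d, "pur.tsv"))
  expect_identical(dim(b$lnc_expr), c(1L, 4L))
  expect_identical(dim(b$mrna_expr), c(2L, 4L))
  expect_identical(b$sample_ids, paste0("S", 1:4))
  expect_equal(unname(b$purity), c(0.5, 0.6, 0.7, 0.8))

  # unannotated genes dropped with a message
  writeLines(c("gene_id\ttype", "G1\tmRNA", "L1\tlncRNA"),
             file.path(d, "ann2.tsv"))
  expect_message(
    b2 <- read_expression(file.path(d, "expr.tsv"), file.path(d, "ann2.tsv"),
                          file.path(d, "pur.tsv")),
    "dropped 1")
  expect_identical(rownames(b2$mrna_expr), "G1")
})

test_that("expression reader rejects malformed inputs by name", {
  d <- withr::local_tempdir()
  writeLines(c("gene_id\tS1\tS2\tS3\tS4",
               "G1\t1\t2\t3\t4", "G1\t1\t1\t1\t1", "L1\t2\t2\t1\t1"),
             file.path(d, "dup.tsv"))
  writeLines(c("gene_id\ttype", "G1\tmRNA", "L1\tlncRNA"), file.path(d, "ann.tsv"))
  writeLines(c("sample_id\tpurity", "S1\t0.5", "S2\t0.6", "S3\t0.7", "S4\t0.8"),
             file.path(d, "pur.tsv"))
  expect_error(read_expression(file.path(d, "dup.tsv"), file.path(d, "ann.tsv"),
                               file.path(d, "pur.tsv")), "G1")

  # purity file missing a sample
  writeLines(c("gene_id\tS1\tS2\tS3\tS4", "G1\t1\t2\t3\t4", "L1\t2\t2\t1\t1"),
             file.path(d, "expr.tsv"))
  writeLines(c("sample_id\tpurity", "S1\t0.5", "S2\t0.6", "S3\t0.7"),
             file.path(d, "pur3.tsv"))
  expect_error(read_expression(file.path(d, "expr.tsv"), file.path(d, "ann.tsv"),
                               file.path(d, "pur3.tsv")), "S4")

  # transposed matrix (gene ids in the header) is rejected, not fixed
  writeLines(c("sample\tG1\tL1", "S1\t1\t2", "S2\t2\t2", "S3\t3\t1", "S4\t4\t1"),
             file.path(d, "t.tsv"))
  expect_error(read_expression(file.path(d, "t.tsv"), file.path(d, "ann.tsv"),
                               file.path(d, "pur.tsv")), "transposed")
})

test_that("preprocessing removes unexpressed genes and log-transforms counts", {
  lnc <- matrix(c(0, 0, 0, 0,
                  3, 0, 1, 7), 2, 4, byrow = TRUE,
                dimnames = list(c("L1", "L2"), paste0("S", 1:4)))
  mr <- matrix(c(3, 3, 3, 3,
                 1, 0, 0, 0), 2, 4, byrow = TRUE,
               dimnames = list(c("G1", "G2"), paste0("S", 1:4)))
  pur <- stats::setNames(rep(0.5, 4), paste0("S", 1:4))
  b <- preprocess(expression_bundle(lnc, mr, pur), counts_are_raw = TRUE)
  expect_identical(rownames(b$lnc_expr), "L2")       # all-zero row gone
  expect_equal(unname(b$mrna_expr["G1", 1]), 2)      # log2(3 + 1)
  expect_identical(nrow(b$mrna_expr), 2L)            # no-op for expressed genes

  # pass-through mode leaves values untouched
  b2 <- preprocess(expression_bundle(lnc, mr, pur), counts_are_raw = FALSE)
  expect_equal(unname(b2$mrna_expr["G1", ]), rep(3, 4))

  neg <- mr; neg[1, 1] <- -2
  expect_error(preprocess(expression_bundle(lnc, neg, pur), counts_are_raw = TRUE),
               "negative")
})

test_that("GMT round-trips and flags malformed lines", {
  d <- withr::local_tempdir()
  writeLines(c("pathA\tdesc\tg1\tg2", "pathB\tx\tg2\tg3\tg4"),
             file.path(d, "ok.gmt"))
  gs <- read_gmt(file.path(d, "ok.gmt"))
  expect_identical(gs$sets$pathA, c("g1", "g2"))
  expect_identical(gs$universe_size, 4L)

  writeLines(c("pathA\tdesc\tg1", "broken\tonlydesc"), file.path(d, "bad.gmt"))
  expect_error(read_gmt(file.path(d, "bad.gmt")), "line 2")
  writeLines(character(0), file.path(d, "empty.gmt"))
  expect_error(read_gmt(file.path(d, "empty.gmt")), "empty")
  writeLines("pathA\tdesc\tg1\tg1\tg2", file.path(d, "dup.gmt"))
  expect_warning(gd <- read_gmt(file.path(d, "dup.gmt")), "duplicate")
  expect_identical(gd$sets$pathA, c("g1", "g2"))

  write_gmt(gs, file.path(d, "out.gmt"))
  expect_identical(read_gmt(file.path(d, "out.gmt"))$sets, gs$sets)
})

test_that("simulated fixtures survive a write/read round trip to 1e-12", {
  sim <- simulate_cohort(n_samples = 20, n_mrna = 40, n_lnc = 12,
                         n_pathways = 3, n_cell_types = 4,
                         n_drivers = 3, n_confounded = 3,
                         marker_universe = 32, pathway_size = 5,
                         n_risk_genes = 2, seed = 11)
  d <- withr::local_tempdir()
  paths <- write_fixture(sim, d)
  b <- preprocess(read_expression(paths[["expression"]], paths[["annotation"]],
                                  paths[["purity"]]))
  expect_equal(b$lnc_expr, sim$bundle$lnc_expr, tolerance = 1e-12)
  expect_equal(b$mrna_expr, sim$bundle$mrna_expr, tolerance = 1e-12)
  expect_equal(b$purity, sim$bundle$purity, tolerance = 1e-12)

  mk <- read_gmt(paths[["markers"]])
  expect_identical(length(mk$sets), 4L)
  expect_identical(mk$universe_size, 32L)
  sv <- read_survival(paths[["survival"]])
  expect_equal(sv$time, sim$survival$time, tolerance = 1e-12)

  # refusal to clobber an existing non-empty directory
  expect_error(write_fixture(sim, d), "overwrite")
})

test_that("survival reader validates its invariants", {
  d <- withr::local_tempdir()
  writeLines(c("sample_id\ttime\tevent", "a\t10\t1", "b\t0\t0"),
             file.path(d, "s.tsv"))
  expect_error(read_survival(file.path(d, "s.tsv")), "positive")
  writeLines(c("sample_id\ttime\tevent", "a\t10\t1", "a\t5\t0"),
             file.path(d, "s2.tsv"))
  expect_error(read_survival(file.path(d, "s2.tsv")), "duplicated")
  writeLines(c("sample_id\ttime\tevent", "a\t10\t2"), file.path(d, "s3.tsv"))
  expect_error(read_survival(file.path(d, "s3.tsv")), "event")
})
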