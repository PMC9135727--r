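test_that("partial correlation matches the closed form and its edge cases", {
  set.seed(1)
  x <- rnorm(50)
  y <- 0.6 * x + rnorm(50)
  # force the covariate exactly orthogonal to x and y
  z0 <- rnorm(50)
  z <- residuals(lm(z0 ~ x + y))
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$pcc, cor(x, y), tolerance = 1e-12)   # covariate drops out

  expect_equal(partial_correlation(x, x + 0, rnorm(50))$pcc, 1, tolerance = 1e-12)

  expect_error(partial_correlation(x, y, rep(1, 50)), "zero-variance")
  expect_error(partial_correlation(x, y, x), "degenerate")
  expect_error(partial_correlation(x[1:3], y[1:3], z[1:3]), "at least 4")
})

test_that("partial correlation equals the Pearson correlation of residuals", {
  set.seed(42)
  for (i in 1:50) {
    z <- rnorm(50)
    x <- 0.8 * z + rnorm(50)
    y <- -0.5 * z + rnorm(50)
    pcc <- partial_correlation(x, y, z)$pcc
    oracle <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
    expect_lt(abs(pcc - oracle), 1e-10)
  }
})

test_that("pcc p-values behave like a proper two-sided test", {
  expect_equal(pcc_pvalue(0, 20), 1)
  expect_lt(pcc_pvalue(0.9, 50), pcc_pvalue(0.9, 10))
  expect_warning(p1 <- pcc_pvalue(1, 20), "0")
  expect_identical(p1, 0)

  # permutation oracle: permute the y residuals, rebuild the partial cor
  set.seed(5)
  m <- 30
  z <- rnorm(m)
  x <- rnorm(m)
  y <- rnorm(m)
  # engineer a partial correlation of ~0.5
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  ry <- 0.5 * rx / sd(rx) * sd(ry) + sqrt(0.75) * ry
  y <- fitted(lm(y ~ z)) + ry
  obs <- partial_correlation(x, y, z)$pcc
  perm <- replicate(10000, {
    yy <- fitted(lm(y ~ z)) + sample(ry)
    partial_correlation(x, yy, z)$pcc
  })
  emp <- mean(abs(perm) >= abs(obs))
  expect_lt(abs(pcc_pvalue(obs, m) - emp), 0.01)
})

test_that("rank scores are signed log p-values with clamping", {
  expect_equal(rank_score(1, 0.5), 0)
  expect_equal(rank_score(0.01, -0.3), -2)
  expect_equal(rank_score(1e-5, 0.8), 5)
  expect_equal(rank_score(1e-320, 1), 300)
  expect_equal(rank_score(0, -1), -300)
})

test_that("ranked lists order genes by signed association", {
  set.seed(8)
  m <- 12
  lnc <- rnorm(m)
  mr <- rbind(A = lnc, B = -lnc, C = rnorm(m))
  colnames(mr) <- sprintf("S%02d", 1:m)
  b <- expression_bundle(
    matrix(lnc, 1, m, dimnames = list("L1", colnames(mr))),
    mr, stats::setNames(runif(m, 0.4, 0.9), colnames(mr)))
  rl <- suppressWarnings(build_ranked_list("L1", b))
  expect_identical(rl$genes, c("A", "C", "B"))
  expect_identical(rl$N, 3L)
  expect_true(all(diff(rl$scores) <= 0))
  expect_error(build_ranked_list("nope", b), "not found")
})

test_that("driver pathway genes rank near the top of their driver's list", {
  sim <- shared_small_cohort()
  tr <- sim$truth
  d <- tr$driver_lncs[1]
  rl <- build_ranked_list(d, sim$bundle)
  pg <- intersect(sim$pathways$sets[[tr$driver_pathway[d]]], rl$genes)
  ranks <- match(pg, rl$genes)
  expect_lt(median(ranks), rl$N / 10)
})

test_that("enrichment scores match hand-computed and brute-force values", {
  # all hits at the head: the hit curve completes before any miss
  rl <- make_ranked(c(4, 3, 2, 1, 0), ids = paste0("g", 1:5))
  expect_equal(enrichment_score(rl, c("g1", "g2")), 1)

  # alternating case, enumerated by hand: deviations -0.5, 0.3, -0.2, 0
  rl2 <- make_ranked(c(3, 2, 1, 0.5), ids = paste0("g", 1:4))
  expect_equal(enrichment_score(rl2, c("g2", "g4")), -0.5)

  set.seed(10)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    scores <- rnorm(n)
    rl3 <- make_ranked(scores)
    set_genes <- sample(rl3$genes, sample(3:10, 1))
    for (p in c(0, 1))
      expect_equal(enrichment_score(rl3, set_genes, p),
                   brute_force_es(rl3$genes, rl3$scores, set_genes, p),
                   tolerance = 1e-12)
  }
})

test_that("enrichment scores respect bounds, rescaling and degenerate sets", {
  set.seed(12)
  rl <- make_ranked(rnorm(40))
  set_genes <- sample(rl$genes, 8)
  es <- enrichment_score(rl, set_genes)
  expect_gte(es, -1); expect_lte(es, 1)
  rl_scaled <- rl; rl_scaled$scores <- rl$scores * 7.3
  expect_equal(enrichment_score(rl_scaled, set_genes), es)

  expect_error(enrichment_score(rl, c("zz1", "zz2")), "no overlap")
  expect_error(enrichment_score(rl, rl$genes), "whole ranked list")
  rl0 <- make_ranked(c(2, 1, rep(0, 8)))
  zero_set <- rl0$genes[rl0$scores == 0][1:3]
  expect_error(enrichment_score(rl0, zero_set, weight_exponent = 1), "N_R = 0")
})

test_that("the analytic enrichment p-value matches its series limits", {
  expect_equal(es_pvalue(0, 200, 20), 1)
  # n = 9 puts lambda at 3 for |es| = 1; first term dominates (plain form)
  p <- es_pvalue(1, 100, 10, correct = FALSE)
  expect_equal(p, 2 * exp(-18), tolerance = 1e-6)
  expect_equal(es_pvalue(0.3, 200, 20, cdf = TRUE),
               1 - es_pvalue(0.3, 200, 20))
  expect_error(es_pvalue(0.5, 10, 10), "n_i < N")
  # monotone: stronger enrichment, smaller p
  ps <- es_pvalue(seq(0.05, 0.9, by = 0.05), 200, 20)
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(100)^sample(1:3, 1)
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-15)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("lncRES combines p and ES sign per the branch rule", {
  expect_equal(lncres_score(0, 1), 1)
  expect_equal(lncres_score(0.5, 0.2), 0)
  expect_equal(lncres_score(0.0025, 0.4), 0.995)
  expect_equal(lncres_score(0.1, -0.4), -0.8)
  expect_equal(lncres_score(0.3, 0), 0)
  # |lncres| non-increasing in p at fixed sign
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(abs(lncres_score(p, 1))) <= 0))
  expect_true(all(abs(lncres_score(runif(50), sample(c(-1, 1), 50, TRUE))) <= 1))
})

test_that("the lncRES screen applies a strict one-sided threshold", {
  tab <- data.frame(lnc_id = c("a", "b", "c", "c"),
                    lncres = c(0.995, 0.999, -0.999, 0.2))
  expect_identical(screen_immune_lncrnas(tab), "b")
  expect_identical(screen_immune_lncrnas(tab, two_sided = TRUE), c("b", "c"))
  expect_warning(out <- screen_immune_lncrnas(tab[0, ]), "empty")
  expect_length(out, 0)
})

test_that("the enrichment table is internally consistent", {
  sim <- shared_small_cohort()
  tab <- lncres_table(sim$bundle, sim$pathways, weight_exponent = 0,
                      lnc_ids = rownames(sim$bundle$lnc_expr)[1:10])
  expect_true(all(tab$qval >= tab$pval - 1e-15))
  expect_true(all(abs(tab$lncres) <= 1))
  expect_true(all(tab$es >= -1 & tab$es <= 1))
  pos <- !is.na(tab$es) & tab$es > 0
  neg <- !is.na(tab$es) & tab$es < 0
  expect_equal(tab$lncres[pos], 1 - 2 * tab$pval[pos])
  expect_equal(tab$lncres[neg], 2 * tab$pval[neg] - 1)
  expect_identical(nrow(tab), 10L * length(sim$pathways$sets))
})

test_that("purity residuals remove the linear purity component", {
  sim <- shared_small_cohort()
  m <- sim$bundle$lnc_expr[1:5, ]
  res <- purity_residuals(m, sim$bundle$purity)
  expect_identical(dim(res), dim(m))
  for (i in 1:5)
    expect_lt(abs(cor(res[i, ], sim$bundle$purity)), 1e-10)
})
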