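make_surv_cohort <- function(n = 120, beta = c(g1 = 0.8, g2 = -0.8),
                             n_noise = 8, censor = 0.3, seed = 31) {
  set.seed(seed)
  genes <- c(names(beta), paste0("n", seq_len(n_noise)))
  expr <- matrix(rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  lp <- as.numeric(crossprod(expr[names(beta), , drop = FALSE], beta))
  t_ev <- rexp(n, rate = exp(lp) * log(2) / 500)
  cmax <- uniroot(function(cm) mean(pmin(t_ev / cm, 1)) - censor,
                  c(1, 1e6))$root
  cens <- runif(n, 0, cmax)
  list(expr = expr,
       surv = survival_table(colnames(expr), pmax(pmin(t_ev, cens), 0.5),
                             as.integer(t_ev <= cens)))
}

test_that("the univariate screen keeps signal, drops noise, skips degenerates", {
  co <- make_surv_cohort()
  expr <- co$expr
  expr <- rbind(expr, flat = rep(3, ncol(expr)))
  expect_message(tab <- univariate_cox_screen(expr, co$surv), "flat")
  expect_false("flat" %in% tab$gene_id)
  expect_true(all(tab$passed[tab$gene_id %in% c("g1", "g2")]))
  expect_lt(mean(tab$passed[grepl("^n", tab$gene_id)]), 0.4)
  expect_equal(tab$hr, exp(tab$coef))
  censored <- survival_table(colnames(co$expr)[1:6], rep(100, 6), rep(0L, 6))
  expect_error(univariate_cox_screen(co$expr[, 1:6], censored), "event")
})

test_that("the risk model recovers implanted coefficients", {
  co <- make_surv_cohort(n = 300, seed = 32)
  model <- fit_risk_model(co$expr, co$surv, c("g1", "g2"))
  expect_s3_class(model, "RiskModel")
  expect_identical(sign(coef(model)), c(g1 = 1, g2 = -1))
  expect_equal(model$hr, exp(model$coefs))
  expect_true(is.finite(model$cutoff))
  expect_error(fit_risk_model(co$expr, co$surv, character(0)), "empty")
  expect_error(fit_risk_model(co$expr, co$surv, c("g1", "nope")), "nope")
  expect_error(fit_risk_model(co$expr[, 1:20], co$surv[1:20, ],
                              paste0("n", 1:6)), "guard")
})

test_that("a collinear panel falls back to a ridge-stabilised fit", {
  co <- make_surv_cohort(seed = 33)
  expr <- rbind(co$expr, g1copy = co$expr["g1", ])
  expect_warning(model <- fit_risk_model(expr, co$surv, c("g1", "g1copy")),
                 "ridge")
  expect_true(all(is.finite(coef(model))))
})

test_that("risk scores are the linear functional they claim to be", {
  model <- structure(list(genes = c("a", "b"),
                          coefs = c(a = 0.5, b = -1), hr = exp(c(a = 0.5, b = -1)),
                          score_mode = "log_hr", cutoff = 0),
                     class = "RiskModel")
  expect_equal(risk_score(model, c(a = 2, b = 1)), 0)
  expect_equal(risk_score(model, c(a = 0, b = 0)), 0)
  x <- c(a = 1, b = 2); y <- c(a = -0.3, b = 0.7)
  expect_equal(risk_score(model, x + y),
               risk_score(model, x) + risk_score(model, y))
  expect_gt(risk_score(model, c(a = 3, b = 1)), risk_score(model, c(a = 2, b = 1)))
  expect_error(risk_score(model, c(a = 1)), "b")
  model$score_mode <- "hr"
  expect_equal(risk_score(model, c(a = 1, b = 1)), exp(0.5) + exp(-1))
})

test_that("median stratification applies its tie and cutoff rules", {
  st <- stratify_median(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
  expect_equal(attr(st, "cutoff"), 2.5)
  expect_identical(st$group, c("low", "low", "high", "high"))
  st3 <- stratify_median(c(a = 1, b = 2, c = 3, d = 2))
  expect_identical(st3$group[st3$sample_id == "b"], "low")   # tie goes low
  ext <- stratify_median(c(a = 1, b = 2, c = 3, d = 9), cutoff = 0.5)
  expect_identical(unique(ext$group), "high")                # frozen cutoff
  expect_error(stratify_median(c(1, 2, 3)), "4 samples")
  expect_error(stratify_median(rep(2, 6)), "identical")
  # invariance under strictly increasing transforms
  sc <- c(s1 = 0.2, s2 = 1.4, s3 = -3, s4 = 0.9, s5 = 2)
  expect_identical(stratify_median(sc)$group, stratify_median(exp(sc))$group)
})

test_that("Kaplan-Meier / log-rank behaves at the null and under signal", {
  # identical duplicated groups: no contrast at all
  surv <- survival_table(sprintf("s%02d", 1:20),
                         rep(c(5, 10, 15, 20, 30), 4),
                         rep(c(1, 0, 1, 1, 0), 4))
  st <- stratify_median(stats::setNames(rep(c(0, 1), each = 10), surv$sample_id),
                        cutoff = 0.5)
  res <- km_logrank(st, surv)
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$pval, 1, tolerance = 1e-10)

  # strong hazard ratio: overwhelming evidence
  co <- make_surv_cohort(n = 200, beta = c(g1 = log(3)), seed = 35)
  st2 <- stratify_median(co$expr["g1", ])
  res2 <- km_logrank(st2, co$surv)
  expect_lt(res2$pval, 0.001)

  # a stratum without events still yields a test, with a warning
  surv0 <- survival_table(surv$sample_id, surv$time,
                          ifelse(st$group == "high", 0L, surv$event))
  expect_warning(res3 <- km_logrank(st, surv0), "zero events")
  expect_true(is.finite(res3$chisq))
})

test_that("log-rank p agrees with a permutation test on a small fixture", {
  co <- make_surv_cohort(n = 40, beta = c(g1 = 0.5), censor = 0.2, seed = 36)
  st <- stratify_median(co$expr["g1", ])
  obs <- km_logrank(st, co$surv)
  set.seed(1)
  y <- survival::Surv(co$surv$time, co$surv$event)
  grp <- factor(st$group[match(co$surv$sample_id, st$sample_id)])
  chis <- replicate(5000, survival::survdiff(y ~ sample(grp))$chisq)
  expect_lt(abs(mean(chis >= obs$chisq - 1e-12) - obs$pval), 0.01)
})

test_that("time-dependent AUC is calibrated at its extremes", {
  # perfect ranking: risk score reproduces the event order, no censoring
  n <- 60
  times <- seq(10, 600, length.out = n)
  surv <- survival_table(sprintf("s%02d", 1:n), times, rep(1L, n))
  scores <- stats::setNames(-times, surv$sample_id)
  auc <- time_dependent_auc(scores, surv, horizons = c(100, 300, 500))
  expect_true(all(auc == 1))
  # antisymmetry
  auc_neg <- time_dependent_auc(-scores, surv, horizons = c(100, 300, 500))
  expect_equal(unname(auc_neg), unname(1 - auc))

  # random scores hover at one half
  co <- make_surv_cohort(n = 500, beta = c(g1 = 0), censor = 0.2, seed = 37)
  rnd <- stats::setNames(rnorm(500), co$surv$sample_id)
  auc0 <- time_dependent_auc(rnd, co$surv, horizons = c(200, 400))
  expect_true(all(abs(auc0 - 0.5) < 0.07))

  expect_warning(
    a <- time_dependent_auc(scores, surv, horizons = c(100, 10000)),
    "beyond")
  expect_true(is.na(a[2]) && !is.na(a[1]))
})

test_that("external application freezes coefficients and guards gene loss", {
  co <- make_surv_cohort(n = 200, seed = 38)
  model <- fit_risk_model(co$expr, co$surv, c("g1", "g2", paste0("n", 1:4)))
  lnc <- matrix(rnorm(200), 1, 200,
                dimnames = list("L1", colnames(co$expr)))
  bundle <- expression_bundle(lnc, co$expr,
                              stats::setNames(runif(200, 0.3, 0.9),
                                              colnames(co$expr)))
  ext <- apply_external(model, bundle, co$surv)
  expect_equal(unname(ext$scores),
               unname(predict(model, co$expr)))            # same cohort, same scores
  expect_gt(ext$cindex, 0.5)

  b_miss <- expression_bundle(lnc, co$expr[-1, ], bundle$purity)
  expect_error(apply_external(model, b_miss, co$surv), "g1")   # refuse by default
  expect_message(
    ext2 <- apply_external(model, b_miss, co$surv, allow_missing = TRUE),
    "dropping")
  expect_identical(ext2$strata$group,
                   stratify_median(ext2$scores)$group)
  b_none <- expression_bundle(lnc, co$expr[1:2, ] * NA_real_ * 0 + 1, bundle$purity)
  b_none <- expression_bundle(lnc, co$expr[7:10, , drop = FALSE], bundle$purity)
  expect_error(apply_external(model, b_none, co$surv, allow_missing = TRUE),
               "missing")
})
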