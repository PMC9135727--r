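#' Univariate Cox screen over a gene panel
#'
#' Fits one proportional-hazards model per gene (Efron ties) and keeps
#' genes with a two-sided Wald p below `p_thresh`. Constant-expression or
#' non-converging genes are skipped with a message, never silently passed.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param survival_tab a [survival_table()] covering the samples.
#' @param p_thresh significance threshold (default 0.05).
#' @return `data.frame`: `gene_id`, `coef`, `hr`, `pval`, `passed`; skipped
#'   genes are absent.
#' @export
univariate_cox_screen <- function(expr, survival_tab, p_thresh = 0.05) {
  stopifnot(inherits(survival_tab, "SurvivalTable"))
  surv <- align_survival(survival_tab, colnames(expr))
  if (sum(surv$event) < 2) stop("need at least 2 events")
  y <- survival::Surv(surv$time, surv$event)
  rows <- lapply(rownames(expr), function(g) {
    x <- expr[g, surv$sample_id]
    if (stats::sd(x) == 0) {
      message("univariate_cox_screen: skipping constant gene ", g)
      return(NULL)
    }
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        f <- suppressWarnings(survival::coxph(y ~ x, ties = "efron"))
        if (any(!is.finite(f$coefficients)) ||
            any(!is.finite(sqrt(diag(f$var))))) NULL else f
      })
    if (is.null(fit) || !is.finite(fit$coefficients[1])) {
      message("univariate_cox_screen: skipping non-converging gene ", g)
      return(NULL)
    }
    s <- summary(fit)$coefficients
    data.frame(gene_id = g, coef = s[1, "coef"], hr = exp(s[1, "coef"]),
               pval = s[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene could be fitted")
  out$passed <- out$pval < p_thresh
  rownames(out) <- NULL
  out
}

#' Fit the multivariate Cox risk model
#'
#' One multivariate proportional-hazards fit over the gene panel (Efron
#' ties). The returned model carries the per-gene log-hazard coefficients,
#' hazard ratios and the training-cohort median risk score as the
#' stratification cutoff. A collinear panel triggers a ridge-stabilized
#' refit with a warning.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param survival_tab a [survival_table()].
#' @param genes gene panel (non-empty, all present in `expr`).
#' @param score_mode weight used by [risk_score()]: `"log_hr"` (the Cox
#'   linear predictor, default) or `"hr"` (`exp(coef)`, the literal
#'   reading of "hazard-ratio coefficient times expression").
#' @param epv_guard maximum panel size as a fraction of the sample count
#'   (default 1/5); override with care.
#' @param ridge_theta penalty for the collinearity fallback.
#' @return An object of class `RiskModel` with elements `genes`, `coefs`,
#'   `hr`, `score_mode`, `cutoff`, `fit`.
#' @export
fit_risk_model <- function(expr, survival_tab, genes,
                           score_mode = c("log_hr", "hr"),
                           epv_guard = 0.2, ridge_theta = 1) {
  score_mode <- match.arg(score_mode)
  if (!length(genes)) stop("empty gene panel")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("genes absent from expression: ",
                            paste(missing, collapse = ", "))
  surv <- align_survival(survival_tab, colnames(expr))
  if (length(genes) > epv_guard * length(surv$sample_id))
    stop("panel too large for the cohort (events-per-variable guard); ",
         "raise epv_guard to override")
  X <- t(expr[genes, surv$sample_id, drop = FALSE])
  y <- survival::Surv(surv$time, surv$event)
  fit <- tryCatch(survival::coxph(y ~ X, ties = "efron"),
                  error = function(e) NULL)
  coefs <- if (!is.null(fit)) fit$coefficients else NA_real_
  if (is.null(fit) || any(!is.finite(coefs))) {
    warning("collinear or unstable panel: refitting with a ridge penalty")
    fit <- survival::coxph(y ~ survival::ridge(X, theta = ridge_theta),
                           ties = "efron")
    coefs <- fit$coefficients
  }
  coefs <- stats::setNames(as.numeric(coefs), genes)
  model <- structure(
    list(genes = genes, coefs = coefs, hr = exp(coefs),
         score_mode = score_mode, cutoff = NA_real_, fit = fit),
    class = "RiskModel")
  scores <- risk_scores(model, expr[, surv$sample_id, drop = FALSE])
  model$cutoff <- stats::median(scores)
  model
}

#' @export
print.RiskModel <- function(x, ...) {
  cat(sprintf("RiskModel: %d genes, score_mode = %s, cutoff = %.4g\n",
              length(x$genes), x$score_mode, x$cutoff))
  print(data.frame(gene = x$genes, coef = round(x$coefs, 4),
                   hr = round(x$hr, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.RiskModel <- function(object, ...) object$coefs

#' Predict risk scores for new samples
#'
#' @param object a `RiskModel`.
#' @param newdata expression matrix, genes x samples, containing all model
#'   genes.
#' @param ... unused.
#' @return Named numeric vector of risk scores.
#' @export
predict.RiskModel <- function(object, newdata, ...) {
  risk_scores(object, newdata)
}

#' Risk score of one sample
#'
#' Sum over the model genes of weight times expression, the weight being
#' the Cox coefficient (`score_mode = "log_hr"`) or its hazard ratio
#' (`"hr"`).
#'
#' @param model a `RiskModel`.
#' @param expr_sample named numeric vector of one sample's expression.
#' @return Numeric score.
#' @export
risk_score <- function(model, expr_sample) {
  stopifnot(inherits(model, "RiskModel"))
  missing <- setdiff(model$genes, names(expr_sample))
  if (length(missing)) stop("expression missing for model gene(s): ",
                            paste(missing, collapse = ", "))
  w <- if (model$score_mode == "hr") model$hr else model$coefs
  sum(w * expr_sample[model$genes])
}

# vectorized over samples
risk_scores <- function(model, expr) {
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) stop("expression missing for model gene(s): ",
                            paste(missing, collapse = ", "))
  w <- if (model$score_mode == "hr") model$hr else model$coefs
  stats::setNames(as.numeric(crossprod(expr[model$genes, , drop = FALSE], w)),
                  colnames(expr))
}

#' Stratify samples into high- and low-risk groups
#'
#' High-risk means score strictly above the cutoff (ties go to low); the
#' cutoff defaults to the median of the supplied scores, or a frozen
#' training cutoff can be passed for external application.
#'
#' @param scores named numeric vector of risk scores (>= 4 samples).
#' @param cutoff optional fixed cutoff; `NULL` uses `median(scores)`.
#' @return A `data.frame` of class `StratifiedCohort`: `sample_id`,
#'   `risk_score`, `group` ("high"/"low"), with the cutoff as attribute.
#' @export
stratify_median <- function(scores, cutoff = NULL) {
  if (length(scores) < 4) stop("need at least 4 samples")
  if (length(unique(scores)) == 1) stop("all risk scores identical; cannot stratify")
  if (is.null(cutoff)) cutoff <- stats::median(scores)
  if (is.null(names(scores))) names(scores) <- paste0("sample", seq_along(scores))
  out <- data.frame(sample_id = names(scores), risk_score = as.numeric(scores),
                    group = ifelse(scores > cutoff, "high", "low"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("StratifiedCohort", "data.frame")
  out
}

#' Kaplan-Meier curves and log-rank test for a stratified cohort
#'
#' @param strata a [stratify_median()] result.
#' @param survival_tab a [survival_table()] covering the samples.
#' @return List with `fit` (a `survival::survfit` object), `chisq`, `df`
#'   and `pval` of the two-group log-rank test.
#' @export
km_logrank <- function(strata, survival_tab) {
  stopifnot(inherits(strata, "StratifiedCohort"))
  surv <- align_survival(survival_tab, strata$sample_id)
  group <- factor(strata$group[match(surv$sample_id, strata$sample_id)],
                  levels = c("low", "high"))
  if (any(table(group) == 0)) stop("both risk groups must be non-empty")
  ev <- tapply(surv$event, group, sum)
  if (any(ev == 0))
    warning("a risk group has zero events; the log-rank test is still computed")
  d <- data.frame(time = surv$time, event = surv$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(surv$event) == 0) {
    # no events anywhere: no information, define chisq = 0
    return(list(fit = fit, chisq = 0, df = 1, pval = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1
  list(fit = fit, chisq = unname(sd_$chisq), df = df,
       pval = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Censoring-adjusted time-dependent AUC
#'
#' Cumulative-case / dynamic-control AUC at fixed horizons with inverse
#' probability of censoring weights (IPCW): at horizon t, cases are samples
#' with an observed event by t (weighted by 1/G(T-), G = Kaplan-Meier
#' estimate of the censoring distribution) and controls are samples still
#' at risk after t; the AUC is the weighted probability that a case
#' outscores a control (ties count 1/2).
#'
#' @param scores named numeric vector of risk scores.
#' @param survival_tab a [survival_table()].
#' @param horizons evaluation times in days; defaults to 1, 3 and 5 years
#'   (365, 1095, 1825).
#' @return Named numeric vector of AUCs, one per horizon; horizons beyond
#'   the last follow-up or with no prior event are `NA` with a warning.
#' @export
time_dependent_auc <- function(scores, survival_tab,
                               horizons = c(365, 1095, 1825)) {
  surv <- align_survival(survival_tab, names(scores))
  s <- scores[surv$sample_id]
  cfit <- survival::survfit(
    survival::Surv(surv$time, 1 - surv$event) ~ 1)
  G <- function(t) {
    # left-continuous KM of censoring at t (probability of being uncensored)
    idx <- findInterval(t - 1e-9, cfit$time)
    c(1, cfit$surv)[idx + 1]
  }
  out <- stats::setNames(rep(NA_real_, length(horizons)),
                         paste0("t", horizons))
  for (h in seq_along(horizons)) {
    t0 <- horizons[h]
    if (t0 > max(surv$time)) {
      warning("horizon ", t0, " is beyond the last follow-up; skipped")
      next
    }
    case <- surv$time <= t0 & surv$event == 1
    ctrl <- surv$time > t0
    if (!any(case) || !any(ctrl)) {
      warning("no cases or no controls at horizon ", t0, "; skipped")
      next
    }
    w <- 1 / pmax(G(surv$time[case]), 1e-8)
    sc <- s[case]; sx <- s[ctrl]
    cmp <- outer(sc, sx, function(a, b) (a > b) + 0.5 * (a == b))
    out[h] <- sum(w * rowSums(cmp)) / (sum(w) * length(sx))
  }
  out
}

#' Apply a frozen risk model to an external cohort
#'
#' Scores the external samples with the training coefficients, stratifies
#' (by the external cohort's own median by default, or the frozen training
#' cutoff), and reports the log-rank test, time-dependent AUCs and Harrell
#' concordance.
#'
#' @param model a `RiskModel`.
#' @param bundle external `ExpressionBundle` (model genes looked up in the
#'   mRNA matrix).
#' @param survival_tab external [survival_table()].
#' @param use_training_cutoff stratify at the frozen training median
#'   instead of the external cohort's own.
#' @param allow_missing tolerate up to 20% missing model genes (their
#'   weights are dropped, with a message).
#' @param horizons passed to [time_dependent_auc()].
#' @return List with `scores`, `strata`, `km` ([km_logrank()] output),
#'   `auc`, `cindex`.
#' @export
apply_external <- function(model, bundle, survival_tab,
                           use_training_cutoff = FALSE,
                           allow_missing = FALSE,
                           horizons = c(365, 1095, 1825)) {
  stopifnot(inherits(model, "RiskModel"), inherits(bundle, "ExpressionBundle"))
  expr <- bundle$mrna_expr
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) {
    frac <- length(missing) / length(model$genes)
    if (frac > 0.2)
      stop(sprintf("%.0f%% of model genes missing from the external cohort: %s",
                   100 * frac, paste(missing, collapse = ", ")))
    if (!allow_missing)
      stop("model gene(s) missing from the external cohort: ",
           paste(missing, collapse = ", "),
           "; set allow_missing = TRUE to drop their weights")
    message("apply_external: dropping missing model gene(s): ",
            paste(missing, collapse = ", "))
    keep <- setdiff(model$genes, missing)
    model$genes <- keep
    model$coefs <- model$coefs[keep]
    model$hr <- model$hr[keep]
  }
  scores <- risk_scores(model, expr)
  strata <- stratify_median(
    scores, cutoff = if (use_training_cutoff) model$cutoff else NULL)
  km <- km_logrank(strata, survival_tab)
  auc <- time_dependent_auc(scores, survival_tab, horizons = horizons)
  surv <- align_survival(survival_tab, names(scores))
  conc <- survival::concordance(
    survival::Surv(surv$time, surv$event) ~ scores[surv$sample_id],
    reverse = TRUE)
  list(scores = scores, strata = strata, km = km, auc = auc,
       cindex = unname(conc$concordance))
}

# align a survival table to a sample-id vector, erroring on gaps
align_survival <- function(survival_tab, sample_ids) {
  stopifnot(inherits(survival_tab, "SurvivalTable"))
  missing <- setdiff(sample_ids, survival_tab$sample_id)
  if (length(missing))
    stop("survival data missing for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  survival_tab[match(sample_ids, survival_tab$sample_id), , drop = FALSE]
}
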