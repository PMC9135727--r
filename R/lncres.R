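#' Purity-adjusted partial correlation of two expression vectors
#'
#' First-order partial correlation of `x` and `y` given the covariate `z`
#' (tumor purity):
#' \deqn{PCC = \frac{R_{xy} - R_{xz} R_{yz}}
#'   {\sqrt{1 - R_{xz}^2}\,\sqrt{1 - R_{yz}^2}}}
#' Removing the linear purity contribution separates genuine
#' lncRNA--mRNA co-expression from correlation induced jointly by the
#' immune/stromal fraction of the bulk sample.
#'
#' @param x,y,z numeric vectors of equal length (m >= 4), each with
#'   non-zero variance.
#' @return A list with the three pairwise Pearson correlations `r_xy`,
#'   `r_xz`, `r_yz` and the partial correlation `pcc`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_correlation(x, y, z)$pcc   # much closer to 0 than cor(x, y)
#' @export
partial_correlation <- function(x, y, z) {
  m <- length(x)
  if (length(y) != m || length(z) != m) stop("x, y, z must have equal length")
  if (m < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("zero-variance input")
  r_xy <- stats::cor(x, y)
  r_xz <- stats::cor(x, z)
  r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate covariate: |correlation with z| = 1")
  pcc <- (r_xy - r_xz * r_yz) / (sqrt(1 - r_xz^2) * sqrt(1 - r_yz^2))
  list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz, pcc = pcc)
}

#' Two-sided p-value for a first-order partial correlation
#'
#' Uses the t-statistic `t = pcc * sqrt((m - 3) / (1 - pcc^2))` on `m - 3`
#' degrees of freedom (m observations, one covariate).
#'
#' @param pcc partial correlation in \[-1, 1\].
#' @param m number of observations.
#' @return Two-sided p-value. `|pcc| = 1` returns 0 with a warning.
#' @export
pcc_pvalue <- function(pcc, m) {
  if (any(m < 4)) stop("need m >= 4")
  p <- rep(NA_real_, length(pcc))
  deg <- abs(pcc) >= 1
  if (any(deg)) {
    warning("|pcc| = 1: p-value set to 0")
    p[deg] <- 0
  }
  ok <- !deg
  tt <- pcc[ok] * sqrt((m - 3) / (1 - pcc[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = m - 3)
  p
}

#' Signed log rank score for a lncRNA-gene pair
#'
#' `RS = -log10(p) * sign(pcc)`; p-values below 1e-300 are clamped so that
#' `RS` stays within \[-300, 300\].
#'
#' @param pval correlation p-value(s) in \[0, 1\].
#' @param pcc matching partial correlation(s); only the sign is used.
#' @return Rank score(s).
#' @export
rank_score <- function(pval, pcc) {
  pval <- pmax(pval, 1e-300)
  -log10(pval) * sign(pcc)
}

#' Residualize expression on tumor purity
#'
#' Removes the linear purity contribution from every gene row (ordinary
#' least squares per gene). Used before clustering so that sample grouping
#' reflects regulation rather than the purity gradient that all immune
#' genes share.
#'
#' @param mat numeric matrix, genes x samples.
#' @param purity per-sample purity vector aligned with the columns.
#' @return Matrix of residuals with the same dimensions and dimnames.
#' @export
purity_residuals <- function(mat, purity) {
  if (ncol(mat) != length(purity)) stop("purity length must match samples")
  p <- purity - mean(purity)
  denom <- sum(p^2)
  if (denom == 0) stop("purity is constant; nothing to adjust for")
  centered <- mat - rowMeans(mat)
  beta <- (centered %*% p) / denom
  res <- centered - beta %*% t(p)
  dimnames(res) <- dimnames(mat)
  res
}

# all-pairs partial correlation of lncRNAs vs mRNAs given purity, vectorized
pcor_matrices <- function(bundle) {
  m <- length(bundle$sample_ids)
  if (m < 4) stop("need at least 4 samples")
  lncs <- t(bundle$lnc_expr)
  mrnas <- t(bundle$mrna_expr)
  keep_l <- apply(lncs, 2, stats::sd) > 0
  keep_g <- apply(mrnas, 2, stats::sd) > 0
  if (!all(keep_g))
    message(sprintf("dropping %d zero-variance mRNA(s)", sum(!keep_g)))
  if (!all(keep_l))
    message(sprintf("dropping %d zero-variance lncRNA(s)", sum(!keep_l)))
  lncs <- lncs[, keep_l, drop = FALSE]
  mrnas <- mrnas[, keep_g, drop = FALSE]
  p <- bundle$purity
  r_lg <- stats::cor(lncs, mrnas)
  r_lp <- drop(stats::cor(lncs, p))
  r_gp <- drop(stats::cor(mrnas, p))
  if (any(abs(r_lp) >= 1) || any(abs(r_gp) >= 1))
    stop("degenerate purity covariate (|correlation| = 1 with a gene)")
  pcc <- (r_lg - outer(r_lp, r_gp)) /
    (sqrt(1 - r_lp^2) %o% sqrt(1 - r_gp^2))
  pcc <- pmin(pmax(pcc, -1), 1)
  tt <- pcc * sqrt((m - 3) / pmax(1 - pcc^2, 1e-15))
  pval <- 2 * stats::pt(-abs(tt), df = m - 3)
  rs <- rank_score(pval, pcc)
  list(pcc = pcc, pval = pval, rs = rs, m = m)
}

#' Purity-adjusted correlation table for one lncRNA against all mRNAs
#'
#' Scores every mRNA against one lncRNA with
#' [partial_correlation()]/[pcc_pvalue()]/[rank_score()]. Set
#' `adjust_purity = FALSE` for the diagnostic mode that ignores purity
#' (plain Pearson correlation); this mode exists to demonstrate the
#' confounding the adjustment removes, not for discovery.
#'
#' @param lnc_id lncRNA id present in the bundle.
#' @param bundle a preprocessed `ExpressionBundle`.
#' @param adjust_purity include tumor purity as the covariate (default).
#' @return A `data.frame` with columns `lnc_id`, `gene_id`, `pcc`, `pval`,
#'   `rs`, one row per retained (non-zero-variance) mRNA.
#' @export
correlation_table <- function(lnc_id, bundle, adjust_purity = TRUE) {
  stopifnot(inherits(bundle, "ExpressionBundle"))
  if (!lnc_id %in% rownames(bundle$lnc_expr))
    stop("lncRNA not found: ", lnc_id)
  m <- length(bundle$sample_ids)
  x <- bundle$lnc_expr[lnc_id, ]
  mrnas <- t(bundle$mrna_expr)
  keep <- apply(mrnas, 2, stats::sd) > 0
  mrnas <- mrnas[, keep, drop = FALSE]
  if (adjust_purity) {
    pc <- pcor_matrices(expression_bundle(
      bundle$lnc_expr[lnc_id, , drop = FALSE], t(mrnas), bundle$purity))
    out <- data.frame(lnc_id = lnc_id, gene_id = colnames(pc$pcc),
                      pcc = pc$pcc[1, ], pval = pc$pval[1, ], rs = pc$rs[1, ],
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    r <- drop(stats::cor(x, mrnas))
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-15))
    pval <- 2 * stats::pt(-abs(tt), df = m - 2)
    out <- data.frame(lnc_id = lnc_id, gene_id = colnames(mrnas),
                      pcc = r, pval = pval, rs = rank_score(pval, r),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Rank all mRNAs for one lncRNA by rank score
#'
#' @inheritParams correlation_table
#' @return A list of class `RankedGeneList`: `lnc_id`, `genes` (ids in
#'   descending rank-score order, ties broken by gene id), `scores`
#'   (the matching rank scores) and `N` (list length).
#' @export
build_ranked_list <- function(lnc_id, bundle, adjust_purity = TRUE) {
  tab <- correlation_table(lnc_id, bundle, adjust_purity = adjust_purity)
  ord <- order(-tab$rs, tab$gene_id)
  structure(list(lnc_id = lnc_id,
                 genes = tab$gene_id[ord],
                 scores = tab$rs[ord],
                 N = nrow(tab)),
            class = "RankedGeneList")
}

#' @export
print.RankedGeneList <- function(x, ...) {
  cat(sprintf("RankedGeneList for %s: %d genes, rank scores [%.3g, %.3g]\n",
              x$lnc_id, x$N, min(x$scores), max(x$scores)))
  invisible(x)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; at each position the running sum gains
#' `|r_j|^p / N_R` for genes in the set ("hits", `N_R` = total hit weight)
#' and loses `1/(N - N_I)` for genes outside it. The enrichment score is the
#' running-sum value of greatest magnitude (signed maximum deviation from
#' zero). Set genes absent from the ranked list are dropped (intersection
#' semantics).
#'
#' @param ranked a `RankedGeneList`.
#' @param gene_set character vector of gene ids.
#' @param weight_exponent exponent `p` on `|r_j|`. The default 0 reduces to
#'   the classic two-sample KS statistic, whose null the analytic
#'   [es_pvalue()] describes; 1 gives standard rank-weighted enrichment,
#'   appropriate only with a permutation null (see the methods vignette).
#' @return Signed enrichment score in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 0) {
  stopifnot(inherits(ranked, "RankedGeneList"))
  hit <- ranked$genes %in% gene_set
  n_i <- sum(hit)
  if (n_i == 0) stop("gene set has no overlap with the ranked list")
  if (n_i == ranked$N) stop("gene set covers the whole ranked list")
  w <- abs(ranked$scores)^weight_exponent
  n_r <- sum(w[hit])
  if (n_r == 0) stop("all hit weights are zero (N_R = 0)")
  p_hit <- cumsum(ifelse(hit, w / n_r, 0))
  p_miss <- cumsum(!hit) / (ranked$N - n_i)
  dev <- p_hit - p_miss
  # earliest position within float tolerance of the maximal deviation
  dev[which(abs(dev) >= max(abs(dev)) - 1e-12)[1]]
}

#' Analytic p-value for a KS enrichment score
#'
#' Asymptotic two-sided Kolmogorov-Smirnov tail probability for an
#' enrichment score computed on a ranked list of `N` genes with `n_i` set
#' members. The effective size is `n = (N - n_i) * n_i / N` and
#' `lambda = |es| * sqrt(n)`; the survival form
#' \deqn{p = 2 \sum_{q \ge 1} (-1)^{q-1} e^{-2 q^2 \lambda^2}}
#' is used so that stronger enrichment yields smaller p (series truncated
#' when a term drops below 1e-12 or q exceeds 100; result clamped to
#' \[0, 1\]). By default `sqrt(n)` carries Stephens' small-sample
#' adjustment, `sqrt(n) + 0.12 + 0.11 / sqrt(n)`, which keeps the analytic
#' tail within about 0.02 of the exact permutation null at the effective
#' sizes typical of pathway sets; `correct = FALSE` gives the plain
#' asymptotic form. `cdf = TRUE` instead returns the asymptotic CDF, i.e.
#' `1 - p`.
#'
#' @param es enrichment score.
#' @param N ranked-list length.
#' @param n_i number of set genes in the list (`1 <= n_i < N`).
#' @param cdf return the asymptotic CDF instead of the tail.
#' @param correct apply Stephens' effective-sample adjustment (default).
#' @return p-value in \[0, 1\]; `es = 0` gives 1 (tail form).
#' @export
es_pvalue <- function(es, N, n_i, cdf = FALSE, correct = TRUE) {
  if (any(n_i < 1) || any(n_i >= N)) stop("need 1 <= n_i < N")
  n_eff <- (N - n_i) * n_i / N
  root_n <- if (correct) sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff) else sqrt(n_eff)
  lam2 <- es^2 * root_n^2
  tail_one <- function(l2) {
    if (l2 == 0) return(1)
    s <- 0
    for (q in seq_len(100)) {
      term <- (-1)^(q - 1) * exp(-2 * q^2 * l2)
      s <- s + term
      if (abs(term) < 1e-12) break
    }
    min(max(2 * s, 0), 1)
  }
  p <- vapply(lam2, tail_one, numeric(1))
  if (cdf) 1 - p else p
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values; each q is at least its p and the q-values are
#' monotone in the p-value ranking.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Combine enrichment p-value and ES sign into the lncRES score
#'
#' `lncRES = 1 - 2p` when `es > 0`, `2p - 1` when `es < 0`, and 0 when
#' `es = 0`; values near +1 indicate strong positive immune-pathway
#' association.
#'
#' @param pval enrichment p-value(s).
#' @param es matching enrichment score(s); only the sign is used.
#' @return lncRES score(s) in \[-1, 1\].
#' @export
lncres_score <- function(pval, es) {
  if (any(pval < 0 | pval > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  ifelse(es > 0, 1 - 2 * pval, ifelse(es < 0, 2 * pval - 1, 0))
}

#' Score every lncRNA against every immune pathway
#'
#' For each lncRNA: build the purity-adjusted ranked gene list, compute the
#' weighted KS enrichment score against each pathway, its analytic p-value,
#' the per-lncRNA BH q-value and the lncRES score. Pathway genes absent
#' from the ranked list are dropped (and counted in the `n_i` column).
#'
#' @param bundle a preprocessed `ExpressionBundle`.
#' @param pathways a `GeneSetCollection` of immune pathways.
#' @param weight_exponent see [enrichment_score()].
#' @param adjust_purity `FALSE` gives the purity-ignoring diagnostic mode.
#' @param lnc_ids optional subset of lncRNAs to score (default all).
#' @return A `data.frame` with columns `lnc_id`, `pathway_id`, `n_i`, `es`,
#'   `pval`, `qval`, `lncres`.
#' @export
lncres_table <- function(bundle, pathways, weight_exponent = 0,
                         adjust_purity = TRUE, lnc_ids = NULL) {
  stopifnot(inherits(bundle, "ExpressionBundle"),
            inherits(pathways, "GeneSetCollection"))
  if (is.null(lnc_ids)) lnc_ids <- rownames(bundle$lnc_expr)
  keep_l <- apply(bundle$lnc_expr[lnc_ids, , drop = FALSE], 1, stats::sd) > 0
  lnc_ids <- lnc_ids[keep_l]
  mrnas <- t(bundle$mrna_expr)
  keep_g <- apply(mrnas, 2, stats::sd) > 0
  sub <- expression_bundle(bundle$lnc_expr[lnc_ids, , drop = FALSE],
                           bundle$mrna_expr[keep_g, , drop = FALSE],
                           bundle$purity)
  if (adjust_purity) {
    pc <- pcor_matrices(sub)
    rs_mat <- pc$rs
  } else {
    m <- length(sub$sample_ids)
    r <- stats::cor(t(sub$lnc_expr), t(sub$mrna_expr))
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-15))
    rs_mat <- rank_score(2 * stats::pt(-abs(tt), df = m - 2), r)
  }
  gene_ids <- colnames(rs_mat)
  N <- length(gene_ids)
  set_names <- names(pathways$sets)
  out <- vector("list", length(lnc_ids))
  for (i in seq_along(lnc_ids)) {
    rs <- rs_mat[i, ]
    ord <- order(-rs, gene_ids)
    ranked <- structure(list(lnc_id = lnc_ids[i], genes = gene_ids[ord],
                             scores = rs[ord], N = N),
                        class = "RankedGeneList")
    es <- numeric(length(set_names))
    n_i <- integer(length(set_names))
    for (k in seq_along(set_names)) {
      members <- intersect(pathways$sets[[k]], gene_ids)
      n_i[k] <- length(members)
      es[k] <- if (n_i[k] == 0 || n_i[k] == N) NA_real_ else
        enrichment_score(ranked, members, weight_exponent)
    }
    ok <- !is.na(es)
    pval <- rep(NA_real_, length(es))
    pval[ok] <- es_pvalue(es[ok], N, n_i[ok])
    out[[i]] <- data.frame(lnc_id = lnc_ids[i], pathway_id = set_names,
                           n_i = n_i, es = es, pval = pval,
                           qval = fdr_adjust(pval),
                           lncres = lncres_score(pval, es),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen lncRNAs by their best lncRES score
#'
#' A lncRNA is called immune-related when its lncRES exceeds the threshold
#' (strictly) in at least one pathway. `two_sided = TRUE` screens on
#' `|lncRES|` instead, which additionally admits strong negative
#' enrichment.
#'
#' @param records output of [lncres_table()].
#' @param threshold screening threshold (default 0.995).
#' @param two_sided screen on the absolute score.
#' @return Sorted character vector of passing lncRNA ids.
#' @export
screen_immune_lncrnas <- function(records, threshold = 0.995, two_sided = FALSE) {
  if (!nrow(records)) {
    warning("empty enrichment table: no lncRNAs to screen")
    return(character(0))
  }
  score <- if (two_sided) abs(records$lncres) else records$lncres
  pass <- !is.na(score) & score > threshold
  sort(unique(records$lnc_id[pass]))
}
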