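#' Resampling-based consensus clustering of samples
#'
#' Monti-style consensus clustering: for each candidate cluster number `k`,
#' samples are repeatedly subsampled without replacement and partitioned by
#' k-means (Euclidean, 10 restarts); the consensus matrix entry (i, j) is
#' the fraction of co-subsampled runs in which i and j landed in the same
#' cluster. Final hard labels come from average-linkage hierarchical
#' clustering of `1 - consensus`. The number of clusters is selected by the
#' classic mean-silhouette criterion: for each k the consensus-derived
#' labels are scored by their average silhouette width on the Euclidean
#' distances of the z-scored input, and the k with the largest value wins
#' (smallest k on ties). The proportion of ambiguous clustering (PAC, the
#' mass of the consensus CDF between `pac_bounds`) and the consensus CDF
#' area are reported per k for inspection; PAC alone is not used for
#' selection because merging two well-separated clusters is itself a stable
#' operation, which ties PAC at zero for every k at or below the true
#' number.
#'
#' Rows (features, e.g. candidate lncRNAs) are z-scored before clustering.
#'
#' @param mat numeric matrix, features x samples (>= 2 features).
#' @param k_range integer vector of candidate cluster counts (all >= 2).
#' @param n_resamples subsampling iterations per k (default 1000).
#' @param subsample_frac fraction of samples kept per iteration
#'   (default 0.8).
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param pac_bounds lower/upper consensus bounds defining "ambiguous"
#'   entries (default 0.1 and 0.9).
#' @param nstart k-means restarts per iteration.
#' @return An object of class `ConsensusResult`: `k_grid`, `consensus`
#'   (named list of sample x sample matrices), `labels` (named list of
#'   per-k assignments), `stability` (data.frame of PAC, CDF area and mean
#'   silhouette per k), `k_opt`, and `cdf_grid`/`cdf` for CDF-curve
#'   inspection.
#' @export
consensus_cluster <- function(mat, k_range = 2:9, n_resamples = 1000,
                              subsample_frac = 0.8, seed = NULL,
                              pac_bounds = c(0.1, 0.9), nstart = 10) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 features to cluster on")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("k_range must contain values >= 2")
  n <- ncol(mat)
  if (n < max(k_range) * 3)
    stop("need at least 3 x max(k_range) samples")
  sds <- apply(mat, 1, stats::sd)
  if (all(sds == 0)) stop("zero-variance input: all samples identical")
  z <- (mat - rowMeans(mat)) / ifelse(sds == 0, 1, sds)
  dat <- t(z)                             # samples x features
  if (nrow(unique(dat)) < max(k_range))
    stop("fewer distinct samples than max(k_range)")
  if (!is.null(seed)) set.seed(seed)
  n_sub <- max(2L, floor(subsample_frac * n))
  samples <- colnames(mat)
  if (is.null(samples)) samples <- paste0("sample", seq_len(n))

  consensus <- labels <- stats::setNames(vector("list", length(k_range)),
                                         paste0("k", k_range))
  pac <- area <- sil <- numeric(length(k_range))
  cdf_grid <- seq(0, 1, by = 0.01)
  cdf <- matrix(NA_real_, length(k_range), length(cdf_grid),
                dimnames = list(paste0("k", k_range), NULL))
  dmat <- as.matrix(stats::dist(dat))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    conn <- matrix(0, n, n)
    tog <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      sub <- sort(sample.int(n, n_sub))
      km <- suppressWarnings(
        stats::kmeans(dat[sub, , drop = FALSE], centers = k,
                      nstart = nstart, iter.max = 50))
      same <- outer(km$cluster, km$cluster, "==")
      conn[sub, sub] <- conn[sub, sub] + same
      tog[sub, sub] <- tog[sub, sub] + 1
    }
    miss <- tog == 0
    diag(miss) <- FALSE
    if (mean(miss) > 0.01)
      stop("more than 1% of sample pairs were never co-subsampled; ",
           "increase n_resamples")
    cons <- ifelse(tog > 0, conn / pmax(tog, 1), 0)
    diag(cons) <- 1
    cons <- (cons + t(cons)) / 2
    dimnames(cons) <- list(samples, samples)
    stopifnot(all(cons >= 0 & cons <= 1))
    upper <- cons[upper.tri(cons)]
    pac[ki] <- mean(upper > pac_bounds[1] & upper < pac_bounds[2])
    cdf[ki, ] <- stats::ecdf(upper)(cdf_grid)
    area[ki] <- mean(cdf[ki, ])
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    lab <- stats::cutree(hc, k = k)
    names(lab) <- samples
    sil[ki] <- mean_silhouette(dmat, lab)
    consensus[[ki]] <- cons
    labels[[ki]] <- lab
  }
  k_opt <- k_range[which.max(sil)]
  structure(list(k_grid = k_range, consensus = consensus, labels = labels,
                 stability = data.frame(k = k_range, pac = pac,
                                        cdf_area = area, silhouette = sil),
                 k_opt = k_opt, cdf_grid = cdf_grid, cdf = cdf),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult\n")
  cat(sprintf("  k grid: %s; selected k_opt = %d (max mean silhouette)\n",
              paste(x$k_grid, collapse = ", "), x$k_opt))
  print(x$stability, row.names = FALSE)
  invisible(x)
}

# mean silhouette width of a labeling given a distance matrix
mean_silhouette <- function(dmat, lab) {
  n <- nrow(dmat)
  groups <- unique(lab)
  if (length(groups) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]
    a <- if (sum(own) > 1) sum(dmat[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(groups, lab[i]),
                    function(g) mean(dmat[i, lab == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Plot consensus CDF curves
#'
#' Empirical CDFs of the off-diagonal consensus values, one curve per k;
#' the flattest curve between the PAC bounds marks the most stable
#' clustering.
#'
#' @param x a `ConsensusResult`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ConsensusResult <- function(x, ...) {
  graphics::matplot(x$cdf_grid, t(x$cdf), type = "l", lty = 1,
                    col = seq_along(x$k_grid),
                    xlab = "consensus index", ylab = "CDF", ...)
  graphics::legend("bottomright", legend = paste0("k=", x$k_grid),
                   col = seq_along(x$k_grid), lty = 1, bty = "n")
  invisible(x)
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Genes are ranked by expression within one sample (highest expression =
#' highest rank); the score is the sum over all list positions of the
#' difference between the rank-weighted in-set ECDF (rank values raised to
#' `alpha`) and the unweighted out-of-set ECDF. Depends on ranks only, so
#' any strictly monotone transform of the expression values leaves the
#' score unchanged.
#'
#' @param expr_column named numeric vector: one sample's expression.
#' @param gene_set character vector of gene ids.
#' @param alpha rank-weight exponent (default 0.25, the conventional
#'   choice; 0 gives the unweighted KS-style sum).
#' @return Numeric score.
#' @export
ssgsea_score <- function(expr_column, gene_set, alpha = 0.25) {
  if (is.null(names(expr_column))) stop("expr_column must be named by gene id")
  genes <- names(expr_column)
  in_set <- genes %in% gene_set
  n_i <- sum(in_set)
  if (n_i == 0) stop("gene set has no overlap with the sample's genes")
  if (n_i == length(genes)) stop("gene set covers all genes")
  rk <- rank(expr_column, ties.method = "average")
  ord <- order(-rk, genes)                # descending expression, ties by id
  hit <- in_set[ord]
  w <- rk[ord]^alpha
  p_in <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  p_out <- cumsum(!hit) / (length(genes) - n_i)
  sum(p_in - p_out)
}

#' ssGSEA score table for all samples and sets
#'
#' @param bundle an `ExpressionBundle`; sets are scored on the mRNA matrix
#'   (genes absent from a sample's matrix are simply not in the ranking).
#' @param sets a `GeneSetCollection` (e.g. the 24 immune-cell marker sets).
#' @param alpha see [ssgsea_score()].
#' @return Matrix, samples x sets, of enrichment scores.
#' @export
score_all <- function(bundle, sets, alpha = 0.25) {
  stopifnot(inherits(bundle, "ExpressionBundle"),
            inherits(sets, "GeneSetCollection"))
  expr <- bundle$mrna_expr
  out <- matrix(NA_real_, ncol(expr), length(sets$sets),
                dimnames = list(colnames(expr), names(sets$sets)))
  for (s in seq_len(ncol(expr))) {
    col <- expr[, s]
    for (g in seq_along(sets$sets)) {
      members <- intersect(sets$sets[[g]], rownames(expr))
      if (!length(members) || length(members) == nrow(expr))
        stop("gene set '", names(sets$sets)[g],
             "' has empty or complete overlap with the expression matrix")
      out[s, g] <- ssgsea_score(col, members, alpha = alpha)
    }
  }
  out
}

#' Nonparametric comparison of a score across sample groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test; more than two:
#' Kruskal-Wallis.
#'
#' @param values_by_group named list of numeric vectors, one per group,
#'   each with at least 3 values.
#' @return List with `statistic`, `pval`, `test`.
#' @export
compare_groups <- function(values_by_group) {
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  sizes <- lengths(values_by_group)
  if (any(sizes < 3)) {
    small <- names(values_by_group)[sizes < 3]
    if (is.null(small)) small <- which(sizes < 3)
    stop("group(s) below minimum size 3: ", paste(small, collapse = ", "))
  }
  if (length(values_by_group) == 2) {
    ht <- suppressWarnings(
      stats::wilcox.test(values_by_group[[1]], values_by_group[[2]]))
    p <- ht$p.value
    if (is.na(p)) p <- 1   # fully tied data carries no information
    list(statistic = unname(ht$statistic), pval = p, test = "wilcoxon")
  } else {
    x <- unlist(values_by_group, use.names = FALSE)
    g <- factor(rep(seq_along(values_by_group), lengths(values_by_group)))
    ht <- stats::kruskal.test(x, g)
    list(statistic = unname(ht$statistic), pval = ht$p.value,
         test = "kruskal-wallis")
  }
}

#' Differential-expression screen between two sample groups
#'
#' Per-gene two-sided rank-sum test with BH adjustment; log2 fold change is
#' the group mean difference on the log2 scale. A gene passes at
#' `p < p_thresh` and `|log2FC| > lfc_thresh` (defaults 0.01 and 1).
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param labels named vector assigning each sample to one of exactly two
#'   groups; the log2FC sign is group2 minus group1 (alphabetical order).
#' @param p_thresh,lfc_thresh significance thresholds.
#' @return `data.frame`: `gene_id`, `log2fc`, `pval`, `qval`, `passed`.
#' @export
de_screen <- function(expr, labels, p_thresh = 0.01, lfc_thresh = 1) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("labels missing for some samples")
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2) stop("labels must define exactly two groups")
  g1 <- colnames(expr)[labels == groups[1]]
  g2 <- colnames(expr)[labels == groups[2]]
  if (length(intersect(g1, g2))) stop("groups overlap")
  if (length(g1) < 3 || length(g2) < 3) stop("both groups need >= 3 samples")
  lfc <- rowMeans(expr[, g2, drop = FALSE]) - rowMeans(expr[, g1, drop = FALSE])
  pval <- vapply(seq_len(nrow(expr)), function(i) {
    suppressWarnings(
      stats::wilcox.test(expr[i, g2], expr[i, g1])$p.value)
  }, numeric(1))
  qval <- fdr_adjust(pval)
  data.frame(gene_id = rownames(expr), log2fc = lfc, pval = pval, qval = qval,
             passed = pval < p_thresh & abs(lfc) > lfc_thresh,
             stringsAsFactors = FALSE, row.names = NULL)
}

# adjusted Rand index between two labelings (internal; cross-checked
# against mclust::adjustedRandIndex in the test suite)
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
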