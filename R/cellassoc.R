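#' mRNAs significantly correlated with a lncRNA
#'
#' Selects the mRNAs whose purity-adjusted correlation with the lncRNA is
#' significant at `alpha`, optionally after BH adjustment across all mRNAs
#' of that lncRNA (the default, which controls the expected false
#' discovery fraction in the selected set).
#'
#' @param lnc_id lncRNA id.
#' @param correlations a [correlation_table()] covering the lncRNA.
#' @param alpha significance threshold (default 0.05).
#' @param use_fdr apply BH adjustment before thresholding (default `TRUE`).
#' @return Sorted character vector of significant mRNA ids.
#' @export
significant_mrnas <- function(lnc_id, correlations, alpha = 0.05, use_fdr = TRUE) {
  rows <- correlations$lnc_id == lnc_id
  if (!any(rows)) stop("no correlation records for lncRNA ", lnc_id)
  p <- correlations$pval[rows]
  if (use_fdr) p <- fdr_adjust(p)
  sort(correlations$gene_id[rows][p < alpha])
}

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, M, n)`: drawing `n` genes from a
#' universe of `N` of which `M` are markers of the cell type, the chance of
#' at least `k` markers in the draw. The enrichment p-value of an observed
#' overlap `k`.
#'
#' @param k observed overlap count.
#' @param n number of genes drawn (significant mRNAs in the universe).
#' @param m_markers number of marker genes of the cell type (M).
#' @param n_universe total marker universe size (N).
#' @return p-value in (0, 1\]; `k = 0` gives 1.
#' @examples
#' hypergeom_tail(3, 5, 4, 10)   # 66/252
#' @export
hypergeom_tail <- function(k, n, m_markers, n_universe) {
  if (any(k < 0) || any(n < 0) || any(m_markers < 0))
    stop("counts must be non-negative")
  if (any(n > n_universe) || any(m_markers > n_universe))
    stop("n and M cannot exceed the universe size N")
  if (any(k > pmin(n, m_markers)))
    stop("k cannot exceed min(n, M)")
  stats::phyper(k - 1, m_markers, n_universe - m_markers, n, lower.tail = FALSE)
}

#' Associate candidate lncRNAs with immune-cell marker sets
#'
#' For each candidate lncRNA, its significantly correlated mRNAs are
#' restricted to the marker universe and tested for over-representation in
#' each cell type's marker set with [hypergeom_tail()]. A lncRNA is flagged
#' immune-disorder-related when at least one cell type shows an overlap of
#' at least `min_overlap` genes (overlaps below 3 are never considered
#' significant) at `pval < p_thresh`.
#'
#' @param candidates character vector of candidate lncRNA ids.
#' @param correlations correlation records covering the candidates (e.g.
#'   [correlation_table()] output, row-bound across lncRNAs).
#' @param markers a `GeneSetCollection` of cell-type marker sets with
#'   `universe_size` set (2025 for the reference catalogue).
#' @param p_thresh significance threshold (default 0.05).
#' @param min_overlap minimum overlap k for a test to count (default 3).
#' @param alpha,use_fdr passed to [significant_mrnas()].
#' @param restrict_universe count `n` inside the marker universe (default;
#'   keeps k, n, M, N in the same urn). `FALSE` counts all significant
#'   mRNAs.
#' @return A list with `records` (a `data.frame`: `lnc_id`, `cell_type`,
#'   `k`, `n`, `M`, `N`, `pval`, `flagged`) and `disorder_lncs` (sorted ids
#'   of flagged lncRNAs).
#' @export
associate_cells <- function(candidates, correlations, markers,
                            p_thresh = 0.05, min_overlap = 3,
                            alpha = 0.05, use_fdr = TRUE,
                            restrict_universe = TRUE) {
  stopifnot(inherits(markers, "GeneSetCollection"))
  if (!length(markers$sets)) stop("empty marker collection")
  universe <- unique(unlist(markers$sets, use.names = FALSE))
  N <- markers$universe_size
  cells <- names(markers$sets)
  out <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    lnc <- candidates[[i]]
    sig <- significant_mrnas(lnc, correlations, alpha = alpha, use_fdr = use_fdr)
    drawn <- if (restrict_universe) intersect(sig, universe) else sig
    n <- length(drawn)
    k <- vapply(markers$sets, function(mk) length(intersect(drawn, mk)), integer(1))
    M <- lengths(markers$sets)
    pval <- if (n == 0) rep(1, length(cells)) else
      hypergeom_tail(k, min(n, N), M, N)
    out[[i]] <- data.frame(lnc_id = lnc, cell_type = cells, k = as.integer(k),
                           n = n, M = as.integer(M), N = N, pval = pval,
                           flagged = k >= min_overlap & pval < p_thresh,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  records <- do.call(rbind, out)
  disorder <- sort(unique(records$lnc_id[records$flagged]))
  list(records = records, disorder_lncs = disorder)
}

#' Intersect the two candidate lncRNA sets
#'
#' Final candidates are lncRNAs that pass both the pathway-level lncRES
#' screen and the immune-cell marker association.
#'
#' @param immune_lncs ids passing [screen_immune_lncrnas()].
#' @param disorder_lncs ids flagged by [associate_cells()].
#' @return Sorted character vector; a warning is raised when empty.
#' @export
intersect_candidates <- function(immune_lncs, disorder_lncs) {
  res <- sort(intersect(immune_lncs, disorder_lncs))
  if (!length(res)) warning("candidate intersection is empty")
  res
}
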