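# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: explicit loops, direct combinatorial sums, and
# permutation nulls.

# enrichment score by a literal position-by-position walk
brute_force_es <- function(genes, scores, gene_set, weight_exponent = 1) {
  N <- length(genes)
  hit <- genes %in% gene_set
  n_i <- sum(hit)
  n_r <- sum(abs(scores[hit])^weight_exponent)
  p_hit <- p_miss <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) p_hit <- p_hit + abs(scores[i])^weight_exponent / n_r
    else p_miss <- p_miss + 1 / (N - n_i)
    dev <- p_hit - p_miss
    if (abs(dev) > abs(best) + 1e-12) best <- dev
  }
  best
}

# Benjamini-Hochberg step-up by explicit sort / cummin
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (idx in seq_along(ord)) {
    i <- ord[idx]
    rank_i <- m - idx + 1
    running <- min(running, p[i] * m / rank_i)
    adj[i] <- min(running, 1)
  }
  adj
}

# upper-tail hypergeometric by direct summation of choose() terms
hyper_oracle <- function(k, n, M, N) {
  total <- 0
  for (j in seq(k, min(n, M))) {
    total <- total + choose(M, j) * choose(N - M, n - j)
  }
  total / choose(N, n)
}

# a RankedGeneList without going through build_ranked_list
make_ranked <- function(scores, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%04d", seq_along(scores))
  ord <- order(-scores, ids)
  structure(list(lnc_id = "test", genes = ids[ord], scores = scores[ord],
                 N = length(scores)),
            class = "RankedGeneList")
}

# tiny deterministic bundle for interface-level tests
make_tiny_bundle <- function(m = 20, n_lnc = 3, n_mrna = 8, seed = 99) {
  set.seed(seed)
  lnc <- matrix(rnorm(n_lnc * m), n_lnc, m,
                dimnames = list(sprintf("L%02d", seq_len(n_lnc)),
                                sprintf("S%02d", seq_len(m))))
  mr <- matrix(rnorm(n_mrna * m), n_mrna, m,
               dimnames = list(sprintf("G%02d", seq_len(n_mrna)),
                               sprintf("S%02d", seq_len(m))))
  pur <- stats::setNames(runif(m, 0.3, 0.95), colnames(lnc))
  expression_bundle(lnc, mr, pur)
}

# a reduced-scale synthetic cohort shared by several slower tests
shared_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(n_samples = 200, n_mrna = 600, n_lnc = 60,
                                n_pathways = 6, n_cell_types = 8,
                                n_drivers = 6, n_confounded = 6,
                                marker_universe = 600, seed = 424)
    cache
  }
})
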