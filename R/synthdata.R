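#' Simulate a purity-confounded tumor cohort with known immune structure
#'
#' Generates a seeded synthetic cohort with the statistical structure the
#' discovery pipeline assumes, plus ground-truth labels for every implanted
#' effect, so each downstream stage can be validated without external data.
#'
#' The generative model, per sample:
#' * tumor purity ~ Beta(5, 2); the standardized immune load is
#'   `u = scale(1 - purity)` — immune content occupies the non-tumor
#'   fraction of the bulk sample.
#' * each immune pathway `k` has a latent activity
#'   `a_k = 3 u + e_k + m(k, subtype)`, `e_k ~ N(0, 4)`: pathway activity is
#'   correlated with (1 - purity), retains a purity-independent component,
#'   and is shifted per subtype (`m(k, s) ~ N(0, subtype_sd^2)`) — immune
#'   subtypes are infiltration states, so the subtype signal rides on the
#'   pathway activities.
#' * pathway member mRNAs: `baseline + pathway_loading * a_k + N(0, 1)`.
#'   Expressed marker genes outside every pathway get a mild direct
#'   immune loading `0.15 u`. All other mRNAs are `baseline + N(0, 1)`.
#' * driver lncRNAs: `baseline + gamma * a_k + N(0, 1)` — their coupling to
#'   pathway genes survives purity adjustment through the shared
#'   purity-independent part of `a_k`, and the subtype shifts reach them
#'   through `a_k` as well.
#' * confounded lncRNAs: `baseline + delta * u + N(0, 1)` — marginally
#'   correlated with immune genes, but the association vanishes once purity
#'   is regressed out.
#' * null lncRNAs: `baseline + N(0, 1)`.
#' * a block of subtype-responsive mRNAs (containing the risk genes) gets
#'   its own per-subtype mean offsets, so the
#'   differential-expression-to-Cox chain has signal that is not purely
#'   immune.
#' * survival: times are exponential with hazard proportional to
#'   `exp(beta_scale * sum(beta_g * z_g))` over the implanted risk genes
#'   (z = standardized expression); independent uniform censoring is
#'   calibrated to the requested censoring fraction.
#'
#' Marker sets: `n_cell_types` immune-cell marker sets whose union is
#' `marker_universe` genes (2025 at defaults, the size of the reference
#' marker catalogue); roughly three quarters of the markers are rows of the
#' mRNA matrix, the remainder are catalogue genes not expressed in the
#' cohort (a situation the association stage must tolerate). Each immune
#' pathway draws its members from the expressed markers of one cell type, so
#' driver lncRNAs are recoverable by the marker-association stage as well.
#'
#' @param n_samples,n_mrna,n_lnc cohort dimensions.
#' @param n_pathways number of immune pathways (latent factors).
#' @param n_cell_types number of immune-cell marker sets (default 24).
#' @param n_drivers,n_confounded number of truly-coupled and
#'   purity-confounded lncRNAs; the remainder are null.
#' @param gamma coupling of driver lncRNAs to their pathway's latent
#'   activity (units of noise SD).
#' @param delta coupling of confounded lncRNAs to (1 - purity).
#' @param K_true number of implanted sample subtypes.
#' @param subtype_sd SD of the per-subtype shifts of the pathway latent
#'   activities (the subtype-responsive mRNA offsets have unit SD).
#' @param pathway_loading loading of pathway member mRNAs on their
#'   pathway's latent activity. The default keeps within-pathway
#'   purity-adjusted co-expression modest; large values make pathway genes
#'   move as a block in every ranked list, which inflates enrichment
#'   scores for unrelated lncRNAs (see the methods vignette).
#' @param n_risk_genes number of mRNAs with non-zero Cox coefficients.
#' @param beta_scale multiplier on the implanted log-hazard coefficients;
#'   0 gives a survival-neutral cohort.
#' @param censor_frac target fraction of censored samples in \[0,1).
#' @param marker_universe total distinct marker genes across the cell-type
#'   sets (default 2025).
#' @param pathway_size genes per immune pathway.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return A list of class `SyntheticCohort`: `bundle`
#'   (an [expression_bundle()], log2-scale values), `pathways` and `markers`
#'   ([gene_set_collection()]s), `survival` (a [survival_table()]), and
#'   `truth` (driver/confounded/null lncRNA ids, the driver-to-pathway map,
#'   subtype labels, the latent pathway activities, risk-gene coefficients,
#'   subtype-responsive mRNAs).
#' @examples
#' sim <- simulate_cohort(n_samples = 60, n_mrna = 300, n_lnc = 60,
#'                        n_pathways = 4, n_cell_types = 6,
#'                        marker_universe = 180, seed = 1)
#' sim$bundle
#' @export
simulate_cohort <- function(n_samples = 200, n_mrna = 2000, n_lnc = 500,
                            n_pathways = 10, n_cell_types = 24,
                            n_drivers = 15, n_confounded = 15,
                            gamma = 1, delta = 2,
                            K_true = 4, subtype_sd = 3.5,
                            n_risk_genes = 10, beta_scale = 1,
                            censor_frac = 0.4,
                            marker_universe = 2025, pathway_size = 15,
                            pathway_loading = 0.15, seed = NULL) {
  if (min(n_samples, n_mrna, n_lnc, n_pathways, n_cell_types) < 2)
    stop("all cohort dimensions must be at least 2")
  if (K_true < 2) stop("K_true must be at least 2")
  if (censor_frac < 0 || censor_frac >= 1) stop("censor_frac must be in [0, 1)")
  if (n_drivers + n_confounded > n_lnc)
    stop("n_drivers + n_confounded exceeds n_lnc")
  if (!is.null(seed)) set.seed(seed)
  if (gamma == 0 && delta == 0)
    warning("gamma = delta = 0: no immune coupling is implanted; ",
            "recovery checks will have nothing to recover")

  samples <- sprintf("S%03d", seq_len(n_samples))
  mrna_ids <- sprintf("G%04d", seq_len(n_mrna))
  lnc_ids <- sprintf("LNC%04d", seq_len(n_lnc))

  purity <- stats::rbeta(n_samples, 5, 2)
  names(purity) <- samples
  u <- as.numeric(scale(1 - purity))

  # subtype labels, near-balanced; subtype effects enter through the
  # pathway activities (immune subtypes are infiltration states)
  labels <- sample(rep(seq_len(K_true), length.out = n_samples))
  names(labels) <- samples
  # subtype activity profiles: max-min design over a few Gaussian draws so
  # that no two "distinct" subtypes coincide by chance
  draw_profiles <- function() matrix(stats::rnorm(K_true * n_pathways,
                                                  sd = subtype_sd),
                                     K_true, n_pathways)
  best <- -Inf
  M <- NULL
  for (try in seq_len(20)) {
    cand <- draw_profiles()
    sep <- min(stats::dist(cand))
    if (sep > best) { best <- sep; M <- cand }
  }

  # latent immune pathway activities: immune load (weight 3 so that marker
  # and pathway genes are visibly purity-confounded at the margin), a
  # purity-independent component, and the subtype shift
  A <- vapply(seq_len(n_pathways),
              function(k) 3 * u + stats::rnorm(n_samples, sd = 2) + M[labels, k],
              numeric(n_samples))                       # samples x pathways

  # ---- marker catalogue and pathways --------------------------------------
  n_expressed_markers <- min(floor(0.75 * marker_universe), n_mrna)
  expressed_markers <- sample(mrna_ids, n_expressed_markers)
  n_ghost <- marker_universe - n_expressed_markers
  ghost_markers <- if (n_ghost > 0) sprintf("MKR%04d", seq_len(n_ghost)) else character(0)
  pool <- sample(c(expressed_markers, ghost_markers))
  sizes <- rep(marker_universe %/% n_cell_types, n_cell_types)
  extra <- marker_universe %% n_cell_types
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  marker_sets <- split(pool, rep(seq_len(n_cell_types), times = sizes))
  names(marker_sets) <- sprintf("cell_%02d", seq_len(n_cell_types))
  markers <- gene_set_collection(marker_sets, universe_size = marker_universe)

  pathway_sets <- vector("list", n_pathways)
  pathway_cell <- integer(n_pathways)
  for (k in seq_len(n_pathways)) {
    cell <- ((k - 1L) %% n_cell_types) + 1L
    pathway_cell[k] <- cell
    avail <- intersect(marker_sets[[cell]], expressed_markers)
    if (length(avail) < 3) stop("cell type has too few expressed markers for a pathway")
    pathway_sets[[k]] <- sample(avail, min(pathway_size, length(avail)))
  }
  names(pathway_sets) <- sprintf("pathway_%02d", seq_len(n_pathways))
  pathways <- gene_set_collection(pathway_sets)

  # ---- mRNA matrix --------------------------------------------------------
  base_m <- stats::runif(n_mrna, 3, 8)
  mrna <- matrix(stats::rnorm(n_mrna * n_samples), n_mrna, n_samples,
                 dimnames = list(mrna_ids, samples)) + base_m
  pathway_members <- unique(unlist(pathway_sets, use.names = FALSE))
  for (k in seq_len(n_pathways)) {
    idx <- match(pathway_sets[[k]], mrna_ids)
    mrna[idx, ] <- mrna[idx, ] + pathway_loading * rep(A[, k], each = length(idx))
  }
  free_markers <- setdiff(expressed_markers, pathway_members)
  if (length(free_markers))
    mrna[match(free_markers, mrna_ids), ] <-
      mrna[match(free_markers, mrna_ids), ] +
      rep(0.15 * u, each = length(free_markers))

  # subtype-responsive mRNAs (risk genes among them) drawn outside the
  # immune blocks so prognostic and immune signals stay separable
  free_mrna <- setdiff(mrna_ids, c(pathway_members, free_markers))
  n_resp <- min(length(free_mrna), n_risk_genes + 40L)
  if (n_resp < n_risk_genes) stop("not enough free mRNAs for the risk genes")
  responsive <- sample(free_mrna, n_resp)
  resp_offsets <- matrix(stats::rnorm(K_true * n_resp, sd = 1), K_true, n_resp)
  mrna[match(responsive, mrna_ids), ] <-
    mrna[match(responsive, mrna_ids), ] + t(resp_offsets[labels, , drop = FALSE])

  # ---- lncRNA matrix ------------------------------------------------------
  base_l <- stats::runif(n_lnc, 1, 5)
  lnc <- matrix(stats::rnorm(n_lnc * n_samples), n_lnc, n_samples,
                dimnames = list(lnc_ids, samples)) + base_l
  ids_shuffled <- sample(lnc_ids)
  driver_ids <- sort(ids_shuffled[seq_len(n_drivers)])
  confounded_ids <- sort(ids_shuffled[n_drivers + seq_len(n_confounded)])
  null_ids <- sort(setdiff(lnc_ids, c(driver_ids, confounded_ids)))

  driver_pathway <- stats::setNames(
    ((seq_len(n_drivers) - 1L) %% n_pathways) + 1L, driver_ids)
  for (d in seq_len(n_drivers)) {
    i <- match(driver_ids[d], lnc_ids)
    lnc[i, ] <- lnc[i, ] + gamma * A[, driver_pathway[d]]
  }
  if (n_confounded > 0) {
    idx <- match(confounded_ids, lnc_ids)
    lnc[idx, ] <- lnc[idx, ] + rep(delta * u, each = length(idx))
  }

  bundle <- expression_bundle(lnc, mrna, purity)

  # ---- survival -----------------------------------------------------------
  risk_ids <- sort(sample(responsive, n_risk_genes))
  beta <- stats::setNames(
    beta_scale * sample(c(-1, 1), n_risk_genes, replace = TRUE) *
      stats::runif(n_risk_genes, 0.4, 0.8),
    risk_ids)
  z <- t(scale(t(mrna[match(risk_ids, mrna_ids), , drop = FALSE])))
  lp <- as.numeric(crossprod(z, beta))
  base_rate <- log(2) / 730     # median ~2 years at lp = 0
  t_event <- stats::rexp(n_samples, rate = base_rate * exp(lp))
  if (censor_frac > 0) {
    # expected censored fraction under C ~ U(0, cmax) is mean(pmin(T/cmax, 1))
    f <- function(cmax) mean(pmin(t_event / cmax, 1)) - censor_frac
    cmax <- stats::uniroot(f, lower = min(t_event) * 1e-3,
                           upper = max(t_event) * 1e3, tol = 1e-8)$root
    cens <- stats::runif(n_samples, 0, cmax)
  } else {
    cens <- rep(Inf, n_samples)
  }
  obs_time <- pmax(pmin(t_event, cens), 1e-3)
  event <- as.integer(t_event <= cens)
  surv <- survival_table(samples, obs_time, event)

  truth <- list(
    driver_lncs = driver_ids,
    confounded_lncs = confounded_ids,
    null_lncs = null_ids,
    driver_pathway = stats::setNames(names(pathway_sets)[driver_pathway], driver_ids),
    pathway_cell = stats::setNames(names(marker_sets)[pathway_cell], names(pathway_sets)),
    subtype_labels = labels,
    pathway_activity = A,
    risk_genes = beta,
    responsive_mrnas = responsive,
    gamma = gamma, delta = delta, K_true = K_true,
    beta_scale = beta_scale, censor_frac = censor_frac
  )
  structure(list(bundle = bundle, pathways = pathways, markers = markers,
                 survival = surv, truth = truth),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort\n")
  print(x$bundle)
  cat(sprintf("  %d drivers, %d confounded, %d null lncRNAs; K_true = %d\n",
              length(x$truth$driver_lncs), length(x$truth$confounded_lncs),
              length(x$truth$null_lncs), x$truth$K_true))
  cat(sprintf("  %d pathways, %d marker sets (universe %d); %d risk genes; %.0f%% censored\n",
              length(x$pathways$sets), length(x$markers$sets),
              x$markers$universe_size, length(x$truth$risk_genes),
              100 * mean(x$survival$event == 0)))
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits the expression TSV (all genes), the gene-type annotation TSV, the
#' purity TSV, pathway and marker GMTs, the survival TSV and the
#' ground-truth JSON, i.e. exactly the files [read_expression()],
#' [read_gmt()], [read_survival()] and [run_pipeline()] consume.
#'
#' @param sim a `SyntheticCohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into a non-empty directory.
#' @param digits significant digits for expression values (15 preserves the
#'   values to within round-trip noise well below 1e-12).
#' @return Named character vector of the file paths written.
#' @export
write_fixture <- function(sim, dir, overwrite = FALSE, digits = 15L) {
  stopifnot(inherits(sim, "SyntheticCohort"))
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " is not empty; set overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$bundle
  expr <- rbind(b$lnc_expr, b$mrna_expr)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    purity = file.path(dir, "purity.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    markers = file.path(dir, "markers.gmt"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(expr, paths[["expression"]], digits = digits)
  utils::write.table(
    data.frame(gene_id = rownames(expr),
               type = rep(c("lncRNA", "mRNA"), c(nrow(b$lnc_expr), nrow(b$mrna_expr)))),
    paths[["annotation"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(b$purity),
               purity = formatC(b$purity, digits = digits, format = "g")),
    paths[["purity"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$pathways, paths[["pathways"]])
  write_gmt(sim$markers, paths[["markers"]])
  utils::write.table(sim$survival, paths[["survival"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$pathway_activity <- NULL
  truth$subtype_labels <- as.list(truth$subtype_labels)
  truth$risk_genes <- as.list(truth$risk_genes)
  truth$driver_pathway <- as.list(truth$driver_pathway)
  truth$pathway_cell <- as.list(truth$pathway_cell)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
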