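#' Default pipeline configuration
#'
#' Returns the full configuration list with every threshold at its default
#' (the values used throughout the package documentation): lncRES screen
#' 0.995, marker-association p 0.05 with minimum overlap 3, consensus k in
#' 2..9, DE thresholds p 0.01 and |log2FC| 1, univariate Cox p 0.05.
#' User-supplied configuration files override individual keys.
#'
#' @return Nested named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    counts_are_raw = FALSE,
    seed = 1L,
    thresholds = list(
      lncres_threshold = 0.995,
      lncres_two_sided = FALSE,
      sig_alpha = 0.05,
      sig_use_fdr = TRUE,
      hyper_p = 0.05,
      min_overlap = 3L,
      k_min = 2L,
      k_max = 9L,
      de_p = 0.01,
      de_lfc = 1,
      cox_p = 0.05,
      weight_exponent = 0,
      ssgsea_alpha = 0.25,
      adjust_purity = TRUE,
      cluster_adjust_purity = TRUE
    ),
    consensus = list(n_resamples = 1000L, subsample_frac = 0.8),
    horizons = c(365, 1095, 1825)
  )
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(extra[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]])
    else base[[nm]] <- extra[[nm]]
  }
  base
}

#' Run the full discovery / subtyping / prognosis pipeline
#'
#' Executes every stage in order on the inputs named in a YAML
#' configuration file: read and preprocess, lncRES scoring and screen,
#' immune-cell marker association and intersection, consensus clustering of
#' samples on the candidate lncRNAs, ssGSEA immune scoring with
#' between-subtype tests, differential expression between the two subtypes
#' with the most divergent survival, the univariate-then-multivariate Cox
#' risk model, median risk stratification with Kaplan-Meier / log-rank and
#' time-dependent AUC, and (when external cohort paths are configured)
#' application of the frozen model to the external cohort. All result
#' tables are TSV; the machine-readable run log is JSON. With the same
#' configuration and seed the output tables are byte-identical across runs.
#'
#' Required configuration keys: `expression`, `annotation`, `purity`,
#' `pathways`, `markers`, `survival`, `out_dir`. Optional:
#' `external_expression`, `external_annotation`, `external_purity`,
#' `external_survival`, `counts_are_raw`, `seed`, and any key of
#' [default_config()].
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list.
#' @param out_dir optional override of the configured output directory.
#' @return Invisibly, a list with the principal results (`candidates`,
#'   `subtypes`, `model`, `strata`, `auc`, ...) and the path of every file
#'   written. Missing inputs raise an error before any computation; a
#'   failing stage raises an error after flagging the partial outputs in
#'   the run log.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(default_config(), cfg)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  req <- c("expression", "annotation", "purity", "pathways", "markers",
           "survival", "out_dir")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("configuration missing key(s): ",
                         paste(miss, collapse = ", "))
  inputs <- unlist(cfg[intersect(names(cfg),
                                 c(req[-7], paste0("external_",
                                   c("expression", "annotation", "purity",
                                     "survival"))))])
  absent <- inputs[!file.exists(inputs)]
  if (length(absent)) stop("input file(s) not found: ",
                           paste(absent, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  set.seed(cfg$seed)

  log <- list(seed = cfg$seed, thresholds = th, status = "running",
              stages = list())
  files <- character(0)
  emit <- function(name, d) {
    path <- file.path(cfg$out_dir, name)
    write_df_tsv(d, path)
    files[[name]] <<- path
    path
  }
  flush_log <- function() {
    jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fail <- function(stage, msg) {
    log$status <<- "failed"
    log$failed_stage <<- stage
    log$partial_outputs <<- names(files)
    flush_log()
    stop(sprintf("pipeline stage '%s' failed: %s", stage, msg), call. = FALSE)
  }

  # -- stage: input ---------------------------------------------------------
  message("stage input: thresholds ", jsonlite::toJSON(th, auto_unbox = TRUE))
  bundle <- preprocess(read_expression(cfg$expression, cfg$annotation, cfg$purity),
                       counts_are_raw = isTRUE(cfg$counts_are_raw))
  pathways <- read_gmt(cfg$pathways)
  markers <- read_gmt(cfg$markers)
  surv <- read_survival(cfg$survival)
  log$stages$input <- list(n_samples = length(bundle$sample_ids),
                           n_lnc = nrow(bundle$lnc_expr),
                           n_mrna = nrow(bundle$mrna_expr),
                           n_pathways = length(pathways$sets),
                           n_marker_sets = length(markers$sets),
                           marker_universe = markers$universe_size)

  # -- stage: lncres --------------------------------------------------------
  message(sprintf("stage lncres: screen lncRES > %g", th$lncres_threshold))
  enr <- lncres_table(bundle, pathways,
                      weight_exponent = th$weight_exponent,
                      adjust_purity = isTRUE(th$adjust_purity))
  enr$passed <- !is.na(enr$lncres) &
    (if (isTRUE(th$lncres_two_sided)) abs(enr$lncres) else enr$lncres) >
      th$lncres_threshold
  emit("lncres.tsv", enr)
  immune_lncs <- screen_immune_lncrnas(enr, threshold = th$lncres_threshold,
                                       two_sided = isTRUE(th$lncres_two_sided))
  log$stages$lncres <- list(n_scored = length(unique(enr$lnc_id)),
                            n_immune = length(immune_lncs))
  if (length(immune_lncs) < 2)
    fail("lncres", "fewer than 2 lncRNAs pass the lncRES screen")

  # -- stage: cellassoc -----------------------------------------------------
  message(sprintf("stage cellassoc: p < %g, k >= %d", th$hyper_p, th$min_overlap))
  cors <- do.call(rbind, lapply(immune_lncs, correlation_table, bundle = bundle,
                                adjust_purity = isTRUE(th$adjust_purity)))
  assoc <- associate_cells(immune_lncs, cors, markers,
                           p_thresh = th$hyper_p, min_overlap = th$min_overlap,
                           alpha = th$sig_alpha, use_fdr = isTRUE(th$sig_use_fdr))
  emit("cell_association.tsv", assoc$records)
  candidates <- tryCatch(
    intersect_candidates(immune_lncs, assoc$disorder_lncs),
    warning = function(w) character(0))
  emit("candidates.tsv", data.frame(lnc_id = candidates))
  log$stages$cellassoc <- list(n_disorder = length(assoc$disorder_lncs),
                               n_candidates = length(candidates))
  if (length(candidates) < 2)
    fail("cellassoc", "fewer than 2 candidate lncRNAs after intersection")

  # -- stage: cluster -------------------------------------------------------
  message(sprintf("stage cluster: k in %d..%d", th$k_min, th$k_max))
  clus_mat <- bundle$lnc_expr[candidates, , drop = FALSE]
  if (isTRUE(th$cluster_adjust_purity))
    clus_mat <- purity_residuals(clus_mat, bundle$purity)
  cons <- consensus_cluster(clus_mat,
                            k_range = th$k_min:th$k_max,
                            n_resamples = cfg$consensus$n_resamples,
                            subsample_frac = cfg$consensus$subsample_frac,
                            seed = cfg$seed)
  labels <- cons$labels[[paste0("k", cons$k_opt)]]
  emit("subtypes.tsv", data.frame(sample_id = names(labels),
                                  subtype = as.integer(labels)))
  emit("consensus_stability.tsv", cons$stability)
  log$stages$cluster <- list(k_opt = cons$k_opt,
                             sizes = as.integer(table(labels)))

  # -- stage: score ---------------------------------------------------------
  message(sprintf("stage score: ssGSEA alpha %g", th$ssgsea_alpha))
  cell_scores <- score_all(bundle, markers, alpha = th$ssgsea_alpha)
  sc <- data.frame(sample_id = rownames(cell_scores), cell_scores,
                   check.names = FALSE)
  emit("ssgsea_cells.tsv", sc)
  tests <- do.call(rbind, lapply(colnames(cell_scores), function(ct) {
    byg <- split(cell_scores[, ct], labels[rownames(cell_scores)])
    byg <- byg[lengths(byg) >= 3]
    if (length(byg) < 2) return(NULL)
    ht <- compare_groups(byg)
    data.frame(set = ct, statistic = ht$statistic, pval = ht$pval,
               test = ht$test, stringsAsFactors = FALSE)
  }))
  if (!is.null(tests)) emit("ssgsea_tests.tsv", tests)

  # -- stage: de ------------------------------------------------------------
  # pick the two subtypes with the most divergent survival (largest
  # prognostic contrast drives the downstream DE and risk model)
  pairs <- utils::combn(sort(unique(labels)), 2, simplify = FALSE)
  pick <- NULL; pick_p <- Inf
  for (pr in pairs) {
    in_pair <- labels %in% pr
    if (sum(labels == pr[1]) < 3 || sum(labels == pr[2]) < 3) next
    sdf <- align_survival(surv, names(labels)[in_pair])
    grp <- factor(ifelse(labels[sdf$sample_id] == pr[1], "low", "high"),
                  levels = c("low", "high"))
    if (sum(sdf$event) == 0) next
    sd_ <- tryCatch(survival::survdiff(
      survival::Surv(sdf$time, sdf$event) ~ grp), error = function(e) NULL)
    if (is.null(sd_)) next
    p <- stats::pchisq(sd_$chisq, 1, lower.tail = FALSE)
    if (p < pick_p) { pick_p <- p; pick <- pr }
  }
  if (is.null(pick)) fail("de", "no subtype pair admits a survival contrast")
  message(sprintf("stage de: subtypes %d vs %d (log-rank p = %.3g), p < %g, |log2FC| > %g",
                  pick[1], pick[2], pick_p, th$de_p, th$de_lfc))
  pair_samples <- names(labels)[labels %in% pick]
  de <- de_screen(bundle$mrna_expr[, pair_samples, drop = FALSE],
                  labels[pair_samples], p_thresh = th$de_p,
                  lfc_thresh = th$de_lfc)
  emit("de_genes.tsv", de)
  degs <- de$gene_id[de$passed]
  log$stages$de <- list(pair = as.integer(pick), logrank_p = pick_p,
                        n_degs = length(degs))
  if (length(degs) < 1) fail("de", "no differentially expressed genes")

  # -- stage: prognosis -----------------------------------------------------
  message(sprintf("stage prognosis: univariate p < %g", th$cox_p))
  uni <- univariate_cox_screen(bundle$mrna_expr[degs, , drop = FALSE], surv,
                               p_thresh = th$cox_p)
  emit("univariate_cox.tsv", uni)
  panel <- uni$gene_id[uni$passed]
  if (length(panel) < 1) fail("prognosis", "no gene passes the univariate screen")
  guard <- max(1L, floor(length(bundle$sample_ids) / 5))
  if (length(panel) > guard) {
    message(sprintf("stage prognosis: truncating panel from %d to %d genes ",
                    length(panel), guard),
            "(events-per-variable guard)")
    panel <- panel[order(uni$pval[match(panel, uni$gene_id)])][seq_len(guard)]
  }
  model <- fit_risk_model(bundle$mrna_expr, surv, panel)
  jsonlite::write_json(
    list(genes = model$genes, coefs = as.list(model$coefs),
         score_mode = model$score_mode, cutoff = model$cutoff),
    file.path(cfg$out_dir, "risk_model.json"), auto_unbox = TRUE, digits = NA)
  files[["risk_model.json"]] <- file.path(cfg$out_dir, "risk_model.json")
  scores <- predict(model, bundle$mrna_expr)
  strata <- stratify_median(scores)
  emit("risk_scores.tsv", as.data.frame(strata))
  km <- km_logrank(strata, surv)
  auc <- time_dependent_auc(scores, surv, horizons = cfg$horizons)
  emit("survival_summary.tsv",
       data.frame(metric = c("logrank_chisq", "logrank_p",
                             paste0("auc_", names(auc))),
                  value = c(km$chisq, km$pval, unname(auc))))
  log$stages$prognosis <- list(n_panel = length(panel), cutoff = model$cutoff,
                               logrank_p = km$pval, auc = as.list(auc))

  # -- stage: external ------------------------------------------------------
  ext <- NULL
  if (!is.null(cfg$external_expression)) {
    message("stage external: applying frozen model")
    ebundle <- preprocess(read_expression(cfg$external_expression,
                                          cfg$external_annotation,
                                          cfg$external_purity),
                          counts_are_raw = isTRUE(cfg$counts_are_raw))
    esurv <- read_survival(cfg$external_survival)
    ext <- apply_external(model, ebundle, esurv,
                          allow_missing = TRUE, horizons = cfg$horizons)
    emit("external_risk_scores.tsv", as.data.frame(ext$strata))
    emit("external_summary.tsv",
         data.frame(metric = c("logrank_p", "cindex",
                               paste0("auc_", names(ext$auc))),
                    value = c(ext$km$pval, ext$cindex, unname(ext$auc))))
    log$stages$external <- list(logrank_p = ext$km$pval, cindex = ext$cindex)
  }

  log$status <- "ok"
  flush_log()
  files[["run_log.json"]] <- file.path(cfg$out_dir, "run_log.json")
  invisible(list(bundle = bundle, enrichment = enr, immune_lncs = immune_lncs,
                 association = assoc, candidates = candidates,
                 consensus = cons, subtypes = labels, cell_scores = cell_scores,
                 de = de, univariate = uni, model = model, scores = scores,
                 strata = strata, km = km, auc = auc, external = ext,
                 files = files, config = cfg))
}
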