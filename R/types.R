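#' Assemble an expression bundle
#'
#' An `ExpressionBundle` holds the aligned pieces every downstream stage
#' consumes: a lncRNA expression matrix, an mRNA expression matrix (both
#' genes x samples, log2 units after [preprocess()]) and a per-sample tumor
#' purity vector. Purity is the malignant-cell fraction of each bulk sample;
#' its complement contains the immune and stromal compartment, which is why
#' it enters every correlation as a covariate.
#'
#' @param lnc_expr numeric matrix, lncRNAs in rows, samples in columns.
#' @param mrna_expr numeric matrix, mRNAs in rows, samples in columns.
#' @param purity named numeric vector of tumor-purity fractions in \[0,1\],
#'   one per sample.
#' @return An object of class `ExpressionBundle`: a list with elements
#'   `lnc_expr`, `mrna_expr`, `purity`, `sample_ids`.
#' @examples
#' lnc <- matrix(rnorm(8), 2, 4, dimnames = list(c("L1", "L2"), paste0("S", 1:4)))
#' mr  <- matrix(rnorm(12), 3, 4, dimnames = list(c("G1", "G2", "G3"), paste0("S", 1:4)))
#' pur <- setNames(runif(4, 0.4, 0.9), paste0("S", 1:4))
#' b <- expression_bundle(lnc, mr, pur)
#' b
#' @export
expression_bundle <- function(lnc_expr, mrna_expr, purity) {
  lnc_expr <- as.matrix(lnc_expr)
  mrna_expr <- as.matrix(mrna_expr)
  if (is.null(rownames(lnc_expr)) || is.null(rownames(mrna_expr)))
    stop("expression matrices must have gene ids as rownames")
  if (is.null(colnames(lnc_expr)) || is.null(colnames(mrna_expr)))
    stop("expression matrices must have sample ids as colnames")
  if (is.null(names(purity))) {
    if (length(purity) != ncol(lnc_expr))
      stop("purity has no names and its length does not match the samples")
    names(purity) <- colnames(lnc_expr)
  }
  samples <- colnames(lnc_expr)
  if (!identical(colnames(mrna_expr), samples))
    stop("sample ids differ between lncRNA and mRNA matrices")
  missing_p <- setdiff(samples, names(purity))
  if (length(missing_p))
    stop("samples missing from purity: ", paste(utils::head(missing_p, 5), collapse = ", "))
  purity <- purity[samples]
  if (anyNA(purity) || any(purity < 0 | purity > 1))
    stop("purity values must lie in [0, 1] with no missing entries")
  dup <- c(rownames(lnc_expr)[duplicated(rownames(lnc_expr))],
           rownames(mrna_expr)[duplicated(rownames(mrna_expr))])
  if (length(dup))
    stop("duplicated gene ids: ", paste(unique(dup), collapse = ", "))
  structure(
    list(lnc_expr = lnc_expr, mrna_expr = mrna_expr,
         purity = purity, sample_ids = samples),
    class = "ExpressionBundle"
  )
}

#' @export
print.ExpressionBundle <- function(x, ...) {
  cat("ExpressionBundle\n")
  cat(sprintf("  %d lncRNAs x %d samples; %d mRNAs\n",
              nrow(x$lnc_expr), length(x$sample_ids), nrow(x$mrna_expr)))
  cat(sprintf("  purity: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$purity), min(x$purity), max(x$purity)))
  invisible(x)
}

#' Build a gene-set collection
#'
#' Container for named gene sets (immune pathways, or the marker genes of the
#' 24 immune cell types) together with the size of the gene universe used by
#' the hypergeometric association test.
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe_size integer, number of genes eligible for membership
#'   (the distinct union of all sets by default). For the immune-cell marker
#'   collection of the reference catalogue this is 2025.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, universe_size = NULL) {
  if (!length(sets)) stop("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must have unique non-empty names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  if (is.null(universe_size))
    universe_size <- length(unique(unlist(sets, use.names = FALSE)))
  universe_size <- as.integer(universe_size)
  if (universe_size < max(lengths(sets)))
    stop("universe_size smaller than the largest set")
  structure(list(sets = sets, universe_size = universe_size),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d, universe %d genes\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              x$universe_size))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Build a survival table
#'
#' @param sample_id character vector of unique sample ids.
#' @param time follow-up time in days, strictly positive.
#' @param event 1 = death observed, 0 = censored.
#' @return A `data.frame` of class `SurvivalTable` with columns
#'   `sample_id`, `time`, `event`.
#' @export
survival_table <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicated sample ids in survival table")
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(sample_id) || length(event) != length(sample_id))
    stop("sample_id, time and event must have equal length")
  if (anyNA(time) || any(time <= 0)) stop("survival times must be strictly positive")
  if (anyNA(event) || !all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  structure(data.frame(sample_id = sample_id, time = time, event = event,
                       stringsAsFactors = FALSE),
            class = c("SurvivalTable", "data.frame"))
}

# samples of a bundle, defensive accessor used across modules
bundle_samples <- function(bundle) {
  stopifnot(inherits(bundle, "ExpressionBundle"))
  bundle$sample_ids
}
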