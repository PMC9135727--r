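#' Read an expression matrix with gene annotation and tumor purity
#'
#' Reads a genes-in-rows TSV expression matrix (header row = sample ids),
#' splits genes into the lncRNA and mRNA namespaces using an annotation
#' table, attaches per-sample tumor purity and returns an aligned
#' [expression_bundle()]. Unannotated genes are dropped with a message.
#' Values are returned as found on disk; apply [preprocess()] afterwards for
#' the not-expressed filter and (for raw counts) the log2 transform.
#'
#' A matrix accidentally written samples-in-rows is rejected rather than
#' silently transposed: if most of the column headers look like annotated
#' gene ids the orientation is considered wrong.
#'
#' @param expr_path TSV, first column gene id, remaining columns samples.
#' @param annotation_path TSV with columns `gene_id` and `type`, `type`
#'   being `lncRNA` or `mRNA`.
#' @param purity_path TSV with columns `sample_id` and `purity` (fraction in
#'   \[0,1\]).
#' @return An `ExpressionBundle`.
#' @export
read_expression <- function(expr_path, annotation_path, purity_path) {
  expr <- read_matrix_tsv(expr_path)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "type") %in% names(ann)))
    stop("annotation must have columns 'gene_id' and 'type'")
  ann$gene_id <- trimws(ann$gene_id)
  if (anyDuplicated(ann$gene_id))
    stop("duplicated gene ids in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  bad_type <- setdiff(unique(ann$type), c("lncRNA", "mRNA"))
  if (length(bad_type))
    stop("unknown annotation type(s): ", paste(bad_type, collapse = ", "))

  # orientation guard: sample headers should not be gene ids
  overlap <- mean(colnames(expr) %in% ann$gene_id)
  if (is.finite(overlap) && overlap > 0.5)
    stop("expression matrix appears transposed (column headers are gene ids); ",
         "expected genes in rows, samples in columns")

  pur <- utils::read.delim(purity_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "purity") %in% names(pur)))
    stop("purity file must have columns 'sample_id' and 'purity'")
  purity <- stats::setNames(as.numeric(pur$purity), trimws(pur$sample_id))
  missing_p <- setdiff(colnames(expr), names(purity))
  if (length(missing_p))
    stop("samples absent from purity file: ",
         paste(utils::head(missing_p, 5), collapse = ", "))

  type <- stats::setNames(ann$type, ann$gene_id)[rownames(expr)]
  n_drop <- sum(is.na(type))
  if (n_drop)
    message(sprintf("read_expression: dropped %d unannotated gene(s)", n_drop))
  keep <- !is.na(type)
  expr <- expr[keep, , drop = FALSE]
  type <- type[keep]
  if (!any(type == "lncRNA") || !any(type == "mRNA"))
    stop("annotation leaves one namespace empty (need both lncRNA and mRNA rows)")
  expression_bundle(expr[type == "lncRNA", , drop = FALSE],
                    expr[type == "mRNA", , drop = FALSE],
                    purity[colnames(expr)])
}

#' Filter unexpressed genes and log2-transform raw counts
#'
#' Removes genes with zero total expression across samples; when
#' `counts_are_raw` the remaining values are transformed as `log2(x + 1)`
#' (the +1 offset handles zeros in count data), otherwise values are passed
#' through unchanged.
#'
#' @param bundle an `ExpressionBundle`.
#' @param counts_are_raw logical; `TRUE` when the matrices contain raw
#'   counts.
#' @return A preprocessed `ExpressionBundle` on the log2 scale.
#' @export
preprocess <- function(bundle, counts_are_raw = FALSE) {
  stopifnot(inherits(bundle, "ExpressionBundle"))
  fix <- function(m) {
    if (counts_are_raw && any(m < 0))
      stop("negative values are not valid raw counts")
    m <- m[rowSums(m != 0) > 0, , drop = FALSE]
    if (!nrow(m)) stop("no expressed genes left after filtering")
    if (counts_are_raw) log2(m + 1) else m
  }
  expression_bundle(fix(bundle$lnc_expr), fix(bundle$mrna_expr), bundle$purity)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#' Duplicate members within a line are removed with a warning.
#'
#' @param path GMT file.
#' @param universe_size optional universe size override; default is the
#'   number of distinct genes across all sets.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path, universe_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members removed", i, fields[[1]]))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    sets[[fields[[1]]]] <- members
  }
  gene_set_collection(sets, universe_size)
}

#' Write gene sets in GMT format
#'
#' @param collection a `GeneSetCollection`.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  nm <- names(collection$sets)
  if (is.null(descriptions)) descriptions <- rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[[i]], descriptions[[i]], collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' @param path TSV with columns `sample_id`, `time` (days), `event` (0/1).
#' @return A `SurvivalTable`.
#' @export
read_survival <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(d)))
    stop("survival file must have columns sample_id, time, event")
  survival_table(d$sample_id, d$time, d$event)
}

# ---- low-level TSV helpers ------------------------------------------------

read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- trimws(as.character(d[[1]]))
  if (anyDuplicated(ids))
    stop("duplicated gene ids in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_matrix_tsv <- function(m, path, id_col = "gene_id", digits = 15L) {
  vals <- formatC(m, digits = digits, format = "g")
  out <- cbind(rownames(m), vals)
  colnames(out) <- c(id_col, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_df_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = 15L, format = "g"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
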