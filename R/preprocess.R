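#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' gzip-compressed files are handled transparently. Values must be dense and
#' numeric: missing or non-numeric cells fail loudly with their coordinates
#' rather than being imputed.
#'
#' @param path Path to the TSV (optionally .gz).
#' @param already_log2 If `FALSE`, linear values are floored at 1 and
#'   log2-transformed on load (so the minimum log2 value is 0 before any
#'   filter-policy flooring).
#' @return A numeric matrix, genes x samples.
#' @export
load_expression_matrix <- function(path, already_log2 = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fill = FALSE)
  if (ncol(raw) < 2L) stopf("'%s': need a gene-id column plus >= 1 sample", path)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stopf("'%s': duplicate gene id(s): %s", path,
          paste(utils::head(dup, 5), collapse = ", "))
  }
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))[1L]
      if (!is.na(bad))
        stopf("'%s': non-numeric value '%s' at row %d (gene %s), column '%s'",
              path, v[bad], bad, ids[bad], names(body)[j])
      body[[j]] <- num
    }
    if (anyNA(body[[j]]))
      stopf("'%s': missing value at row %d (gene %s), column '%s'",
            path, which(is.na(body[[j]]))[1L],
            ids[which(is.na(body[[j]]))[1L]], names(body)[j])
  }
  x <- as.matrix(body)
  rownames(x) <- ids
  if (!already_log2) x <- log2(pmax(x, 1))
  check_matrix(x, path)
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression_matrix()]: gene ids in the first column
#' (header `gene_id`), one column per sample.
#'
#' @param x Numeric matrix, genes x samples.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  check_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_(df, path)
}

#' Expression filter policies
#'
#' Two dialects of the non-expressed-gene filter used on log2 expression:
#' \describe{
#'   \item{`ekaryo`}{drop a gene iff its log2 value is below `low_threshold`
#'     (default 1) in \emph{all} samples; floor survivors at 1.}
#'   \item{`gemm`}{drop a gene iff its log2 value is below `low_threshold`
#'     (default 5.5) in strictly more than `max_low_frac` (default 20\%) of
#'     samples; floor survivors at 5. Used when comparing against microarray
#'     panels of engineered mouse mammary tumor models.}
#' }
#'
#' @param mode `"ekaryo"` or `"gemm"`.
#' @param low_threshold,floor,max_low_frac Override the dialect defaults;
#'   `max_low_frac` is ignored in `ekaryo` mode. `floor` must not exceed
#'   `low_threshold`.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(mode = c("ekaryo", "gemm"), low_threshold = NULL,
                          floor = NULL, max_low_frac = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    ekaryo = list(low_threshold = 1, floor = 1, max_low_frac = NA_real_),
    gemm = list(low_threshold = 5.5, floor = 5, max_low_frac = 0.20))
  p <- list(mode = mode,
            low_threshold = if (is.null(low_threshold)) defaults$low_threshold
                            else check_number(low_threshold, "low_threshold"),
            floor = if (is.null(floor)) defaults$floor
                    else check_number(floor, "floor"),
            max_low_frac = if (is.null(max_low_frac)) defaults$max_low_frac
                           else check_number(max_low_frac, "max_low_frac", 0, 1))
  if (p$floor > p$low_threshold)
    stopf("floor (%.3g) must not exceed low_threshold (%.3g)",
          p$floor, p$low_threshold)
  structure(p, class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  rule <- if (x$mode == "ekaryo") "below threshold in ALL samples"
          else sprintf("below threshold in > %g%% of samples", 100 * x$max_low_frac)
  cat(sprintf("filter_policy '%s': drop genes %s (threshold %g), floor at %g\n",
              x$mode, rule, x$low_threshold, x$floor))
  invisible(x)
}

#' Apply an expression filter policy
#'
#' Drops non-expressed genes according to the policy's rule and floors the
#' surviving values at the policy floor. Applying the same policy twice is a
#' no-op after the first application.
#'
#' @param x Log2 expression matrix (genes x samples).
#' @param policy A [filter_policy()].
#' @return The filtered, floored matrix.
#' @export
apply_filter_policy <- function(x, policy) {
  check_matrix(x)
  if (!inherits(policy, "filter_policy")) stopf("`policy` must be a filter_policy")
  low <- x < policy$low_threshold
  drop <- if (policy$mode == "ekaryo") {
    rowSums(low) == ncol(x)
  } else {
    rowMeans(low) > policy$max_low_frac  # strictly greater, 20% itself survives
  }
  if (all(drop))
    stopf("filter policy '%s' removed every gene", policy$mode)
  out <- x[!drop, , drop = FALSE]
  out[out < policy$floor] <- policy$floor
  out
}

#' Comparative values against a reference panel
#'
#' Subtracts, per gene, the center (median by default, mean optionally) of
#' the reference samples from every sample, yielding the deviation track that
#' e-karyotyping segments. With a median center and an odd reference count
#' the per-gene median over the reference samples of the result is exactly 0.
#'
#' @param x Log2 expression matrix.
#' @param reference Character vector of reference (normal) sample ids,
#'   non-empty, all present in `x`.
#' @param center `"median"` or `"mean"`.
#' @return A matrix of the same shape with attributes `center` and
#'   `reference_samples`.
#' @export
comparative_values <- function(x, reference, center = c("median", "mean")) {
  check_matrix(x)
  center <- match.arg(center)
  if (length(reference) == 0L) stopf("`reference` must be non-empty")
  missing_ref <- setdiff(reference, colnames(x))
  if (length(missing_ref))
    stopf("reference sample(s) not in matrix: %s",
          paste(missing_ref, collapse = ", "))
  ref <- x[, reference, drop = FALSE]
  ctr <- if (center == "median") apply(ref, 1L, stats::median) else rowMeans(ref)
  out <- x - ctr
  attr(out, "center") <- center
  attr(out, "reference_samples") <- reference
  out
}

#' Order matrix rows by genomic position
#'
#' Sorts genes by (chromosome order, start, gene id); genes missing from the
#' annotation are dropped and reported.
#'
#' @param x Expression or comparative matrix.
#' @param annotation Annotation data.frame (`gene_id`, `chromosome`,
#'   `start`); chromosome order is taken from the factor levels (or first
#'   appearance).
#' @return A list: `matrix` (genome-ordered rows), `annotation` (matching
#'   rows, same order) and `dropped` (gene ids absent from the annotation).
#' @export
order_by_genome <- function(x, annotation) {
  check_matrix(x)
  ann <- validate_annotation(annotation)
  keep <- intersect(rownames(x), ann$gene_id)
  if (length(keep) == 0L)
    stopf("no overlap between matrix genes and annotation")
  dropped <- setdiff(rownames(x), keep)
  ann <- ann[ann$gene_id %in% keep, , drop = FALSE]
  ord <- order(as.integer(ann$chromosome), ann$start, ann$gene_id)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  list(matrix = x[ann$gene_id, , drop = FALSE], annotation = ann,
       dropped = dropped)
}

#' Remove additive batch offsets by per-batch mean centering
#'
#' For each gene, subtracts the batch mean and adds back the gene's grand
#' mean, removing constant per-batch shifts while preserving gene-wise grand
#' means. This is deliberately simple plumbing for combining expression
#' panels measured in separate batches.
#'
#' @param x Log2 expression matrix.
#' @param batch Batch label per sample (named by sample id, or positional).
#' @return The centered matrix.
#' @export
batch_center <- function(x, batch) {
  check_matrix(x)
  if (!is.null(names(batch))) {
    missing_lab <- setdiff(colnames(x), names(batch))
    if (length(missing_lab))
      stopf("no batch label for sample(s): %s", paste(missing_lab, collapse = ", "))
    batch <- batch[colnames(x)]
  }
  if (length(batch) != ncol(x)) stopf("need one batch label per sample")
  if (anyNA(batch)) stopf("batch labels must not be missing")
  batch <- as.character(batch)
  grand <- rowMeans(x)
  out <- x
  for (b in unique(batch)) {
    cols <- batch == b
    out[, cols] <- x[, cols, drop = FALSE] -
      rowMeans(x[, cols, drop = FALSE]) + grand
  }
  out
}

#' Read a genome annotation TSV
#'
#' Columns `gene_id`, `chromosome`, `start` (0-based) and optionally
#' `symbol`; chromosome order is the order of first appearance.
#'
#' @param path Path to the TSV (optionally .gz).
#' @return An annotation data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fill = FALSE)
  validate_annotation(ann)
}

#' Write a genome annotation TSV
#' @param annotation Annotation data.frame.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  ann <- validate_annotation(annotation)
  ann$chromosome <- as.character(ann$chromosome)
  write_tsv_(ann, path)
}
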