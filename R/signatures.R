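#' Read a gene set
#'
#' Accepts either one symbol per line, or a single-line GMT record
#' (name, description, then symbols, tab-separated).
#'
#' @param path Path to the file.
#' @param name Gene-set name (defaults to the file name, or the GMT name
#'   field).
#' @return A list of class `gene_set` with `name` and `symbols`.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("'%s': empty gene set", path)
  if (length(lines) == 1L && grepl("\t", lines[1L])) {
    fields <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stopf("'%s': malformed GMT record", path)
    if (is.null(name)) name <- fields[1L]
    symbols <- fields[-(1:2)]
  } else {
    symbols <- trimws(lines)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  }
  symbols <- unique(symbols[nzchar(symbols)])
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' EMT sum scores per sample
#'
#' For each sample, the score is the sum of the comparative expression values
#' (log2 deviations from the normal-panel center) over the gene-set members
#' that are present in the matrix, i.e. that survived the active expression
#' filter. Gene-symbol matching is case-insensitive; an optional
#' `symbol_map` (named character, set symbol -> matrix symbol) supports
#' cross-species sets such as a human EMT signature scored on mouse tumors.
#'
#' @param cmp Comparative-value matrix (genes x samples), already filtered.
#' @param gene_set A `gene_set` (from [read_gene_set()]) or a character
#'   vector of symbols.
#' @param symbol_map Optional named character vector translating set symbols
#'   to matrix symbols before matching.
#' @return A data.frame: `sample_id`, `score`, `n_genes_used`.
#' @export
emt_score <- function(cmp, gene_set, symbol_map = NULL) {
  check_matrix(cmp)
  symbols <- if (inherits(gene_set, "gene_set")) gene_set$symbols
             else as.character(gene_set)
  if (length(symbols) == 0L) stopf("gene set is empty")
  if (!is.null(symbol_map)) {
    hit <- symbols %in% names(symbol_map)
    symbols[hit] <- symbol_map[symbols[hit]]
  }
  rows <- match(toupper(symbols), toupper(rownames(cmp)))
  rows <- rows[!is.na(rows)]
  rows <- unique(rows)
  if (length(rows) == 0L)
    stopf("no gene-set member found in the matrix")
  sub <- cmp[rows, , drop = FALSE]
  data.frame(sample_id = colnames(cmp),
             score = unname(colSums(sub)),
             n_genes_used = length(rows),
             stringsAsFactors = FALSE)
}

#' Mean signature score per group
#'
#' Averages per-sample scores within groups (e.g. tumor model types) and
#' ranks the groups by mean score, highest first. Samples with a missing
#' group label are excluded with a warning.
#'
#' @param scores Score table from [emt_score()].
#' @param groups Group label per sample (named by sample id, or positional in
#'   the order of `scores`).
#' @return A data.frame ordered by decreasing `mean_score`: `group`,
#'   `mean_score`, `n`.
#' @export
group_mean_scores <- function(scores, groups) {
  stopifnot(is.data.frame(scores), all(c("sample_id", "score") %in% names(scores)))
  if (!is.null(names(groups))) groups <- groups[scores$sample_id]
  if (length(groups) != nrow(scores))
    stopf("need one group label per scored sample")
  keep <- !is.na(groups)
  if (any(!keep))
    warning(sprintf("%d sample(s) without a group label excluded", sum(!keep)))
  if (!any(keep)) stopf("no labeled samples to average")
  means <- tapply(scores$score[keep], as.character(groups[keep]), mean)
  out <- data.frame(group = names(means), mean_score = as.numeric(means),
                    n = as.integer(table(as.character(groups[keep]))[names(means)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_score), ]
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the matrix columns with Euclidean distances
#' and complete linkage (cluster distance = maximum pairwise distance), the
#' standard recipe for unsupervised expression dendrograms.
#'
#' @param x Numeric matrix (genes x samples); columns are clustered.
#' @return An [stats::hclust] object.
#' @export
hierarchical_cluster <- function(x) {
  check_matrix(x)
  if (ncol(x) < 2L) stopf("need >= 2 samples to cluster")
  stats::hclust(stats::dist(t(x), method = "euclidean"), method = "complete")
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are merge-height differences, so leaf depth equals the
#' merge height of the root.
#'
#' @param hc An [stats::hclust] object.
#' @param path Output path.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Mean-center genes for heatmap display
#'
#' Subtracts each gene's mean across samples, the scaling conventionally
#' applied before expression heatmaps. Idempotent; preserves all pairwise
#' sample differences within a gene.
#'
#' @param x Log2 expression matrix.
#' @return The row-centered matrix.
#' @export
scale_for_heatmap <- function(x) {
  check_matrix(x)
  x - rowMeans(x)
}
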