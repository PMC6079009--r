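#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Returns
#' `NA` when either vector is constant, where the rank correlation is
#' undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The correlation in [-1, 1], or `NA_real_` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stopf("`x` (%d) and `y` (%d) differ in length", length(x), length(y))
  if (length(x) < 3L) stopf("need at least 3 paired values")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Read a centroid table
#'
#' TSV with gene symbols in the first column and one column per subtype
#' (e.g. the five intrinsic breast cancer subtypes of a PAM50-style
#' classifier).
#'
#' @param path Path to the TSV.
#' @return A numeric matrix, genes x subtypes.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fill = FALSE)
  if (ncol(df) < 3L) stopf("centroid table needs >= 2 subtype columns")
  if (anyDuplicated(df[[1L]])) stopf("centroid table has duplicate genes")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  check_matrix(m, path)
  m
}

#' Assign a molecular subtype by nearest centroid
#'
#' Computes the Spearman rank correlation between a sample's log2 expression
#' and every subtype centroid over their shared genes, and assigns the
#' subtype of the most correlated centroid. When the top two correlations
#' differ by less than `mixed_margin` (or tie exactly), the sample is called
#' `"mixed"`, reflecting a profile carrying signatures of two subtypes.
#'
#' @param expr Named numeric vector of log2 expression (names = gene
#'   symbols), or a one-column matrix.
#' @param centroids Centroid matrix (genes x subtypes), as from
#'   [read_centroids()].
#' @param mixed_margin Minimum lead of the top correlation over the runner-up
#'   for an unambiguous call; `0` reserves `"mixed"` for exact ties.
#' @return A list of class `subtype_call`: `assigned` (a subtype or
#'   `"mixed"`), `rho` (named correlations), `margin` (top minus second) and
#'   `n_shared_genes`.
#' @export
assign_subtype <- function(expr, centroids, mixed_margin = 0.05) {
  if (is.matrix(expr)) {
    stopifnot(ncol(expr) == 1L)
    expr <- stats::setNames(expr[, 1L], rownames(expr))
  }
  if (is.null(names(expr))) stopf("`expr` must be named by gene symbol")
  check_matrix(centroids, "centroids")
  mixed_margin <- check_number(mixed_margin, "mixed_margin", min = 0)
  shared <- intersect(names(expr), rownames(centroids))
  if (length(shared) < 3L)
    stopf("only %d gene(s) shared with the centroid table; need >= 3",
          length(shared))
  rho <- vapply(colnames(centroids), function(st)
    spearman_rho(expr[shared], centroids[shared, st]), numeric(1))
  if (all(is.na(rho)))
    stopf("all correlations undefined (constant expression over shared genes)")
  ord <- order(rho, decreasing = TRUE, na.last = TRUE)
  top <- rho[ord[1L]]
  second <- if (length(rho) > 1L) rho[ord[2L]] else NA_real_
  margin <- if (is.na(second)) NA_real_ else unname(top - second)
  # margins below 1e-12 are exact ties up to floating-point summation order
  assigned <- if (!is.na(margin) && (margin < mixed_margin || margin <= 1e-12))
    "mixed" else names(rho)[ord[1L]]
  structure(list(assigned = assigned, rho = rho, margin = margin,
                 n_shared_genes = length(shared)), class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("subtype call: %s (margin %.3f over %d shared genes)\n",
              x$assigned, x$margin, x$n_shared_genes))
  print(round(sort(x$rho, decreasing = TRUE), 3))
  invisible(x)
}

#' Classify a cohort by nearest centroid
#'
#' Applies [assign_subtype()] to every sample of a log2 expression matrix.
#' Samples that cannot be classified (e.g. too few genes shared with the
#' centroid table) are reported in `failed` and do not block the rest of the
#' cohort.
#'
#' @param x Log2 expression matrix (genes x samples).
#' @param centroids Centroid matrix.
#' @param mixed_margin Passed to [assign_subtype()].
#' @return A list: `calls` (data.frame with `sample_id`, `assigned`,
#'   `margin` and one `rho_<subtype>` column per centroid), `summary`
#'   (named count of assigned labels) and `failed` (named character of
#'   error messages for unclassifiable samples).
#' @export
classify_cohort <- function(x, centroids, mixed_margin = 0.05) {
  check_matrix(x)
  calls <- list()
  failed <- character(0)
  for (s in colnames(x)) {
    res <- tryCatch(assign_subtype(x[, s], centroids, mixed_margin),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[s] <- conditionMessage(res)
      next
    }
    row <- data.frame(sample_id = s, assigned = res$assigned,
                      margin = res$margin, stringsAsFactors = FALSE)
    for (st in names(res$rho)) row[[paste0("rho_", st)]] <- res$rho[[st]]
    calls[[s]] <- row
  }
  calls_df <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(0), assigned = character(0),
               margin = numeric(0))
  rownames(calls_df) <- NULL
  summary <- if (nrow(calls_df)) table(calls_df$assigned) else table(character(0))
  list(calls = calls_df, summary = summary, failed = failed)
}
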