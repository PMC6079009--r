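#' @keywords internal
"_PACKAGE"

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so generators never perturb an enclosing simulation stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(min), format(max))
  as.numeric(x)
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix", name)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("`%s` must carry gene rownames and sample colnames", name)
  if (anyDuplicated(rownames(x)))
    stopf("`%s` has duplicate gene ids", name)
  if (anyDuplicated(colnames(x)))
    stopf("`%s` has duplicate sample ids", name)
  if (any(!is.finite(x)))
    stopf("`%s` contains missing or non-finite values", name)
  invisible(x)
}

write_tsv_ <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
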