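#' Write segments as a SEG table
#'
#' Tab-separated, IGV-compatible columns: `sample`, `chromosome`,
#' `start_bp`, `end_bp`, `n_genes`, `mean_log2`. All segments are written,
#' including neutral ones; an empty segment list yields a header-only file.
#'
#' @param segments Segment table from [ekaryotype()].
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  need <- c("sample_id", "chromosome", "start_bp", "end_bp", "n_genes",
            "mean_log2")
  if (!all(need %in% names(segments)))
    stopf("segments must have columns %s", paste(need, collapse = ", "))
  df <- segments[, need]
  names(df)[1L] <- "sample"
  write_tsv_(df, path)
}

#' Read a SEG table written by [write_seg()]
#' @param path Path to the SEG file.
#' @return A data.frame with columns `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_genes`, `mean_log2`.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fill = FALSE)
  names(df)[names(df) == "sample"] <- "sample_id"
  df
}

#' Write aberrant segments as BED6
#'
#' Only gain/loss segments are emitted (0-based half-open coordinates), with
#' `name` = the call, `score` = `min(1000, round(1000 * |mean_log2|))` and
#' `strand` = ".". BED has no header.
#'
#' @param segments Segment table from [ekaryotype()].
#' @param path Output path.
#' @export
write_bed <- function(segments, path) {
  ab <- segments[segments$call != "neutral", , drop = FALSE]
  bed <- data.frame(chrom = ab$chromosome,
                    start = ab$start_bp,
                    end = ab$end_bp,
                    name = ab$call,
                    score = pmin(1000, round(1000 * abs(ab$mean_log2))),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Score recovery of planted copy-number events
#'
#' Compares a planted-event truth table against called segments by set
#' overlap in within-chromosome gene indices. A truth event counts as
#' detected when some called aberration of the same sample, chromosome and
#' sign covers at least `min_overlap` of the event's genes; a called
#' aberration counts as a false positive when no same-sign truth event
#' covers at least `min_overlap` of the call's genes.
#'
#' @param truth Planted-event table (see [planted_events()]).
#' @param segments Segment calls from [ekaryotype()].
#' @param min_overlap Required overlap fraction (default 0.5).
#' @return A list: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, and
#'   `detected` (logical per truth event).
#' @export
score_event_recovery <- function(truth, segments, min_overlap = 0.5) {
  min_overlap <- check_number(min_overlap, "min_overlap", 0, 1)
  ab <- segments[segments$call != "neutral", , drop = FALSE]
  overlap_len <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))
  detected <- logical(nrow(truth))
  fp_flag <- rep(TRUE, nrow(ab))
  for (i in seq_len(nrow(truth))) {
    tv <- truth[i, ]
    t_start <- tv$start_gene_index
    t_end <- t_start + tv$n_genes
    t_call <- if (tv$log2_effect > 0) "gain" else "loss"
    for (j in seq_len(nrow(ab))) {
      if (ab$sample_id[j] != tv$sample_id ||
          ab$chromosome[j] != tv$chromosome || ab$call[j] != t_call) next
      ov <- overlap_len(t_start, t_end, ab$start_gene_index[j],
                        ab$end_gene_index[j])
      if (ov >= min_overlap * tv$n_genes) detected[i] <- TRUE
      if (ov >= min_overlap * ab$n_genes[j]) fp_flag[j] <- FALSE
    }
  }
  tp <- sum(detected)
  fp <- sum(fp_flag)
  fn <- sum(!detected)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, detected = detected)
}
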