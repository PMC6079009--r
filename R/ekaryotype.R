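#' Segmentation and calling parameters for e-karyotyping
#'
#' Bundles the tunable parameters of the copy-number inference: the minimum
#' absolute segment mean for an aberration call (`least_allowed_deviation`,
#' log2 units), the minimum aberration size in genes
#' (`least_allowed_aberration_size`), the winsorization quantile applied to
#' each sample's deviation track before segmentation, the per-breakpoint
#' penalty of the piecewise-constant fit, and the significance level of the
#' per-segment location test (`threshold`). The defaults are the parameter
#' set commonly used for expression-based karyotyping of RNA-seq cohorts.
#'
#' @param least_allowed_deviation Minimum |segment mean| (log2) to call.
#' @param least_allowed_aberration_size Minimum segment length in genes.
#' @param winsorize_quantile Winsorization quantile in [0, 0.5).
#' @param penalty Per-breakpoint penalty (>= 0) of the PCF objective.
#' @param threshold Significance level of the per-segment test against 0.
#' @return An object of class `pcf_params`.
#' @export
pcf_params <- function(least_allowed_deviation = 0.25,
                       least_allowed_aberration_size = 30,
                       winsorize_quantile = 0.001,
                       penalty = 12,
                       threshold = 0.01) {
  p <- list(
    least_allowed_deviation = check_number(least_allowed_deviation,
                                           "least_allowed_deviation", min = 0),
    least_allowed_aberration_size =
      check_count(least_allowed_aberration_size, "least_allowed_aberration_size"),
    winsorize_quantile = check_number(winsorize_quantile, "winsorize_quantile",
                                      min = 0),
    penalty = check_number(penalty, "penalty", min = 0),
    threshold = check_number(threshold, "threshold", 0, 1))
  if (p$winsorize_quantile >= 0.5)
    stopf("winsorize_quantile must be < 0.5")
  structure(p, class = "pcf_params")
}

#' @export
print.pcf_params <- function(x, ...) {
  cat(sprintf(paste0("pcf_params: deviation >= %g, size >= %d genes, ",
                     "winsorize q = %g, penalty = %g, test threshold = %g\n"),
              x$least_allowed_deviation, x$least_allowed_aberration_size,
              x$winsorize_quantile, x$penalty, x$threshold))
  invisible(x)
}

#' Winsorize a deviation track
#'
#' Caps the `k = floor(q * n)` most extreme values on each side at the
#' (k+1)-th smallest / largest remaining value (the classic order-statistic
#' winsorization underlying the winsorized mean). This convention is
#' idempotent: winsorizing a winsorized track changes nothing.
#'
#' @param x Numeric vector (one sample's comparative values).
#' @param q Quantile in [0, 0.5); `q = 0` is the identity.
#' @return The winsorized vector, element order preserved.
#' @export
winsorize <- function(x, q) {
  if (length(x) == 0L) stopf("cannot winsorize an empty track")
  if (any(!is.finite(x))) stopf("track contains missing or non-finite values")
  q <- check_number(q, "q", min = 0)
  if (q >= 0.5) stopf("`q` must be < 0.5")
  n <- length(x)
  k <- floor(q * n)
  if (k == 0L) return(x)
  s <- sort(x)
  pmin(pmax(x, s[k + 1L]), s[n - k])
}

#' Exact penalized piecewise-constant fit
#'
#' Segments a genome-ordered deviation track into constant-mean blocks by
#' minimizing the penalized least-squares objective
#' \deqn{\sum_{segments} \sum_{i \in seg} (x_i - \bar{x}_{seg})^2 +
#'       \lambda (\#segments - 1),}
#' solved exactly by dynamic programming over breakpoint positions (O(n^2)).
#' Among equal-cost solutions, one with fewer segments and earlier segment
#' starts is preferred; the optimum objective value is always attained.
#'
#' @param x Numeric vector: a single chromosome's (winsorized) comparative
#'   values in genome order.
#' @param penalty Per-breakpoint cost `lambda` (>= 0). `penalty = 0` fits
#'   every point as its own segment.
#' @return A data.frame of segments with columns `start`, `end` (1-based,
#'   half-open gene indices: the segment covers `start .. end-1`), `n_genes`
#'   and `mean` (the arithmetic mean of its members).
#' @export
pcf_segment <- function(x, penalty) {
  n <- length(x)
  if (n == 0L) stopf("cannot segment an empty track")
  if (any(!is.finite(x))) stopf("track contains missing or non-finite values")
  penalty <- check_number(penalty, "penalty", min = 0)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  # dp[i+1]: optimal cost of x[1..i] minus one penalty (so a single segment
  # over the whole track costs its SSE); nseg tracks segment counts for
  # tie-breaking, back[j] the start of the last segment ending at j.
  dp <- numeric(n + 1L)
  dp[1L] <- -penalty
  nseg <- integer(n + 1L)
  back <- integer(n)
  tol <- 1e-9
  for (j in seq_len(n)) {
    i <- seq_len(j)
    len <- j - i + 1
    sse <- (cs2[j + 1L] - cs2[i]) - (cs[j + 1L] - cs[i])^2 / len
    cand <- dp[i] + penalty + sse
    best <- min(cand)
    tied <- which(cand <= best + tol)
    if (length(tied) > 1L) tied <- tied[order(nseg[tied], tied)]
    pick <- tied[1L]
    dp[j + 1L] <- cand[pick]
    nseg[j + 1L] <- nseg[pick] + 1L
    back[j] <- pick
  }
  starts <- integer(0)
  j <- n
  while (j > 0L) {
    starts <- c(back[j], starts)
    j <- back[j] - 1L
  }
  ends <- c(starts[-1L], n + 1L)
  data.frame(start = starts, end = ends, n_genes = ends - starts,
             mean = (cs[ends] - cs[starts]) / (ends - starts))
}

#' Call gains and losses on fitted segments
#'
#' A segment is called `gain` (or `loss`) when all three rules hold: its
#' fitted mean is at least `least_allowed_deviation` above (below) zero, it
#' spans at least `least_allowed_aberration_size` genes, and a two-sided
#' one-sample t-test of its member values against zero is significant at
#' `threshold`. Everything else is `neutral`. Adjacent segments with the same
#' call are merged, with the pooled mean recomputed from the track.
#'
#' @param segments Output of [pcf_segment()] tiling one chromosome.
#' @param x The track the segments were fitted on (needed for the test and
#'   pooled means).
#' @param params A [pcf_params()].
#' @return A data.frame with `start`, `end` (half-open), `n_genes`,
#'   `mean_log2`, `call`.
#' @export
call_aberrations <- function(segments, x, params = pcf_params()) {
  stopifnot(is.data.frame(segments), all(c("start", "end") %in% names(segments)))
  if (!inherits(params, "pcf_params")) stopf("`params` must be pcf_params")
  if (nrow(segments) == 0L) stopf("no segments to call")
  if (segments$start[1L] != 1L || segments$end[nrow(segments)] != length(x) + 1L ||
      any(segments$start[-1L] != segments$end[-nrow(segments)]))
    stopf("segments must tile the track with no gaps or overlaps")
  call <- character(nrow(segments))
  for (k in seq_len(nrow(segments))) {
    v <- x[segments$start[k]:(segments$end[k] - 1L)]
    m <- mean(v)
    ok_dev <- abs(m) >= params$least_allowed_deviation
    ok_size <- length(v) >= params$least_allowed_aberration_size
    call[k] <- if (ok_dev && ok_size &&
                   segment_test_p(v) <= params$threshold) {
      if (m > 0) "gain" else "loss"
    } else "neutral"
  }
  # merge runs of identical calls, pooling the mean over the merged range
  runs <- rle(call)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  out <- data.frame(
    start = segments$start[idx_start],
    end = segments$end[idx_end],
    call = runs$values, stringsAsFactors = FALSE)
  out$n_genes <- out$end - out$start
  out$mean_log2 <- vapply(seq_len(nrow(out)), function(k)
    mean(x[out$start[k]:(out$end[k] - 1L)]), numeric(1))
  out[, c("start", "end", "n_genes", "mean_log2", "call")]
}

# Two-sided one-sample t-test p-value against 0, with degenerate cases
# resolved deterministically: a constant segment is certain evidence (p = 0)
# unless it sits exactly at 0, and a single gene is never significant.
segment_test_p <- function(v) {
  n <- length(v)
  if (n < 2L) return(1)
  s <- stats::sd(v)
  if (s == 0) return(if (mean(v) == 0) 1 else 0)
  tval <- mean(v) / (s / sqrt(n))
  2 * stats::pt(-abs(tval), df = n - 1L)
}

#' E-karyotype a cohort
#'
#' The full expression-based copy-number inference for every sample of a
#' comparative-value matrix: genes are ordered along the genome, each
#' sample's deviation track is winsorized (across the whole genome), each
#' chromosome is segmented by the exact penalized piecewise-constant fit,
#' and segments are called gain/loss/neutral. Breakpoints never cross
#' chromosome boundaries.
#'
#' With the default raw-scale penalty, a breakpoint between blocks whose
#' means differ by `delta` pays off only when the harmonic mean of the
#' flanking block sizes exceeds about `2 * penalty / delta^2` genes; broad
#' events (arm- or chromosome-scale, which need no interior breakpoints) are
#' the intended targets. `normalize_noise = TRUE` rescales each sample's
#' track by a robust per-sample noise estimate (median absolute successive
#' difference / sqrt(2)) before segmentation, making the penalty
#' noise-relative and focal events far easier to split out; gain/loss calls
#' are always made on the raw log2 scale.
#'
#' @param cmp Comparative-value matrix (genes x samples), e.g. from
#'   [comparative_values()] after [apply_filter_policy()].
#' @param annotation Genome annotation covering the matrix genes.
#' @param params A [pcf_params()].
#' @param normalize_noise Segment on noise-rescaled tracks (default `FALSE`,
#'   i.e. the penalty applies to raw winsorized log2 values).
#' @return A data.frame of segments: `sample_id`, `chromosome`,
#'   `start_gene_index`, `end_gene_index` (1-based half-open,
#'   within-chromosome genome order), `start_bp`, `end_bp` (start of first
#'   gene, start of last gene + 1), `n_genes`, `mean_log2`, `call`.
#' @examples
#' ann <- simulate_annotation(2, 60, seed = 2)
#' sim <- simulate_expression_cohort(ann, 3, 2,
#'   planted_events("T1", "chr2", 1, 60, -0.4),
#'   low_expr_frac = 0, noise_sd = 0.1, seed = 2)
#' cmp <- comparative_values(sim$expression, c("N1", "N2", "N3"))
#' segs <- ekaryotype(cmp, ann)
#' subset(segs, call != "neutral")
#' @export
ekaryotype <- function(cmp, annotation, params = pcf_params(),
                       normalize_noise = FALSE) {
  if (!inherits(params, "pcf_params")) stopf("`params` must be pcf_params")
  ord <- order_by_genome(cmp, annotation)
  x <- ord$matrix
  ann <- ord$annotation
  chroms <- levels(droplevels(ann$chromosome))
  res <- vector("list", ncol(x) * length(chroms))
  k <- 0L
  for (s in colnames(x)) {
    track <- winsorize(x[, s], params$winsorize_quantile)
    scale <- if (normalize_noise) {
      # robust noise sd: successive differences are unaffected by broad
      # shifts; a floor guards against degenerate noise-free tracks
      max(stats::mad(diff(track)) / sqrt(2), 1e-3)
    } else 1
    for (ch in chroms) {
      rows <- which(as.character(ann$chromosome) == ch)
      v <- track[rows]
      segs <- pcf_segment(v / scale, params$penalty)
      calls <- call_aberrations(segs, v, params)
      starts_bp <- ann$start[rows]
      k <- k + 1L
      res[[k]] <- data.frame(
        sample_id = s, chromosome = ch,
        start_gene_index = calls$start, end_gene_index = calls$end,
        start_bp = starts_bp[calls$start],
        end_bp = starts_bp[calls$end - 1L] + 1L,
        n_genes = calls$n_genes, mean_log2 = calls$mean_log2,
        call = calls$call, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Moving average of a track ("valid" convention)
#'
#' Sliding arithmetic mean over windows fully inside the track; the output
#' has `n - window + 1` values (empty, with a warning, when the window
#' exceeds the track).
#'
#' @param x Numeric vector.
#' @param window Window size in genes (>= 1); `window = 1` is the identity.
#' @return Numeric vector of window means.
#' @export
moving_average <- function(x, window) {
  window <- check_count(window, "window")
  n <- length(x)
  if (window > n) {
    warning(sprintf("window (%d) exceeds track length (%d); empty result",
                    window, n))
    return(numeric(0))
  }
  cs <- c(0, cumsum(unname(x)))
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Moving-average tracks along the genome
#'
#' Smooths each sample's comparative values per chromosome and attaches the
#' genomic position of each window's center gene, producing the track tables
#' behind locus-level expression plots (e.g. around a tumor-suppressor locus
#' on one chromosome).
#'
#' @param cmp Comparative-value matrix.
#' @param annotation Genome annotation.
#' @param window Window size in genes (default 50).
#' @return A data.frame: `sample_id`, `chromosome`, `position` (bp of the
#'   window-center gene), `smoothed`.
#' @export
moving_average_tracks <- function(cmp, annotation, window = 50) {
  window <- check_count(window, "window")
  ord <- order_by_genome(cmp, annotation)
  x <- ord$matrix
  ann <- ord$annotation
  res <- list()
  for (ch in levels(droplevels(ann$chromosome))) {
    rows <- which(as.character(ann$chromosome) == ch)
    if (length(rows) < window) next
    centers <- ann$start[rows][seq_len(length(rows) - window + 1L) +
                                 (window - 1L) %/% 2L]
    for (s in colnames(x)) {
      sm <- moving_average(x[rows, s], window)
      res[[length(res) + 1L]] <- data.frame(
        sample_id = s, chromosome = ch, position = centers, smoothed = sm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(sample_id = character(0), chromosome = character(0),
                      position = integer(0), smoothed = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
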