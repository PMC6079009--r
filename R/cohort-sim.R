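#' Simulate a genome annotation
#'
#' Builds a gene annotation table (gene id, chromosome, start coordinate,
#' symbol) with genes laid out in strictly increasing positions along each
#' chromosome, mimicking the genome ordering that e-karyotyping requires.
#'
#' @param n_chromosomes Number of chromosomes (19 approximates the mouse
#'   autosome count).
#' @param genes_per_chromosome Number of genes placed on each chromosome.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data.frame with columns `gene_id`, `chromosome` (factor whose
#'   level order is the genome order), `start` (0-based bp) and `symbol`,
#'   sorted by (chromosome, start).
#' @examples
#' ann <- simulate_annotation(2, 5, seed = 1)
#' @export
simulate_annotation <- function(n_chromosomes, genes_per_chromosome, seed) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  genes_per_chromosome <- check_count(genes_per_chromosome, "genes_per_chromosome")
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chromosomes))
    per_chrom <- lapply(chroms, function(ch) {
      # strictly increasing starts: cumulative sum of positive gaps
      gaps <- ceiling(stats::runif(genes_per_chromosome, 1e3, 2e5))
      starts <- cumsum(gaps) - gaps[1L]
      data.frame(
        gene_id = sprintf("%s_g%04d", ch, seq_len(genes_per_chromosome)),
        chromosome = ch,
        start = as.integer(starts),
        symbol = sprintf("Sym_%s_%04d", sub("chr", "", ch),
                         seq_len(genes_per_chromosome)),
        stringsAsFactors = FALSE
      )
    })
    ann <- do.call(rbind, per_chrom)
    ann$chromosome <- factor(ann$chromosome, levels = chroms)
    rownames(ann) <- NULL
    ann
  })
}

#' Describe planted copy-number events
#'
#' Convenience constructor for the planted-event truth table consumed by
#' [simulate_expression_cohort()] and compared against segmentation output by
#' [score_event_recovery()]. Gene indices are 1-based within the chromosome
#' and half-open: an event covers within-chromosome genes
#' `start_gene_index .. start_gene_index + n_genes - 1`, the same convention
#' segment calls use.
#'
#' @param sample_id,chromosome,start_gene_index,n_genes,log2_effect Vectors,
#'   recycled to a common length. `log2_effect` is the shift added to the
#'   affected genes' log2 expression (e.g. -0.4 for a single-copy loss).
#' @return A data.frame with one row per event.
#' @export
planted_events <- function(sample_id, chromosome, start_gene_index, n_genes,
                           log2_effect) {
  ev <- data.frame(sample_id = sample_id, chromosome = as.character(chromosome),
                   start_gene_index = as.integer(start_gene_index),
                   n_genes = as.integer(n_genes),
                   log2_effect = as.numeric(log2_effect),
                   stringsAsFactors = FALSE)
  if (any(ev$n_genes < 1L)) stopf("event `n_genes` must be >= 1")
  if (any(ev$start_gene_index < 1L)) stopf("event `start_gene_index` must be >= 1")
  ev
}

#' Simulate an expression cohort with planted copy-number events
#'
#' Generates a log2 gene-by-sample expression matrix for a panel of normal
#' reference samples plus tumor samples, where tumors may carry contiguous
#' chromosomal segments shifted by a fixed log2 effect (planted gains or
#' losses). Per-gene baselines are drawn once from `baseline_range`, a
#' configurable fraction of genes is placed below the expression filter to
#' exercise filtering, and i.i.d. Gaussian noise on the log2 scale is added on
#' top. At `noise_sd = 0` the planted effects are exactly recoverable from the
#' comparative values.
#'
#' @param annotation A genome annotation as from [simulate_annotation()]
#'   (ordered by chromosome and start).
#' @param n_normal,n_tumor Sample counts; normals are named `N1..`, tumors
#'   `T1..`.
#' @param events `NULL` or a planted-event table (see [planted_events()]);
#'   `sample_id` must name tumor samples and each event must fit inside its
#'   chromosome's gene range.
#' @param baseline_range Range of the Uniform distribution the per-gene log2
#'   baselines are drawn from.
#' @param low_expr_frac Fraction of genes whose baseline is redrawn from
#'   `low_expr_range`, i.e. below the default expression filter threshold.
#' @param low_expr_range Baseline range for the low-expression genes.
#' @param noise_sd Standard deviation of the Gaussian log2 noise (>= 0).
#' @param seed Integer seed.
#' @return A list with `expression` (log2 matrix, genes x samples),
#'   `condition` (named character, "normal"/"tumor"), `annotation`, and
#'   `truth` (the validated event table).
#' @examples
#' ann <- simulate_annotation(2, 50, seed = 1)
#' ev <- planted_events("T1", "chr2", 1, 50, -0.4)
#' sim <- simulate_expression_cohort(ann, 3, 2, ev, noise_sd = 0.3, seed = 1)
#' @export
simulate_expression_cohort <- function(annotation, n_normal, n_tumor,
                                       events = NULL,
                                       baseline_range = c(2, 10),
                                       low_expr_frac = 0.05,
                                       low_expr_range = c(0, 0.9),
                                       noise_sd = 0.3, seed = 1) {
  n_normal <- check_count(n_normal, "n_normal")
  n_tumor <- check_count(n_tumor, "n_tumor", min = 0L)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  low_expr_frac <- check_number(low_expr_frac, "low_expr_frac", 0, 1)
  ann <- validate_annotation(annotation)
  n_genes <- nrow(ann)
  normals <- paste0("N", seq_len(n_normal))
  tumors <- if (n_tumor > 0L) paste0("T", seq_len(n_tumor)) else character(0)
  samples <- c(normals, tumors)

  if (is.null(events)) {
    events <- planted_events(character(0), character(0), integer(0),
                             integer(0), numeric(0))
  }
  chrom_sizes <- table(ann$chromosome)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$sample_id %in% tumors)
      stopf("event %d targets '%s', which is not a tumor sample", i, ev$sample_id)
    if (!ev$chromosome %in% names(chrom_sizes))
      stopf("event %d references unknown chromosome '%s'", i, ev$chromosome)
    if (ev$start_gene_index + ev$n_genes - 1L > chrom_sizes[[ev$chromosome]])
      stopf("event %d exceeds the %d genes of %s", i,
            chrom_sizes[[ev$chromosome]], ev$chromosome)
  }

  with_seed(seed, {
    baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
    n_low <- round(low_expr_frac * n_genes)
    if (n_low > 0L) {
      low <- sample.int(n_genes, n_low)
      baseline[low] <- stats::runif(n_low, low_expr_range[1], low_expr_range[2])
    }
    x <- matrix(baseline, n_genes, length(samples)) +
      matrix(stats::rnorm(n_genes * length(samples), 0, noise_sd),
             n_genes, length(samples))
    dimnames(x) <- list(ann$gene_id, samples)
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      rows <- which(as.character(ann$chromosome) == ev$chromosome)
      rows <- rows[seq(ev$start_gene_index, length.out = ev$n_genes)]
      x[rows, ev$sample_id] <- x[rows, ev$sample_id] + ev$log2_effect
    }
    condition <- stats::setNames(
      rep(c("normal", "tumor"), c(n_normal, n_tumor)), samples)
    list(expression = x, condition = condition, annotation = ann,
         truth = events)
  })
}

validate_annotation <- function(annotation) {
  need <- c("gene_id", "chromosome", "start")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stopf("annotation must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(annotation$gene_id))
    stopf("annotation has duplicate gene_ids")
  if (any(annotation$start < 0)) stopf("annotation starts must be >= 0")
  if (!is.factor(annotation$chromosome))
    annotation$chromosome <- factor(annotation$chromosome,
                                    levels = unique(annotation$chromosome))
  annotation
}

#' Simulate samples around subtype centroids
#'
#' Each sample is a centroid expression profile plus i.i.d. Gaussian noise,
#' giving a panel with known subtype labels for testing nearest-centroid
#' assignment. At `noise_sd = 0` a sample equals its centroid exactly.
#'
#' @param centroids Numeric matrix, genes x subtypes (rownames = genes).
#' @param labels Character vector of subtype names, one per sample to
#'   generate; each must be a centroid column.
#' @param noise_sd Gaussian noise standard deviation (log2 scale).
#' @param seed Integer seed.
#' @return A log2 expression matrix (genes x samples) with samples named
#'   `<label>_<i>`; the true label is recoverable from the column name and is
#'   also attached as the `"true_label"` attribute.
#' @export
simulate_subtype_samples <- function(centroids, labels, noise_sd = 0.1,
                                     seed = 1) {
  check_matrix(centroids, "centroids")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  labels <- as.character(labels)
  bad <- setdiff(labels, colnames(centroids))
  if (length(bad))
    stopf("unknown subtype label(s): %s", paste(unique(bad), collapse = ", "))
  with_seed(seed, {
    x <- centroids[, labels, drop = FALSE] +
      matrix(stats::rnorm(nrow(centroids) * length(labels), 0, noise_sd),
             nrow(centroids), length(labels))
    colnames(x) <- sprintf("%s_%d", labels, seq_along(labels))
    attr(x, "true_label") <- stats::setNames(labels, colnames(x))
    x
  })
}

#' Simulate a two-gene perturbation table with a controlled association
#'
#' Draws per-sample perturbation status for two genes from the joint
#' Bernoulli distribution whose marginals are `p_geneA`/`p_geneB` and whose
#' odds ratio is `odds_ratio` (the Plackett construction: the joint cell
#' probability solves a quadratic and lies in
#' `[max(0, pA+pB-1), min(pA, pB)]`). Perturbed samples are assigned a status
#' from `{mutated, deleted, both}` with probabilities `status_probs`;
#' unperturbed samples are `WT`.
#'
#' @param n_samples Cohort size.
#' @param p_geneA,p_geneB Marginal perturbation probabilities in [0, 1].
#' @param odds_ratio Target odds ratio (>= 0) between the two perturbation
#'   indicators.
#' @param genes Names of the two gene columns.
#' @param status_probs Probabilities of `mutated`, `deleted`, `both` given
#'   that a gene is perturbed.
#' @param seed Integer seed.
#' @return A data.frame with `sample_id` and one status column per gene.
#' @export
simulate_perturbation_table <- function(n_samples, p_geneA, p_geneB,
                                        odds_ratio, genes = c("geneA", "geneB"),
                                        status_probs = c(mutated = 1/3,
                                                         deleted = 1/3,
                                                         both = 1/3),
                                        seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  pA <- check_number(p_geneA, "p_geneA", 0, 1)
  pB <- check_number(p_geneB, "p_geneB", 0, 1)
  or <- check_number(odds_ratio, "odds_ratio", min = 0)
  stopifnot(length(genes) == 2L, !anyDuplicated(genes))
  cells <- joint_cell_probs(pA, pB, or)
  with_seed(seed, {
    draw <- sample.int(4L, n_samples, replace = TRUE, prob = cells)
    a_pert <- draw %in% c(1L, 2L)  # cells: 11, 10, 01, 00
    b_pert <- draw %in% c(1L, 3L)
    status <- function(flag) {
      s <- rep("WT", n_samples)
      k <- sum(flag)
      if (k > 0L)
        s[flag] <- sample(c("mutated", "deleted", "both"), k, replace = TRUE,
                          prob = status_probs)
      s
    }
    out <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                      status(a_pert), status(b_pert),
                      stringsAsFactors = FALSE)
    names(out)[2:3] <- genes
    out
  })
}

# Plackett joint cell probabilities (p11, p10, p01, p00) for given marginals
# and odds ratio; errors when the combination is infeasible.
joint_cell_probs <- function(pA, pB, or) {
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  p11 <- if (or == 1) {
    pA * pB
  } else if (or == 0) {
    lo
  } else {
    s <- 1 + (pA + pB) * (or - 1)
    disc <- s^2 - 4 * or * (or - 1) * pA * pB
    if (disc < 0) stopf("no valid joint distribution for these marginals and odds ratio")
    (s - sqrt(disc)) / (2 * (or - 1))
  }
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stopf("infeasible (p_geneA, p_geneB, odds_ratio) combination")
  p11 <- min(max(p11, lo), hi)
  cells <- c(p11, pA - p11, pB - p11, 1 - pA - pB + p11)
  if (any(cells < -1e-12))
    stopf("infeasible (p_geneA, p_geneB, odds_ratio) combination")
  pmax(cells, 0)
}

#' Simulate grouped exponential survival times with censoring
#'
#' Event times are Exponential with a per-group hazard; an independent
#' Exponential censoring time with rate `censor_rate` is drawn per subject,
#' the observed time is the minimum, and the event flag records which came
#' first. `censor_rate = 0` yields fully observed events.
#'
#' @param group_sizes Named integer vector: subjects per group.
#' @param group_hazards Named numeric vector of positive hazard rates; names
#'   must match `group_sizes`.
#' @param censor_rate Censoring hazard (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with `sample_id`, `time`, `event` (1 = event,
#'   0 = censored) and `group`.
#' @export
simulate_survival <- function(group_sizes, group_hazards, censor_rate = 0,
                              seed = 1) {
  if (length(group_sizes) == 0L) stopf("`group_sizes` must name at least one group")
  if (is.null(names(group_sizes)) || is.null(names(group_hazards)) ||
      !setequal(names(group_sizes), names(group_hazards)))
    stopf("`group_sizes` and `group_hazards` must share the same group names")
  if (any(group_hazards <= 0)) stopf("hazard rates must be > 0")
  censor_rate <- check_number(censor_rate, "censor_rate", min = 0)
  with_seed(seed, {
    recs <- lapply(names(group_sizes), function(g) {
      n <- check_count(group_sizes[[g]], paste0("group_sizes[", g, "]"))
      t_event <- stats::rexp(n, rate = group_hazards[[g]])
      t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else rep(Inf, n)
      data.frame(time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 group = g, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    out <- cbind(sample_id = sprintf("P%04d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
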