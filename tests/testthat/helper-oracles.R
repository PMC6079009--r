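# Independent oracles and fixtures shared across the suite. Each oracle is a
# deliberately naive implementation kept separate from the package code path
# it checks.

# Exhaustive penalized piecewise-constant fit: tries every breakpoint subset
# (2^(n-1) candidates) and returns the minimum objective value.
pcf_objective_oracle <- function(x, penalty) {
  n <- length(x)
  if (n == 1L) return(0)
  best <- Inf
  for (mask in 0:(2^(n - 1L) - 1L)) {
    bps <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
    bounds <- c(0L, bps, n)
    cost <- penalty * (length(bounds) - 2L)
    for (s in seq_len(length(bounds) - 1L)) {
      seg <- x[(bounds[s] + 1L):bounds[s + 1L]]
      cost <- cost + sum((seg - mean(seg))^2)
      if (cost >= best) break
    }
    best <- min(best, cost)
  }
  best
}

# Objective value of a fitted segmentation.
pcf_objective_of <- function(segments, x, penalty) {
  sse <- sum(vapply(seq_len(nrow(segments)), function(k) {
    seg <- x[segments$start[k]:(segments$end[k] - 1L)]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  sse + penalty * (nrow(segments) - 1L)
}

# Naive agglomerative complete-linkage clustering of matrix columns;
# returns merge heights in merge order.
complete_linkage_oracle <- function(x) {
  d <- as.matrix(stats::dist(t(x)))
  clusters <- as.list(seq_len(ncol(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Two-sided Fisher p by direct log-binomial enumeration (probability-mass
# rule), coded independently of the package's dhyper route.
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; kk <- a + c_
  ks <- max(0L, kk - n2):min(kk, m)
  logp <- lchoose(m, ks) + lchoose(n2, kk - ks) - lchoose(m + n2, kk)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n2, c_) - lchoose(m + n2, kk))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Small synthetic centroid table: three subtypes over 30 genes with
# well-separated rank profiles.
make_centroids <- function(n_genes = 30L,
                           subtypes = c("basal", "luminal", "mesenchymal"),
                           seed = 42L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- sapply(subtypes, function(s) runif(n_genes, 4, 12))
  rownames(m) <- sprintf("G%02d", seq_len(n_genes))
  m
}

# A sample equidistant (in rank correlation) from centroids A and B: take
# B = A with genes reversed (an involution), so the elementwise mean M
# satisfies rho(M, A) == rho(M, B) exactly by symmetry.
make_mixed_fixture <- function(n_genes = 30L, seed = 7L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  a <- runif(n_genes, 4, 12)
  b <- rev(a)
  cen <- cbind(A = a, B = b)
  rownames(cen) <- sprintf("G%02d", seq_len(n_genes))
  list(centroids = cen, sample = setNames((a + b) / 2, rownames(cen)))
}

# Shared study conditions for planted-truth copy-number recovery: a
# desk-scale cohort of 3 normals and 4 tumors over 5 chromosomes x 300
# genes, with a whole-chromosome single-copy loss (-0.4 log2) planted on
# chr2 in tumors T1-T3 and Gaussian noise sd 0.3.
cna_recovery_run <- function(seed, noise_sd = 0.3) {
  ann <- simulate_annotation(5, 300, seed = seed)
  truth <- planted_events(c("T1", "T2", "T3"), "chr2", 1, 300, -0.4)
  sim <- simulate_expression_cohort(ann, 3, 4, truth,
                                    noise_sd = noise_sd, seed = seed)
  x <- apply_filter_policy(sim$expression, filter_policy("ekaryo"))
  cmp <- comparative_values(x, names(sim$condition)[sim$condition == "normal"])
  segs <- ekaryotype(cmp, sim$annotation)
  sc <- score_event_recovery(sim$truth, segs)
  loss_chr2 <- unique(segs$sample_id[segs$chromosome == "chr2" &
                                       segs$call == "loss"])
  list(score = sc, truth = sim$truth,
       tumors_called = sort(loss_chr2),
       exact_id = setequal(loss_chr2, c("T1", "T2", "T3")))
}
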