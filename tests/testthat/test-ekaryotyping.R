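test_that("winsorization caps the extremes and is idempotent", {
  x <- c(-10, 0, 0, 0, 10)
  expect_identical(winsorize(x, 0), x)
  # k = floor(0.2 * 5) = 1 value clamped on each side, to the 2nd/4th
  # order statistic (both 0)
  expect_equal(winsorize(x, 0.2), rep(0, 5))

  set.seed(50)
  for (i in 1:20) {
    y <- rnorm(sample(5:200, 1))
    q <- runif(1, 0, 0.4)
    w <- winsorize(y, q)
    expect_identical(winsorize(w, q), w)
    # untouched elements keep both value and position
    inside <- y > min(w) & y < max(w)
    expect_identical(w[inside], y[inside])
    expect_true(max(w) <= max(y) && min(w) >= min(y))
  }
  expect_error(winsorize(numeric(0), 0.1), "empty")
  expect_error(winsorize(c(1, NA), 0.1), "missing")
  expect_error(winsorize(1:5, 0.5), "< 0.5")
})

test_that("PCF returns one segment for constant tracks and splits clear steps", {
  segs <- pcf_segment(rep(0.7, 40), penalty = 12)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$mean, 0.7)
  expect_equal(c(segs$start, segs$end), c(1, 41))

  # two-level track: breakpoint cost 12 beats the one-segment SSE of 25
  x <- c(rep(0, 50), rep(1, 50))
  segs <- pcf_segment(x, penalty = 12)
  expect_equal(segs$start, c(1, 51))
  expect_equal(segs$end, c(51, 101))
  expect_equal(segs$mean, c(0, 1))

  # penalty above the SSE saving keeps one segment
  expect_equal(nrow(pcf_segment(x, penalty = 26)), 1)

  expect_error(pcf_segment(numeric(0), 12), "empty")
  expect_error(pcf_segment(c(1, NaN, 2), 12), "missing")
})

test_that("PCF objective matches exhaustive enumeration on short tracks", {
  set.seed(60)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    x <- if (i %% 2 == 0) sample(c(-1, 0, 1), n, replace = TRUE) else rnorm(n)
    penalty <- sample(c(0.1, 0.5, 2, 12), 1)
    segs <- pcf_segment(x, penalty)
    expect_equal(pcf_objective_of(segs, x, penalty),
                 pcf_objective_oracle(x, penalty), tolerance = 1e-8)
  }
})

test_that("PCF segments tile the track and reproduce member means", {
  set.seed(61)
  x <- rnorm(300) + rep(c(0, 0.8, 0), c(100, 80, 120))
  segs <- pcf_segment(x, penalty = 12)
  expect_equal(segs$start[1], 1)
  expect_equal(segs$end[nrow(segs)], length(x) + 1)
  expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  expect_equal(sum(segs$n_genes), length(x))
  for (k in seq_len(nrow(segs)))
    expect_equal(segs$mean[k], mean(x[segs$start[k]:(segs$end[k] - 1)]),
                 tolerance = 1e-9)
})

test_that("segment count is non-increasing in the penalty", {
  set.seed(62)
  x <- rnorm(200) + rep(c(0, 0.6, -0.5, 0), each = 50)
  counts <- vapply(c(0.5, 2, 6, 12, 30, 100),
                   function(p) nrow(pcf_segment(x, p)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("adding a constant shifts segment means but not breakpoints", {
  set.seed(63)
  x <- rnorm(150) + rep(c(0, 0.9), c(70, 80))
  a <- pcf_segment(x, 12)
  b <- pcf_segment(x + 3, 12)
  expect_equal(a$start, b$start)
  expect_equal(b$mean, a$mean + 3)
})

test_that("aberration calls apply deviation, size and significance rules", {
  params <- pcf_params()
  seg1 <- data.frame(start = 1, end = 201)

  set.seed(64)
  loss <- rnorm(200, -0.4, 0.3)
  out <- call_aberrations(seg1, loss, params)
  expect_equal(out$call, "loss")

  # same shift but only 10 genes: fails the size rule
  short <- c(rnorm(10, -0.4, 0.1), rnorm(190, 0, 0.1))
  segs <- data.frame(start = c(1, 11), end = c(11, 201))
  out <- call_aberrations(segs, short, params)
  expect_equal(out$call[1], "neutral")

  # large but shallow segment: fails the deviation rule
  shallow <- rnorm(500, -0.1, 0.05)
  out <- call_aberrations(data.frame(start = 1, end = 501), shallow, params)
  expect_equal(out$call, "neutral")

  # constant (zero-variance) segments are resolved deterministically
  out <- call_aberrations(data.frame(start = 1, end = 41), rep(-0.4, 40), params)
  expect_equal(out$call, "loss")
  out <- call_aberrations(data.frame(start = 1, end = 41), rep(0, 40), params)
  expect_equal(out$call, "neutral")

  expect_error(call_aberrations(data.frame(start = 1, end = 10), rnorm(20),
                                params), "tile")
})

test_that("adjacent same-call segments merge with pooled means", {
  x <- c(rep(0.5, 40), rep(0.9, 40))
  segs <- data.frame(start = c(1, 41), end = c(41, 81))
  out <- call_aberrations(segs, x, pcf_params())
  expect_equal(nrow(out), 1)
  expect_equal(out$call, "gain")
  expect_equal(out$mean_log2, 0.7)
  expect_equal(out$n_genes, 80)
})

test_that("zero-noise planted losses are recovered with exact boundaries", {
  # a 200-gene loss centered in a 1000-gene chromosome: the between-segment
  # sum of squares (200*800/1000 * 0.4^2 = 25.6) exceeds the two-breakpoint
  # cost of 24, so the exact fit isolates the event precisely
  ann <- simulate_annotation(1, 1000, seed = 70)
  ev <- planted_events("T1", "chr1", 401, 200, -0.4)
  sim <- simulate_expression_cohort(ann, 3, 1, ev, low_expr_frac = 0,
                                    noise_sd = 0, seed = 70)
  cmp <- comparative_values(sim$expression, paste0("N", 1:3))
  segs <- ekaryotype(cmp, sim$annotation)
  hit <- segs[segs$call == "loss", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$sample_id, "T1")
  expect_equal(hit$chromosome, "chr1")
  expect_equal(hit$start_gene_index, 401)
  expect_equal(hit$end_gene_index, 601)
  expect_equal(hit$mean_log2, -0.4)
  # every sample x chromosome tiles its gene range
  for (s in unique(segs$sample_id)) {
    sub <- segs[segs$sample_id == s, ]
    expect_equal(sub$start_gene_index[1], 1)
    expect_equal(sub$end_gene_index[nrow(sub)], 1001)
  }
})

test_that("noise-normalized segmentation resolves focal events", {
  # a 50-gene loss is far below the raw-penalty detection limit
  # (harmonic flank size >= 2 * 12 / 0.4^2 = 150 genes) but easy once the
  # track is rescaled by its noise level
  ann <- simulate_annotation(1, 300, seed = 73)
  ev <- planted_events("T1", "chr1", 101, 50, -0.4)
  sim <- simulate_expression_cohort(ann, 3, 1, ev, low_expr_frac = 0,
                                    noise_sd = 0.3, seed = 73)
  cmp <- comparative_values(sim$expression, paste0("N", 1:3))
  raw <- ekaryotype(cmp, sim$annotation)
  expect_equal(sum(raw$call == "loss"), 0)
  norm <- ekaryotype(cmp, sim$annotation, normalize_noise = TRUE)
  sc <- score_event_recovery(sim$truth, norm)
  expect_equal(sc$tp, 1)
  expect_equal(sc$fp, 0)
})

test_that("moving averages use the valid-window convention", {
  expect_equal(moving_average(c(5, 1, 4), 1), c(5, 1, 4))
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 3), c(1, 1, 1))
  expect_warning(out <- moving_average(1:3, 5), "exceeds")
  expect_length(out, 0)
  # constant tracks smooth to themselves
  expect_equal(moving_average(rep(2, 10), 5), rep(2, 6))
})

test_that("moving-average tracks attach window-center positions", {
  ann <- simulate_annotation(1, 20, seed = 71)
  sim <- simulate_expression_cohort(ann, 2, 1, low_expr_frac = 0,
                                    noise_sd = 0.1, seed = 71)
  cmp <- comparative_values(sim$expression, c("N1", "N2"))
  tr <- moving_average_tracks(cmp, ann, window = 5)
  one <- tr[tr$sample_id == "T1", ]
  expect_equal(nrow(one), 16)
  expect_equal(one$position, ann$start[3:18])  # centers of 5-gene windows
  expect_equal(one$smoothed, moving_average(cmp[, "T1"], 5))
})

test_that("SEG round-trips and BED keeps only aberrant segments", {
  ann <- simulate_annotation(2, 120, seed = 72)
  ev <- planted_events("T1", "chr2", 1, 120, -0.4)
  sim <- simulate_expression_cohort(ann, 3, 1, ev, low_expr_frac = 0,
                                    noise_sd = 0.2, seed = 72)
  cmp <- comparative_values(sim$expression, paste0("N", 1:3))
  segs <- ekaryotype(cmp, sim$annotation)

  segf <- withr::local_tempfile(fileext = ".seg")
  write_seg(segs, segf)
  back <- read_seg(segf)
  expect_equal(back$sample_id, segs$sample_id)
  expect_equal(back$mean_log2, segs$mean_log2, tolerance = 1e-12)
  expect_equal(back$n_genes, segs$n_genes)

  bedf <- withr::local_tempfile(fileext = ".bed")
  write_bed(segs, bedf)
  bed <- read.table(bedf, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bed), sum(segs$call != "neutral"))
  expect_true(all(bed$V4 %in% c("gain", "loss")))
  expect_true(any(segs$call == "neutral"))  # SEG kept them, BED did not

  empty <- segs[0, ]
  write_seg(empty, segf)
  expect_equal(length(readLines(segf)), 1)  # header only
})
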