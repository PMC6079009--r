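hand_table <- function() {
  data.frame(
    sample_id = paste0("S", 1:6),
    TP53 = c("deleted", "mutated", "WT", "both", "WT", "WT"),
    WWOX = c("deleted", "WT", "deleted", "WT", "WT", "mutated"),
    stringsAsFactors = FALSE)
}

test_that("contingency tables count joint perturbation status", {
  allwt <- data.frame(sample_id = paste0("S", 1:7),
                      A = rep("WT", 7), B = rep("WT", 7))
  t0 <- build_contingency(allwt, "A", "B", "homdel")
  expect_equal(as.vector(t0), c(0, 0, 0, 7))

  tab <- hand_table()
  # homdel: TP53 perturbed = S1, S4; WWOX perturbed = S1, S3
  th <- build_contingency(tab, "TP53", "WWOX", "homdel")
  expect_equal(as.vector(th), c(1, 1, 1, 3))
  # mut_or_del adds S2 (TP53) and S6 (WWOX), both singly perturbed
  tm <- build_contingency(tab, "TP53", "WWOX", "mut_or_del")
  expect_equal(as.vector(tm), c(1, 2, 2, 1))
  # switch changed only mutated-not-deleted samples
  expect_equal(sum(tm) , sum(th))

  # orientation: rows follow geneA, columns follow geneB
  asym <- data.frame(sample_id = paste0("S", 1:3),
                     A = c("deleted", "deleted", "WT"),
                     B = c("WT", "WT", "deleted"))
  ta <- build_contingency(asym, "A", "B", "homdel")
  expect_equal(ta["perturbed", "WT"], 2)
  expect_equal(ta["WT", "perturbed"], 1)

  expect_error(build_contingency(tab, "TP53", "BRCA1"), "BRCA1")
  bad <- tab; bad$TP53[1] <- "amplified"
  expect_error(build_contingency(bad, "TP53", "WWOX"), "amplified")
})

test_that("two-sided Fisher p matches frozen and reference values", {
  res <- fisher_exact_two_sided(rbind(c(1, 11), c(9, 3)))
  expect_equal(res$p_value, 0.002759456, tolerance = 1e-7)
  expect_equal(res$odds_ratio, (1 * 3) / (9 * 11))

  expect_equal(fisher_exact_two_sided(rbind(c(5, 5), c(5, 5)))$p_value, 1)

  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)), "all-zero")
  expect_equal(fisher_exact_two_sided(rbind(c(3, 0), c(0, 3)))$odds_ratio, Inf)
  expect_true(is.nan(fisher_exact_two_sided(rbind(c(0, 3), c(0, 3)))$odds_ratio))
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(100)
  for (i in 1:200) {
    t <- matrix(rpois(4, sample(1:15, 1)), 2, 2)
    if (sum(t) == 0) next
    mine <- fisher_exact_two_sided(t)$p_value
    ref <- stats::fisher.test(t)$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("Fisher p is invariant under transposition and label swaps", {
  set.seed(101)
  for (i in 1:50) {
    t <- matrix(rpois(4, 8), 2, 2)
    if (sum(t) == 0) next
    p <- fisher_exact_two_sided(t)$p_value
    expect_equal(fisher_exact_two_sided(t(t))$p_value, p, tolerance = 1e-12)
    swapped <- t[2:1, 2:1]  # swap both row and column labels
    expect_equal(fisher_exact_two_sided(swapped)$p_value, p, tolerance = 1e-12)
  }
})

test_that("KM curves reproduce product-limit arithmetic", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(1, 2/3, 1/3, 0))
  expect_equal(km$time, c(0, 1, 2, 3))

  cens <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(cens$survival, 1)  # only the t = 0 anchor; no drops

  # interleaved censoring, hand-computed products:
  # t=1 event (risk 6): 5/6; t=3 event (risk 4): 5/6 * 3/4 = 0.625;
  # t=5 event (risk 2): 0.625 * 1/2 = 0.3125
  km6 <- km_curve(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(km6$survival, c(1, 5/6, 0.625, 0.3125))

  expect_error(km_curve(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(102)
  t <- round(rexp(40, 0.2), 2)
  km <- km_curve(t, rep(1, 40))
  for (k in seq_len(nrow(km)))
    expect_equal(km$survival[k], mean(t > km$time[k]))
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("log-rank behaves at the null, under relabeling, and with power", {
  recs <- simulate_survival(c(g1 = 80, g2 = 80), c(g1 = 0.1, g2 = 0.1),
                            censor_rate = 0.02, seed = 7)
  # two copies of the same data in two groups: no signal at all
  dup <- rbind(recs, recs)
  dup$group <- rep(c("x", "y"), each = nrow(recs))
  res <- logrank_test(dup)
  expect_lt(res$chisq, 1e-10)
  expect_equal(res$df, 1)
  expect_gt(res$p_value, 0.999)

  # invariance under group relabeling
  a <- logrank_test(recs)
  relab <- recs
  relab$group <- c(g1 = "B", g2 = "A")[relab$group]
  b <- logrank_test(relab)
  expect_equal(a$chisq, b$chisq)

  # three groups: chi-square on k - 1 df
  r3 <- simulate_survival(c(a = 40, b = 40, c = 40),
                          c(a = 0.1, b = 0.1, c = 0.1), seed = 8)
  expect_equal(logrank_test(r3)$df, 2)

  # a 3x hazard ratio in groups of 200 is overwhelmingly significant
  hr <- simulate_survival(c(lo = 200, hi = 200), c(lo = 0.1, hi = 0.3),
                          censor_rate = 0.02, seed = 9)
  expect_lt(logrank_test(hr)$p_value, 1e-4)

  one <- recs[recs$group == "g1", ]
  expect_error(logrank_test(one), ">= 2 groups")
})

test_that("perturbation grouping produces the four-level vocabulary", {
  tab <- hand_table()
  g <- perturbation_groups(tab, "TP53", "WWOX", "mut_or_del")
  expect_equal(unname(g["S1"]), "both-perturbed")
  expect_equal(unname(g["S2"]), "TP53-perturbed")
  expect_equal(unname(g["S6"]), "WWOX-perturbed")
  expect_equal(unname(g["S5"]), "both-WT")
})

test_that("perturbation and survival tables round-trip through TSV", {
  tab <- simulate_perturbation_table(50, 0.3, 0.2, 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  ekaryotypeR:::write_tsv_(tab, f)
  expect_equal(read_perturbation_table(f), tab)

  recs <- simulate_survival(c(a = 30, b = 30), c(a = 0.2, b = 0.1),
                            censor_rate = 0.05, seed = 4)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  ekaryotypeR:::write_tsv_(recs, f2)
  back <- read_survival_table(f2)
  expect_equal(back$time, recs$time, tolerance = 1e-12)
  expect_equal(back$group, recs$group)
})
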