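perturb_status_levels <- c("WT", "mutated", "deleted", "both")

# TRUE where a status counts as perturbed under the chosen definition.
perturbed_flag <- function(status, definition = c("homdel", "mut_or_del")) {
  definition <- match.arg(definition)
  bad <- setdiff(unique(status), perturb_status_levels)
  if (length(bad))
    stopf("unknown perturbation status: %s", paste(bad, collapse = ", "))
  if (definition == "homdel") status %in% c("deleted", "both")
  else status != "WT"
}

#' Build a 2x2 perturbation contingency table
#'
#' Cross-counts samples by their perturbed status for two genes. The
#' `definition` selects what counts as perturbed: `"homdel"` (homozygous
#' deletion, i.e. status `deleted` or `both`) or `"mut_or_del"` (any
#' non-WT status).
#'
#' @param table Perturbation data.frame: `sample_id` plus one status column
#'   per gene, statuses from \{WT, mutated, deleted, both\}.
#' @param geneA,geneB Column names of the two genes.
#' @param definition `"homdel"` or `"mut_or_del"`.
#' @return A 2x2 integer matrix (rows: geneA perturbed/WT; columns: geneB
#'   perturbed/WT), cell [1,1] counting doubly perturbed samples.
#' @export
build_contingency <- function(table, geneA, geneB,
                              definition = c("homdel", "mut_or_del")) {
  definition <- match.arg(definition)
  for (g in c(geneA, geneB))
    if (!g %in% names(table)) stopf("gene column '%s' not in table", g)
  if (anyDuplicated(table$sample_id)) stopf("duplicate sample_id in table")
  a_flag <- perturbed_flag(table[[geneA]], definition)
  b_flag <- perturbed_flag(table[[geneB]], definition)
  m <- matrix(c(sum(a_flag & b_flag), sum(!a_flag & b_flag),
                sum(a_flag & !b_flag), sum(!a_flag & !b_flag)),
              nrow = 2L,
              dimnames = list(c("perturbed", "WT"), c("perturbed", "WT")))
  names(dimnames(m)) <- c(geneA, geneB)
  m
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by the probability-mass rule: with margins fixed, sum the
#' hypergeometric probabilities of every table whose probability does not
#' exceed the observed table's (a relative buffer of 1e-7 absorbs floating
#' ties). The odds ratio is the sample cross-product ratio `(a d)/(b c)`,
#' with `Inf`/`0` for empty off-diagonal/diagonal cells.
#'
#' @param t A 2x2 matrix of non-negative counts (e.g. from
#'   [build_contingency()]), laid out as `rbind(c(a, c), c(b, d))` so that
#'   `a` counts joint successes.
#' @return A list: `p_value`, `odds_ratio`, `table`.
#' @export
fisher_exact_two_sided <- function(t) {
  if (!is.matrix(t) || !all(dim(t) == 2L))
    stopf("`t` must be a 2x2 matrix")
  if (any(t < 0) || any(t != round(t)))
    stopf("cells must be non-negative integers")
  a <- t[1L, 1L]; c_ <- t[1L, 2L]; b <- t[2L, 1L]; d <- t[2L, 2L]
  if (sum(t) == 0L) stopf("all-zero table: test undefined")
  m <- a + b          # column-1 total (white balls)
  n2 <- c_ + d        # column-2 total
  kk <- a + c_        # row-1 total (draws)
  support <- max(0L, kk - n2):min(kk, m)
  probs <- stats::dhyper(support, m, n2, kk)
  p_obs <- stats::dhyper(a, m, n2, kk)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c_ > 0) (a * d) / (b * c_)
        else if (a * d > 0) Inf
        else NaN
  list(p_value = p, odds_ratio = or, table = t)
}

#' Four-level perturbation grouping of a cohort
#'
#' Labels every sample by its joint status for two genes, the grouping used
#' to compare survival across e.g. TP53/WWOX perturbation combinations.
#'
#' @inheritParams build_contingency
#' @return A character vector named by sample id, with levels `both-WT`,
#'   `<geneA>-perturbed`, `<geneB>-perturbed`, `both-perturbed`.
#' @export
perturbation_groups <- function(table, geneA, geneB,
                                definition = c("homdel", "mut_or_del")) {
  definition <- match.arg(definition)
  for (g in c(geneA, geneB))
    if (!g %in% names(table)) stopf("gene column '%s' not in table", g)
  a_flag <- perturbed_flag(table[[geneA]], definition)
  b_flag <- perturbed_flag(table[[geneB]], definition)
  lab <- ifelse(a_flag & b_flag, "both-perturbed",
         ifelse(a_flag, paste0(geneA, "-perturbed"),
         ifelse(b_flag, paste0(geneB, "-perturbed"), "both-WT")))
  stats::setNames(lab, table$sample_id)
}

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate: S(0) = 1, steps down only at event times,
#' censored subjects leave the risk set after their time (ties between
#' events and censorings at the same time are resolved events-first).
#'
#' @param time Non-negative observation times (or a data.frame with `time`
#'   and `event` columns).
#' @param event Event indicator (1 = event, 0 = censored); ignored when
#'   `time` is a data.frame.
#' @return A data.frame step table: `time`, `n_risk`, `n_event`,
#'   `survival`, starting at the `time = 0, survival = 1` anchor.
#' @export
km_curve <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  if (length(time) == 0L) stopf("need at least one record")
  if (any(time < 0)) stopf("survival times must be >= 0")
  if (is.null(event) || length(event) != length(time))
    stopf("need one event flag per time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  sm <- summary(fit, censored = FALSE)
  data.frame(time = c(0, sm$time),
             n_risk = c(length(time), sm$n.risk),
             n_event = c(0, sm$n.event),
             survival = c(1, sm$surv))
}

#' Log-rank test across survival groups
#'
#' The standard k-group log-rank test: observed versus expected events per
#' group summed over distinct event times, with a chi-square reference on
#' k - 1 degrees of freedom.
#'
#' @param time Observation times (or a data.frame with `time`, `event`,
#'   `group` columns).
#' @param event Event indicators.
#' @param group Group label per subject; at least two non-empty groups.
#' @return A list: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event = NULL, group = NULL) {
  if (is.data.frame(time)) {
    group <- time$group
    event <- time$event
    time <- time$time
  }
  if (any(time < 0)) stopf("survival times must be >= 0")
  group <- as.character(group)
  k <- length(unique(group))
  if (k < 2L) stopf("need >= 2 groups for a log-rank test")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- k - 1L
  list(chisq = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

#' Read a perturbation table TSV
#' @param path TSV with `sample_id` plus one status column per gene.
#' @return A data.frame.
#' @export
read_perturbation_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fill = FALSE)
  if (!"sample_id" %in% names(df)) stopf("'%s': missing sample_id column", path)
  df
}

#' Read a survival table TSV
#' @param path TSV with columns `sample_id`, `time`, `event`, `group`.
#' @return A data.frame.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fill = FALSE)
  need <- c("sample_id", "time", "event", "group")
  if (!all(need %in% names(df)))
    stopf("'%s': need columns %s", path, paste(need, collapse = ", "))
  if (any(df$time < 0)) stopf("'%s': negative survival time", path)
  df
}
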