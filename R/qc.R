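# Contaminant removal and low-abundance culling.

#' Prevalence-based contaminant identification
#'
#' For each ASV, builds the 2x2 presence/absence by negative/true-sample
#' table and scores it with the one-sided p-value against the alternative
#' "more prevalent in negative controls": a chi-square test halved in the
#' observed direction, falling back to the one-sided Fisher exact test
#' whenever any expected cell is below 5.  ASVs with `score < threshold`
#' are flagged and dropped.  An ASV absent from all negatives can never be
#' flagged at the default threshold (its one-sided score is >= 0.5 by
#' construction).
#'
#' @param table a [count_table()] containing both true samples and negative
#'   controls.
#' @param samples sample metadata with a `compartment` column
#'   (`"negative_control"` marks negatives).
#' @param threshold score threshold in (0, 1); default 0.5.
#' @return list with `report` (one row per ASV: prevalences, score, flagged)
#'   and `table` (the input with flagged ASVs removed).
#' @export
decontam_prevalence <- function(table, samples, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  samples <- samples[match(rownames(table), samples$sample_id), , drop = FALSE]
  is_neg <- samples$compartment == "negative_control"
  n_neg <- sum(is_neg); n_true <- sum(!is_neg)
  if (n_neg == 0L)
    stop("no negative-control samples: skip decontamination for this table")
  if (n_true == 0L) stop("no true samples in table")
  m <- ct_matrix(table)
  pres_neg <- colSums(m[is_neg, , drop = FALSE] > 0)
  pres_true <- colSums(m[!is_neg, , drop = FALSE] > 0)
  score <- vapply(seq_len(ncol(m)), function(j) {
    prevalence_score(pres_neg[j], n_neg, pres_true[j], n_true)
  }, numeric(1))
  report <- data.frame(
    asv_id = colnames(m),
    prevalence_in_negatives = pres_neg / n_neg,
    prevalence_in_samples = pres_true / n_true,
    score = score,
    flagged = score < threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  keep <- !report$flagged
  cleaned <- count_table(m[, keep, drop = FALSE])
  list(report = report, table = cleaned)
}

# One-sided p for "presence is more frequent in negatives than true samples".
prevalence_score <- function(a, n_neg, b, n_true) {
  tab <- rbind(present = c(a, b), absent = c(n_neg - a, n_true - b))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    return(unname(stats::fisher.test(tab, alternative = "greater")$p.value))
  }
  p2 <- unname(stats::chisq.test(tab, correct = FALSE)$p.value)
  if (a / n_neg > b / n_true) p2 / 2 else 1 - p2 / 2
}

#' Cull low-read samples and ASVs
#'
#' Drops samples whose read total is `<= min_sample_reads`, then ASVs whose
#' read total is `<= min_asv_reads`, repeating the two passes (always in that
#' order) until a fixed point, so the result is idempotent.  Thresholds of
#' zero remove exactly the all-zero rows and columns.  Study-style defaults
#' are (300, 3) for fungal and (2901, 4) for bacterial tables.
#'
#' @param table a [count_table()].
#' @param min_sample_reads,min_asv_reads inclusive read-total thresholds
#'   (totals *at or below* are removed).
#' @return the culled [count_table()], with attribute `culled` listing the
#'   removed sample and ASV ids.
#' @export
cull <- function(table, min_sample_reads = 300, min_asv_reads = 3) {
  stopifnot(min_sample_reads >= 0, min_asv_reads >= 0)
  m <- ct_matrix(table)
  dropped_s <- character(0); dropped_a <- character(0)
  repeat {
    rs <- rowSums(m)
    kill_s <- rs <= min_sample_reads
    if (any(kill_s)) {
      dropped_s <- c(dropped_s, rownames(m)[kill_s])
      m <- m[!kill_s, , drop = FALSE]
    }
    if (nrow(m) == 0L)
      stop("all samples culled at min_sample_reads = ", min_sample_reads)
    cs <- colSums(m)
    kill_a <- cs <= min_asv_reads
    if (any(kill_a)) {
      dropped_a <- c(dropped_a, colnames(m)[kill_a])
      m <- m[, !kill_a, drop = FALSE]
    }
    if (!any(kill_s) && !any(kill_a)) break
  }
  out <- count_table(m)
  attr(out, "culled") <- list(samples = dropped_s, asvs = dropped_a)
  out
}

#' Suggest a culling threshold from breaks in log read totals
#'
#' Scans the sorted, log-transformed read totals for the largest gap within
#' the lower half of the distribution and suggests the geometric midpoint of
#' that gap as an inclusive cull threshold.  Ties between equally large gaps
#' are broken toward the smallest threshold.  Purely advisory: the suggestion
#' is never auto-applied, and the confidence flag is `"low"` whenever the
#' winning gap does not clearly dominate the others (e.g. a single cluster or
#' a geometric sequence of totals).
#'
#' @param totals per-sample or per-ASV read totals, all > 0, length >= 5.
#' @return list with `threshold`, `gap` (log-scale width), `confidence`
#'   (`"high"` or `"low"`).
#' @export
suggest_break_threshold <- function(totals) {
  stopifnot(length(totals) >= 5, all(totals > 0))
  lt <- sort(log(totals))
  n <- length(lt)
  gaps <- diff(lt)
  lower <- seq_len(min(ceiling(n / 2), length(gaps)))
  g <- gaps[lower]
  # first gap within numerical tolerance of the maximum: ties (e.g. a
  # geometric sequence) break toward the smallest threshold
  i <- which(g >= max(g) - 1e-9)[1L]
  second <- if (length(g) > 1L) max(g[-i]) else 0
  confidence <- if (g[i] > 1.5 * second && g[i] > log(2)) "high" else "low"
  list(threshold = exp((lt[i] + lt[i + 1L]) / 2),
       gap = unname(g[i]), confidence = confidence)
}
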