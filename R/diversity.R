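# Richness, accumulation/sufficiency, Hill-number evenness, compartment
# overlap, and group comparisons of richness.

#' Pool replicate samples by island, compartment and locus
#'
#' Replicates are pooled by count summation.  Negative controls (island NA)
#' are excluded.
#'
#' @param table a [count_table()].
#' @param samples sample metadata.
#' @return integer matrix, one row per island x compartment x locus group,
#'   rownames `island|compartment|locus`, with attribute `groups` holding the
#'   key data.frame.
#' @export
pool_counts <- function(table, samples) {
  samples <- samples[match(rownames(table), samples$sample_id), , drop = FALSE]
  keep <- samples$compartment != "negative_control" & !is.na(samples$island_id)
  m <- ct_matrix(table)[keep, , drop = FALSE]
  s <- samples[keep, , drop = FALSE]
  key <- paste(s$island_id, s$compartment, s$locus, sep = "|")
  pooled <- rowsum(m, key)
  groups <- unique(data.frame(key = key, island_id = s$island_id,
                              compartment = s$compartment, locus = s$locus,
                              stringsAsFactors = FALSE))
  groups <- groups[match(rownames(pooled), groups$key), , drop = FALSE]
  rownames(groups) <- NULL
  attr(pooled, "groups") <- groups
  pooled
}

#' Observed ASV richness
#'
#' Counts ASVs with at least one read per unit.  With
#' `group_by = "island_compartment"` replicate samples are pooled by count
#' summation (per island x compartment x locus) before counting, so an ASV
#' seen in any replicate counts once.
#'
#' @param table a [count_table()].
#' @param samples sample metadata (required for island_compartment grouping).
#' @param group_by `"sample"` or `"island_compartment"`.
#' @return named integer vector (per sample) or a data.frame with columns
#'   island_id, compartment, locus, richness.
#' @export
observed_richness <- function(table, samples = NULL,
                              group_by = c("sample", "island_compartment")) {
  group_by <- match.arg(group_by)
  if (nrow(table) == 0L) stop("empty count table")
  if (group_by == "sample") return(rowSums(ct_matrix(table) > 0))
  if (is.null(samples)) stop("island_compartment grouping needs sample metadata")
  pooled <- pool_counts(table, samples)
  g <- attr(pooled, "groups")
  data.frame(g[c("island_id", "compartment", "locus")],
             richness = unname(rowSums(pooled > 0)),
             stringsAsFactors = FALSE)
}

#' Rarefaction (interpolated species accumulation) curve
#'
#' Expected richness at subsample depth m under sampling without replacement:
#' `E[S(m)] = S_obs - sum_i C(N - N_i, m) / C(N, m)`, evaluated through
#' [vegan::rarefy()] (log-space binomial coefficients).  No extrapolation
#' beyond the observed depth N is allowed.  The curve is declared saturated
#' when the average slope over the final 10% of the depth grid falls below
#' `asymptote_tol` species per read.
#'
#' @param counts a single (pooled) count vector.
#' @param depths increasing integer depth grid; default 50 points from 1 to N.
#' @param asymptote_tol slope tolerance for declaring an asymptote.
#' @return list of class `accumulation_curve` with `depths`,
#'   `expected_richness`, `final_slope`, `asymptote_reached`.
#' @export
rarefaction_curve <- function(counts, depths = NULL, asymptote_tol = 1e-3) {
  counts <- counts[counts > 0]
  n_reads <- sum(counts)
  if (n_reads < 1) stop("community has no reads")
  if (is.null(depths))
    depths <- unique(round(seq(1, n_reads, length.out = 50)))
  depths <- sort(unique(as.integer(depths)))
  if (max(depths) > n_reads)
    stop("depth ", max(depths), " exceeds total reads ", n_reads,
         " (no extrapolation)")
  es <- as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = depths))
  tail_from <- depths >= stats::quantile(range(depths), 0.9)
  idx <- which(tail_from)
  final_slope <- if (length(idx) >= 2L) {
    (es[max(idx)] - es[min(idx)]) / (depths[max(idx)] - depths[min(idx)])
  } else if (length(depths) >= 2L) {
    k <- length(depths)
    (es[k] - es[k - 1L]) / (depths[k] - depths[k - 1L])
  } else NA_real_
  structure(list(depths = depths, expected_richness = es,
                 final_slope = final_slope,
                 asymptote_reached = is.finite(final_slope) &&
                   final_slope < asymptote_tol),
            class = "accumulation_curve")
}

#' Hill number of order one (effective species number)
#'
#' `exp(-sum p_i ln p_i)` over the relative abundances of the non-zero
#' entries; an evenness-sensitive effective number of species, equal to the
#' richness for a perfectly even community and 1 for a monoculture.
#' Invariant to rescaling the counts.
#'
#' @param counts count vector with positive total.
#' @return effective species number in `[1, richness]`.
#' @export
hill_q1 <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("community has no reads")
  p <- counts[counts > 0] / total
  exp(-sum(p * log(p)))
}

#' Per-island evenness records
#'
#' Hill q = 1 and richness per pooled island x compartment x locus community.
#'
#' @param table a [count_table()].
#' @param samples sample metadata.
#' @return data.frame with island_id, compartment, locus, richness, q1.
#' @export
evenness_records <- function(table, samples) {
  pooled <- pool_counts(table, samples)
  g <- attr(pooled, "groups")
  data.frame(g[c("island_id", "compartment", "locus")],
             richness = unname(rowSums(pooled > 0)),
             q1 = apply(pooled, 1, hill_q1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress evenness on log island size
#'
#' Diagnoses "disproportionate effects": a significant slope of Hill q = 1
#' on log area means community evenness itself changes with island size.
#'
#' @param records output of [evenness_records()] (one compartment/locus).
#' @param islands island metadata.
#' @param size_field `"detritus_weight_mg"` or `"water_volume_ml"`.
#' @return an `island_regression` (slope, R-squared, two-sided p).
#' @export
evenness_vs_size <- function(records, islands,
                             size_field = c("detritus_weight_mg",
                                            "water_volume_ml")) {
  size_field <- match.arg(size_field)
  size <- islands[[size_field]][match(records$island_id, islands$island_id)]
  simple_regression(log(size), records$q1,
                    xlab = paste0("log(", size_field, ")"), ylab = "q1")
}

#' ASV overlap among compartments
#'
#' Pools presence per compartment (union over all samples) and returns every
#' Venn region count over the observed compartments, plus pairwise shared
#' fractions.  Region counts form an exact partition of the pooled union.
#'
#' @param table a [count_table()].
#' @param samples sample metadata.
#' @param locus optional locus to restrict to.
#' @return list with `presence` (compartment x ASV logical matrix), `regions`
#'   (named counts, names like `"detritus+water"`), `union_size`, and
#'   `shared_fraction` (matrix: fraction of row compartment's ASVs also in
#'   column compartment).
#' @export
compartment_overlap <- function(table, samples, locus = NULL) {
  samples <- samples[match(rownames(table), samples$sample_id), , drop = FALSE]
  keep <- samples$compartment != "negative_control"
  if (!is.null(locus)) keep <- keep & samples$locus == locus
  m <- ct_matrix(table)[keep, , drop = FALSE]
  s <- samples[keep, , drop = FALSE]
  comps <- intersect(COMPARTMENTS, unique(s$compartment))
  if (length(comps) < 2L) stop("need at least 2 compartments")
  presence <- t(vapply(comps, function(cc) {
    colSums(m[s$compartment == cc, , drop = FALSE] > 0) > 0
  }, logical(ncol(m))))
  rownames(presence) <- comps
  in_union <- colSums(presence) > 0
  pat <- apply(presence[, in_union, drop = FALSE], 2, function(v)
    paste(comps[v], collapse = "+"))
  regions <- table(pat)
  shared <- outer(comps, comps, Vectorize(function(a, b) {
    na <- sum(presence[a, ])
    if (na == 0) return(NA_real_)
    sum(presence[a, ] & presence[b, ]) / na
  }))
  dimnames(shared) <- list(comps, comps)
  list(presence = presence,
       regions = stats::setNames(as.integer(regions), names(regions)),
       union_size = sum(in_union),
       shared_fraction = shared)
}

#' One-way ANOVA of richness among compartments with Tukey HSD
#'
#' @param richness numeric richness values.
#' @param groups compartment labels (coerced to factor).
#' @return list with `f`, `p`, `tukey` (data.frame of pairwise comparisons
#'   with studentized-range adjusted p), and the underlying `aov` fit.
#' @export
richness_anova <- function(richness, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("need at least 2 observations per group")
  fit <- stats::aov(richness ~ groups)
  tab <- summary(fit)[[1L]]
  f <- tab[["F value"]][1L]; p <- tab[["Pr(>F)"]][1L]
  if (!is.finite(f)) { f <- NA_real_; p <- NA_real_ }
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
  list(f = f, p = p, tukey = tukey, aov = fit)
}
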