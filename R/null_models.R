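# Null-model inference: abundance-weighted Raup-Crick Bray-Curtis turnover,
# NODF nestedness, margin-preserving binary randomization, and
# z-score/permutation significance summaries.

#' Abundance-weighted Raup-Crick Bray-Curtis
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity
#' against a null in which each sample's observed richness of species is
#' drawn without replacement with probability proportional to occurrence
#' frequency across the table's samples, and its observed read total is then
#' distributed multinomially over the drawn species with probability
#' proportional to metacommunity relative abundance.  The percentile of the
#' observed value in the null distribution (ties counted half) is rescaled to
#' `[-1, 1]`: values <= -0.95 indicate communities more similar than the
#' null expects (homogenizing processes), >= +0.95 more divergent
#' (environmental filtering / dispersal limitation with drift), and
#' intermediate values are consistent with drift.
#'
#' @param table a [count_table()] (the metacommunity = all its samples).
#' @param reps null replicates per pair; convention 999.
#' @param seed RNG seed.
#' @return object of class `rc_bray`: `values` (symmetric matrix, diagonal
#'   NA), `reps`, `seed`.
#' @export
rc_bray <- function(table, reps = 999, seed = NULL) {
  m <- ct_matrix(table)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 samples with reads")
  occ <- colSums(m > 0)
  pool <- which(occ > 0)
  freq <- occ[pool]
  gamma <- colSums(m)[pool]
  gamma <- gamma / sum(gamma)
  S <- rowSums(m > 0)
  if (any(S > length(pool)))
    stop("sample richness exceeds the species pool")
  totals <- rowSums(m)
  obs <- as.matrix(vegan::vegdist(m, method = "bray"))
  vals <- matrix(NA_real_, n, n, dimnames = dimnames(obs))
  with_seed(seed, {
    null_sample <- function(i) {
      sp <- sample(seq_along(pool), S[i], replace = FALSE, prob = freq)
      reads <- stats::rmultinom(1, totals[i], gamma[sp])[, 1L]
      list(sp = sp, reads = reads)
    }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d_obs <- obs[i, j]
        below <- 0; equal <- 0
        for (r in seq_len(reps)) {
          a <- null_sample(i); b <- null_sample(j)
          union_sp <- union(a$sp, b$sp)
          va <- numeric(length(union_sp)); vb <- numeric(length(union_sp))
          va[match(a$sp, union_sp)] <- a$reads
          vb[match(b$sp, union_sp)] <- b$reads
          d_null <- sum(abs(va - vb)) / (totals[i] + totals[j])
          if (d_null < d_obs - 1e-12) below <- below + 1
          else if (abs(d_null - d_obs) <= 1e-12) equal <- equal + 1
        }
        rc <- (below + 0.5 * equal) / reps
        vals[i, j] <- vals[j, i] <- 2 * (rc - 0.5)
      }
    }
  })
  structure(list(values = vals, reps = as.integer(reps), seed = seed),
            class = "rc_bray")
}

#' @export
print.rc_bray <- function(x, ...) {
  v <- upper_tri(x$values)
  cat(sprintf("rc_bray: %d pairs, reps = %d; fraction > 0.95: %.3f, < -0.95: %.3f\n",
              length(v), x$reps, mean(v > 0.95), mean(v < -0.95)))
  invisible(x)
}

#' Compartment presence-absence matrix
#'
#' Pools all samples within each compartment (union of observed ASVs) into a
#' binary compartments x ASVs matrix, rows ordered detritus, water,
#' invertebrate.  All-zero ASV columns are removed; empty compartments are
#' dropped with a warning.
#'
#' @param table a [count_table()].
#' @param samples sample metadata.
#' @param locus optional locus restriction.
#' @return binary integer matrix.
#' @export
build_compartment_matrix <- function(table, samples, locus = NULL) {
  samples <- samples[match(rownames(table), samples$sample_id), , drop = FALSE]
  keep <- samples$compartment != "negative_control"
  if (!is.null(locus)) keep <- keep & samples$locus == locus
  m <- ct_matrix(table)[keep, , drop = FALSE]
  s <- samples[keep, , drop = FALSE]
  comps <- intersect(c("detritus", "water", "invertebrate"),
                     unique(s$compartment))
  if (length(comps) < 2L) stop("need at least 2 compartments")
  out <- t(vapply(comps, function(cc) {
    as.integer(colSums(m[s$compartment == cc, , drop = FALSE] > 0) > 0)
  }, integer(ncol(m))))
  rownames(out) <- comps
  empty <- rowSums(out) == 0
  if (any(empty)) {
    warning("empty compartment(s) dropped: ", id_list(comps[empty]))
    out <- out[!empty, , drop = FALSE]
  }
  out[, colSums(out) > 0, drop = FALSE]
}

#' NODF nestedness of a binary matrix
#'
#' For every pair of rows (and, symmetrically, columns) with unequal fills,
#' the paired nestedness is `100 * |overlap| / fill_smaller`; equal fills
#' contribute 0.  NODF is the sum over all row pairs and all column pairs
#' divided by the total number of pairs `R(R-1)/2 + C(C-1)/2`.  The matrix is
#' used as given — no re-sorting is needed because the pairwise fill
#' comparison makes the statistic order-independent.
#'
#' @param m binary matrix, at least 2 x 2.
#' @return NODF in `[0, 100]`.
#' @export
nodf <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("NODF needs a binary (0/1) matrix")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least 2 rows and 2 columns")
  storage.mode(m) <- "double"
  paired_sum <- function(overlap, fill) {
    # sum over ordered pairs (i, j), fill_i > fill_j > 0, of 100*O_ij/fill_j
    fi <- matrix(fill, length(fill), length(fill))          # fill_i by row
    fj <- t(fi)                                             # fill_j by col
    contrib <- 100 * overlap / fj
    contrib[!(fi > fj & fj > 0)] <- 0
    sum(contrib)
  }
  # grouping columns by their (few) distinct patterns gives the identical
  # sum at O(#patterns^2) instead of O(C^2) when rows are few
  paired_sum_cols_grouped <- function(m) {
    pat <- as.integer(2^(seq_len(nrow(m)) - 1) %*% m)
    counts <- table(pat)
    reps <- m[, match(as.integer(names(counts)), pat), drop = FALSE]
    fill <- colSums(reps)
    ov <- crossprod(reps)
    n <- as.numeric(counts)
    tot <- 0
    for (p in seq_along(n)) for (q in seq_along(n)) {
      if (fill[p] > fill[q] && fill[q] > 0)
        tot <- tot + n[p] * n[q] * 100 * ov[p, q] / fill[q]
    }
    tot
  }
  srow <- paired_sum(tcrossprod(m), rowSums(m))
  scol <- if (2^nrow(m) < ncol(m) / 2) paired_sum_cols_grouped(m)
          else paired_sum(crossprod(m), colSums(m))
  npairs <- nrow(m) * (nrow(m) - 1) / 2 + ncol(m) * (ncol(m) - 1) / 2
  (srow + scol) / npairs
}

#' Margin-preserving binary matrix randomization
#'
#' Generates null binary matrices with exactly the input's row and column
#' sums.  `"quasiswap"` builds each null independently: a random integer
#' matrix with the target margins (Patefield's algorithm,
#' [stats::r2dtable()]) is reduced to binarity by 2x2 quasiswap updates that
#' never increase the sum of squares, then mixed with `mix_trials` trial
#' swaps (random 2x2 submatrix, swapped iff it is a checkerboard).  The
#' trial-swap chain has a symmetric transition kernel whose stationary
#' distribution over the margin class is uniform, removing the small
#' constructive bias of the reduction alone.  `"curveball"` is the
#' sequential pairwise row-trade chain with burn-in and thinning.
#'
#' @param m binary matrix.
#' @param n_sim number of null matrices.
#' @param seed RNG seed.
#' @param method `"quasiswap"` or `"curveball"`.
#' @param mix_trials trial swaps per null (quasiswap); default
#'   `max(1000, 2 * fill)`.
#' @param burnin,thin curveball trade counts before the first sample and
#'   between samples.
#' @return list of binary matrices, length `n_sim`.
#' @export
quasiswap_nulls <- function(m, n_sim = 1, seed = NULL,
                            method = c("quasiswap", "curveball"),
                            mix_trials = NULL, burnin = 1000, thin = 100) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("need a binary (0/1) matrix")
  storage.mode(m) <- "integer"
  with_seed(seed, {
    if (method == "quasiswap") {
      if (is.null(mix_trials)) mix_trials <- max(1000L, 2L * sum(m))
      starts <- stats::r2dtable(n_sim, rowSums(m), colSums(m))
      lapply(starts, function(x) {
        out <- quasiswap_binarize(x, as.integer(mix_trials))
        dimnames(out) <- dimnames(m)
        out
      })
    } else {
      cur <- m
      out <- vector("list", n_sim)
      for (k in seq_len(n_sim)) {
        cur <- curveball_trades(cur, as.integer(if (k == 1L) burnin else thin))
        keep <- cur
        dimnames(keep) <- dimnames(m)
        out[[k]] <- keep
      }
      out
    }
  })
}

#' @rdname quasiswap_nulls
#' @export
quasiswap <- function(m, seed = NULL, method = c("quasiswap", "curveball")) {
  quasiswap_nulls(m, n_sim = 1, seed = seed, method = match.arg(method))[[1L]]
}

#' Null-model significance summary
#'
#' z-score and two-sided permutation p for an observed statistic against
#' `n_null` margin-preserving randomizations:
#' `z = (obs - mean(null)) / sd(null)`;
#' `p = min(1, 2 * min((#null <= obs) + 1, (#null >= obs) + 1) / (n_null + 1))`.
#' With a degenerate null (sd 0) z is NA but p is still reported from counts.
#'
#' @param observed observed statistic.
#' @param statistic function mapping a binary matrix to the statistic.
#' @param m binary matrix defining the margin class.
#' @param n_null null matrices (>= 99); convention 1000.
#' @param seed RNG seed.
#' @param method randomization algorithm, see [quasiswap_nulls()].
#' @return object of class `nestedness_result`: `observed`, `null_mean`,
#'   `null_sd`, `z`, `p`, `n_null`.
#' @export
null_compare <- function(observed, statistic, m, n_null = 1000, seed = NULL,
                         method = "quasiswap") {
  if (n_null < 99) stop("need at least 99 null matrices")
  nulls <- quasiswap_nulls(m, n_sim = n_null, seed = seed, method = method)
  stat_null <- vapply(nulls, statistic, numeric(1))
  mu <- mean(stat_null); sdn <- stats::sd(stat_null)
  z <- if (sdn > 0) (observed - mu) / sdn else NA_real_
  p_low <- (sum(stat_null <= observed) + 1) / (n_null + 1)
  p_high <- (sum(stat_null >= observed) + 1) / (n_null + 1)
  structure(list(observed = observed, null_mean = mu, null_sd = sdn,
                 z = z, p = min(1, 2 * min(p_low, p_high)),
                 n_null = as.integer(n_null)),
            class = "nestedness_result")
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf("null model: observed = %.3f, null = %.3f +/- %.3f, z = %.2f, p = %.4g (%d nulls)\n",
              x$observed, x$null_mean, x$null_sd, x$z, x$p, x$n_null))
  invisible(x)
}

#' NODF nestedness test for the compartment matrix
#'
#' Convenience wrapper: builds the compartments x ASVs presence matrix,
#' computes observed NODF and compares it against margin-preserving nulls.
#'
#' @param table a [count_table()].
#' @param samples sample metadata.
#' @param locus optional locus restriction.
#' @param n_null null matrices; convention 1000.
#' @param seed RNG seed.
#' @return a `nestedness_result` with the matrix in `$matrix`.
#' @export
nodf_test <- function(table, samples, locus = NULL, n_null = 1000,
                      seed = NULL) {
  m <- build_compartment_matrix(table, samples, locus = locus)
  res <- null_compare(nodf(m), nodf, m, n_null = n_null, seed = seed)
  res$matrix <- m
  res
}
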