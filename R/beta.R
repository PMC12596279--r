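# Spatial turnover: Bray-Curtis dissimilarity, Mantel tests against island
# size, composition-vs-size regressions with island-resampled bootstrap
# slopes, and within-island multivariate beta dispersion.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on raw counts (via
#' [vegan::vegdist()]); symmetric, zero diagonal, values in `[0, 1]`.
#' Samples with zero reads are an error — drop them upstream (e.g. [cull()]).
#'
#' @param table a [count_table()] or count matrix.
#' @return a `dist` object with sample ids as labels.
#' @export
bray_curtis <- function(table) {
  m <- ct_matrix(table)
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty))
    stop("samples with zero reads (drop upstream): ", id_list(empty))
  vegan::vegdist(m, method = "bray")
}

#' Pairwise island-size distance matrix
#'
#' `d(i, j) = |log size_i - log size_j|` by default (SARs are fitted in log
#' space); `log = FALSE` gives raw differences.
#'
#' @param islands island metadata.
#' @param size_field `"detritus_weight_mg"` or `"water_volume_ml"`.
#' @param log log-transform sizes first (default TRUE).
#' @return a `dist` object with island ids as labels.
#' @export
size_distance <- function(islands, size_field = c("detritus_weight_mg",
                                                  "water_volume_ml"),
                          log = TRUE) {
  size_field <- match.arg(size_field)
  v <- islands[[size_field]]
  stopifnot(all(v > 0))
  if (log) v <- base::log(v)
  d <- stats::dist(v)
  attr(d, "Labels") <- islands$island_id
  d
}

# align two dist objects on shared labels, in the order of the first
align_dists <- function(d1, d2) {
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (is.null(l1) || is.null(l2)) {
    if (attr(d1, "Size") != attr(d2, "Size"))
      stop("distance matrices differ in size and carry no labels")
    return(list(d1 = d1, d2 = d2))
  }
  common <- intersect(l1, l2)
  if (length(common) < 4L) stop("fewer than 4 shared ids between matrices")
  m1 <- as.matrix(d1)[common, common]
  m2 <- as.matrix(d2)[common, common]
  list(d1 = stats::as.dist(m1), d2 = stats::as.dist(m2))
}

#' Mantel test with Spearman correlation
#'
#' Spearman correlation of the unfolded upper triangles, with a one-sided
#' (greater) permutation p-value obtained by jointly permuting the rows and
#' columns of one matrix: `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`
#' (via [vegan::mantel()]).  A constant triangle in either matrix leaves r
#' undefined and is reported as NA.
#'
#' @param d_comm,d_size `dist` objects with matching ids.
#' @param n_perm number of permutations; study convention 9999.
#' @param seed RNG seed for reproducible permutations.
#' @return object of class `mantel_result`: `r`, `p`, `n_perm`, `seed`, `n`.
#' @export
mantel_spearman <- function(d_comm, d_size, n_perm = 9999, seed = NULL) {
  al <- align_dists(d_comm, d_size)
  n <- attr(al$d1, "Size")
  if (n < 4L) stop("need at least 4 objects")
  if (stats::sd(al$d1) == 0 || stats::sd(al$d2) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          seed = seed, n = n,
                          note = "constant distance matrix: r undefined"),
                     class = "mantel_result"))
  }
  mt <- with_seed(seed, vegan::mantel(al$d1, al$d2, method = "spearman",
                                      permutations = n_perm))
  structure(list(r = unname(mt$statistic), p = mt$signif,
                 n_perm = n_perm, seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (Spearman): r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Regression of community dissimilarity on island-size distance
#'
#' OLS of the unfolded Bray-Curtis upper triangle on the unfolded size
#' distances, with a bootstrap slope distribution.  The default bootstrap
#' resamples *islands* (rebuilding both triangles from the resampled index
#' set) rather than pairwise entries, respecting the dependence among pairs
#' that share an island; `scheme = "pairs"` gives the naive pair bootstrap
#' for comparison.
#'
#' @param d_comm,d_size `dist` objects with matching ids.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param scheme `"islands"` (default) or `"pairs"`.
#' @return list with `fit` (`island_regression`) and `slopes`
#'   (`bootstrap_slopes`-like object).
#' @export
composition_size_regression <- function(d_comm, d_size, B = 1000, seed = NULL,
                                        scheme = c("islands", "pairs")) {
  scheme <- match.arg(scheme)
  if (B < 2) stop("B must be at least 2")
  al <- align_dists(d_comm, d_size)
  mc <- as.matrix(al$d1); ms <- as.matrix(al$d2)
  y <- upper_tri(mc); x <- upper_tri(ms)
  if (stats::sd(x) == 0) stop("constant size distances")
  fit <- simple_regression(x, y, xlab = "size distance",
                           ylab = "community dissimilarity")
  n <- nrow(mc)
  ut <- upper.tri(mc)
  slopes <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        if (scheme == "islands") {
          idx <- sample.int(n, n, replace = TRUE)
          xb <- ms[idx, idx][ut]; yb <- mc[idx, idx][ut]
        } else {
          pk <- sample.int(length(x), length(x), replace = TRUE)
          xb <- x[pk]; yb <- y[pk]
        }
        if (stats::var(xb) > 0) break
      }
      unname(ols_coef(xb, yb)["slope"])
    }, numeric(1))
  })
  list(fit = fit,
       slopes = structure(list(slopes = slopes, B = as.integer(B),
                               seed = seed, point = fit$slope, n = n),
                          class = "bootstrap_slopes"))
}

#' Multivariate beta dispersion (distance to group centroid)
#'
#' Principal-coordinates embedding of the dissimilarity matrix with
#' Anderson's negative-eigenvalue correction: squared centroid distances are
#' the squared distances in the positive-eigenvalue axes minus those in the
#' negative-eigenvalue axes, clamped at zero before the square root (via
#' [vegan::betadisper()], `type = "centroid"`).  Singleton groups get
#' distance 0.
#'
#' @param d a `dist` object (e.g. [bray_curtis()]).
#' @param groups island id per sample.
#' @return object of class `dispersion_result`: `distances` (named per
#'   sample), `groups`, `n_negative_eig`, `max_negative_eig`.
#' @export
beta_dispersion <- function(d, groups) {
  groups <- factor(groups)
  if (!any(table(groups) >= 2L))
    stop("need at least one group with 2 or more members")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  eig <- bd$eig
  structure(list(distances = bd$distances, groups = groups,
                 n_negative_eig = sum(eig < 0),
                 max_negative_eig = if (any(eig < 0)) max(abs(eig[eig < 0]))
                                    else 0,
                 betadisper = bd),
            class = "dispersion_result")
}

#' Regress per-sample beta dispersion on log island size
#'
#' @param disp a [beta_dispersion()] result grouped by island.
#' @param islands island metadata.
#' @param size_field `"detritus_weight_mg"` or `"water_volume_ml"`.
#' @return an `island_regression`.
#' @export
dispersion_vs_size <- function(disp, islands,
                               size_field = c("detritus_weight_mg",
                                              "water_volume_ml")) {
  size_field <- match.arg(size_field)
  tab <- table(disp$groups)
  multi <- names(tab)[tab >= 2L]
  if (length(multi) < 3L)
    stop("need at least 3 islands with 2+ samples")
  keep <- disp$groups %in% multi
  size <- islands[[size_field]][match(as.character(disp$groups)[keep],
                                      islands$island_id)]
  simple_regression(log(size), disp$distances[keep],
                    xlab = paste0("log(", size_field, ")"),
                    ylab = "distance to centroid")
}
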