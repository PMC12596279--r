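# Power-law species-area relationship fitting, bootstrap slope
# distributions, and multiplicity-corrected slope comparisons.

#' Fit a power-law species-area relationship
#'
#' OLS of log richness on log island size (natural logs): the power law
#' `S = c A^z` becomes `log S = log c + z log A`.  The slope is the SAR
#' exponent z; the intercept is log c on the natural-log scale.  Zero
#' richness values are an error (log undefined): drop those islands or apply
#' an explicit offset upstream — no silent `+1` is applied.
#'
#' @param richness per-island richness values, all > 0.
#' @param sizes per-island sizes, all > 0, same length.
#' @param compartment,locus,size_field optional labels carried into the
#'   result.
#' @return object of class `sar_fit`: slope, intercept, slope_se, r_squared,
#'   p_value (two-sided slope test), n, labels.
#' @export
fit_sar <- function(richness, sizes, compartment = NA_character_,
                    locus = NA_character_, size_field = NA_character_) {
  if (length(richness) != length(sizes))
    stop("richness and sizes differ in length")
  keep <- is.finite(richness) & is.finite(sizes)
  richness <- richness[keep]; sizes <- sizes[keep]
  if (length(richness) < 3L) stop("need at least 3 islands")
  if (any(richness <= 0))
    stop("zero or negative richness: drop those islands or apply an explicit ",
         "offset before fitting (no silent +1)")
  if (any(sizes <= 0)) stop("island sizes must be positive")
  reg <- simple_regression(log(sizes), log(richness),
                           xlab = "log(size)", ylab = "log(richness)")
  structure(list(compartment = compartment, locus = locus,
                 size_field = size_field,
                 slope = reg$slope, intercept = reg$intercept,
                 slope_se = reg$slope_se, r_squared = reg$r_squared,
                 p_value = reg$p_value, p_adjusted = NA_real_, n = reg$n),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR fit%s: z = %.4f (SE %.3g), log c = %.3f, R2 = %.3f, p = %.3g, n = %d\n",
              if (is.na(x$compartment)) "" else paste0(" [", x$compartment,
                if (is.na(x$locus)) "" else paste0("/", x$locus), "]"),
              x$slope, x$slope_se, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Fit the full SAR family for a bundle
#'
#' Mirrors the study design: per locus, four SARs — detritus richness over
#' detritus weight, water richness over water volume, and invertebrate
#' richness over both detritus weight and water volume.  Richness is pooled
#' per island x compartment.  p-values are Benjamini-Hochberg corrected
#' across the whole family, and the SAR exponent is reported as `z_score`
#' only for family-significant fits (adjusted p <= alpha).
#'
#' @param bundle a `sar_bundle`.
#' @param alpha significance level for reporting z-scores.
#' @return data.frame, one row per fitted SAR.
#' @export
sar_table <- function(bundle, alpha = 0.05) {
  rich <- observed_richness(bundle$table, bundle$samples,
                            group_by = "island_compartment")
  plan <- data.frame(
    compartment = c("detritus", "water", "invertebrate", "invertebrate"),
    size_field = c("detritus_weight_mg", "water_volume_ml",
                   "detritus_weight_mg", "water_volume_ml"),
    stringsAsFactors = FALSE)
  rows <- list()
  for (locus in unique(rich$locus)) {
    for (k in seq_len(nrow(plan))) {
      comp <- plan$compartment[k]; sf <- plan$size_field[k]
      sub <- rich[rich$locus == locus & rich$compartment == comp &
                    rich$richness > 0, , drop = FALSE]
      if (nrow(sub) < 3L) next
      sizes <- bundle$islands[[sf]][match(sub$island_id,
                                          bundle$islands$island_id)]
      f <- fit_sar(sub$richness, sizes, compartment = comp, locus = locus,
                   size_field = sf)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, compartment = comp, size_field = sf,
        n = f$n, r_squared = f$r_squared, slope = f$slope,
        slope_se = f$slope_se, intercept = f$intercept, p_value = f$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$significant <- out$p_adjusted <= alpha
  out$z_score <- ifelse(out$significant, out$slope, NA_real_)
  out
}

#' Case-bootstrap distribution of SAR slopes
#'
#' Resamples (richness, size) island pairs jointly with replacement to the
#' original n, refits the log-log OLS slope, B times.  Resamples with zero
#' size variance (all draws the same island) are redrawn and counted in the
#' `n_redrawn` attribute.
#'
#' @param richness,sizes per-island values, all > 0.
#' @param B number of bootstrap replicates (>= 2); study convention 1000.
#' @param seed RNG seed; same seed gives an identical slope vector.
#' @return object of class `bootstrap_slopes`: `slopes` (length B), `B`,
#'   `seed`, `point` (the full-data OLS slope), `n`.
#' @export
bootstrap_slopes <- function(richness, sizes, B = 1000, seed = NULL) {
  if (B < 2) stop("B must be at least 2")
  stopifnot(length(richness) == length(sizes), all(richness > 0),
            all(sizes > 0))
  n <- length(richness)
  if (n < 3L) stop("need at least 3 islands")
  lx <- log(sizes); ly <- log(richness)
  point <- unname(ols_coef(lx, ly)["slope"])
  n_redrawn <- 0L
  slopes <- with_seed(seed, {
    boot_slope_block <- function(b) {
      idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
      X <- matrix(lx[idx], nrow = n); Y <- matrix(ly[idx], nrow = n)
      mx <- colMeans(X); my <- colMeans(Y)
      vx <- colMeans(X * X) - mx * mx
      s <- (colMeans(X * Y) - mx * my) / vx
      s[vx <= 0] <- NA_real_
      s
    }
    s <- boot_slope_block(B)
    while (anyNA(s)) {
      bad <- which(is.na(s))
      n_redrawn <- n_redrawn + length(bad)
      s[bad] <- boot_slope_block(length(bad))
    }
    s
  })
  structure(list(slopes = slopes, B = as.integer(B), seed = seed,
                 point = point, n = n, n_redrawn = n_redrawn),
            class = "bootstrap_slopes")
}

#' @export
print.bootstrap_slopes <- function(x, ...) {
  q <- stats::quantile(x$slopes, c(0.025, 0.975))
  cat(sprintf("bootstrap_slopes: B = %d, point = %.4f, mean = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$B, x$point, mean(x$slopes), q[1], q[2]))
  invisible(x)
}

#' Welch comparison of two bootstrap slope distributions
#'
#' Welch two-sample t-test on the two slope vectors with
#' Welch-Satterthwaite degrees of freedom (always <= B_a + B_b - 2).  When
#' both vectors are constant the statistic is undefined and reported as NA.
#'
#' @param a,b `bootstrap_slopes` objects.
#' @param labels optional length-2 character labels for the pair.
#' @return object of class `slope_comparison`: `t`, `df`, `p_value`,
#'   `p_adjusted` (NA until corrected across a family), `labels`.
#' @export
compare_slopes <- function(a, b, labels = c("a", "b")) {
  stopifnot(inherits(a, "bootstrap_slopes"), inherits(b, "bootstrap_slopes"))
  if (stats::var(a$slopes) == 0 && stats::var(b$slopes) == 0) {
    return(structure(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                          p_adjusted = NA_real_, labels = labels),
                     class = "slope_comparison"))
  }
  tt <- stats::t.test(a$slopes, b$slopes, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, p_adjusted = NA_real_,
                 labels = labels),
            class = "slope_comparison")
}

#' All pairwise slope comparisons with BH correction
#'
#' @param boots named list of `bootstrap_slopes`.
#' @return data.frame of Welch statistics with `p_adjusted` corrected across
#'   the comparison family.
#' @export
compare_slopes_table <- function(boots) {
  stopifnot(is.list(boots), length(boots) >= 2L, !is.null(names(boots)))
  pairs <- utils::combn(names(boots), 2)
  rows <- apply(pairs, 2, function(pr) {
    cmp <- compare_slopes(boots[[pr[1]]], boots[[pr[2]]], labels = pr)
    data.frame(a = pr[1], b = pr[2], t = cmp$t, df = cmp$df,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' preserving input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
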