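# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic per-stage child seed
#'
#' Derives a stage-specific seed from a master seed so that toggling one
#' pipeline stage never shifts the random stream of another.
#'
#' @param seed master seed (integer).
#' @param stage stage name (character scalar).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop()/warning() with a comma-separated enumeration of every offending id
id_list <- function(ids, max_show = 50L) {
  ids <- as.character(ids)
  if (length(ids) > max_show) {
    ids <- c(ids[seq_len(max_show)], sprintf("... (%d more)", length(ids) - max_show))
  }
  paste(ids, collapse = ", ")
}

# Closed-form OLS of y on x; returns c(slope, intercept).  Used on hot paths
# (bootstrap) where lm() would dominate runtime.
ols_coef <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- mean(x * x) - mx * mx
  if (vx <= 0) return(c(slope = NA_real_, intercept = NA_real_))
  b <- (mean(x * y) - mx * my) / vx
  c(slope = b, intercept = my - b * mx)
}

# Simple OLS fit with slope inference, shared by the *_vs_size regressions.
simple_regression <- function(x, y, xlab = "x", ylab = "y") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("regression needs at least 3 complete observations, got ", length(x))
  if (stats::var(x) == 0)
    stop("predictor '", xlab, "' has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope_row <- stats::coef(sm)["x", ]
  structure(
    list(slope = unname(slope_row["Estimate"]),
         intercept = unname(stats::coef(fit)[1L]),
         slope_se = unname(slope_row["Std. Error"]),
         r_squared = sm$r.squared,
         p_value = unname(slope_row["Pr(>|t|)"]),
         n = length(x), xlab = xlab, ylab = ylab, fit = fit),
    class = "island_regression")
}

#' @export
print.island_regression <- function(x, ...) {
  cat(sprintf("OLS %s ~ %s: slope = %.4g (SE %.3g), R2 = %.3f, p = %.3g, n = %d\n",
              x$ylab, x$xlab, x$slope, x$slope_se, x$r_squared, x$p_value, x$n))
  invisible(x)
}

upper_tri <- function(m) m[upper.tri(m)]
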