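# Environmental-predictor modelling: AIC stepwise multiple regression and
# LMG relative-importance decomposition.

# error if any candidate pair is (near-)collinear, naming the pair
check_collinearity <- function(X, tol = 0.999) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(invisible(X))
  cm <- suppressWarnings(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  cm[lower.tri(cm, diag = TRUE)] <- 0
  bad <- which(abs(cm) > tol, arr.ind = TRUE)
  if (nrow(bad)) {
    pr <- bad[1L, ]
    stop("collinear candidate predictors: '", colnames(X)[pr[1]], "' and '",
         colnames(X)[pr[2]], "' (|r| > ", tol, ")")
  }
  const <- colnames(X)[apply(X, 2, function(v) stats::var(v) == 0)]
  if (length(const))
    stop("constant candidate predictor(s): ", id_list(const))
  invisible(X)
}

#' Stepwise AIC model selection
#'
#' Greedy stepwise linear-model selection minimizing
#' `AIC = n log(RSS/n) + 2k` (the conventional lm stepwise criterion, via
#' [MASS::stepAIC()]).  `"both"` and `"backward"` start from the full model;
#' `"forward"` from the intercept.  Rows with missing values are dropped
#' (complete-case) and counted.
#'
#' @param response numeric response vector.
#' @param candidates data.frame of candidate predictors.
#' @param direction `"both"`, `"forward"` or `"backward"`.
#' @return object of class `stepwise_model`: `selected` predictor names,
#'   `coefficients` (data.frame with estimates and p-values), `aic`,
#'   `r_squared`, `n`, `n_dropped` (incomplete rows), `trace` (step, AIC).
#' @export
step_aic <- function(response, candidates,
                     direction = c("both", "forward", "backward")) {
  direction <- match.arg(direction)
  candidates <- as.data.frame(candidates)
  df <- cbind(data.frame(.response = response), candidates)
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  k <- ncol(candidates)
  if (nrow(df) <= k + 2L)
    stop("need n > k + 2 complete cases for the full model (n = ", nrow(df),
         ", k = ", k, ")")
  check_collinearity(df[, -1L, drop = FALSE])
  full_formula <- stats::reformulate(colnames(candidates), response = ".response")
  full <- stats::lm(full_formula, data = df)
  null <- stats::lm(.response ~ 1, data = df)
  scope <- list(lower = .response ~ 1, upper = full_formula)
  start <- if (direction == "forward") null else full
  fit <- MASS::stepAIC(start, scope = scope, direction = direction, trace = 0)
  sm <- summary(fit)
  cf <- stats::coef(sm)
  trace <- data.frame(step = as.character(fit$anova$Step),
                      aic = fit$anova$AIC, stringsAsFactors = FALSE)
  structure(list(
    selected = setdiff(rownames(cf), "(Intercept)"),
    coefficients = data.frame(term = rownames(cf),
                              estimate = cf[, "Estimate"],
                              p_value = cf[, "Pr(>|t|)"],
                              row.names = NULL, stringsAsFactors = FALSE),
    aic = stats::extractAIC(fit)[2L],
    r_squared = sm$r.squared,
    n = nrow(df), n_dropped = n_dropped,
    trace = trace, fit = fit),
    class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("stepwise_model: %s (AIC %.2f, R2 %.3f, n %d)\n",
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "(intercept only)", x$aic, x$r_squared, x$n))
  invisible(x)
}

#' LMG relative importance of predictors
#'
#' Decomposes the full linear model's R-squared into per-predictor shares:
#' each predictor's share is its incremental R-squared when added, averaged
#' over all orderings of the predictors (computed over the 2^k subsets with
#' ordering weights `|S|! (k - |S| - 1)! / k!`).  Shares always sum to the
#' full-model R-squared and are invariant to predictor order.
#'
#' @param response numeric response.
#' @param predictors data.frame or matrix of predictors, k <= 10.
#' @return named numeric vector of shares, with attribute `r_squared` (full
#'   model).
#' @export
lmg_importance <- function(response, predictors) {
  X <- as.matrix(as.data.frame(predictors))
  k <- ncol(X)
  if (k > 10L)
    stop("LMG enumeration limited to k <= 10 predictors; pass a subset")
  cc <- stats::complete.cases(cbind(response, X))
  y <- response[cc]; X <- X[cc, , drop = FALSE]
  check_collinearity(X)
  n <- length(y)
  if (n <= k + 1L) stop("too few complete cases")
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  # cache R^2 for every subset, indexed by bitmask
  r2_cache <- numeric(2^k)
  for (mask in seq_len(2^k - 1L))
    r2_cache[mask + 1L] <- r2(which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0))
  shares <- numeric(k)
  lfact <- lfactorial(0:k)
  for (i in seq_len(k)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(2^k - 1L)) {
      if (bitwAnd(mask, bit_i) > 0) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0)
      w <- exp(lfact[s + 1L] + lfact[k - s] - lfact[k + 1L])
      shares[i] <- shares[i] +
        w * (r2_cache[bitwOr(mask, bit_i) + 1L] - r2_cache[mask + 1L])
    }
  }
  names(shares) <- colnames(X)
  attr(shares, "r_squared") <- r2_cache[2^k]
  shares
}

# Candidate sets mirroring the study design
env_candidates <- function(islands, compartment) {
  common <- data.frame(
    diameter = islands$diameter_cm,
    height = islands$height_cm,
    complexity = islands$complexity,
    invertebrate_number = islands$invertebrate_number,
    log_invertebrate_wt = log(pmax(islands$invertebrate_weight_mg, 0.1)))
  extra <- switch(compartment,
    detritus = data.frame(percent_carbon = islands$percent_carbon,
                          percent_nitrogen = islands$percent_nitrogen),
    water = data.frame(dissolved_oxygen = islands$dissolved_oxygen_mg_l,
                       pH = islands$pH,
                       temperature = islands$temperature_C,
                       nitrate = islands$nitrate_conc),
    invertebrate = NULL)
  if (is.null(extra)) common else cbind(common, extra)
}

#' AIC-selected environmental models per compartment and locus
#'
#' For each compartment x locus, regresses per-sample log richness on the
#' compartment's candidate environmental and physical predictors (common:
#' diameter, height, complexity, invertebrate number, log invertebrate
#' weight; detritus adds %C and %N; water adds dissolved oxygen, pH,
#' temperature and nitrate), selecting the final model by stepwise AIC.
#'
#' @param bundle a `sar_bundle`.
#' @param direction passed to [step_aic()].
#' @return list of `stepwise_model` objects named `locus|compartment`, each
#'   with an `importance` element (LMG shares in the full model).
#' @export
env_model_table <- function(bundle, direction = "both") {
  rich <- observed_richness(bundle$table, group_by = "sample")
  s <- bundle$samples
  out <- list()
  for (locus in unique(s$locus)) {
    for (comp in c("detritus", "water", "invertebrate")) {
      idx <- which(s$locus == locus & s$compartment == comp &
                     rich[s$sample_id] > 0)
      if (length(idx) < 10L) next
      isl <- bundle$islands[match(s$island_id[idx],
                                  bundle$islands$island_id), , drop = FALSE]
      cand <- env_candidates(isl, comp)
      y <- log(unname(rich[s$sample_id[idx]]))
      key <- paste(locus, comp, sep = "|")
      mdl <- tryCatch(step_aic(y, cand, direction = direction),
                      error = function(e) e)
      if (inherits(mdl, "error")) next
      mdl$importance <- tryCatch(lmg_importance(y, cand),
                                 error = function(e) NULL)
      out[[key]] <- mdl
    }
  }
  out
}
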