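test_that("NODF matches hand examples and a brute-force pairwise oracle", {
  expect_equal(nodf(rbind(c(1, 1), c(1, 0))), 100)
  expect_equal(nodf(diag(2)), 0)
  expect_error(nodf(matrix(c(0, 2, 1, 1), 2)), "binary")

  # independent oracle: explicit loop over row pairs and column pairs
  nodf_oracle <- function(m) {
    pair_sum <- function(mm) {
      tot <- 0
      for (i in seq_len(nrow(mm) - 1)) for (j in (i + 1):nrow(mm)) {
        fi <- sum(mm[i, ]); fj <- sum(mm[j, ])
        if (fi == fj || min(fi, fj) == 0) next
        lo <- if (fi > fj) j else i
        hi <- if (fi > fj) i else j
        tot <- tot + 100 * sum(mm[hi, ] & mm[lo, ]) / sum(mm[lo, ])
      }
      tot
    }
    (pair_sum(m) + pair_sum(t(m))) /
      (choose(nrow(m), 2) + choose(ncol(m), 2))
  }
  set.seed(23)
  for (k in 1:100) {
    m <- matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6, 6)
    expect_equal(nodf(m), nodf_oracle(m), tolerance = 1e-12)
  }
  # and against vegan's fill-sorted NODF as an independent implementation
  set.seed(24)
  for (k in 1:20) {
    m <- matrix(rbinom(48, 1, 0.5), 6, 8)
    v <- unname(vegan::nestednodf(m, order = TRUE, weighted = FALSE)$statistic["NODF"])
    expect_equal(nodf(m), v, tolerance = 1e-10)
  }
})

test_that("margin-preserving nulls keep exact margins, binarity and total fill", {
  set.seed(3)
  m <- matrix(rbinom(200, 1, 0.3), 10, 20)
  for (method in c("quasiswap", "curveball")) {
    nulls <- quasiswap_nulls(m, n_sim = 50, seed = 5, method = method)
    for (x in nulls) {
      expect_true(all(x %in% 0:1))
      expect_equal(rowSums(x), rowSums(m))
      expect_equal(colSums(x), colSums(m))
      expect_equal(sum(x), sum(m))
    }
  }
  # the 2x2 case has exactly two members in its margin class
  out <- vapply(quasiswap_nulls(diag(2), n_sim = 50, seed = 1),
                function(x) paste(x, collapse = ""), "")
  expect_true(all(out %in% c("1001", "0110")))
  expect_length(unique(out), 2)  # both occur in 50 draws
  # determinism under seed
  a <- quasiswap_nulls(m, n_sim = 5, seed = 9)
  b <- quasiswap_nulls(m, n_sim = 5, seed = 9)
  expect_identical(a, b)
})

test_that("null_compare computes the documented count-based p and z", {
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  # observed above every null value
  res_hi <- null_compare(1e9, function(x) sum(x), m, n_null = 1000, seed = 1)
  expect_equal(res_hi$p, 2 / 1001, tolerance = 1e-12)
  expect_true(is.na(res_hi$z) || res_hi$z > 0)
  # statistic constant across nulls and equal to observed: capped p = 1, z NA
  res_eq <- null_compare(sum(m), function(x) sum(x), m, n_null = 200, seed = 1)
  expect_equal(res_eq$p, 1)
  expect_true(is.na(res_eq$z))
  # z sign matches the direction of the departure
  set.seed(2)
  big <- matrix(rbinom(80, 1, 0.4), 8, 10)
  obs <- nodf(big) + 20
  res <- null_compare(obs, nodf, big, n_null = 99, seed = 3)
  expect_gt(res$z, 0)
})

test_that("compartment matrix is the union over pooled samples, consistent with richness", {
  sim <- simulate_metacommunity(small_config(seed = 19))
  cm <- build_compartment_matrix(sim$table, sim$samples)
  expect_identical(rownames(cm), c("detritus", "water", "invertebrate"))
  expect_true(all(cm %in% 0:1))
  expect_true(all(colSums(cm) >= 1))
  # row fill equals pooled compartment richness on the same ASV universe
  pooled <- pool_counts(sim$table, sim$samples)
  g <- attr(pooled, "groups")
  for (comp in rownames(cm)) {
    rich_union <- sum(colSums(pooled[g$compartment == comp, , drop = FALSE]) > 0)
    expect_equal(sum(cm[comp, ]), rich_union)
  }
  # an ASV present in any water replicate shows as 1 in the water row
  wa <- sim$samples$sample_id[sim$samples$compartment == "water"]
  seen_water <- colnames(sim$table)[colSums(unclass(sim$table)[wa, , drop = FALSE]) > 0]
  expect_true(all(cm["water", intersect(seen_water, colnames(cm))] == 1))
})

test_that("RC-Bray hits its limit behaviours and stays within [-1, 1]", {
  set.seed(8)
  pool_n <- 200
  ab <- sort(rlnorm(pool_n), decreasing = TRUE); ab <- ab / sum(ab)
  # two identical rich samples: observed BC = 0, far below any null
  x <- rmultinom(1, 5000, ab)[, 1]
  m_same <- rbind(s1 = x, s2 = x)
  colnames(m_same) <- paste0("a", seq_len(pool_n))
  # pad the metacommunity with background samples defining the pool
  bg <- t(rmultinom(6, 5000, ab))
  rownames(bg) <- paste0("bg", 1:6); colnames(bg) <- colnames(m_same)
  rc_same <- rc_bray(count_table(rbind(m_same, bg)), reps = 199, seed = 4)
  expect_lte(rc_same$values["s1", "s2"], -0.95)

  # two disjoint samples over a large shared pool: observed BC = 1
  y1 <- integer(pool_n); y2 <- integer(pool_n)
  y1[1:40] <- rmultinom(1, 4000, ab[1:40])[, 1]
  y2[101:140] <- rmultinom(1, 4000, ab[101:140])[, 1]
  m_disj <- rbind(s1 = y1, s2 = y2)
  colnames(m_disj) <- colnames(m_same)
  rc_disj <- rc_bray(count_table(rbind(m_disj, bg)), reps = 199, seed = 4)
  expect_gte(rc_disj$values["s1", "s2"], 0.95)

  # bounds, symmetry, NA diagonal on a random table
  tt <- random_count_table(5, 30, lambda = 3)
  rcr <- rc_bray(tt, reps = 49, seed = 2)
  v <- rcr$values
  expect_true(all(is.na(diag(v))))
  expect_equal(v, t(v))
  expect_true(all(abs(v[upper.tri(v)]) <= 1))
})

test_that("RC-Bray is calibrated when communities are themselves null draws", {
  # assemble samples by the null's own recipe: occurrence-weighted species
  # draws, metacommunity-abundance reads; extreme values should be rare
  set.seed(44)
  pool_n <- 80
  ab <- rlnorm(pool_n); ab <- ab / sum(ab)
  n_samp <- 10
  m <- matrix(0L, n_samp, pool_n,
              dimnames = list(paste0("s", 1:n_samp), paste0("a", 1:pool_n)))
  for (i in seq_len(n_samp)) {
    sp <- sample(pool_n, 30)
    m[i, sp] <- rmultinom(1, 3000, ab[sp])[, 1]
  }
  rcr <- rc_bray(count_table(m), reps = 99, seed = 5)
  v <- rcr$values[upper.tri(rcr$values)]
  expect_lte(mean(abs(v) > 0.95), 0.10)
})
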