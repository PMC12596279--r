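test_that("observed richness counts presences, pooling replicates by union", {
  expect_equal(unname(observed_richness(toy_table())), c(3, 2, 2))
  rich <- observed_richness(toy_table(), toy_samples(),
                            group_by = "island_compartment")
  # s1 (asv1,3,4) + s2 (asv1,2) pool to 4 distinct ASVs on island i1
  expect_equal(rich$richness[rich$island_id == "i1"], 4)
  expect_equal(rich$richness[rich$island_id == "i2"], 2)

  m <- rbind(r1 = c(1L, 0L, 0L), r2 = c(0L, 1L, 0L))
  colnames(m) <- paste0("a", 1:3)
  s <- data.frame(sample_id = c("r1", "r2"), island_id = "i1",
                  compartment = "water", locus = "16S",
                  replicate_index = 1:2)
  expect_equal(observed_richness(count_table(m), s,
                                 group_by = "island_compartment")$richness, 2)
  expect_equal(unname(observed_richness(count_table(m))["r1"]), 1)
})

test_that("hill_q1 matches closed forms and is scale-invariant", {
  expect_equal(hill_q1(c(10, 10, 10, 10)), 4)
  expect_equal(hill_q1(c(0, 42, 0)), 1)
  expect_equal(hill_q1(c(75, 25)), exp(-(0.75 * log(0.75) + 0.25 * log(0.25))))
  expect_equal(round(hill_q1(c(75, 25)), 4), 1.7548)
  set.seed(1)
  x <- rpois(20, 10)
  expect_equal(hill_q1(x), hill_q1(x * 7L))
  # agrees with the exponential Shannon route
  expect_equal(hill_q1(x), exp(vegan::diversity(x, index = "shannon")))
  expect_error(hill_q1(c(0, 0)), "no reads")
})

test_that("rarefaction interpolation is exact at the endpoints and matches Monte Carlo", {
  set.seed(33)
  x <- rpois(20, 8) + 1L  # 20 species, all present
  n_reads <- sum(x)
  cur <- rarefaction_curve(x, depths = c(1, 10, 25, 50, 100, n_reads))
  expect_equal(cur$expected_richness[1], 1)                    # one read, one species
  expect_equal(cur$expected_richness[length(cur$depths)], 20)  # E[S(N)] = S_obs
  # Monte-Carlo oracle at m = 25: subsample reads without replacement
  reads <- rep(seq_along(x), x)
  mc <- replicate(1e4, length(unique(sample(reads, 25))))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(cur$expected_richness[cur$depths == 25] - mean(mc)), 3 * se)
  # no extrapolation
  expect_error(rarefaction_curve(x, depths = n_reads + 1), "exceeds")
})

test_that("rarefaction curves are non-decreasing and concave", {
  set.seed(9)
  x <- rpois(30, 5)
  cur <- rarefaction_curve(x, depths = seq(1, sum(x), by = 3))
  d1 <- diff(cur$expected_richness)
  expect_true(all(d1 >= -1e-10))
  expect_true(all(diff(d1) <= 1e-10))
  expect_true(rarefaction_curve(rep(1000L, 3))$asymptote_reached)
})

test_that("evenness regression matches a hand OLS computation", {
  # printed 5-point toy set
  logsize <- c(0, 1, 2, 3, 4)
  q1 <- c(2.0, 2.6, 2.9, 3.8, 4.1)
  n <- 5
  sxx <- sum((logsize - mean(logsize))^2)
  slope <- sum((logsize - mean(logsize)) * (q1 - mean(q1))) / sxx
  resid <- q1 - mean(q1) - slope * (logsize - mean(logsize))
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  islands <- data.frame(island_id = paste0("i", 1:5),
                        water_volume_ml = exp(logsize),
                        detritus_weight_mg = 1)
  rec <- data.frame(island_id = islands$island_id, q1 = q1)
  fit <- evenness_vs_size(rec, islands, "water_volume_ml")
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$slope_se, se, tolerance = 1e-12)
  expect_equal(fit$p_value, 2 * pt(-abs(slope / se), n - 2), tolerance = 1e-12)

  # exact linearity gives R^2 = 1; constant response a zero slope
  rec2 <- data.frame(island_id = islands$island_id, q1 = 1 + 0.5 * logsize)
  expect_equal(evenness_vs_size(rec2, islands, "water_volume_ml")$r_squared, 1)
  rec3 <- data.frame(island_id = islands$island_id, q1 = rep(2, 5))
  expect_equal(evenness_vs_size(rec3, islands, "water_volume_ml")$slope, 0)
})

test_that("compartment overlap regions partition the union", {
  sim <- simulate_metacommunity(small_config(seed = 12))
  ov <- compartment_overlap(sim$table, sim$samples)
  expect_equal(sum(ov$regions), ov$union_size)
  expect_equal(ov$union_size, sum(colSums(ov$presence) > 0))
  expect_equal(diag(ov$shared_fraction), rep(1, nrow(ov$shared_fraction)),
               ignore_attr = TRUE)

  # disjoint compartments: no intersection regions
  m <- rbind(d1 = c(1L, 0L, 0L, 0L), w1 = c(0L, 0L, 2L, 3L))
  colnames(m) <- paste0("a", 1:4)
  s <- data.frame(sample_id = c("d1", "w1"), island_id = "i1",
                  compartment = c("detritus", "water"), locus = "18S",
                  replicate_index = 1L)
  ov2 <- compartment_overlap(count_table(m), s)
  expect_false(any(grepl("\\+", names(ov2$regions))))
  # identical compartments: only the full intersection region
  m2 <- rbind(d1 = c(1L, 1L, 0L), w1 = c(2L, 5L, 0L))
  colnames(m2) <- paste0("a", 1:3)
  ov3 <- compartment_overlap(count_table(m2), transform(s, sample_id = c("d1", "w1")))
  expect_identical(names(ov3$regions), "detritus+water")
})

test_that("richness ANOVA agrees with the pooled t-test for two groups", {
  set.seed(8)
  x <- c(rnorm(10, 50, 5), rnorm(12, 60, 5))
  g <- rep(c("water", "detritus"), c(10, 12))
  a <- richness_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)

  # equal group means: F ~ 0
  y <- c(1, 2, 3, 1, 2, 3)
  expect_lt(richness_anova(y, rep(c("a", "b"), each = 3))$f, 1e-10)
})

test_that("Tukey adjusted p-values shrink as mean separation grows", {
  set.seed(15)
  base <- rnorm(10)
  p_at_delta <- vapply(c(0.5, 1.5, 3), function(delta) {
    x <- c(base, base + delta, base + 2 * delta)
    g <- rep(c("g1", "g2", "g3"), each = 10)
    max(richness_anova(x, g)$tukey$p.adj)
  }, numeric(1))
  expect_true(all(diff(p_at_delta) < 0))
})
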