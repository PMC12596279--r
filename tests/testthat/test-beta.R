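test_that("Bray-Curtis matches the direct formula", {
  m <- rbind(x = c(2L, 0L, 1L), y = c(1L, 1L, 1L), z = c(0L, 0L, 1L))
  colnames(m) <- paste0("a", 1:3)
  d <- as.matrix(bray_curtis(count_table(m)))
  expect_equal(d["x", "y"], 1 / 3, tolerance = 1e-12)  # sum|diff|=2, sum=6
  expect_equal(diag(d), c(x = 0, y = 0, z = 0))
  expect_equal(d, t(d))
  # disjoint support: dissimilarity 1
  m2 <- rbind(x = c(1L, 1L, 0L), y = c(0L, 0L, 1L))
  colnames(m2) <- paste0("a", 1:3)
  expect_equal(as.numeric(bray_curtis(count_table(m2))), 1)
  # zero-read sample is an error naming it
  m3 <- rbind(x = c(1L, 0L), dead = c(0L, 0L))
  colnames(m3) <- c("a1", "a2")
  expect_error(bray_curtis(count_table(m3)), "dead")
})

test_that("size distances are log-additive and symmetric", {
  isl <- data.frame(island_id = c("i1", "i2", "i3"),
                    water_volume_ml = c(10, 100, 1000),
                    detritus_weight_mg = c(5, 5, 5))
  d <- as.matrix(size_distance(isl, "water_volume_ml"))
  expect_equal(d["i1", "i3"], d["i1", "i2"] + d["i2", "i3"], tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(i1 = 0, i2 = 0, i3 = 0))
  expect_true(all(as.matrix(size_distance(isl, "detritus_weight_mg")) == 0))
})

test_that("Mantel r is rank-invariant and label-permutation invariant", {
  set.seed(6)
  x <- runif(10, 1, 5)
  d_size <- dist(x)
  attr(d_size, "Labels") <- paste0("i", 1:10)
  # strictly increasing transform of the same distances: r = 1
  d_comm <- as.dist(sqrt(as.matrix(d_size)) + as.matrix(d_size)^2)
  attr(d_comm, "Labels") <- paste0("i", 1:10)
  mt <- mantel_spearman(d_comm, d_size, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_lte(mt$p, 0.05)
  expect_gte(mt$p, 1 / 100)

  # permuting sample order of both matrices identically leaves r unchanged
  perm <- sample(10)
  mc <- as.matrix(d_comm)[perm, perm]; ms <- as.matrix(d_size)[perm, perm]
  mt2 <- mantel_spearman(as.dist(mc), as.dist(ms), n_perm = 99, seed = 1)
  expect_equal(mt2$r, mt$r, tolerance = 1e-12)

  # monotone transform invariance of r on random matrices
  d1 <- dist(runif(8)); d2 <- dist(runif(8))
  r_raw <- mantel_spearman(d1, d2, n_perm = 49, seed = 2)$r
  r_log <- mantel_spearman(d1, as.dist(log1p(as.matrix(d2))), n_perm = 49,
                           seed = 2)$r
  expect_equal(r_raw, r_log, tolerance = 1e-12)

  # constant matrix: undefined r reported as NA
  expect_true(is.na(mantel_spearman(dist(rep(1, 5)), dist(runif(5)),
                                    n_perm = 49)$r))
})

test_that("composition-size regression recovers exact relations and respects island dependence", {
  set.seed(13)
  x <- runif(12, 1, 6)
  ids <- paste0("i", 1:12)
  d_size <- dist(x); attr(d_size, "Labels") <- ids
  d_comm <- as.dist(0.1 * as.matrix(d_size)); attr(d_comm, "Labels") <- ids
  cs <- composition_size_regression(d_comm, d_size, B = 99, seed = 1)
  expect_equal(cs$fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(cs$fit$r_squared, 1, tolerance = 1e-12)

  # constant dissimilarity: slope 0
  d_const <- as.dist(matrix(0.5, 12, 12) - diag(0.5, 12))
  attr(d_const, "Labels") <- ids
  expect_equal(composition_size_regression(d_const, d_size, B = 50,
                                           seed = 1)$fit$slope, 0)

  # island-resampled bootstrap spreads wider than naive pair resampling
  # when residuals are island-structured
  set.seed(40)
  n <- 16; ids <- paste0("i", 1:n)
  sizev <- runif(n, 1, 6)
  island_effect <- rnorm(n, 0, 0.4)
  msize <- as.matrix(dist(sizev))
  mcomm <- 0.05 * msize + outer(island_effect, island_effect, "+") +
    matrix(rnorm(n * n, 0, 0.01), n, n)
  mcomm <- (mcomm + t(mcomm)) / 2; diag(mcomm) <- 0
  dc <- as.dist(mcomm); ds <- as.dist(msize)
  attr(dc, "Labels") <- ids; attr(ds, "Labels") <- ids
  sd_isl <- sd(composition_size_regression(dc, ds, B = 400, seed = 3)$slopes$slopes)
  sd_pair <- sd(composition_size_regression(dc, ds, B = 400, seed = 3,
                                            scheme = "pairs")$slopes$slopes)
  expect_gt(sd_isl, sd_pair)
})

test_that("beta dispersion reproduces plane geometry and Euclidean centroid distances", {
  # four corners of a unit square: all centroid distances are half the diagonal
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  rownames(pts) <- paste0("p", 1:4)
  disp <- beta_dispersion(dist(pts), rep("g1", 4))
  expect_equal(unname(disp$distances), rep(sqrt(2) / 2, 4), tolerance = 1e-10)

  # PCoA route equals direct coordinate-space centroid distances
  set.seed(17)
  coords <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("p", 1:10), NULL))
  groups <- rep(c("a", "b"), each = 5)
  disp2 <- beta_dispersion(dist(coords), groups)
  direct <- unlist(lapply(split(seq_len(10), groups), function(idx) {
    ctr <- colMeans(coords[idx, , drop = FALSE])
    sqrt(rowSums((coords[idx, , drop = FALSE] -
                    rep(ctr, each = length(idx)))^2))
  }), use.names = FALSE)
  expect_equal(unname(disp2$distances)[order(groups)], direct, tolerance = 1e-10)
  expect_equal(disp2$n_negative_eig, 0)

  # singleton group sits on its own centroid
  disp3 <- beta_dispersion(dist(coords[1:4, ]), c("a", "a", "a", "b"))
  expect_equal(unname(disp3$distances[4]), 0, tolerance = 1e-10)
})

test_that("dispersion-size regression detects size-dependent within-island variability", {
  # islands whose within-island scatter grows with log size (population
  # R^2 ~ 0.4): the slope test should reject at 5% in nearly every world
  n_isl <- 32; reps <- 3
  isl <- data.frame(island_id = sprintf("i%02d", 1:n_isl),
                    water_volume_ml = 1, detritus_weight_mg = NA)
  n_sig <- 0; n_rep <- 30
  set.seed(71)
  for (r in seq_len(n_rep)) {
    ls <- runif(n_isl, 0, 4.5)
    isl$detritus_weight_mg <- exp(ls)
    sigma <- 0.2 + 0.2 * ls
    coords <- do.call(rbind, lapply(seq_len(n_isl), function(i)
      matrix(rnorm(reps * 2, 0, sigma[i]), reps, 2)))
    rownames(coords) <- paste0(rep(isl$island_id, each = reps), "_", 1:reps)
    disp <- beta_dispersion(dist(coords), rep(isl$island_id, each = reps))
    fit <- dispersion_vs_size(disp, isl, "detritus_weight_mg")
    if (fit$slope > 0 && fit$p_value <= 0.05) n_sig <- n_sig + 1
  }
  expect_gte(n_sig / n_rep, 0.8)
})

test_that("dispersion-size regression matches a hand OLS on a 6-point toy set", {
  isl <- data.frame(island_id = paste0("i", 1:3),
                    water_volume_ml = c(10, 100, 1000),
                    detritus_weight_mg = 1)
  disp <- structure(list(
    distances = c(a1 = 0.10, a2 = 0.14, b1 = 0.20, b2 = 0.26,
                  c1 = 0.30, c2 = 0.38),
    groups = factor(rep(c("i1", "i2", "i3"), each = 2))),
    class = "dispersion_result")
  fit <- dispersion_vs_size(disp, isl, "water_volume_ml")
  x <- log(rep(c(10, 100, 1000), each = 2)); y <- disp$distances
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, unname(slope), tolerance = 1e-12)
  # constant dispersion: slope 0; linear-in-log dispersion: R^2 = 1
  disp0 <- disp; disp0$distances[] <- 0.2
  expect_equal(dispersion_vs_size(disp0, isl, "water_volume_ml")$slope, 0)
  displ <- disp; displ$distances <- 0.05 * x + 0.01
  expect_equal(dispersion_vs_size(displ, isl, "water_volume_ml")$r_squared, 1,
               tolerance = 1e-12)
})
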