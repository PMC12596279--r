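test_that("island sizes span the configured fold ranges exactly", {
  cfg <- synth_config(seed = 3)
  isl <- with_seed(3, generate_islands(cfg))
  expect_equal(max(isl$detritus_weight_mg) / min(isl$detritus_weight_mg), 250)
  expect_equal(max(isl$water_volume_ml) / min(isl$water_volume_ml), 90)
  expect_equal(nrow(isl), 32L)
  expect_error(generate_islands(synth_config(n_islands = 2)), "3 islands")
})

test_that("pH tracks island size as configured", {
  cfg0 <- synth_config(ph_size_slope = 0, ph_noise_sd = 0, seed = 5)
  isl0 <- with_seed(5, generate_islands(cfg0))
  expect_equal(var(isl0$pH), 0)
  cfg1 <- synth_config(ph_noise_sd = 0, seed = 5)
  isl1 <- with_seed(5, generate_islands(cfg1))
  expect_equal(unname(coef(lm(pH ~ log(water_volume_ml), isl1))[2]), -0.25,
               tolerance = 1e-10)
})

test_that("regional pool abundances are normalized, sorted, and even when sdlog = 0", {
  cfg <- synth_config(seed = 4)
  pool <- with_seed(4, generate_regional_pool(cfg))
  expect_equal(sum(pool$abundance), 1, tolerance = 1e-12)
  expect_true(all(diff(pool$abundance) <= 0))
  expect_length(pool$host_admissible, round(0.3 * 500))

  flat <- with_seed(4, generate_regional_pool(synth_config(pool_sdlog = 0)))
  expect_equal(unname(flat$abundance), rep(1 / 500, 500))
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_metacommunity(small_config(seed = 9))
  b <- simulate_metacommunity(small_config(seed = 9))
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$islands, b$islands)
  expect_identical(a$truth, b$truth)
  c <- simulate_metacommunity(small_config(seed = 10))
  expect_false(identical(unclass(a$table), unclass(c$table)))
})

test_that("z = 0 with zero noise gives constant richness; deep sampling realizes S* exactly", {
  cfg <- synth_config(n_islands = 8L, pool_size = 200L,
                      sar_exponent = c(detritus = 0, water = 0, invertebrate = 0),
                      sar_intercept = c(detritus = log(40), water = log(40),
                                        invertebrate = log(10)),
                      noise_sd_log_richness = 0,
                      replicates = c(detritus = 2L, water = 2L, invertebrate = 1L),
                      depth_mean = 60000, depth_dispersion = 1e6,  # ~fixed depth >> 50 S*
                      contaminant_count = 0L, loci = "18S", seed = 21)
  sim <- simulate_metacommunity(cfg)
  rich <- observed_richness(sim$table, sim$samples, group_by = "island_compartment")
  det <- rich$richness[rich$compartment == "detritus"]
  expect_true(all(det == 40L))
  expect_true(all(rich$richness[rich$compartment == "invertebrate"] == 10L))
})

test_that("host communities are subsets of the admissible pool fraction", {
  sim <- simulate_metacommunity(small_config(seed = 14))
  inv_ids <- sim$samples$sample_id[sim$samples$compartment == "invertebrate"]
  m <- unclass(sim$table)[inv_ids, , drop = FALSE]
  seen <- colnames(m)[colSums(m) > 0]
  seen <- setdiff(seen, sim$truth$contaminants[["18S"]])
  expect_true(all(seen %in% sim$truth$host_admissible[["18S"]]))
})

test_that("host-in-environment nesting strengthens as the host filter tightens", {
  # containment of the invertebrate row inside each environmental row
  # (the row-pair paired-nestedness terms involving hosts); the aggregate
  # NODF of a 3 x C matrix also folds in column-margin balance, so the
  # row-level containment is the clean readout of the filtering mechanism
  containment <- vapply(c(1, 0.5, 0.2), function(h) {
    sim <- simulate_metacommunity(small_config(seed = 31, pool_size = 600L,
                                               host_filter_strength = h,
                                               contaminant_count = 0L))
    m <- build_compartment_matrix(sim$table, sim$samples)
    inv <- m["invertebrate", ] > 0
    mean(c(sum(inv & m["detritus", ] > 0), sum(inv & m["water", ] > 0)) / sum(inv))
  }, numeric(1))
  expect_true(containment[1] < containment[2],
              info = paste(containment, collapse = ", "))
  expect_true(containment[2] < containment[3],
              info = paste(containment, collapse = ", "))
})

test_that("negative controls carry contaminants only, at high prevalence", {
  cfg <- small_config(seed = 8)
  sim <- simulate_metacommunity(cfg)
  negs <- sim$samples$sample_id[sim$samples$compartment == "negative_control"]
  m <- unclass(sim$table)[negs, , drop = FALSE]
  contam <- sim$truth$contaminants[["18S"]]
  expect_length(contam, cfg$contaminant_count)
  expect_true(all(colnames(m)[colSums(m) > 0] %in% contam))
  # each designated contaminant present in at least half the negatives
  prev <- colSums(m[, contam, drop = FALSE] > 0)
  expect_true(all(prev >= length(negs) / 2))
  # contaminant_count = 0: all-zero negatives
  sim0 <- simulate_metacommunity(small_config(seed = 8, contaminant_count = 0L))
  negs0 <- sim0$samples$sample_id[sim0$samples$compartment == "negative_control"]
  expect_true(all(unclass(sim0$table)[negs0, ] == 0))
})

test_that("fit_sar recovers the generating exponent across many islands", {
  cfg <- synth_config(n_islands = 200L, pool_size = 600L,
                      noise_sd_log_richness = 0.05,
                      replicates = c(detritus = 2L, water = 1L, invertebrate = 1L),
                      contaminant_count = 0L, loci = "18S", seed = 77)
  sim <- simulate_metacommunity(cfg, compartments = "detritus")
  rich <- observed_richness(sim$table, sim$samples, group_by = "island_compartment")
  sizes <- sim$islands$detritus_weight_mg[match(rich$island_id,
                                                sim$islands$island_id)]
  f <- fit_sar(rich$richness, sizes)
  expect_equal(f$slope, 0.12, tolerance = 0.15)
  expect_true(abs(f$slope - 0.12) < 3 * f$slope_se)
})
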