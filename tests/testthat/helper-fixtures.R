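# Shared fixtures, built in code.

# tiny hand-specified count table
toy_table <- function() {
  m <- rbind(s1 = c(5L, 0L, 1L, 2L),
             s2 = c(1L, 2L, 0L, 0L),
             s3 = c(0L, 0L, 3L, 3L))
  colnames(m) <- paste0("asv", 1:4)
  count_table(m)
}

toy_samples <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             island_id = c("i1", "i1", "i2"),
             compartment = c("detritus", "detritus", "water"),
             locus = "18S", replicate_index = c(1L, 2L, 1L),
             stringsAsFactors = FALSE)
}

toy_islands <- function() {
  data.frame(island_id = c("i1", "i2"),
             water_volume_ml = c(100, 400),
             detritus_weight_mg = c(1000, 250),
             diameter_cm = c(50, 70), height_cm = c(30, 45),
             complexity = c(20L, 35L),
             invertebrate_number = c(4L, 9L),
             invertebrate_weight_mg = c(8, 20),
             pH = c(6.1, 5.4), temperature_C = c(22, 23),
             dissolved_oxygen_mg_l = c(6, 5.5),
             nitrate_conc = c(0.05, 0.04),
             percent_carbon = c(44, 46), percent_nitrogen = c(1.4, 1.6),
             stringsAsFactors = FALSE)
}

random_count_table <- function(n_samples = 6, n_asvs = 10, lambda = 5) {
  m <- matrix(rpois(n_samples * n_asvs, lambda), n_samples, n_asvs,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("asv%03d", seq_len(n_asvs))))
  count_table(m)
}

# small synthetic world for pipeline-level tests (overridable defaults)
small_config <- function(seed = 101, ...) {
  args <- list(n_islands = 12L, pool_size = 150L,
               host_filter_strength = 0.5,
               sar_intercept = c(detritus = log(25), water = log(18),
                                 invertebrate = log(8)),
               replicates = c(detritus = 3L, water = 2L, invertebrate = 1L),
               depth_mean = 5000, loci = "18S", seed = seed)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# all permutations of a vector (tiny n), for factorial oracles
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# fixture run configuration shared by pipeline and determinism tests
fixture_run_config <- function(seed = 77) {
  run_config(simulate = list(n_islands = 10L, pool_size = 100L,
                             sar_intercept = c(detritus = log(20),
                                               water = log(15),
                                               invertebrate = log(6)),
                             replicates = c(detritus = 3L, water = 2L,
                                            invertebrate = 1L),
                             depth_mean = 4000, loci = "18S"),
             qc = list(decontam_threshold = 0.5,
                       min_sample_reads = c("18S" = 300),
                       min_asv_reads = c("18S" = 3)),
             bootstrap_B = 99, mantel_permutations = 99,
             nodf_nulls = 99, rc_reps = 19,
             seed = seed)
}
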