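# Synthetic island-metacommunity generator.
#
# Emulates the statistical structure the downstream analyses assume: a fixed
# number of habitat islands whose detrital and aquatic sizes span configured
# fold ranges, per-compartment power-law richness scaling realized as
# log S = log c + z log A + noise, lognormal regional species pools sampled
# without replacement, host filtering restricting invertebrate communities to
# an admissible pool fraction (inducing host-in-environment nestedness),
# island-size-correlated pH, replicated multinomial read sampling, and
# contaminant ASVs shared with negative controls.

#' Configuration for the synthetic island metacommunity
#'
#' Defaults describe the study conditions the generator emulates: 32 islands,
#' a 250-fold detrital and 90-fold aquatic size range (30-2700 ml of water),
#' per-compartment SAR exponents and natural-log intercepts of
#' detritus 0.12/3.95, water 0.10/3.25, invertebrates 0/2.96, replicate
#' sampling of 10 detritus / 3 water / 1 invertebrate sample per island,
#' and pH decreasing with aquatic island size.
#'
#' @param n_islands number of habitat islands (>= 3).
#' @param detritus_fold_range,water_fold_range ratio max/min island size
#'   realized *exactly* by the generated sizes.
#' @param detritus_weight_min_mg,water_volume_min_ml smallest island sizes.
#' @param sar_exponent,sar_intercept named per-compartment z and log c of the
#'   power law log S = log c + z log A (natural logs; A = detritus weight for
#'   detritus, water volume for water and invertebrates).
#' @param pool_size number of species in each locus's regional pool.
#' @param pool_meanlog,pool_sdlog lognormal rank-abundance parameters of the
#'   pool; `pool_sdlog = 0` gives a perfectly even pool.
#' @param host_filter_strength fraction of the pool admissible to
#'   invertebrate hosts, in (0, 1]; smaller values mean stronger filtering
#'   and stronger nestedness of host in environmental communities.
#' @param replicates named per-compartment replicate samples per island.
#' @param depth_mean,depth_dispersion negative-binomial sequencing depth per
#'   replicate (mean and size).
#' @param contaminant_count number of contaminant ASVs shared between
#'   negative controls and true samples.
#' @param contaminant_prob_negative,contaminant_prob_sample per-sample
#'   presence probability of each contaminant in negatives / true samples.
#' @param n_negatives negative-control samples per locus.
#' @param ph_baseline,ph_size_slope,ph_noise_sd pH model:
#'   `ph = baseline + slope * log(water_volume_ml) + N(0, noise)`.
#' @param noise_sd_log_richness SD of the log-richness noise around the SAR
#'   line.
#' @param loci marker loci to simulate (independent pools per locus).
#' @param seed master seed; all randomness flows from it.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_islands = 32L,
                         detritus_fold_range = 250,
                         water_fold_range = 90,
                         detritus_weight_min_mg = 100,
                         water_volume_min_ml = 30,
                         sar_exponent = c(detritus = 0.12, water = 0.10,
                                          invertebrate = 0),
                         sar_intercept = c(detritus = 3.95, water = 3.25,
                                           invertebrate = 2.96),
                         pool_size = 500L,
                         pool_meanlog = 0,
                         pool_sdlog = 1,
                         host_filter_strength = 0.3,
                         replicates = c(detritus = 10L, water = 3L,
                                        invertebrate = 1L),
                         depth_mean = 20000,
                         depth_dispersion = 10,
                         contaminant_count = 10L,
                         contaminant_prob_negative = 0.9,
                         contaminant_prob_sample = 0.15,
                         n_negatives = 6L,
                         ph_baseline = 7.4,
                         ph_size_slope = -0.25,
                         ph_noise_sd = 0.2,
                         noise_sd_log_richness = 0.5,
                         loci = c("16S", "18S"),
                         seed = 1L) {
  cfg <- list(n_islands = as.integer(n_islands),
              detritus_fold_range = detritus_fold_range,
              water_fold_range = water_fold_range,
              detritus_weight_min_mg = detritus_weight_min_mg,
              water_volume_min_ml = water_volume_min_ml,
              sar_exponent = sar_exponent, sar_intercept = sar_intercept,
              pool_size = as.integer(pool_size),
              pool_meanlog = pool_meanlog, pool_sdlog = pool_sdlog,
              host_filter_strength = host_filter_strength,
              replicates = replicates,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              contaminant_count = as.integer(contaminant_count),
              contaminant_prob_negative = contaminant_prob_negative,
              contaminant_prob_sample = contaminant_prob_sample,
              n_negatives = as.integer(n_negatives),
              ph_baseline = ph_baseline, ph_size_slope = ph_size_slope,
              ph_noise_sd = ph_noise_sd,
              noise_sd_log_richness = noise_sd_log_richness,
              loci = match.arg(loci, LOCI, several.ok = TRUE),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$detritus_fold_range > 1, cfg$water_fold_range > 1,
            all(is.finite(cfg$sar_exponent)),
            cfg$host_filter_strength > 0, cfg$host_filter_strength <= 1,
            cfg$pool_size >= 2L, cfg$noise_sd_log_richness >= 0,
            cfg$contaminant_count >= 0L, cfg$n_negatives >= 0L,
            cfg$contaminant_count <= cfg$pool_size,
            all(cfg$replicates >= 1L),
            all(c("detritus", "water", "invertebrate") %in% names(cfg$sar_exponent)),
            all(c("detritus", "water", "invertebrate") %in% names(cfg$sar_intercept)),
            all(c("detritus", "water", "invertebrate") %in% names(cfg$replicates)))
  invisible(cfg)
}

#' Generate island metadata
#'
#' Island sizes are log-uniform so that log A is uniform (balanced leverage
#' for SAR fitting) and span the configured fold ranges exactly
#' (`max/min == fold`).  pH decreases with log water volume at
#' `ph_size_slope`; other covariates are drawn independently of size.
#'
#' @param config a [synth_config()].
#' @return island metadata data.frame.
#' @export
generate_islands <- function(config) {
  validate_synth_config(config)
  n <- config$n_islands
  if (n < 3L) stop("need at least 3 islands for any regression")
  log_unif_span <- function(n, minval, fold) {
    u <- stats::runif(n)
    u <- (u - min(u)) / (max(u) - min(u))  # pin endpoints: max/min == fold
    minval * fold^u
  }
  detritus <- log_unif_span(n, config$detritus_weight_min_mg,
                            config$detritus_fold_range)
  water <- log_unif_span(n, config$water_volume_min_ml, config$water_fold_range)
  ph <- config$ph_baseline + config$ph_size_slope * log(water) +
    stats::rnorm(n, 0, config$ph_noise_sd)
  inv_n <- stats::rpois(n, 8)
  data.frame(
    island_id = sprintf("isl%02d", seq_len(n)),
    detritus_weight_mg = detritus,
    water_volume_ml = water,
    diameter_cm = pmax(10, stats::rnorm(n, 60, 15)),
    height_cm = pmax(5, stats::rnorm(n, 40, 10)),
    complexity = pmax(1L, as.integer(round(stats::runif(n, 15, 60)))),
    invertebrate_number = inv_n,
    invertebrate_weight_mg = inv_n * stats::rlnorm(n, log(2), 0.4),
    pH = ph,
    temperature_C = stats::rnorm(n, 22, 1.5),
    dissolved_oxygen_mg_l = pmax(0.5, stats::rnorm(n, 6, 1)),
    nitrate_conc = stats::rlnorm(n, -3, 0.5),
    percent_carbon = stats::rnorm(n, 45, 3),
    percent_nitrogen = pmax(0.1, stats::rnorm(n, 1.5, 0.3)),
    stringsAsFactors = FALSE)
}

#' Generate a regional species pool
#'
#' Relative abundances are lognormal, normalized to sum to one and sorted in
#' decreasing order.  The top `host_filter_strength` fraction of the pool by
#' abundance is marked admissible to invertebrate hosts: host-compatible taxa
#' are the environmentally prevalent pool members.  The same admissible set
#' applies to every island, which is what induces nestedness of host
#' communities inside environmental ones — the tighter the filter, the more
#' hosts concentrate on common, environmentally ubiquitous species, so
#' host-in-environment containment increases monotonically as the admissible
#' fraction shrinks.
#'
#' @param config a [synth_config()].
#' @param locus label used to prefix ASV ids.
#' @return list with `asv_ids`, `abundance`, `host_admissible`.
#' @export
generate_regional_pool <- function(config, locus = "18S") {
  validate_synth_config(config)
  p <- config$pool_size
  ab <- stats::rlnorm(p, config$pool_meanlog, config$pool_sdlog)
  ab <- sort(ab / sum(ab), decreasing = TRUE)
  ids <- sprintf("%s_ASV%04d", locus, seq_len(p))
  n_adm <- max(1L, round(config$host_filter_strength * p))
  admissible <- seq_len(n_adm)  # abundances are sorted decreasing
  list(asv_ids = ids, abundance = stats::setNames(ab, ids),
       host_admissible = ids[admissible], locus = locus)
}

#' Generate one island-compartment community with replicate read samples
#'
#' Target richness is `S* = round(exp(log c + z log A + N(0, noise)))` with
#' A the compartment's island-size measure.  S* member species are drawn
#' without replacement from the pool weighted by pool abundance, restricted
#' for invertebrates to the host-admissible fraction.  Each replicate gets a
#' negative-binomial read depth distributed multinomially over the member
#' species in proportion to their pool abundances.
#'
#' @param island one row of [generate_islands()] output.
#' @param compartment `"detritus"`, `"water"` or `"invertebrate"`.
#' @param pool a [generate_regional_pool()].
#' @param config a [synth_config()].
#' @return list with `counts` (replicates x pool), `samples` metadata rows
#'   and `members` (drawn species ids).
#' @export
generate_community <- function(island, compartment, pool, config) {
  stopifnot(compartment %in% c("detritus", "water", "invertebrate"))
  area <- if (compartment == "detritus") island$detritus_weight_mg
          else island$water_volume_ml
  mu <- config$sar_intercept[[compartment]] +
    config$sar_exponent[[compartment]] * log(area) +
    stats::rnorm(1, 0, config$noise_sd_log_richness)
  s_target <- max(1L, as.integer(round(exp(mu))))
  admissible <- if (compartment == "invertebrate") pool$host_admissible
                else pool$asv_ids
  if (s_target > length(admissible)) {
    warning("target richness ", s_target, " exceeds admissible pool (",
            length(admissible), ") for ", island$island_id, "/", compartment,
            "; clamped")
    s_target <- length(admissible)
  }
  w <- pool$abundance[admissible]
  members <- sample(admissible, s_target, replace = FALSE, prob = w)
  n_rep <- config$replicates[[compartment]]
  counts <- matrix(0L, n_rep, length(pool$asv_ids),
                   dimnames = list(NULL, pool$asv_ids))
  pm <- pool$abundance[members]
  for (r in seq_len(n_rep)) {
    depth <- max(1L, stats::rnbinom(1, mu = config$depth_mean,
                                    size = config$depth_dispersion))
    counts[r, members] <- stats::rmultinom(1, depth, pm)[, 1L]
  }
  sample_ids <- sprintf("%s_%s_%s_r%d", island$island_id, compartment,
                        pool$locus, seq_len(n_rep))
  rownames(counts) <- sample_ids
  samples <- data.frame(sample_id = sample_ids,
                        island_id = island$island_id,
                        compartment = compartment, locus = pool$locus,
                        replicate_index = seq_len(n_rep),
                        stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, members = members,
       target_richness = s_target)
}

#' Generate negative-control samples and designate contaminant ASVs
#'
#' `contaminant_count` pool species are designated contaminants; each is
#' present in each negative control with probability
#' `contaminant_prob_negative`.  Negatives contain contaminant reads only.
#'
#' @param config a [synth_config()].
#' @param pool a [generate_regional_pool()].
#' @return list with `counts`, `samples`, and ground-truth `contaminants`.
#' @export
generate_negatives <- function(config, pool) {
  validate_synth_config(config)
  k <- config$contaminant_count
  contaminants <- if (k > 0L) sample(pool$asv_ids, k) else character(0)
  n <- config$n_negatives
  counts <- matrix(0L, n, length(pool$asv_ids),
                   dimnames = list(NULL, pool$asv_ids))
  for (i in seq_len(n)) {
    hit <- contaminants[stats::runif(k) < config$contaminant_prob_negative]
    if (length(hit))
      counts[i, hit] <- stats::rpois(length(hit), 200) + 1L
  }
  ids <- sprintf("neg_%s_%02d", pool$locus, seq_len(n))
  rownames(counts) <- ids
  samples <- data.frame(sample_id = ids, island_id = NA_character_,
                        compartment = "negative_control", locus = pool$locus,
                        replicate_index = seq_len(n) %||% integer(0),
                        stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, contaminants = contaminants)
}

#' Simulate a complete island metacommunity
#'
#' Runs the full generator: islands, per-locus pools, per-island-compartment
#' communities with replicate read samples, negative controls, and
#' contaminant reads sprinkled into true samples.  All randomness flows from
#' `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a [synth_config()].
#' @param compartments compartments to generate (default all three).
#' @return a list of class `island_simulation` with elements `table`
#'   ([count_table()]), `samples`, `islands`, `truth` (ground-truth SAR
#'   parameters, contaminants and host-admissible pools) and `config`.
#' @export
simulate_metacommunity <- function(config = synth_config(),
                                   compartments = c("detritus", "water",
                                                    "invertebrate")) {
  validate_synth_config(config)
  compartments <- match.arg(compartments, several.ok = TRUE)
  with_seed(config$seed, {
    islands <- generate_islands(config)
    blocks <- list(); meta <- list(); truth_contam <- list(); hosts <- list()
    for (locus in config$loci) {
      pool <- generate_regional_pool(config, locus)
      hosts[[locus]] <- pool$host_admissible
      loc_counts <- list(); loc_samples <- list()
      for (i in seq_len(nrow(islands))) {
        for (comp in compartments) {
          cm <- generate_community(islands[i, ], comp, pool, config)
          loc_counts[[length(loc_counts) + 1L]] <- cm$counts
          loc_samples[[length(loc_samples) + 1L]] <- cm$samples
        }
      }
      counts <- do.call(rbind, loc_counts)
      neg <- generate_negatives(config, pool)
      truth_contam[[locus]] <- neg$contaminants
      # sprinkle contaminant reads into true samples
      for (asv in neg$contaminants) {
        hitrows <- which(stats::runif(nrow(counts)) < config$contaminant_prob_sample)
        if (length(hitrows))
          counts[hitrows, asv] <- counts[hitrows, asv] +
            stats::rpois(length(hitrows), 30) + 1L
      }
      blocks[[locus]] <- rbind(counts, neg$counts)
      meta[[locus]] <- rbind(do.call(rbind, loc_samples), neg$samples)
    }
    # loci have disjoint ASV id spaces; assemble a block-diagonal table
    all_asvs <- unlist(lapply(blocks, colnames), use.names = FALSE)
    all_samples <- unlist(lapply(blocks, rownames), use.names = FALSE)
    full <- matrix(0L, length(all_samples), length(all_asvs),
                   dimnames = list(all_samples, all_asvs))
    for (locus in names(blocks))
      full[rownames(blocks[[locus]]), colnames(blocks[[locus]])] <- blocks[[locus]]
    samples <- do.call(rbind, meta)
    rownames(samples) <- NULL
    structure(list(
      table = count_table(full),
      samples = samples,
      islands = islands,
      truth = list(sar_exponent = config$sar_exponent,
                   sar_intercept = config$sar_intercept,
                   contaminants = truth_contam,
                   host_admissible = hosts),
      config = config), class = "island_simulation")
  })
}

#' @export
print.island_simulation <- function(x, ...) {
  cat(sprintf("island_simulation: %d islands, loci %s, seed %d\n",
              nrow(x$islands), paste(x$config$loci, collapse = "/"),
              x$config$seed))
  print(x$table)
  invisible(x)
}

#' Bundle a simulation for downstream analysis
#'
#' @param sim an [simulate_metacommunity()] result.
#' @return a `sar_bundle` (see [join_metadata()]).
#' @export
as_bundle <- function(sim) {
  stopifnot(inherits(sim, "island_simulation"))
  suppressWarnings(join_metadata(sim$table, sim$samples, sim$islands))
}
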