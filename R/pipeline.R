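# Config-driven end-to-end orchestration with machine-readable reports.

#' Build or read a pipeline run configuration
#'
#' A run takes either input paths (`counts`, `samples`, `islands` TSVs) or a
#' `simulate` block of [synth_config()] arguments — exactly one of the two.
#' Stage toggles, QC thresholds per locus, and replication counts for the
#' resampling stages are all explicit so a run is fully described by its
#' config plus the master seed.
#'
#' @param path optional YAML file to read the configuration from.
#' @param ... fields overriding the defaults (see [run_pipeline()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    counts = NULL, samples = NULL, islands = NULL,
    simulate = NULL,
    qc = list(decontam_threshold = 0.5,
              min_sample_reads = c("16S" = 2901, "18S" = 300),
              min_asv_reads = c("16S" = 4, "18S" = 3)),
    stages = c(qc = TRUE, diversity = TRUE, sar = TRUE, envmodel = TRUE,
               beta = TRUE, nullmodels = TRUE),
    bootstrap_B = 1000, mantel_permutations = 9999,
    nodf_nulls = 1000, rc_reps = 999,
    alpha = 0.05,
    seed = 1L)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, y)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  has_paths <- !is.null(cfg$counts)
  has_sim <- !is.null(cfg$simulate)
  if (has_paths == has_sim)
    stop("exactly one of input paths ('counts'/'samples'/'islands') or a ",
         "'simulate' block must be given")
  stopifnot(cfg$bootstrap_B >= 1, cfg$mantel_permutations >= 1,
            cfg$nodf_nulls >= 1, cfg$rc_reps >= 1)
  structure(cfg, class = "run_config")
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_json <- function(x, dir, name) {
  jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
}

#' Run the full analysis pipeline
#'
#' Executes qc, diversity, sar, envmodel, beta and nullmodels stages in
#' order, writing each stage's outputs as TSV/JSON under `out_dir` plus a
#' `manifest.json` recording the package version, seed, stage log and config
#' hash.  A single master seed spawns per-stage child seeds keyed by stage
#' name, so toggling one stage never shifts another's random stream; reruns
#' with the same config and seed are byte-identical.  Significance flags use
#' `alpha` (default 0.05) throughout.  A stage failure aborts the run naming
#' the stage; outputs of completed stages are retained.
#'
#' @param config a [run_config()] (or YAML path understood by it).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- run_config(path = config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log <- list()
  results <- list()

  stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    res <- tryCatch(fun(child_seed(seed, name)),
                    error = function(e)
                      stop("pipeline stage '", name, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    results[[name]] <<- res
    res
  }

  # -- input ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- child_seed(seed, "simulate")
    sim <- do.call(synth_config, sim_args)
    world <- simulate_metacommunity(sim)
    write_count_table(world$table, file.path(out_dir, "counts.tsv"))
    write_tsv(world$samples, out_dir, "samples.tsv")
    write_tsv(world$islands, out_dir, "islands.tsv")
    write_json(world$truth, out_dir, "truth.json")
    table <- world$table; samples <- world$samples; islands <- world$islands
    results$simulate <- world
  } else {
    table <- read_count_table(config$counts)
    samples <- read_sample_metadata(config$samples)
    islands <- read_island_metadata(config$islands)
  }
  log$input <- list(samples = nrow(table), asvs = ncol(table))

  loci <- intersect(LOCI, unique(samples$locus))

  # -- qc ---------------------------------------------------------------
  if (config$stages[["qc"]]) {
    reports <- list(); kept <- list()
    for (locus in loci) {
      ids <- samples$sample_id[samples$locus == locus]
      sub <- count_table(ct_matrix(table)[rownames(table) %in% ids, ,
                                          drop = FALSE])
      sub <- count_table(ct_matrix(sub)[, colSums(ct_matrix(sub)) > 0,
                                        drop = FALSE])
      dc <- decontam_prevalence(sub, samples,
                                threshold = config$qc$decontam_threshold)
      reports[[locus]] <- cbind(locus = locus, dc$report)
      # drop negatives before culling: controls are shallow by design
      keep_true <- samples$compartment[match(rownames(dc$table),
                                             samples$sample_id)] !=
        "negative_control"
      truec <- count_table(ct_matrix(dc$table)[keep_true, , drop = FALSE])
      kept[[locus]] <- cull(truec,
                            min_sample_reads = config$qc$min_sample_reads[[locus]],
                            min_asv_reads = config$qc$min_asv_reads[[locus]])
    }
    report <- do.call(rbind, reports)
    write_tsv(report, out_dir, "contaminants.tsv")
    all_s <- unlist(lapply(kept, rownames), use.names = FALSE)
    all_a <- unlist(lapply(kept, colnames), use.names = FALSE)
    clean <- matrix(0L, length(all_s), length(all_a),
                    dimnames = list(all_s, all_a))
    for (locus in loci)
      clean[rownames(kept[[locus]]), colnames(kept[[locus]])] <-
        ct_matrix(kept[[locus]])
    table <- count_table(clean)
    samples <- samples[samples$sample_id %in% rownames(table), , drop = FALSE]
    write_count_table(table, file.path(out_dir, "counts_clean.tsv"))
    log$qc <- list(samples_kept = nrow(table), asvs_kept = ncol(table),
                   flagged = sum(report$flagged))
    results$qc <- report
  } else {
    samples <- samples[samples$compartment != "negative_control", ,
                       drop = FALSE]
    table <- count_table(ct_matrix(table)[samples$sample_id, , drop = FALSE])
  }
  bundle <- suppressWarnings(join_metadata(table, samples, islands))

  # -- diversity --------------------------------------------------------
  if (config$stages[["diversity"]]) {
    stage("diversity", TRUE, function(sd) with_seed(sd, {
      ev <- evenness_records(bundle$table, bundle$samples)
      write_tsv(ev, out_dir, "richness_evenness.tsv")
      an <- lapply(loci, function(locus) {
        sub <- ev[ev$locus == locus, ]
        a <- richness_anova(sub$richness, sub$compartment)
        list(locus = locus, f = a$f, p = a$p, tukey = a$tukey)
      })
      ov <- lapply(loci, function(locus)
        compartment_overlap(bundle$table, bundle$samples, locus = locus))
      names(ov) <- loci
      write_json(list(anova = an,
                      overlap = lapply(ov, function(o)
                        list(regions = as.list(o$regions),
                             union_size = o$union_size))),
                 out_dir, "diversity_summary.json")
      list(evenness = ev, anova = an, overlap = ov)
    }))
  }

  # -- sar --------------------------------------------------------------
  if (config$stages[["sar"]]) {
    stage("sar", TRUE, function(sd) with_seed(sd, {
      tab <- sar_table(bundle, alpha = config$alpha)
      write_tsv(tab, out_dir, "sar_table.tsv")
      rich <- observed_richness(bundle$table, bundle$samples,
                                group_by = "island_compartment")
      boots <- list()
      for (k in seq_len(nrow(tab))) {
        sub <- rich[rich$locus == tab$locus[k] &
                      rich$compartment == tab$compartment[k] &
                      rich$richness > 0, ]
        sizes <- bundle$islands[[tab$size_field[k]]][
          match(sub$island_id, bundle$islands$island_id)]
        key <- paste(tab$locus[k], tab$compartment[k], tab$size_field[k],
                     sep = "|")
        boots[[key]] <- bootstrap_slopes(sub$richness, sizes,
                                         B = config$bootstrap_B,
                                         seed = child_seed(sd, key))
      }
      cmp <- list()
      for (locus in loci) {
        keys <- grep(paste0("^", locus, "\\|"), names(boots), value = TRUE)
        if (length(keys) >= 2L)
          cmp[[locus]] <- cbind(locus = locus,
                                compare_slopes_table(boots[keys]))
      }
      cmp <- do.call(rbind, cmp)
      if (!is.null(cmp)) write_tsv(cmp, out_dir, "slope_comparisons.tsv")
      list(table = tab, bootstraps = boots, comparisons = cmp)
    }))
  }

  # -- envmodel ---------------------------------------------------------
  if (config$stages[["envmodel"]]) {
    stage("envmodel", TRUE, function(sd) with_seed(sd, {
      models <- env_model_table(bundle)
      rows <- lapply(names(models), function(key) {
        m <- models[[key]]
        data.frame(model = key, term = m$coefficients$term,
                   estimate = m$coefficients$estimate,
                   p_value = m$coefficients$p_value,
                   significant = m$coefficients$p_value <= config$alpha,
                   aic = m$aic, r_squared = m$r_squared, n = m$n,
                   stringsAsFactors = FALSE)
      })
      write_tsv(do.call(rbind, rows), out_dir, "env_models.tsv")
      imp <- lapply(names(models), function(key) {
        im <- models[[key]]$importance
        if (is.null(im)) return(NULL)
        data.frame(model = key, predictor = names(im),
                   lmg_share = as.numeric(im),
                   full_r_squared = attr(im, "r_squared"),
                   stringsAsFactors = FALSE)
      })
      imp <- do.call(rbind, imp)
      if (!is.null(imp)) write_tsv(imp, out_dir, "env_importance.tsv")
      models
    }))
  }

  # -- beta -------------------------------------------------------------
  if (config$stages[["beta"]]) {
    stage("beta", TRUE, function(sd) with_seed(sd, {
      pooled <- pool_counts(bundle$table, bundle$samples)
      g <- attr(pooled, "groups")
      mantel_rows <- list(); disp_rows <- list(); disp_reg <- list()
      for (locus in loci) {
        for (comp in intersect(c("detritus", "water", "invertebrate"),
                               unique(g$compartment))) {
          sel <- g$compartment == comp & g$locus == locus &
            rowSums(pooled) > 0
          if (sum(sel) < 4L) next
          sub <- pooled[sel, , drop = FALSE]
          rownames(sub) <- g$island_id[sel]
          d_comm <- bray_curtis(sub)
          sf <- if (comp == "detritus") "detritus_weight_mg"
                else "water_volume_ml"
          isl <- bundle$islands[bundle$islands$island_id %in%
                                  g$island_id[sel], , drop = FALSE]
          d_size <- size_distance(isl, sf)
          key <- paste(locus, comp, sep = "|")
          mt <- mantel_spearman(d_comm, d_size,
                                n_perm = config$mantel_permutations,
                                seed = child_seed(sd, paste0("mantel|", key)))
          cs <- composition_size_regression(
            d_comm, d_size, B = config$bootstrap_B,
            seed = child_seed(sd, paste0("csr|", key)))
          mantel_rows[[key]] <- data.frame(
            locus = locus, compartment = comp, size_field = sf,
            mantel_r = mt$r, mantel_p = mt$p,
            regression_slope = cs$fit$slope,
            regression_r_squared = cs$fit$r_squared,
            regression_p = cs$fit$p_value, stringsAsFactors = FALSE)
        }
        # within-island dispersion for free-living compartments
        for (comp in c("detritus", "water")) {
          ids <- bundle$samples$sample_id[
            bundle$samples$locus == locus &
              bundle$samples$compartment == comp]
          sub <- ct_matrix(bundle$table)[rownames(bundle$table) %in% ids, ,
                                         drop = FALSE]
          sub <- sub[rowSums(sub) > 0, , drop = FALSE]
          if (nrow(sub) < 6L) next
          isl_of <- bundle$samples$island_id[match(rownames(sub),
                                                   bundle$samples$sample_id)]
          if (length(unique(isl_of)) < 3L) next
          dd <- tryCatch(beta_dispersion(bray_curtis(sub), isl_of),
                         error = function(e) NULL)
          if (is.null(dd)) next
          key <- paste(locus, comp, sep = "|")
          disp_rows[[key]] <- data.frame(
            locus = locus, compartment = comp,
            sample_id = names(dd$distances),
            distance_to_centroid = as.numeric(dd$distances),
            stringsAsFactors = FALSE)
          sf <- if (comp == "detritus") "detritus_weight_mg"
                else "water_volume_ml"
          rg <- tryCatch(dispersion_vs_size(dd, bundle$islands, sf),
                         error = function(e) NULL)
          if (!is.null(rg))
            disp_reg[[key]] <- data.frame(
              locus = locus, compartment = comp, size_field = sf,
              slope = rg$slope, r_squared = rg$r_squared,
              p_value = rg$p_value, stringsAsFactors = FALSE)
        }
      }
      mr <- do.call(rbind, mantel_rows)
      if (!is.null(mr)) write_tsv(mr, out_dir, "mantel.tsv")
      dr <- do.call(rbind, disp_rows)
      if (!is.null(dr)) write_tsv(dr, out_dir, "dispersion.tsv")
      dg <- do.call(rbind, disp_reg)
      if (!is.null(dg)) write_tsv(dg, out_dir, "dispersion_regressions.tsv")
      list(mantel = mr, dispersion = dr, dispersion_regressions = dg)
    }))
  }

  # -- nullmodels -------------------------------------------------------
  if (config$stages[["nullmodels"]]) {
    stage("nullmodels", TRUE, function(sd) with_seed(sd, {
      pooled <- pool_counts(bundle$table, bundle$samples)
      g <- attr(pooled, "groups")
      nodf_out <- list(); rc_out <- list()
      for (locus in loci) {
        nt <- nodf_test(bundle$table, bundle$samples, locus = locus,
                        n_null = config$nodf_nulls,
                        seed = child_seed(sd, paste0("nodf|", locus)))
        nodf_out[[locus]] <- list(observed = nt$observed,
                                  null_mean = nt$null_mean,
                                  null_sd = nt$null_sd, z = nt$z, p = nt$p,
                                  n_null = nt$n_null)
        for (comp in unique(g$compartment)) {
          sel <- g$compartment == comp & g$locus == locus &
            rowSums(pooled) > 0
          if (sum(sel) < 2L) next
          sub <- pooled[sel, colSums(pooled[sel, , drop = FALSE]) > 0,
                        drop = FALSE]
          rownames(sub) <- g$island_id[sel]
          rcb <- rc_bray(count_table(sub), reps = config$rc_reps,
                         seed = child_seed(sd, paste0("rc|", locus, comp)))
          v <- upper_tri(rcb$values)
          rc_out[[paste(locus, comp, sep = "|")]] <- list(
            n_pairs = length(v),
            fraction_above_0.95 = mean(v > 0.95),
            fraction_below_minus_0.95 = mean(v < -0.95),
            mean = mean(v))
        }
      }
      write_json(list(nodf = nodf_out, rc_bray = rc_out), out_dir,
                 "nullmodels.json")
      list(nodf = nodf_out, rc_bray = rc_out)
    }))
  }

  # -- manifest ---------------------------------------------------------
  cfg_file <- file.path(out_dir, "config_echo.json")
  write_json(unclass(config), out_dir, "config_echo.json")
  manifest <- list(
    package = "islesar",
    version = as.character(utils::packageVersion("islesar")),
    seed = seed,
    alpha = config$alpha,
    config_md5 = unname(tools::md5sum(cfg_file)),
    stages_run = names(which(config$stages)),
    log = log)
  write_json(manifest, out_dir, "manifest.json")
  invisible(results)
}
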