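# islesar

Species–area relationships (SARs) for island microbiome metacommunities.

Discrete habitat islands — here modelled on bromeliad phytotelmata, whose
water and detritus holdings form aquatic habitat islands for free-living and
host-associated (invertebrate) fungi and bacteria — let one ask whether
microbial richness obeys the classic power law

&nbsp;&nbsp;&nbsp;&nbsp;*S = c·A^z*,&nbsp;&nbsp; i.e. &nbsp;log *S* = log *c* + *z*·log *A*,

where *S* is ASV richness, *A* island size (detritus dry weight in mg, or
water volume in ml), and the exponent *z* is conventionally read as an
indicator of dispersal limitation. `islesar` packages the full analysis a
study of this design needs:

* **QC** — prevalence-based contaminant screening against negative controls
  (`decontam_prevalence()`, one-sided chi-square / Fisher scores), read-count
  culling (`cull()`) and a break-point diagnostic for choosing thresholds
  (`suggest_break_threshold()`).
* **Diversity** — observed richness with replicate pooling
  (`observed_richness()`), hypergeometric rarefaction curves with asymptote
  diagnostics (`rarefaction_curve()`), Hill q = 1 evenness (`hill_q1()`),
  compartment overlap (`compartment_overlap()`), and ANOVA/Tukey richness
  comparisons (`richness_anova()`).
* **SAR inference** — log–log OLS fits (`fit_sar()`, `sar_table()`),
  case-bootstrap slope distributions (`bootstrap_slopes()`), Welch
  comparisons between slopes (`compare_slopes()`), Benjamini–Hochberg
  correction (`bh_adjust()`).
* **Environmental models** — stepwise-AIC multiple regression
  (`step_aic()`) and exact LMG relative-importance decomposition
  (`lmg_importance()`).
* **Turnover** — Bray–Curtis dissimilarity (`bray_curtis()`), Mantel tests
  against island-size distance (`mantel_spearman()`),
  dissimilarity-vs-size regressions with island-resampled bootstraps
  (`composition_size_regression()`), and beta dispersion
  (`beta_dispersion()`, `dispersion_vs_size()`).
* **Null models** — abundance-weighted Raup–Crick Bray–Curtis (`rc_bray()`),
  NODF nestedness (`nodf()`), uniform margin-preserving binary
  randomizations in compiled code (`quasiswap_nulls()`), and
  z-score/permutation summaries (`null_compare()`, `nodf_test()`).
* **Synthetic metacommunities** — `simulate_metacommunity()` generates
  islands, regional pools, host-filtered communities, replicate read
  samples and contaminated negative controls with known ground truth, so
  every stage of the pipeline is testable end to end.
* **Orchestration** — `run_pipeline()` executes the whole chain from a
  single config and master seed, writing TSV/JSON reports that rerun
  byte-identically.

## Worked example

Simulate a 32-island metacommunity at the package's default study
conditions and fit the SAR family for the fungal locus:

```r
library(islesar)

sim <- simulate_metacommunity(synth_config(seed = 42))
sim
#> island_simulation: 32 islands, loci 16S/18S, seed 42
#> count_table: 908 samples x 1000 ASVs, 17,867,154 reads total

b   <- as_bundle(sim)
tab <- sar_table(b)
tab[tab$locus == "18S", c("compartment", "size_field", "n", "r_squared",
                          "slope", "intercept", "p_adjusted")]
#>   compartment         size_field  n r_squared  slope intercept p_adjusted
#>      detritus detritus_weight_mg 32    0.0147 0.0432      4.48     0.6506
#>         water    water_volume_ml 32    0.2380 0.1383      2.93     0.0369
#>  invertebrate detritus_weight_mg 32    0.0109 0.0319      2.73     0.6506
#>  invertebrate    water_volume_ml 32    0.0132 0.0436      2.72     0.6506
```

Each row is one SAR: `slope` is the exponent *z* from the log–log OLS fit of
pooled per-island richness on island size, `intercept` is log *c* (natural
logs), and `p_adjusted` is the slope's p-value after Benjamini–Hochberg
correction across the whole fitted family.  In this particular world only
the aquatic SAR clears α = 0.05 — with only 32 islands and realistic noise,
individual worlds scatter widely around the generating exponents
(z = 0.12/0.10/0), which is exactly why slope inference goes through
bootstrap distributions:

```r
rich <- observed_richness(b$table, b$samples, group_by = "island_compartment")
det  <- rich[rich$locus == "18S" & rich$compartment == "detritus", ]
sz   <- b$islands$detritus_weight_mg[match(det$island_id, b$islands$island_id)]
bootstrap_slopes(det$richness, sz, B = 1000, seed = 1)
#> bootstrap_slopes: B = 1000, point = 0.0432, mean = 0.0455, 95% CI [-0.0822, 0.1625]
```

The 95% interval comfortably covers the generating z = 0.12.  A full run of
every stage, written to disk with a manifest:

```r
cfg <- run_config(simulate = list(), seed = 1)   # defaults throughout
run_pipeline(cfg, "run_out/")
```

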