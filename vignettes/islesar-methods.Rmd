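---
title: "Island microbiome species–area analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Island microbiome species–area analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islesar)
```

`islesar` analyses how microbial richness, evenness and community turnover
scale with habitat-island size in discrete island systems — the motivating
system being bromeliad phytotelmata, where each plant's standing water and
accumulated detritus form an aquatic island hosting free-living microbes
and invertebrate (mosquito-larva) hosts.  This vignette explains the models
the package fits, the parameters that matter, what the synthetic generator
does and does not emulate, and the design decisions taken where a choice
was genuinely open.

## The species–area model

Richness is modelled as a power law of island size, $S = c A^z$, fitted as
an ordinary least-squares regression of $\log S$ on $\log A$ (natural logs
throughout; the exponent $z$ is base-invariant, intercepts are reported on
the natural-log scale).  Island size is detritus dry weight (mg) for
detrital communities and water volume (ml) for aquatic ones; invertebrate
(host-associated) communities are regressed on both measures, giving a
family of four SARs per locus.  p-values within one fitted family are
corrected together by Benjamini–Hochberg, and the exponent is reported as a
"z-score" only for family-significant fits.

Zero richness is a hard error in `fit_sar()`: silently adding one read
would change the exponent, so the caller must drop those islands or choose
an explicit offset.

**Slope uncertainty and comparisons.**  "Randomly pairing richness and
area with replacement" is implemented as a joint case bootstrap: islands —
$(S_i, A_i)$ pairs — are resampled with replacement to the original $n$ and
the log–log slope refitted, $B = 1000$ times by convention.  The
alternative reading (resampling $S$ and $A$ independently) would destroy
the very slope the comparisons need, producing distributions centred on
zero rather than on the observed slopes; significant pairwise differences
between compartments are only meaningful under the joint scheme.
Degenerate resamples with zero size variance are redrawn and counted.
Slope distributions are compared with Welch's $t$ (Welch–Satterthwaite
degrees of freedom), corrected within the comparison family by
Benjamini–Hochberg.

## Quality control

Contaminant screening follows the prevalence logic: for each ASV a
$2\times2$ presence/absence by negative/true-sample table is scored with
the one-sided p-value against "more prevalent in negatives" — a chi-square
test halved in the observed direction, replaced by the one-sided Fisher
exact test whenever any expected cell is below 5.  The score is an exactly
testable quantity (it equals a hypergeometric tail in the exact branch);
ASVs scoring below the threshold (default 0.5, the conventional choice; the
underlying study does not report its threshold) are removed.  An ASV absent
from all negatives has a one-sided score of at least 0.5 and can never be
flagged at the default.

Read-count culling drops samples at or below a per-sample read threshold,
then ASVs at or below a per-ASV threshold, and repeats the two passes (in
that order) to a fixed point.  The fixed point matters: a single pass is
not idempotent, because removing low-count ASVs can push a sample below its
threshold.  Study-style defaults are (300, 3) for fungal and (2901, 4) for
bacterial tables.  Because such thresholds were historically chosen by eye
from breaks in plotted log read totals, `suggest_break_threshold()`
automates the diagnostic — the geometric midpoint of the largest log-scale
gap in the lower half of the distribution, ties broken toward the smallest
threshold, with a low-confidence flag when no gap dominates — but the
suggestion is advisory and never auto-applied: reproducibility requires
explicit thresholds in the config.

## Diversity and evenness

Observed richness (not Chao/ACE-style extrapolation) is the alpha metric:
the analysis design assumes saturated sampling, checked per community with
hypergeometric rarefaction, $E[S(m)] = S_{obs} - \sum_i \binom{N-N_i}{m} /
\binom{N}{m}$, computed in log space.  A curve is declared asymptotic when
the mean slope over the final 10% of the depth grid falls below a tolerance
(default $10^{-3}$ species/read).  Replicates are pooled by count summation
— the simplest reading of "pooling all samples within each compartment" —
rather than by union of rarefied replicates.

Evenness is the Hill number of order one, $\exp(-\sum p_i \ln p_i)$, an
effective species number lying between 1 and the richness; regressing it on
log island size diagnoses "disproportionate effects" (evenness itself
changing with area).  Group comparisons of richness use one-way ANOVA with
Tukey HSD.

## Turnover and dispersion

Beta diversity is Bray–Curtis on raw counts.  Turnover versus island size
is tested two ways: a Mantel test (Spearman correlation of unfolded upper
triangles; one-sided *greater* p from jointly permuting one matrix's rows
and columns, 9999 permutations by convention) and an OLS regression of
dissimilarity on pairwise size distance.  Size distances default to
differences of log size — the SARs live in log space — with a raw-scale
option.  The regression's bootstrap resamples **islands** and rebuilds both
triangles, not pairwise entries: entries sharing an island are dependent,
and the pair bootstrap understates slope uncertainty (a property test pins
the direction of that inequality).

Within-island dispersion embeds the dissimilarity matrix by principal
coordinates and measures each sample's distance to its island centroid,
with the standard negative-eigenvalue correction (squared distances in
negative axes subtracted, clamped at zero).  Dispersion regressed on log
island size asks whether larger islands hold more variable communities.

## Null models

**Raup–Crick Bray–Curtis.**  For each sample pair the observed Bray–Curtis
value is ranked (ties counted half) within a null distribution built by
reassembling both samples: species drawn without replacement with
probability proportional to occurrence frequency across the table, each
sample's observed read total then distributed multinomially in proportion
to metacommunity relative abundance.  The rank is rescaled to $[-1, 1]$;
values beyond $\pm 0.95$ flag divergence (environmental filtering/dispersal
limitation with drift) or homogenization.  Replicates default to 999 (the
method's convention; the study does not state its count), read totals are
fixed at observed values, and the metacommunity is simply the table passed
in — scoping to a locus or compartment set is done by subsetting upstream.

**Nestedness.**  NODF is computed from pairwise fill comparisons: for rows
(and symmetrically columns) with unequal fills, the paired term is
$100\,|{\rm overlap}|/{\rm fill_{smaller}}$, summed over all pairs and
divided by the total pair count.  This form is order-independent, so no
re-sorting is applied (it coincides with the fill-sorted variant of the
usual implementations, which is the cross-check used in the tests).

**Margin-preserving randomization.**  Null matrices preserve both row and
column sums exactly.  The quasiswap construction — a random integer matrix
with the target margins reduced to binarity by $2\times2$ updates — is
known to carry a small constructive bias that is actually detectable on
enumerable margin classes at a few thousand draws.  The package therefore
follows the construction with trial-swap mixing (a random $2\times2$
submatrix is swapped iff it is a checkerboard; every trial counts as a
step).  That chain's transition kernel is symmetric, so its stationary
distribution over the margin class is uniform; the default of
$\max(1000, 2\,\mathrm{fill})$ trials fully mixes small matrices and
empirically passes chi-square uniformity tests that the bare construction
fails.  A curveball (pairwise row-trade) chain is available as an
alternative.  Both run in compiled code under R's RNG, so fixed seeds
reproduce exactly.

**A structural caveat for 3-row compartment matrices.**  The pooled
compartments-by-ASVs presence matrix has only three rows, and with both
margins fixed the column fills (1, 2 or 3 compartments) encode nearly all
of the nesting information: columns of fill 3 are identical in every member
of the margin class, and the null NODF distribution collapses to a very
narrow band.  In consequence, NODF z-scores against margin-preserving nulls
cannot meaningfully exceed zero for such matrices — even an idealized
perfect containment chain (water ⊂ detritus, hosts ⊂ water) scores
*negative* z, a result we confirmed against an independent implementation.
The package still exposes `nodf_test()` for the compartment matrix, but the
generator's host-filtering mechanism is validated on the artifact-free
quantity: the containment of the invertebrate row inside each environmental
row, which increases monotonically as the admissible host fraction shrinks.

## Environmental models

Stepwise model selection minimizes the conventional linear-model AIC,
$n\ln(\mathrm{RSS}/n) + 2k$ (the constant term dropped consistently),
starting from the full model for the default bidirectional search.
Candidate sets mirror the study design: diameter, height, complexity (leaf
count), invertebrate number and log invertebrate weight everywhere;
detritus models add %C and %N; water models add dissolved oxygen, pH,
temperature and nitrate.  Fitting is complete-case with the dropped-row
count reported, since per-compartment models legitimately differ in degrees
of freedom.  Near-collinear candidate pairs are rejected by name rather
than silently absorbed.

Two selection caveats are worth stating plainly.  First, AIC's fixed
penalty of 2 retains a pure-noise predictor with probability
$P(\chi^2_1 > 2) \approx 0.157$ *regardless of sample size*, so with $k$
noise candidates the intercept-only model is recovered in only about
$0.843^k$ of datasets — selection is not consistent, and the tests assert
that rate rather than a near-certain collapse.  Second, the greedy search
occasionally parks in a local AIC optimum; agreement with exhaustive
best-subset search measured ≈ 94–95% at $k = 6$, and the corresponding test
asserts a bound safely below that measured rate so that binomial noise in
the spot check cannot fail a correct implementation.

Relative importance uses the LMG decomposition: each predictor's share of
the full-model $R^2$ is its incremental $R^2$ averaged over all predictor
orderings, computed exactly over the $2^k$ subsets with ordering weights
$|S|!\,(k-|S|-1)!/k!$ (hence the $k \le 10$ limit).  Shares sum to the full
$R^2$ and are invariant to predictor order.

## The synthetic generator

`simulate_metacommunity()` generates the study conditions the analyses
assume: 32 islands whose detrital sizes span a 250-fold range and aquatic
sizes a 90-fold range (30–2700 ml) — log-uniform, so that $\log A$ has
balanced leverage, with endpoints pinned so the realized fold range is
exact; per-compartment SAR exponents and intercepts (defaults
$z = 0.12/0.10/0$ and $\log c = 3.95/3.25/2.96$ for detritus, water and
invertebrates — the fungal point estimates of the motivating design);
replicate sampling of 10 detritus, 3 water and 1 invertebrate sample per
island (study medians); and pH decreasing with log water volume
(−0.25/log-unit around a 7.4 baseline, noise SD 0.2), while all other
covariates are drawn independently of size so environmental-model tests can
separate size effects from covariate effects.

Richness — not read count — carries the SAR signal: target richness is
$S^\ast = \mathrm{round}(\exp(\log c + z \log A + \varepsilon))$,
$\varepsilon \sim N(0, \sigma)$, and sequencing depth is decoupled
(negative binomial, mean 20 000, size 10), mimicking saturated sampling.
The default $\sigma = 0.5$ was chosen analytically, once: with
$\log A$ uniform over a 250-fold range the population log–log $R^2$ is
$z^2\mathrm{Var}(\log A)/(z^2\mathrm{Var}(\log A)+\sigma^2) \approx 0.125$
for detritus and $\approx 0.09$ for water — the weak-signal regime the
motivating estimates (0.12, 0.07) sit in.  Species pools are lognormal
(meanlog 0, sdlog 1 — a modelling choice; the abundance family of the real
communities is unknown), of 500 species per locus, a desk-scale stand-in
for the thousands of ASVs in real tables.  Hosts draw only from the top
`host_filter_strength` fraction of the pool by abundance — host-compatible
taxa modelled as the environmentally prevalent members — which makes
host-in-environment containment increase monotonically as the filter
tightens.  Contaminants (10 per locus) appear in each of 6 negative
controls with probability 0.9 and are sprinkled into true samples with
probability 0.15.

What the generator does **not** emulate: sequence-level error, taxonomic
structure, phylogenetic signal, temporal dynamics (flushing/succession),
spatial autocorrelation among islands, and any built-in coupling between
community *composition* and island size beyond richness — default worlds
are drift-assembled from a common pool, so Mantel correlations and
Raup–Crick values on them sit near the null, which is exactly what makes
them useful for calibration tests.  Passing tests on synthetic data
demonstrate that the estimators recover known structure under these
idealized conditions, not that real bromeliad data satisfy them.

## Numerical choices and reproducibility

* All log transforms are natural; Bray–Curtis ties in Raup–Crick ranking
  are resolved at $10^{-12}$ tolerance on the rational count ratios.
* Bootstrap slopes use a closed-form OLS on the resample matrix (identical
  arithmetic to `lm`, vectorized across replicates).
* Permutation p-values are of the form $(\mathrm{count}+1)/(B+1)$, never
  zero; two-sided null-model p's are twice the smaller tail, capped at 1.
* Every stochastic operation takes a seed; `run_pipeline()` derives
  per-stage child seeds from the master seed keyed by stage name, so
  toggling one stage never shifts another's stream, and reruns are
  byte-identical.
* Degenerate cases are reported, not patched: undefined Mantel r on a
  constant triangle, undefined Welch t for two constant slope vectors, and
  undefined null z when the null distribution has zero spread all surface
  as `NA` with the count-based p still reported where defined.

## Problem sizes used in the shipped tests

The test suite and acceptance script run at desk scale, chosen as the
package's own balance between statistical resolution and turnaround:
100 replicate worlds (32 islands each) for bootstrap-coverage checks,
200 flat worlds for family-wise type-I control, 500 simulations at 199
permutations for Mantel calibration, 999–1000 replicates for single-shot
null models, and reduced pools/replication (e.g. 100–150-species pools,
10–12 islands) in fixture worlds used by smoke and determinism tests.

## Known limitations

* The NODF/quasiswap combination is uninformative for 3-row pooled
  compartment matrices (see the structural caveat above); row-level
  containment or larger matrices (e.g. islands × ASVs) are the workable
  alternatives.
* `decontam`-style frequency (DNA-concentration) scoring and batch-aware
  decontamination are out of scope; the prevalence method assumes
  reasonably many true samples per locus.
* Stepwise-AIC selection inherits the instability of all greedy selection;
  the LMG decomposition is exact but limited to 10 predictors.
* Raup–Crick run time grows with pairs × replicates; tables are best
  pooled per island (the pipeline does so) before calling `rc_bray()`.
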