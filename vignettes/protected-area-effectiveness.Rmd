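---
title: "Quantifying local biodiversity inside and outside protected areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local biodiversity inside and outside protected areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paeffect)
```

## The question and the design

Whether terrestrial protected areas actually hold more biodiversity than
comparable unprotected land is hard to answer from site-level survey data,
because surveys differ enormously in method, taxon and effort, and because
protected areas are not placed at random. `paeffect` implements an analysis
design built around multi-study compilations of site-level surveys (one
"study" = one survey campaign with a consistent method): sites within a study
straddle a protected-area boundary, so the inside/outside comparison is made
*within* studies and among-study methodology differences are absorbed by
random effects.

The pipeline has five stages, each usable on its own:

1. **measures** — four responses per site;
2. **spatial** — protection assignment by point-in-polygon overlay,
   management-category grouping, and a within-study land-use-matched subset;
3. **glmm** — mixed-effects models with likelihood-ratio backward
   elimination and back-transformed percentage contrasts;
4. **effectiveness** — the counterfactual algebra converting modelled
   inside/outside ratios into a global effectiveness score and two policy
   scenarios;
5. **synthetic data** — a generator with known ground truth, so all of the
   above is testable end to end.

## The four biodiversity measures

For each site we compute:

* **Species richness** `S`: the number of taxa recorded with a positive
  measurement.
* **Total abundance** `N`: the summed measurements (undefined for
  occurrence-only studies).
* **Rarefied richness** `E[S_n]`: the expected number of species in a
  uniform subsample of `n` individuals drawn without replacement, with `n`
  fixed per study at the smallest site total so all of a study's sites are
  compared at equal effort. We use the analytic hypergeometric form
  `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`, computed with
  log-binomials for stability; it is restricted to studies recording
  integer counts, because rarefaction is defined on individuals and
  rounding density data would invent them. If any site of a study is empty
  (`n = 0`), the measure is undefined for the whole study.
* **Endemicity**: the reciprocal of the community-weighted mean (CWM) log10
  geographic range size, `1 / (sum_i a_i log10 R_i / sum_i a_i)`, with
  equal weights for occurrence data. Higher values mean assemblages
  dominated by narrow-ranged species. Range sizes are an input table; taxa
  without an entry are dropped from both sums and counted in a warning.

"Inverse" CWM range size could mean reciprocal or sign reversal; the two
give identical inference up to sign. We report the reciprocal as the value
and, in the models, fit `ln(CWM)` as a well-behaved Gaussian response and
negate the protection coefficient, so the back-transformed contrast is
exactly the percentage difference in `1/CWM`. (Fitting raw CWM would leave
the contrast in log10-km2 units, which cannot be put on the percentage
scale the other measures use.)

## Protection assignment and matching

A site is protected when its coordinates fall inside any protected-area
polygon. Containment is even-odd ray casting in plain longitude/latitude —
containment is topological, so no projection is needed — with two
conventions chosen for determinism: boundary points count as inside, and
polygons spanning more than 180 degrees of longitude are rejected rather
than silently mishandled at the antimeridian. When areas overlap, the most
restrictive management category wins (I-II over III-VI over unknown),
mirroring the ordering of the management-group factor.

IUCN categories collapse to four groups (unprotected, III-VI, unknown,
I-II) and each protected site gets a size/age class from its area's age at
the reference year (default 2014, the register vintage) and reported area:
young is strictly under 20 years, small strictly under 400 km2. Ages above
85 years or areas above 12,000 km2 describe the tails of the sample the
thresholds were designed for, so they are accepted with a warning rather
than rejected.

The **matched-sites** subset keeps, within each study, only sites whose
land-use class occurs on both sides of the protection boundary; studies
with no such class drop out. This controls the comparison for land use
without covariate-based statistical matching (which the sparse geographic
coverage of such compilations cannot support). Whether matching should also
require equal use intensity is not decidable from the design alone; land
use alone is the default and intensity matching is a switch
(`match_intensity`).

## The models

Each measure is modelled with study and block-within-study random
intercepts, by maximum likelihood (not REML) so that likelihood-ratio
tests on fixed effects are valid:

* richness: Poisson with log link; an observation-level random intercept is
  added automatically when the Pearson dispersion exceeds 1.5;
* abundance: Gaussian on `ln(N + 1)`;
* rarefied richness: Gaussian on `ln(E[S_n] + 1)`;
* endemicity: Gaussian on `ln(CWM)`, contrast negated.

Fitting is by Laplace-approximated maximum likelihood via `lme4`; the test
suite cross-checks the Poisson path against an independently implemented
adaptive Gauss-Hermite quadrature oracle (25 nodes, single grouping factor)
to 1e-3 in the coefficients, and the Gaussian path against closed-form
least squares in the single-study limit. Random terms whose grouping factor
has fewer than two levels are dropped, which is what makes that limit
well-defined.

Three confounders of protected-area placement — elevation, slope and
agricultural suitability — enter every model as z-scored covariates
(standardisation is our choice; it makes slopes comparable and helps the
optimizer). Backward elimination repeatedly drops the least significant
droppable term (P >= 0.05 by LRT), never touching the term of interest and
never dropping a main effect while an interaction containing it survives.
The reported chi-square for protection is a single LRT of the final model
with and without it.

The model set mirrors the design: protection-only; the four-level
management-category factor; protection x land use (whose interaction LRT
asks whether protection does more than prevent land-use change);
matched-data re-runs; and the five-level size/age-class model on matched
data. Percentage differences are `100 (exp(beta) - 1)` with Wald 95%
intervals.

## The effectiveness algebra

Let `i` and `o` be average site-level biodiversity inside and outside
protected areas as proportions of the pristine level, `a` the protected
fraction of land, and `r` the global average proportional loss of
site-level biodiversity (an external input, default 0.136; `a` defaults to
0.154). The per-land-use modelled ratios `rho_l = i_l / o_l` are combined
with global land-use area weights `w_l` into `rho = sum w_l rho_l` (the
weighted arithmetic mean; a ratio-of-weighted-means variant is available
when relative outside levels are supplied). The global-state identity
`1 - r = a i + (1 - a) o` then pins down both levels:
`o = (1 - r) / (1 + a (rho - 1))`, `i = rho o`, and effectiveness is

```
e = 1 - (1 - i) / (1 - o)
```

zero when protection makes no difference, one when protected sites match
pristine ones, bounded at neither end. Two scenarios follow. The
*restrictive-management* scenario re-solves the system with the ratio
implied by the most restrictive management categories (`rho*`), holding the
global state fixed. The *required-area* question inverts the algebra: how
much land must be protected, at the current per-hectare effect, to reach
the outcome the restrictive network would deliver. Re-solving with the
global state held fixed would leave the outcome unchanged by construction,
so the scenario outcome level is defined holding the outside level at its
current value, `G* = a rho* o + (1 - a) o`, giving
`a' = a (rho* - 1) / (rho - 1)`. Both interpretations are exposed and the
choice is a flag.

All internal computation uses proportions; percentages appear only at I/O,
so units can never mix. Uncertainty in `e`, `e*` and `a'` is propagated by
parametric Monte Carlo: each of 10,000 seeded draws samples every land
use's log ratio from its coefficient sampling distribution (normal on the
link scale) and runs the entire algebra; the 2.5/97.5 percentiles give the
interval. The default land-use area weights are round figures consistent
with global land-cover syntheses and are plainly inputs — override them
wherever weights are accepted.

## What the synthetic generator emulates

`generate_world()` builds a multi-study world: each study has its own taxon
pool (log-normal expected counts, uniform baseline occupancies, log-normal
range sizes), its own 1-degree extent partly covered by one rectangular
protected area, spatial blocks, a use intensity per site, and either count
or presence/absence recording (a configurable fraction of studies is
occurrence-only, thresholding counts at one). Expected counts are
multiplicative: pool mean x land-use factor x protection factor x
exponentiated confounder slopes x study and block intercepts, with Poisson
observation noise (gamma-mixed when overdispersion is configured).
Protection acts on two knobs so the two headline ratios are separately
controllable: inside a protected area every taxon's occupancy probability
is multiplied by the target richness ratio, and the count rate by
(abundance ratio / richness ratio), making the expected inside/outside
ratios of richness and total abundance equal the configured targets.
(Richness hits its target exactly when the two ratios are equal; when the
abundance ratio is larger, the higher count rate inside also lifts the
detection of occupied taxa, so the realized richness ratio sits slightly
above the occupancy target — about one percentage point at the defaults.)
Non-random placement is emulated by shifting confounder means
inside protected areas by a configurable number of SDs.

Defaults are set at the scale of the real all-sites analyses this design
comes from — 156 studies, a few dozen sites each, roughly 30% of sites
protected, target ratios 1.106 (richness) and 1.145 (abundance) — and they
are the study conditions, not tuning knobs. Rectangular protected areas are
deliberate: they exercise point-in-polygon and the boundary convention
while keeping the truth label exact. The generator does *not* emulate
species-area or distance-decay spatial structure, phylogenetic signal, or
temporal dynamics, so passing tests say nothing about those aspects of real
data; what they do show is that every pipeline stage recovers a known truth
under realistic multi-study heterogeneity.

`generate_matched_fixture()` is a four-study world whose matched subset is
known by hand enumeration (cropland matched across the boundary in one
study, a study entirely inside, primary vegetation matched in a third, an
occurrence-only study with matched secondary vegetation), used to pin down
the matching rule exactly.

## Numerical choices and degenerate inputs

* Rarefaction works in log-binomial space; `E[S_N] = S` and `E[S_0] = 0`
  hold exactly, and the curve is nondecreasing in `n`.
* Log-likelihood tolerance: a decrease beyond `1e-3 x max(1, |l|)` when
  adding terms raises a refit error instead of a silently negative
  chi-square; small negatives are clamped to zero.
* Singular fits (variance components at zero) are allowed and flagged;
  non-converged fits are flagged and refused by the LRT.
* Inestimable protection x land-use cells are dropped from contrast tables
  with a warning naming the land use.
* Ties in elimination resolve to the first-listed term; the trace records
  every test so the path is auditable.
* Seeds: one run seed is fanned out to per-stage child seeds by fixed
  offsets, so a stage re-run in isolation reproduces its in-pipeline
  behaviour; generators restore the caller's RNG state.

## Problem sizes used by the shipped checks

The test suite exercises parameter recovery at 200 studies x 30 sites (100
replicates) for Wald coverage of the true protection effect, elimination
behaviour at 40 studies x 20 sites (100 replicates, a strong effect and a
pure-noise covariate), and the end-to-end run at 60 studies of 20-35 sites,
checking that the truth-implied effectiveness lies inside the pipeline's
Monte-Carlo interval. The acceptance script runs the full pipeline at the
generator's default 156-study scale. These sizes are the package's choice
of a demonstration scale: large enough for the asymptotics the checks rely
on, small enough to run routinely.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(
  synthetic = world_config(n_studies = 60, random_seed = 1),
  out_dir = "pa_run", seed = 17)
res <- run_all(cfg)
res$suite$contrasts          # percentage differences per measure and model
res$effectiveness$richness   # rho, i, o, e with Monte-Carlo intervals
```

## Known limitations

* The generator's protection effect is constant across land uses, so
  synthetic worlds cannot probe interaction *recovery* beyond the null
  (the interaction's type-I behaviour is tested instead).
* Land-use area weights, `a` and `r` are inputs; nothing in the package
  estimates them.
* Flat-earth containment is exact for the data it accepts but rejects
  antimeridian-crossing polygons outright.
* The Monte-Carlo interval for `e` propagates coefficient uncertainty
  only; uncertainty in the weights, `a` and `r` is not modelled.
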