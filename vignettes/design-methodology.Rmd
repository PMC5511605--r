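---
title: "Optimal trial networks for phenology-model calibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal trial networks for phenology-model calibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optimet)
```

This vignette is the package's account of its science: the statistical
model, the design criterion, the phenology simulator and its assumptions,
the samplers and estimators, the synthetic-data generators, and the
numerical and design choices made where more than one reasonable option
existed.

## Statistical model

Observed heading dates are modeled as crop-model output plus independent
Gaussian observation error,

$$Y_{ijk} = f(\theta_i, E_j) + e_{ijk}, \qquad
e_{ijk} \sim \mathcal N(0, \sigma_e^2),$$

for variety $i$, environment $j$ and replication $k$. $\theta_i$ is the
p = 3 vector of genetic parameters (VAI, SLDL, Phyl) and $E_j$ the
environment's daily mean temperature and day-length series. The default
error standard deviation of 2 days reflects how precisely heading can be
scored in the field. A heteroscedastic variant attributes one residual
variance per environment; it is the appropriate model for real trials
whose heritabilities differ, and is selected with
`prior_spec(heteroscedastic = TRUE)`.

## The phenology model

Development from sowing to heading has three phases, driven by daily mean
temperature and astronomical day length:

1. **Sowing to emergence.** Thermal time (daily mean temperature, base
   0 °C) accumulates to `tt_em` = 150 °Cd.
2. **Emergence to flag leaf.** From the emergence instant, vernalization
   progress accumulates at daily rate $VBEE + VAI \cdot T$, with $T$ the
   daily mean clamped into the effective window [0, 18] °C and
   `vbee` = 0.01 day⁻¹ the baseline, saturating at 1. The final leaf
   number is

   $$FLN = L_{base} + \underbrace{\kappa \,\frac{C(t_{sat}) - tt_{em}}{Phyl}}_{\text{vernalization delay}}
   + SLDL \cdot \max(0, DL_{sat} - DL),$$

   where $C(t_{sat})$ is cumulative thermal time at vernalization
   saturation, $\kappa$ (`vern_leaf_frac` = 0.5) is the fraction of
   pre-saturation leaves that delay the flag leaf, and $DL$ is the day
   length on the day vernalization saturates (or the emergence day if
   saturation precedes emergence), with `dl_sat` = 15 h and
   `l_base` = 8 leaves.
3. **Flag leaf to heading.** `n_tail` = 2 further phyllochrons. Heading
   occurs when post-sowing thermal time reaches
   $tt_{em} + (FLN + n_{tail})\,Phyl$, never earlier than vernalization
   saturation.

Sub-day resolution comes from linear interpolation of the thermal-time
accumulator within the heading day; without it, nearby parameter vectors
produce tied integer outputs and the design criterion goes blind to their
difference.

Three structural choices deserve comment, because the compact model could
have been written otherwise:

* **Vernalization starts at emergence, not sowing.** Reference phenology
  models progress vernalization in the emerged seedling. The choice also
  matters statistically: with sowing-start accumulation, saturation
  completes before emergence whenever
  $T/(tt_{em}(VBEE + VAI\,T)) < 1$ — which holds for all temperate
  temperatures once VAI exceeds roughly $1/tt_{em} \cdot (1 - \ldots)$
  ≈ 0.007 — and the vernalization signal vanishes over the top of the
  prior range.
* **The vernalization leaf delay.** Flag-leaf appearance integrates
  vernalization *and* photoperiod. If vernalization acted only by moving
  the day on which the photoperiod deficit is read, its effect would be
  proportional to SLDL and the two parameters would be confounded (the
  profile likelihood over VAI is then flat for low-SLDL varieties). The
  delay term gives vernalization its own, SLDL-independent route into the
  leaf number.
* **The temperature clamp.** The vernalization rate uses the daily
  temperature clamped into [0, 18] °C rather than zeroed outside it, so
  warm spring genotypes vernalize promptly (a hard zero above 18 °C would
  stall vernalization through any warm spell, and would contradict the
  near-immediate saturation expected of high-VAI material).

The prior (and grid) bounds are the expert ranges VAI ∈ [0, 0.01] day⁻¹
°C⁻¹, SLDL ∈ [0, 1] leaves h⁻¹, Phyl ∈ [80, 120] °Cd leaf⁻¹. Under
constant temperature and constant day length the whole model has a closed
form, which the test suite checks to 10⁻² days on a 3 × 3 × 3 parameter
grid (at the equator day length is exactly 12 h every day, which makes the
oracle exact).

Day length itself uses the standard agronomic declination formula
($\delta = 23.45^\circ \sin(2\pi(284 + doy)/365)$, day length
$(24/\pi)\arccos(-\tan\phi\tan\delta)$ with the argument clamped to
[−1, 1]). Which twilight convention the reference simulator uses is not
documented; this sunrise-to-sunset definition is therefore a documented
choice, not an inference, and only day-length *contrasts* between
candidate environments matter to the criterion.

## The design criterion

The criterion asks: if two a-priori parameter vectors are far apart, does
the candidate design produce outputs far enough apart to tell them apart
at noise level $\sigma_e$? With likelihood matrix

$$L^d_{uv} = (4\pi\sigma_e^2)^{-n_y/2}
\exp\!\left(-\frac{(\Delta^d_{uv})'\Delta^d_{uv}}{4\sigma_e^2}\right),$$

weights $W_{uv} = L_{uv}/\sum_u L_{uv}$ and the range-normalized distance,
the score $\sum_{u,v} \mathrm{dist}(\theta_u,\theta_v) W_{uv}$ is the
expected distance between parameter vectors that the design *confuses*.
Two limits anchor the intuition, and the tests: as $\sigma_e^2 \to
\infty$ the weights flatten to $1/m$ and the score tends to the mean
pairwise grid distance (the design carries no information); as
$\sigma_e^2 \to 0$ on a design whose outputs separate all grid rows, the
score tends to 0.

Numerical choices:

* All likelihood algebra is done in log space with a per-column maximum
  shift before normalization. The raw $(4\pi\sigma^2)^{-n_y/2}
  e^{-\Delta'\Delta/4\sigma^2}$ underflows for realistic output gaps (tens
  of days at $\sigma_e = 2$), and a column that underflows to zero cannot
  be normalized — the matrix API refuses it with a pointer to the
  log-space path.
* The normalization index (rows vs columns of the symmetric $L$) does not
  affect the score because the distance matrix is symmetric; the package
  normalizes columns, and a property test confirms row-normalization
  yields the same value on random instances.
* K replications multiply $\Delta'\Delta$ by K and set $n_y = ZK$; the
  prefactor cancels in $W$, so only the exponent matters.
* The criterion's $\sigma_e^2$ defaults to 4 days² (matching the 2-day
  phenotyping error); it sets the contrast scale at which designs are
  ranked and is exposed as a parameter.
* The hot path (`optimet_criterion()`) is a fused C++ evaluation of the
  column-softmax average; an R matrix path (`likelihood_matrix()`,
  `weight_matrix()`, `optimet_value()`) produces the same numbers (tested
  to 10⁻⁹) and exists for inspection and teaching.

The a-priori grid discretizes each parameter interval into g = 10 regular
levels (m = 1000 vectors) by default. Any m × p matrix is accepted in its
place, so informative or correlated prior samples can be swapped in
without touching the criterion code.

## Design search and baseline samplers

The exchange search swaps one in-design environment (chosen uniformly)
for one out-of-design environment (uniformly) and accepts only strict
improvements — equal values reject, so the accepted-value trace is
strictly decreasing and the search cannot cycle. Defaults are 3000
iterations and 4 random restarts. On enumerable instances
(`exhaustive_search()`, capped at 10⁵ subsets, lexicographic tie-break)
the restarted exchange recovers the global optimum in at least 19 of 20
seeded runs of the acceptance suite's 12-candidate instance.

Baseline samplers mirror the comparison strategies a breeder would use:
uniform random subsets; composition-constrained subsets with a fixed
number of winter sowings (winter = sown September–December, spring =
January–May; configurable); and "reasoned" subsets in which every sowing
period (October; November/December; January/February; March/April) is
represented. A small named fixture (`expert_met_fixture()`) encodes the
classic expert design — a north-to-south latitude gradient of November
sowings plus a spring sowing at the southernmost site to expose
vernalization — with synthetic coordinates; the pipeline derives its
expert design from the candidate table by the same rationale (latitude
extremes and median for late-autumn sowings, southernmost spring sowing).
Whether a sampled design may repeat a site across sowing dates was left
open by the strategy descriptions; here (site, date) pairs are unique,
sites may recur across dates.

## Bayesian estimation

Priors are uniform on the expert bounds for each genetic parameter and
inverse-gamma (shape 4, scale 0.2, shape–scale parameterization: prior
mean 0.2/3 ≈ 0.067 days²) on the residual variance. The shape/scale
reading of that prior is a documented choice; the prior is weak relative
to any realistic data size, so the reading has no practical consequence.

The sampler is a block Metropolis-within-Gibbs: per sweep, each variety's
three coordinates are updated jointly by a Gaussian random-walk proposal
(varieties are conditionally independent given the variance, so all
proposals are evaluated in one vectorized crop-model call), then the
variance block. The variance update is a random walk on
$\log\sigma^2$ with Jacobian correction by default — positivity without
rejection waste — with a conjugate inverse-gamma Gibbs draw available
(`sigma_update = "gibbs"`); on a linearized toy (VAI and SLDL pinned,
constant temperature, so heading is affine in Phyl) the Gibbs chain is
checked against the analytic flat-prior/inverse-gamma marginal.

Proposal scales were not documented in the method description. They start
diagonal at 2.5% of each prior range and adapt during burn-in: each
variety's proposal covariance tracks the empirical covariance of its
recent draws (scaled 2.38²/p, Cholesky-factored, with a small diagonal
jitter), and a per-variety scalar multiplier targets a 20–40% acceptance
rate. The covariance adaptation matters because the posterior has ridge
directions (vernalization and photoperiod trade off against each other);
a spherical proposal tuned to the tightest direction mixes far too slowly
along the ridge. Adaptation freezes at the end of burn-in so the retained
chain is a valid Markov chain. Chains are seeded and bit-reproducible.

Point estimates are posterior modes: a Gaussian-kernel density
(Silverman's bandwidth, 512-point grid) over the retained draws,
restricted to the prior support, with the draws reflected at both bounds
before smoothing. The reflection corrects the kernel's boundary bias —
posteriors of bounded parameters often pile up near a bound, where an
uncorrected kernel mode is biased inward by a bandwidth-sized amount.
Defaults follow the 20,000-iteration, 1,000-burn-in protocol (19,000
retained draws); the mode estimator itself was unspecified and is a
documented choice.

## Synthetic data generators

**Weather.** Daily mean temperature per site and year is a seasonal
sinusoid — annual mean 13.5 − 0.25·(lat − 45) °C, amplitude 8 °C, coldest
day at day-of-year 20 — plus AR(1) noise (marginal sd 2.5 °C, lag-1
autocorrelation 0.7). These are plausible temperate values; the criterion
only consumes *contrasts* between environments, so the generator's job is
to produce a realistic spread of thermal and photoperiod regimes across a
43–50.5° latitude band, not to emulate any particular station. The
"average year" collapses ≥ 2 years into per-calendar-day means; Feb 29 is
dropped before averaging (index by month–day), the simplest gap-free
convention.

**Genotypes.** Inbred lines are 0/1 haplotypes generated along a genetic
map by a refresh chain: each allele is copied from the previous marker or
refreshed with the Haldane recombination fraction of `mosaic_depth` × the
inter-marker distance (default 8 accumulated meioses, the depth of a
founder mosaic after several generations). This yields LD that decays
with map distance — complete at 0 cM, mean r² < 0.05 beyond 50 cM — which
is what the association scan and G-BLUP need to be meaningfully tested.
The desk-scale genome default (7 chromosomes × 150 markers × 150 cM)
stands in for a dense SNP array.

**Trait architectures.** Each parameter receives 25 QTL with effects in a
geometric series (ratio 0.9, random signs), and per-line raw scores are
affinely rescaled so the population spans the central 90% of the prior
range. All QTL markers are then removed from the analysis matrix, so
detection must operate through linked markers. The geometric ratio,
random signs and rescale map were not fixed by the method description and
are exposed as arguments.

What passing tests on these generators do *not* show: real weather has
fronts, inter-annual trends and spatial correlation the sinusoid lacks;
real panels have population structure (the scan deliberately fits no
structure covariates) and non-geometric architectures; and real heading
scores have observer and plot effects beyond i.i.d. Gaussian noise. The
benchmark measures the design question under controlled conditions, not
field performance.

## Downstream genetics

Kinship is the VanRaden dosage estimator on 0/2-recoded inbred genotypes.
G-BLUP estimates the variance ratio by restricted-likelihood maximization
profiled to a one-dimensional search over λ = σ²ₑ/σ²_g on the spectral
decomposition of the training kinship (bracket 10⁻⁴–10⁴ on the log scale,
tolerance 10⁻⁶), then predicts test lines by the usual conditional mean;
tests verify it against a direct mixed-model-equation solve. The
association scan fits the variance components once under the null and
reuses them for every marker (the P3D scheme), reducing each marker test
to generalized least squares in whitened coordinates with a Wald
chi-square p-value; constant markers return p = 1 with a flag. A QTL
counts as detected when a same-chromosome marker within 1 cM is
significant at 0.05/25.

## The benchmark pipeline

`run_pipeline()` chains the whole comparison: weather → average year →
candidate environments → genotypes → QTL → calibration/validation split →
design selection (criterion-optimal, expert-style, random) → per
experiment year: phenotype simulation, MCMC, NRMSE against simulated
truth, detection power from scans of the estimates, G-BLUP prediction of
validation-line parameters, and heading-time prediction in held-out
validation environments by running the predicted parameters back through
the crop model. Everything derives from one seed; identical config + seed
gives identical reports. Stage timings are logged and artifacts (weather,
genotypes, designs, estimates, report) are written under the run
directory when requested.

Default configuration values follow the protocol where it states them
(Z = 4, K = 1, 2-day noise, g = 10 grid, 3000 exchange iterations with 4
restarts, 20,000 MCMC iterations with 1,000 burn-in, detection threshold
0.05/25 within 1 cM) and desk-scale sizes elsewhere (10 sites, 3
experiment years, 60 calibration + 120 validation lines, 7 × 150-marker
genome). The test suite and the acceptance script run deliberately
smaller instances — 5³–6³ grids for design search inside tests, 20–40
varieties, 2,500-sweep chains in the replicated design comparison —
chosen so the whole suite exercises every claim at meaningful power while
remaining a routine desk run; the full protocol sizes remain reachable
through the configuration.

## Known limitations

* **VAI is the weakly identified parameter.** Vernalization rate reaches
  heading only through saturation timing, and the delay's sensitivity to
  VAI decays as $1/(VBEE + VAI\,T)^2$: over the upper half of the prior
  range a 0.001 change in VAI moves heading by only ~0.3–0.5 days against
  2-day noise, so per-line posteriors there stay wide under any Z = 4
  design. The acceptance suite documents this honestly: SLDL and Phyl
  recover within 15% of their ranges under the protocol conditions, VAI
  does not always, though halving the observation noise improves every
  parameter and the criterion-optimal design consistently beats random
  designs on the across-parameter mean.
* The criterion ranks designs of a given size; it does not estimate the
  absolute precision a design will deliver, and optimizing Z itself is
  out of scope.
* The average-year proxy assumes next season resembles the multi-year
  mean; erratic covariates (rainfall-driven models) would need a weather
  generator and a multi-year criterion instead.
* Degenerate inputs are refused loudly rather than patched: environments
  whose horizon is exhausted raise a phase-carrying "no-heading" error,
  underflowing likelihood columns point to the log-space path,
  monomorphic-only genotype matrices and constant phenotype vectors are
  errors, and unsatisfiable design constraints name the empty class.
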