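# optimet

Optimal multi-environment trial (MET) design for estimating the genetic
parameters of a crop phenology model.

## The problem

Crop growth models predict genotype × environment interaction by separating
what belongs to the variety (genetic parameters, stable across
environments) from what belongs to the environment (daily temperature and
day length). For wheat heading date, three genetic parameters drive the
three-phase development from sowing to heading: the response of
vernalization rate to temperature (**VAI**, day⁻¹ °C⁻¹), the day-length
response of leaf production (**SLDL**, leaves h⁻¹), and the phyllochron
(**Phyl**, °Cd leaf⁻¹). Once these parameters are estimated for a panel of
varieties, their QTL can be mapped, genomic prediction models calibrated,
and heading predicted in any new environment by running the model forward.

The quality of all of this rests on the parameter estimates, which in turn
rest on *which* field environments — location × sowing date combinations —
the varieties were phenotyped in. This package answers the design
question: out of J candidate environments, which subset of Z should be
grown?

## The criterion

Before any data exist, the only handles are the crop model f, historical
weather (collapsed into an "average year" of per-calendar-day mean
temperatures), and prior bounds on the parameters. Discretizing each
parameter interval into g regularly spaced values gives m = g^p a-priori
parameter vectors θ₁…θ_m (g = 10, m = 1000 by default). For a design d
with n_y = Z·K observations per variety, each pair (u, v) gets the
likelihood of θ_u given noise-free data generated by θ_v:

```
L_uv = (4πσ_e²)^(−n_y/2) · exp( −Δ'_uv Δ_uv / (4σ_e²) ),
Δ_uv = ( f(θ_u, E_j) − f(θ_v, E_j) ),  j ∈ d
```

normalized into a column-stochastic weight matrix W_uv = L_uv / Σ_u L_uv,
and the criterion is the weight-averaged normalized parameter distance

```
score(d) = Σ_{u,v} dist(θ_u, θ_v) · W_uv ,
dist(θ_u, θ_v) = sqrt( Σ_s ((θ_us − θ_vs) / (M_s − m_s))² ).
```

Small values are good: a design whose outputs separate distant parameter
vectors concentrates the weights on the diagonal, where distances vanish.
The minimizing subset is found by a greedy exchange search (random swaps
of one in-design environment for one outside, accepted when the score
strictly decreases; several random restarts).

The package also contains everything needed to benchmark the approach by
simulation: a compact three-phase phenology simulator (Rcpp), a synthetic
weather generator, LD-structured inbred genotypes with geometric-series
QTL architectures, a Metropolis-within-Gibbs sampler for per-variety
parameter estimation from heading dates, VanRaden kinship, G-BLUP genomic
prediction, a P3D mixed-model association scan, and the error metrics
(NRMSE, NRMSE*, NPSE, detection power, prediction accuracy).

## Worked example

```r
library(optimet)

# a candidate network: 6 sites on a latitude gradient, 4 sowing dates
sites      <- sites_table(sprintf("s%02d", 1:6), seq(44, 50, length.out = 6))
weather    <- generate_synthetic_weather(sites, years = 2008:2016, seed = 42)
sowings    <- as.Date(c("2015-09-15", "2015-10-15", "2015-11-15", "2015-03-15"))
candidates <- build_environments(sites, sowings, weather)   # 24 environments

# score designs against the m = 1000 a-priori parameter grid
outputs <- candidate_outputs(build_grid(default_bounds(), g = 10), candidates)
search  <- exchange_search(nrow(candidates), Z = 4,
                           optimet_criterion(outputs, sigma2_e = 4),
                           n_iter = 3000, n_restarts = 4, seed = 1)
search
#> <exchange_result> value = 207.303; Z = 4; indices: 9, 12, 20, 23
candidates$env_id[search$design$indices]
#> [1] "s03_2015-09-15" "s03_2015-03-15" "s05_2015-03-15" "s06_2015-11-15"
```

The optimizer picks two autumn sowings plus two spring sowings at
contrasting latitudes — the combinations that decorrelate vernalization,
photoperiod and leaf-rate effects. Phenotype a panel there and estimate
its parameters:

```r
set.seed(7)
varieties <- tibble::tibble(genotype_id = sprintf("v%02d", 1:12),
                            VAI  = runif(12, 0.001, 0.009),
                            SLDL = runif(12, 0.1, 0.9),
                            Phyl = runif(12, 85, 115))
trial  <- candidates[search$design$indices, ]
phenos <- simulate_phenotypes(varieties, trial, K = 1, noise_sd = 2, seed = 2)

chains <- run_mcmc(phenos, trial, n_iter = 8000, burn_in = 1000, seed = 3)
glance(chains)
#>   n_iter n_retained n_varieties mean_theta_acceptance sigma_acceptance
#> 1   8000       7000          12                 0.321            0.354

estimates <- posterior_estimates(chains)   # posterior modes per variety
nrmse(estimates, varieties)
#>   parameter  nrmse
#> 1 VAI       0.0856
#> 2 SLDL      0.0685
#> 3 Phyl      0.0884
```

The NRMSE values are root-mean-square estimation errors normalized by each
parameter's prior range: the four optimized environments recover all three
parameters to within about 7–9% of their ranges from a single noisy
observation per environment.

`run_pipeline(optimet_config(...))` chains the full benchmark — QTL
simulation, design selection, phenotyping, MCMC, QTL detection, G-BLUP
prediction of held-out varieties, and heading-time prediction in
independent environments — and returns a long metric table with `tidy()`,
`glance()` and `autoplot()` methods. A command-line wrapper for scoring,
optimizing and the pipeline lives in `inst/cli/optimet.R`.

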