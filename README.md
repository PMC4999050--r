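# macrocomp

Does biotic competition put an upper limit on species richness in deep time —
and if so, in what mode? `macrocomp` is an R package for asking that question
of a fossil richness time series. It discretises species durations into equal
time bins, fits a hierarchy of discrete-time competition models to the
one-step richness transitions by nonlinear least squares, and compares the
models with AICc weights, grouped support and model averaging across a sweep
of bin lengths. It is aimed at palaeobiologists and macroevolution researchers
working with clades whose fossil record is complete enough to count standing
species richness through time (the motivating case is Cenozoic macroperforate
planktonic foraminifera), together with environmental driver series such as a
deep-ocean temperature reconstruction and macrostratigraphic sediment-package
counts.

## The models

Writing `x_t` for species richness at the start of a bin and `x_{t+1}` at its
end, the three biotic functional forms are

| Mode | Map | Behaviour |
|---|---|---|
| Scramble (Ricker) | `x_{t+1} = x_t exp(r (1 − x_t/K))` | overcompensatory: overshoot-and-crash about `K` |
| Contest (Beverton–Holt) | `x_{t+1} = k1 x_t / (1 + k2 x_t)` | compensatory: non-decreasing approach to a finite limit |
| Damped increase (Hassell) | `x_{t+1} = k1 x_t / (1 + k2 x_t)^c` | `c = 1` recovers contest; `0 < c < 1` slows growth without the contest bound; `c > 1` is scramble-like |

Abiotic "no competition" nulls take the form `x_{t+1} = x_t (r + wT)(aP^b)`,
with terms present as drivers allow. Environmental dynamics enter the biotic
forms linearly through the rate (`r + wT + vO`, with `T` mean-centred
temperature and `O` the rate of sediment-package origination) and through the
limit via a species–area form (`K → aP^b`, with `P` the package count;
optionally `× exp(gT)`). Crossing 3 forms × 4 rate-driver × 4 limit-driver
combinations plus 4 nulls gives the 52-model global set. Fitting regresses the
observed richness at the end of each bin on the mapped richness at its start
(Levenberg–Marquardt, seeded Latin-hypercube multi-starts); `AICc = n ln(RSS/n)
+ 2k + 2k(k+1)/(n−k−1)` scores each model, and Akaike weights
`w_i ∝ exp(−Δ_i/2)` feed grouped support and model-averaged predictions.

A synthetic-data module simulates all three inputs — richness trajectories
under any model in the hierarchy, mean-reverting temperature anomalies, and
package count/origination series — plus species-duration tables from a
diversity-dependent birth–death process, so the entire pipeline runs and is
tested without any external data.

## Worked example

```r
library(macrocomp)

# a 65-Myr clade limited at ~40 species, and its environment
durations <- simulate_durations(seed = 42, base_speciation_rate = 0.35,
                                base_extinction_rate = 0.2, limit = 40, span = 65)
env <- simulate_environment(simulation_config(n_steps = 650, step_length = 0.1,
                                              seed = 43))

# discretise into 1-Myr bins and fit one model
binned <- bin_all(durations, env, bin_length = 1, oldest_age = 65)
fit <- fit_model(model_spec("contest"), binned)
fit
#> <fit_result> contest rss = 214.6, n = 65, k = 3, converged = TRUE
#>              k1     k2
#> estimate 1.0675 0.0062
#> se       0.0824 0.0058

round(implied_limits(fit$estimates), 2)
#>         ratio   fixed_point k2_from_ratio
#>        173.14         10.95          0.01
```

The contest fit says richness grows by a factor `k1 = 1.07` per Myr at low
diversity, damped by crowding at `k2 = 0.0062` per species; the map's fixed
point `(k1−1)/k2 = 10.95` is the equilibrium richness it implies, while
`k1/k2` is the same density coefficient re-expressed under the ratio
convention for a quoted limit.

Comparing the full model set across bin lengths:

```r
sw <- sweep_bin_lengths(durations, env, lengths = c(0.5, 1, 2),
                        model_set = build_model_set(), seed = 1,
                        options = fit_options(n_starts = 8), oldest_age = 65)
sw
#> <sweep_result> 3 bin lengths, 52 models
#> mean support by form:
#>        scramble         contest damped_increase         abiotic
#>          0.5334          0.3459          0.0957          0.0250
#> mean support by response:
#>    neither       rate      limit rate+limit    abiotic
#>     0.0089     0.0340     0.2374     0.6947     0.0250
#> median c = 5.000 (median upper 95% limit 3.931)

av <- sw$per_length[["1"]]$averaged
squared_correlation(av$observed, av$fitted)
#> 0.911
```

Here the biotic forms carry 97.5% of the mean Akaike weight, models in which
both the diversification rate and the upper limit respond to the environment
dominate (69%), and the model-averaged one-step predictions explain 91% of the
observed variation in 1-Myr bins. The competition coefficient summary comes
from the best-weighted damped-increase model per bin length.

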