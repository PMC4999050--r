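---
title: "Modes of macroevolutionary competition: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modes of macroevolutionary competition: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrocomp)
```

## The question and the approach

Diversity-dependent signatures — diversification slowing as standing richness
rises — are compatible with very different mechanisms: a hard ecological
ceiling filled by niche incumbency (contest competition), overshoot-and-crash
dynamics in which a rising clade destabilises its own niches (scramble
competition), or an unbounded slowdown in which diversity damps, but never
halts, further diversification. `macrocomp` distinguishes these modes
statistically. Richness is discretised into equal time bins and each candidate
one-step map is fitted to the transitions `x_t -> x_{t+1}` by least squares;
AICc weights then quantify the relative support for each map, for groups of
maps sharing a property (functional form; which environmental variables leave
a signature; whether rate and/or limit responds), and for model-averaged
predictions.

The whole analysis is repeated across bin lengths (0.5–2.0 Myr by 0.1 by
default) because no single bin length is privileged when discretising the
continuous processes of diversification, climate change and sedimentation.
Per-length analyses are fully independent — nothing is shared across lengths
except the data — and across-length summaries are unweighted arithmetic means
of the per-length group supports (and medians for the competition
coefficient). Model- and time-averaged fitted values treat each bin equally.

## Functional forms

The three biotic maps and the abiotic nulls are described in `?model_spec`.
Three structural conventions deserve explanation because the field's notation
underdetermines them:

* **Dynamic-limit parameterisation.** In the contest and damped forms the
  dynamic limit replaces the *density coefficient*: the denominator becomes
  `(1 + (a P^b) x_t)^c`, i.e. `a P^b` plays the role of `k2`, while in the
  scramble form `a P^b` replaces `K` directly. This is the literal reading of
  the model hierarchy's table of forms; an alternative reading ("`a N^b` is a
  saturating limit") would put `k1/(a P^b)` in the `K` position. Because both
  conventions appear in practice, `implied_limits()` reports both the ratio
  `k1/k2` and the map's true fixed point `(k1 − 1)/k2`, and asserts neither as
  *the* limit.
* **Temperature in the limit.** A power law `a T^b` is undefined for
  mean-centred (negative) temperature anomalies, so temperature enters the
  limit multiplicatively as `exp(g T)`: always positive, and reducing exactly
  to the `a P^b` form at `g = 0`. When temperature is the *only* limit driver
  the limit is `a exp(g T)`; a residual `reference^b` factor with a free `b`
  would be unidentifiable (any reference scale is absorbed by `a`), so `b` is
  only free when `P` drives the limit.
* **The abiotic null set.** Four nulls — `x_t r`, `x_t (r + wT)`,
  `x_t (a P^b)`, `x_t (r + wT)(a P^b)` — complete the hierarchy. Diversity
  enters only as the multiplier `x_t`, never inside a competition term, so
  these models carry environmental signal without biotic regulation.

One symbol note: sources describing this hierarchy use `a` both for the
temperature coefficient on the rate and for the limit scale. Here the rate
coefficient is `w` everywhere and `a` is reserved for the limit scale.

## Binning conventions

* **Richness is standing richness at bin edges** (instantaneous counts), not
  a within-bin total: the maps are one-step relations between states, so
  `x_t` and `x_{t+1}` must be the same kind of quantity. Membership is
  origination-inclusive and extinction-exclusive in age coordinates
  (`extinction_age < t <= origin_age`); survivors to the present are flagged
  `extant` rather than encoded with a sentinel age.
* **Bins are half-open** `[older, younger)` in age and anchored so every
  series ends at 0 Ma; the partial remainder older than the last full bin is
  discarded.
* **Drivers per bin**: mean temperature (re-centred so the binned series has
  mean zero), mean package count rounded half-up to an integer, and summed
  package originations (an origination belongs to the bin its age falls in,
  whether or not the package persists — so refining the bin length partitions
  originations exactly). A bin with no environmental samples is an error, not
  an interpolation: silently inventing driver values would fabricate data.
* Whether within-bin temperature should be averaged or point-sampled is
  genuinely open; averaging is used because it is the sufficient summary
  under the additive-noise model.

## Fitting and selection

Least squares is the estimator throughout, which implicitly assumes additive
Gaussian observation noise on richness with constant variance; the synthetic
generator uses exactly that noise model (truncated at zero) so that simulated
and assumed error models agree. Each model is minimised by
Levenberg–Marquardt (`minpack.lm::nls.lm`) restarted from a seeded Latin
hypercube of 25 starting points (default) within box bounds, plus one
data-informed start (growth factor 1.5, limit at the observed maximum). The
bounds keep the maps finite rather than encode prior knowledge: rates in
(−10, 10); `K`, `a` in (1e−6, 10 × max observed richness); `b` in (−2, 2);
`c` in (1e−3, 5); `w`, `v`, `g` in (−10, 10); `k2` in (1e−8, 10). The best
converged start wins (ties in RSS resolved by first occurrence in start
order, which is deterministic given the seed); a model for which no start
converges is retained with an infinite-RSS sentinel and therefore zero Akaike
weight, keeping every weight denominator well defined. Standard errors are
Wald, from the Gauss–Newton covariance `sigma^2 (J'J)^{-1}` at the optimum.

AICc uses the Gaussian least-squares form with `k` counting the residual
variance as a parameter; it is undefined for `n <= k + 1` and for a zero RSS,
both of which raise errors rather than returning sentinels. The upper
confidence limit on the competition coefficient is a one-sided Wald limit
`c + z_level SE(c)` — matching the standard output of `nls`-type toolchains;
a profile-likelihood limit would be the natural alternative but is not what
those toolchains report. In the sweep, the per-length `c` summary comes from
the damped-increase model with the largest Akaike weight at that length.

Within a sweep, the multi-start RNG is seeded per (bin length, model) from
the master seed, keyed on the length *value* so that per-length results do
not depend on the order lengths are requested in, and the whole `SweepResult`
is reproducible from one integer.

## What the synthetic data emulate — and what they do not

`simulate_environment()` produces a mean-reverting Gaussian walk plus an
optional slow cosine trend (default amplitude 4 °C across the span, reversion
0.2 per step, innovation sd 0.5 °C), mean-centred — matching the use of
mean-centred temperature anomalies without asserting any climate model.
Package counts are Poisson (negative binomial if over-dispersion is
requested) around a constant mean of 20, and originations Poisson with mean 1
per bin: the observable series' statistical texture, not a sedimentation
model. `simulate_durations()` is a continuous-time birth–death process with a
linear diversity-dependence on speciation only (`lambda (1 − N/limit)`) —
the simplest mechanism that yields a bounded clade. Default study conditions,
chosen once: a 65-Myr span, limit 40 species, speciation 0.35 and extinction
0.2 per lineage per Myr.

These generators deliberately do **not** reproduce: phylogenetic topology or
trait structure; preservation and sampling failure (every simulated lineage
is perfectly observed); autocorrelated or state-dependent observation error;
abrupt climate excursions; or any causal coupling between the temperature,
package and richness series (they are independent unless a driver-dependent
model generates the richness). Passing tests therefore show that the pipeline
recovers truth *under its own assumptions* — unbiased binning, correct map
algebra, well-behaved least squares, calibrated model selection — not that
those assumptions hold for any real fossil record.

Two calibration facts worth knowing when interpreting selection results. The
damped-increase map nests contest at `c = 1`, so on contest-generated data
the damped model fits at least as well and overtakes contest's AICc whenever
its RSS gain exceeds the one-parameter penalty — which happens with the usual
~15% probability of a chi-square exceedance even when contest is true.
Contest therefore wins the form comparison in most, not all, replicates, and
the test suite checks exactly that (at least 80 of 100 seeds on 120-transition
series with noise sd 0.5, the package's definition of a low-noise power
condition). Conversely, on data generated under a temperature-driven abiotic
null, the bounded biotic group must *not* accrue dominant support; this
guards against the structural bias that bounded forms, having more shape
flexibility, could soak up weight everywhere.

The damped-increase map itself deserves a caveat: for any `k1 > 1` and
`c > 0` it has a finite fixed point `(k1^{1/c} − 1)/k2`. "Unbounded" is
therefore a statement about the regime relative to the contest bound — the
trajectory rises monotonically straight past `k1/k2` toward a fixed point
that grows without bound as `c` shrinks — not about literal divergence at any
fixed `c`.

## Problem sizes

The test suite and the acceptance script use series of 60–130 transitions,
100-seed replications for parameter-recovery and power checks, 50 seeds for
the abiotic guard, a 200 × 200 grid as the exhaustive-search oracle for the
two-parameter fits, and the full 52-model set over 16 bin lengths for the
end-to-end sweep — sizes at which every property being tested is already
stable under reseeding.

## Known limitations

* Transitions are treated as independent observations; residual
  autocorrelation is checked post hoc (`residual_autocorrelation()`) rather
  than modelled (no generalised least squares).
* Wald intervals can be poor near parameter bounds (a `c` estimate at its
  bound makes its upper limit untrustworthy; the sweep reports it anyway and
  leaves judgement to the analyst).
* Model weights are conditional on the candidate set: a 52-model set with
  many near-equivalent members dilutes individual weights, which is why
  grouped supports are the primary summary.
* The equal-bin discretisation assumes the duration table's age calibration
  is exact; dating uncertainty is outside the model.
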