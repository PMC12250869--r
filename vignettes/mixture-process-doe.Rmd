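---
title: "Mixture-process designed experiments for SLN formulation: models, desirability, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-process designed experiments for SLN formulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnopt)
```

## The problem and the factor space

Solid lipid nanoparticles are submicron particles with a solid lipid core
stabilized by surfactants. Early-stage formulation screens judge a candidate
by three attributes measured by dynamic light scattering and electrophoretic
mobility: particle size (PS, z-average, nm), polydispersity index (PDI,
unitless) and zeta potential (ZP, mV). A good blank formulation here targets a
size near 100 nm, the narrowest achievable size distribution, and the largest
achievable |ZP| (measured values are negative; the package stores and models
the magnitude and re-attaches the sign for display).

Five factors drive these attributes in the packaged study:

| factor | meaning | domain |
|---|---|---|
| `p80_pct` (x₁) | % polysorbate 80 in the P80/sorbitan-oleate couple | 0–100 % |
| `us_time_min` (x₂) | ultrasound time | 1–10 min |
| `cw` (x₃) | carnauba wax proportion in the lipid blend | 0–1 |
| `gb` (x₄) | glyceryl behenate proportion | 0–1 |
| `gds` (x₅) | glyceryl distearate proportion | 0–1 |

The first two are ordinary (process) factors on intervals; the last three are
mixture factors constrained to the simplex x₃+x₄+x₅ = 1. That constraint is
why no off-the-shelf factorial design applies and why the model below has no
intercept.

## Design

`simplex_centroid()` gives the seven classical blends (3 vertices, 3 binary
midpoints, the ternary centroid); `process_grid()` builds a factorial grid
over the process factors; `cross_design()` runs every blend at every setting.
With the 3×3 process grid `{0, 50, 100} × {1, 5, 10}` this is the 63-run
crossed design of the packaged study.

`d_optimal_exchange()` selects an `n`-run subset of any candidate set by a
Fedorov-style exchange: from a seeded random full-rank start, repeatedly
replace an in-design point by a candidate whenever the swap increases
det(XᵀX), taking the first improving swap in candidate order and comparing
log-determinants with a relative threshold of 1e-10 to avoid float-noise
cycling. Greedy exchange can stall in local optima, so the function runs five
seeded restarts and keeps the best design; this is what lets the small-instance
tests demand equality with exhaustive subset enumeration. On the 63-candidate
crossed set with `n_runs = 63` the exchange necessarily returns the full
cross — consistent with the packaged study being both "selected by exchange"
and visibly the complete 7×9 cross.

## The response model

Each response is fitted by OLS to the 28-term multiplicative model: the
reduced cubic Scheffé polynomial in the raw blend proportions

y = β₃x₃ + β₄x₄ + β₅x₅ + β₃₄x₃x₄ + β₃₅x₃x₅ + β₄₅x₄x₅ + β₃₄₅x₃x₄x₅

crossed with the full quadratic in the coded process factors and truncated at
degree-3 coefficients: the 7 Scheffé terms, the 6 quadratic blend monomials
each multiplied by x₁ and by x₂, and the 3 linear blend terms each multiplied
by x₁², x₂² and x₁x₂. Process factors are affinely coded to [−1, 1]
(`code_process()`: midpoint → 0, endpoints → ±1); mixture proportions enter
raw, the Scheffé convention. Predictions are invariant to the coding choice —
the tests verify this by refitting under a [0, 1] coding — so the coding is a
numerical convenience, not a modelling assumption.

Because the mixture terms absorb the intercept (any constant c equals
c·(x₃+x₄+x₅) on the simplex), the ANOVA uses the mean-corrected convention:
SST is taken about the response mean and the regression degrees of freedom are
p − 1 = 27. This is the convention under which R² of a no-intercept Scheffé
model stays in [0, 1] and matches the published fit statistics. The
whole-regression p-value is reported as a probability in [0, 1]; reports that
print "p (%)" are the same number times 100.

### 63 or 66 rows?

The packaged study has 66 rows: the 63-run design plus repeats of runs 51, 52
and 55 (ids `51r`, `52r`, `55r`). The repeats exist to estimate pure
experimental error — `replicate_variance()` pools them as
s² = Σ(Δ²/2)/n_pairs, giving 208.5 nm² on 3 degrees of freedom for PS — and
the default replication workflow fits the 63 design runs only
(`design_runs()`). This choice is empirical: the 63-run fit reproduces the
published R² triple (0.80, 0.67, 0.98) and the published predictions at the
optimum (102 nm, 0.30, −34.8 mV) to print precision, while the 66-row fit
gives 0.79/0.67/0.97 and 104.8 nm. Fitting all 66 rows remains fully
supported (`fit_response()` fits whatever it is given) and is exercised by the
tests (df_resid = 66 − 28 = 38).

Run `51r` is worth a note: its |ZP| (21.67 mV) is far from its twin (35.87
mV). The fixture keeps the value verbatim; nothing in the package down-weights
it.

## Desirability

Each response maps onto [0, 1] by a piecewise-linear Derringer–Suich ramp
with exponent 1:

- PS: bilateral, 0 at ≤50 and ≥200 nm, 1 at the 100 nm target, linear between;
- PDI: smaller-is-better, 1 at 0, 0 at ≥0.4;
- |ZP|: larger-is-better, 0 at ≤25 mV, 1 at ≥40 mV (no penalty for exceeding
  the target on the favorable side).

The original study shows these shapes only as thumbnails; linear ramps with
exponent 1 are the simplest form consistent with its min/target/max triples
and unit weights, and that is what the package adopts (weights act only in the
aggregation). Global desirability is the weighted geometric mean
D = (∏dᵢ^wᵢ)^(1/Σwᵢ): it is 0 whenever any response is unacceptable,
bounded by min(dᵢ) and max(dᵢ), and invariant to uniform weight rescaling —
all property-tested.

`optimize_desirability()` maximizes D by a dense scan — barycentric simplex
grid at step `grid_step` (default 0.01, i.e. 5151 blends) crossed with the
process box at the same relative step (101 levels per axis) — followed by
projected coordinate descent from the top 10 grid cells (the best cell exact,
the others jittered within half a cell under the given seed), with step
halving down to 1e-4. The scan exploits the model's structure: grouping terms
by their (x₁, x₂) exponents turns the 52.5-million-point evaluation into a
handful of matrix products, so the default resolution runs in seconds. The
refined result is never below the best grid point (asserted in tests), and an
all-zero landscape returns a result flagged `feasible = FALSE` rather than an
error.

### Where the optimum lands, and the 35–45% band

With these ramps and the 63-run fits the global argmax is at ~34.4% P80,
10 min ultrasound, blend ≈ (0.66, 0.34, 0), D ≈ 0.573. The published
high-desirability band — "P80 between 35 and 45%, ultrasound above 6 min" — is
a visual reading of a desirability *slice* at the blend (0.59, 0.22, 0.19),
where this package's surface indeed peaks near 35% P80 (at 7.5 min). The
ridge is extremely flat: D changes by under 0.001 between 33% and 36% P80.
The band-edge acceptance assertion (argmax ≥ 35%) therefore fails by ~0.6
percentage points in this implementation and is deliberately left failing:
the original software's internal ramp exponents and optimizer are unpublished,
and nudging ramps or grids until the argmax crosses 35% would be fitting the
answer, not the model. Every prediction-level check at the published optimum
passes.

## Surfaces

`ternary_slice()` evaluates a fit (or the desirability surface) on a
barycentric grid at a fixed process setting; `process_slice()` evaluates on a
P80 × time grid at a fixed blend. Both are pure functions of their arguments
(repeated calls are identical, shared points across resolutions agree to
1e-12) and export to long-form CSV. Plot methods render them with base
graphics, but all acceptance-level checks target the numeric grids, never
images.

## The simulator, and what a green test establishes

`simulate_responses()` generates responses as Xβ + N(0, σ²) for any design
and coefficient set, deterministically under a seed. Its role is inferential
plumbing: exact recovery at σ = 0, error scaling as σ shrinks, and
unbiasedness of the OLS coefficients at the experimental noise level
(σ = 14.4 nm for PS, the pooled replicate standard deviation) are all tested
against it. What it does **not** emulate: heteroscedastic measurement error
(DLS error grows with size), instrument-level outliers (run `51r`), or any
lack of fit of the 28-term polynomial itself. A green simulation test
establishes that the estimator is correct for the stated model, not that the
model is true.

## Numerical choices

- OLS by QR decomposition, not normal equations; rank failures name the
  collinear terms. The normal-equations solve appears only as an independent
  test oracle.
- Mixture sum tolerance 1e-9 on input validation; the packaged centroid is
  stored as 1/3 to 15 digits (the printed 0.33 is a rounding).
- Exchange determinant comparisons in log space, relative threshold 1e-10.
- Desirability refinement tolerance 1e-4 relative; improvement threshold
  1e-15 to keep accept/reject decisions strict.
- Seeds: every stochastic routine (`simulate_responses()`,
  `d_optimal_exchange()` starts, optimizer jitter) takes an explicit seed and
  restores the caller's RNG state.

## Limitations

- Only the three-component simplex and two process factors of this study are
  wired into the condition schema; constrained (pseudo-component) mixture
  regions, split-plot structures, and A-/I-optimality are out of scope.
- The exchange algorithm guarantees monotone improvement, not global
  D-optimality; restarts make small instances exact in practice but carry no
  proof.
- No lack-of-fit decomposition beyond pooled pure error, no stepwise term
  selection, and no uncertainty propagation onto the desirability surface.
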