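# slnopt

Mixture-process designed experiments for solid lipid nanoparticle (SLN)
formulation development.

Formulating SLNs means choosing a lipid blend and process settings so that
three colloidal quality attributes land where you want them: particle size
(PS, z-average in nm), polydispersity index (PDI) and zeta potential (ZP, mV —
more negative means more colloidal stability). `slnopt` implements the full
statistical workflow for doing this with a *crossed mixture-process design*:

- **Design construction** — the 7-point simplex-centroid design over the lipid
  blend (carnauba wax CW, glyceryl behenate GB, glyceryl distearate GDS,
  proportions summing to 1) crossed with a factorial grid over two process
  factors: the percentage of polysorbate 80 in the P80/sorbitan-oleate
  surfactant couple (0–100%) and ultrasound time (1–10 min). Subsets can be
  selected by a Fedorov-style exchange algorithm maximizing the D-optimality
  criterion det(XᵀX).
- **Response modelling** — ordinary least squares on the 28-term
  multiplicative model: the reduced cubic Scheffé polynomial in the blend
  proportions (x₃, x₄, x₅),

  y = β₃x₃ + β₄x₄ + β₅x₅ + β₃₄x₃x₄ + β₃₅x₃x₅ + β₄₅x₄x₅ + β₃₄₅x₃x₄x₅ + …,

  crossed with the quadratic in the coded process factors (x₁, x₂), truncated
  at degree-3 coefficients. There is no intercept and no pure process term:
  both are absorbed by the mixture constraint x₃+x₄+x₅ = 1. ANOVA reports R²,
  the regression F statistic and its p-value; repeated runs give a pooled
  pure-error variance.
- **Multi-response optimization** — Derringer–Suich desirability: each
  predicted response is mapped onto [0, 1] by a piecewise-linear ramp
  (bilateral for PS with target 100 nm inside [50, 200]; smaller-is-better for
  PDI with cutoff 0.4; larger-is-better for |ZP| from 25 to 40 mV), and the
  global desirability D = (∏ dᵢ^wᵢ)^(1/Σwᵢ) is maximized over the simplex ×
  process box by a dense grid scan plus seeded local refinement.
- **Isoresponse surfaces** — ternary slices (fixed process setting) and
  process-plane slices (fixed blend) of any fit or of the desirability
  surface, as numeric grids with CSV export and base-graphics plots.

A complete 66-run SLN study (63 design runs + 3 repeats) ships with the
package, and a seeded simulator generates responses from known coefficients so
the whole pipeline is testable offline.

## Worked example

```r
library(slnopt)

study <- sln_runs()          # 66 rows: run_id, factors, ps_nm, pdi, zp_abs_mv
design <- design_runs(study) # the 63 design runs (repeats estimate pure error)

spec <- model_spec("multiplicative_deg3")
fits <- lapply(c(ps_nm = "ps_nm", pdi = "pdi", zp_abs_mv = "zp_abs_mv"),
               function(r) fit_response(design, spec, r))
fits$ps_nm
#> <sln_fit: ps_nm ~ multiplicative_deg3 (28 terms), n = 63>
#>   R2 = 0.7972  F(27, 35) = 5.097  p = 5.45e-06

sapply(fits, function(f) round(f$r2, 2))
#>     ps_nm       pdi zp_abs_mv
#>      0.80      0.67      0.98

# predictions at a candidate optimum (41% P80, 7.5 min, CW-rich blend)
at <- data.frame(p80_pct = 40.8, us_time_min = 7.5, cw = 0.59, gb = 0.22, gds = 0.19)
sapply(fits, predict, newdata = at)
#>       ps_nm         pdi   zp_abs_mv
#> 102.4482009   0.3047726  34.8083887

replicate_variance(study, "ps_nm")
#> $pooled_variance
#> [1] 208.5178      # nm^2 pure-error variance from the three repeated runs
#> $df
#> [1] 3

opt <- optimize_desirability(fits, sln_desirability_specs(), seed = 1,
                             grid_step = 0.01)
opt
#> <sln_optimum: D = 0.5734>
#>   p80 = 34.44%  us = 10.00 min  blend = (0.663, 0.337, 0.000)
#>   ps_nm      predicted 115  d = 0.850
#>   pdi        predicted 0.288  d = 0.280
#>   zp_abs_mv  predicted 36.89  d = 0.793
```

Read: the fitted models explain 80% / 67% / 98% of the variance in PS / PDI /
|ZP|. At the 40.8% P80, 7.5 min, (0.59, 0.22, 0.19) condition the models
predict a 102 nm particle, PDI 0.30 and ZP −34.8 mV. The unconstrained
desirability maximum (D = 0.57) sits at ~34% P80 and maximal ultrasound time
with a CW/GB binary blend — the desirability ridge in P80 is very flat between
roughly 30% and 40% (see the methods vignette for why the reported band edge
of 35% is soft).

There is also a command-line interface (`inst/cli/slnopt`) with subcommands
`design`, `fit`, `predict`, `optimize`, `surface` and `simulate`, driven by a
YAML config; see `?sln_cli`.

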