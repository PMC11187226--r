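# splicekin

Quantitative analysis of small-molecule inhibition of group II intron
self-splicing, for RNA biochemists and RNA-targeted drug-discovery
groups who quantify splicing assays, binding experiments and alchemical
free-energy calculations.

Group II introns excise themselves from precursor RNA in two sequential
first-order steps: the precursor (5e-I-3e) is cleaved at the 5' splice
junction with rate constant *k*₁ to give the intron-3'-exon intermediate
(I-3e), which resolves with rate constant *k*₂ into ligated exons and
the free intron (I). splicekin implements, end to end:

* **Splicing kinetics** — the closed-form (Bateman) solution of the
  P → I₃ₑ → I scheme, and joint or sequential nonlinear least-squares
  estimation of (*k*₁, *k*₂) from quantified gel time courses, with fit
  and replicate (s.e.m.) uncertainties.
* **Inhibition inference** — the competitive model
  *k*obs = *k*max/(1 + [I]/*K*ᵢ), normalised dose-response hyperbolas
  (% = 100/(1 + [I]/IC₅₀)) for both gel and FRET readouts, and
  step-selectivity fold-changes.
* **Binding thermodynamics** — ΔG = RT ln(K_D/c°); single-site ITC
  isotherm fitting (N, K_D, ΔH, with overflow-cell dilution
  bookkeeping); global biphasic (2:1 heterogeneous) BLI kinetics with
  K_D,i = k_off,i/k_on,i; and relative binding free energies
  ΔΔG = RT ln(K_i,B/K_i,A) with delta-method errors.
* **Thermodynamic integration** — ΔG = Σᵢ wᵢ ⟨∂U/∂λ⟩λᵢ over a
  Gauss–Legendre λ-window schedule (the published 12-window scheme is
  the order-12 rule on [0,1]), Metropolis sampling of analytic toy
  alchemical systems with closed-form oracles, and thermodynamic-cycle
  assembly ΔΔG = ΔG_bound − ΔG_unbound.
* **Synthetic data** — seeded generators reproducing the assay designs
  (triplicate gels, dose ladders, 16 × 2.5 µL ITC titrations, 300 s BLI
  phases), so the whole pipeline is testable without external data.

A command-line interface (`splicekin_cli()`, wrapped by
`inst/cli/splicekin`) exposes the stages as subcommands
(`simulate`, `fit-kinetics`, `fit-ki`, `fit-ic50`, `fit-itc`,
`fit-bli`, `ddg`, `ti-run`, `report`) over documented CSV/YAML/JSON
formats; every report embeds the resolved configuration and seed.

## Worked example

Simulate a triplicate gel experiment at the control and 50 µM inhibitor
conditions, refit the rate constants, and quantify step selectivity:

```r
library(splicekin)

design <- assay_design(concentrations = c(0, 50), replicates = 3,
                       noise_sd = 0.02, seed = 42)
gels <- generate_gel_timecourses(
  list(`0`  = splicing_rates(0.037, 0.031),    # control
       `50` = splicing_rates(0.007, 0.001)),   # 50 uM inhibitor
  design)

fit_rate_constants(gels[gels$conc_uM == 0, ])
#> Two-step splicing fit (joint mode, 3 replicate(s))
#>   k1 = 0.036333 +/- 0.00055 min^-1
#>   k2 = 0.031218 +/- 0.00071 min^-1
#>   s.e.m. across replicates: k1 0.00058, k2 0.0011

step_selectivity(splicing_rates(0.037, 0.031), splicing_rates(0.007, 0.001))
#> $fold_1
#> [1] 5.285714
#> $fold_2
#> [1] 31
#> $selectivity_ratio
#> [1] 5.864865
```

The noisy triplicate gels give back the generating constants to within
about 2%, and the fold-changes show the second splicing step slowed
~31-fold versus ~5-fold for the first — the second step is inhibited
roughly 6-fold more potently.

Relative binding free energy from two inhibition constants (25 °C):

```r
ddG_from_Ki(5.3, 3.9, 0.2, 0.5, labels = c("compound 12", "compound 17"))
#> ddG(compound 12 -> compound 17) = -0.182 +/- 0.079 kcal/mol [experimental_Ki]
```

i.e. compound 17 binds 0.18 kcal/mol more favourably than compound 12.
The full thermodynamic triple from an ITC-measured K_D:

```r
binding_thermodynamics(7.58e-6, -10.04)
#> Single-site binding thermodynamics (T = 298.15 K)
#>   K_D  = 7.58e-06 M (7.58 uM)
#>   N    = 1
#>   dH   = -10.04 kcal/mol
#>   dG   = -6.985 kcal/mol
#>   -TdS = 3.055 kcal/mol
```

showing enthalpy-driven binding with an entropic penalty.

See `vignettes/splicing-inhibition-analysis.Rmd` for the models,
numerical choices and the limits of the synthetic-data emulation.

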