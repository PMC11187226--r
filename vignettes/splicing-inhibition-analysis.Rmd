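---
title: "Quantifying small-molecule inhibition of group II intron splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying small-molecule inhibition of group II intron splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicekin)
```

## The system and the model

Group II introns are self-splicing ribozymes that excise themselves from
precursor RNA in two sequential chemical steps: the precursor (5e-I-3e)
is cleaved at the 5' splice junction to give a linear intron-3'-exon
intermediate (I-3e), which then resolves into ligated exons and the free
intron (I). On a denaturing gel the three RNA species are resolved as
distinct bands, and quantified band intensities give the species
fractions over time.

splicekin models this as the irreversible sequential first-order scheme

$$P \xrightarrow{k_1} I_{3e} \xrightarrow{k_2} I$$

with unit initial precursor. The closed-form (Bateman) solution is

$$P(t) = e^{-k_1 t},\qquad
I_{3e}(t) = \frac{k_1}{k_2 - k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right),\qquad
I(t) = 1 - P - I_{3e},$$

with the continuous limit $I_{3e}(t) = k\,t\,e^{-k t}$ at $k_1 = k_2 = k$.
Both rate constants are in min^-1; time is in minutes throughout. The
model treats each gel species as a single pool: the double bands caused
by cryptic cleavage sites are expected to be aggregated during image
quantification, before data enter the package.

```{r}
rates <- splicing_rates(0.037, 0.031)   # uninhibited control constants
species_fractions(c(0, 15, 30, 60), rates)
intermediate_peak_time(rates)            # minutes
```

Numerical choices: the degenerate branch is taken when
$|k_1 - k_2| < 10^{-6}\max(k_1,k_2)$, evaluated at the mean rate, which
avoids the catastrophic cancellation in $k_1/(k_2-k_1)$ while keeping the
branch switch continuous to well below any fitting tolerance.

## Fitting rate constants

`fit_rate_constants()` estimates $(k_1, k_2)$ by nonlinear least squares
on the log-parameter scale (enforcing positivity without active bounds).
The default `joint` mode minimises the residuals of all three species
simultaneously with equal weight; a `sequential` mode (precursor decay
first, then the intermediate with $k_1$ fixed) is provided because
published rate constants are sometimes derived that way, and neither mode
is privileged by the data layout. Starting values come from the
log-linear precursor decay (for $k_1$) and the post-peak intermediate
decay (for $k_2$), with a fallback multistart grid over
$10^{-3}\dots1$ min^-1; ties are broken by the lowest residual sum of
squares. Uncertainties are reported two ways: standard errors from the
fit covariance, and, when at least two replicates are supplied, the
across-replicate s.e.m. of per-replicate refits -- the s.e.m. is the
headline number for triplicate assay designs.

A time course whose precursor never reacts leaves $k_1$ (and everything
downstream) unconstrained; the fit either fails outright or returns a
vanishing $k_1$ with the `nonidentifiable` flag set.

## Inhibition constants and dose responses

At a fixed inhibitor concentration $[I]$ the observed rate constant of a
competitively inhibited step follows

$$k_{obs} = \frac{k_{max}}{1 + [I]/K_i},$$

fitted by `fit_ki()`. Because rate constants estimated from exponential
fits carry roughly constant *relative* error -- and because the
synthetic-data generator draws multiplicative log-normal noise -- the
default objective minimises relative residuals. This choice is what makes
the reported standard errors calibrated: in simulation at the triplicate
design, 95% Wald intervals cover the true $K_i$ about 93% of the time,
whereas absolute-residual or s.e.m.-weighted fits (weights estimated from
only three replicates are extremely noisy) cover markedly less.
Inverse-variance weighting remains available via `weighted = TRUE`.

Dose responses are normalised hyperbolas,
$\% = 100/(1 + [I]/IC_{50})$, fitted with the single free parameter
$IC_{50}$ by `fit_ic50()`. Two response kinds are supported: the gel
readout (percent reacted precursor at 15 min, normalised between the
DMSO and highest-concentration references by
`percent_reacted_precursor()`) and the FRET spliced-exon-reopening
readout (percent activity from initial slopes relative to DMSO,
`fret_initial_slopes()`; the slope window defaults to the first 20% of
time points, configurable). Step selectivity is summarised by
`step_selectivity()` as the two fold-slowdowns and their ratio:

```{r}
step_selectivity(splicing_rates(0.037, 0.031), splicing_rates(0.007, 0.001))
```

Note that the second-step fold computed from the rounded printed
constants is 31; a published "34-fold" from unrounded constants cannot
and should not be reproduced from rounded inputs, so the package always
reports the recomputed value.

## Binding thermodynamics

Free energies use $\Delta G = RT\ln(K_D/c^\circ)$ with
$R = 1.9872042586\times10^{-3}$ kcal mol^-1 K^-1, $c^\circ = 1$ M,
natural logarithms, and a default temperature of 298.15 K (25 C, the
binding-assay temperature; the printed experimental $\Delta\Delta G$
values are reproduced at 298.15 K and not at physiological 310 K).
Relative binding free energies of two inhibitors come directly from
their inhibition constants,

$$\Delta\Delta G_{A\to B} = RT\,(\ln K_{i,B} - \ln K_{i,A}),$$

with first-order (delta-method) error propagation. The log-difference
form keeps the antisymmetry $\Delta\Delta G_{AB} = -\Delta\Delta G_{BA}$
exact in floating point. The package reports its own error propagation
and never adjusts it toward externally published error bars.

```{r}
ddG_from_Ki(5.3, 3.9, 0.2, 0.5, labels = c("compound 12", "compound 17"))
```

### ITC

`simulate_itc()`/`fit_itc_single_site()` implement the single-site
isotherm with explicit overflow-cell bookkeeping: each injection of
volume $v$ displaces the fraction $v/V_0$ of the pre-injection cell
content, totals are updated as $c \leftarrow c(1 - v/V_0) + c_{syr}v/V_0$,
the bound concentration solves the single-site quadratic exactly, and
the heat of injection $i$ is
$Q_i = \Delta H V_0([MX]_i - [MX]_{i-1}(1 - v_i/V_0))$, normalised per
mole of injected ligand. The fitted parameters are $N$, $K_D$,
$\Delta H$ and a constant per-injection offset modelling the residual
of blank subtraction; $\Delta G$ and $-T\Delta S$ are derived, so the
Gibbs identity holds by construction. The default design is the study's:
30 uM receptor in the cell, 600 uM ligand in the syringe, 16 injections
of 2.5 uL at 25 C. The working cell volume is not part of the assay
description; the 200 uL nominal volume of the instrument class used for
such titrations is adopted as the fixed default. A warning is raised
when the Wiseman c-value $N[{\rm cell}]/K_D$ leaves $[1, 1000]$, outside
which the isotherm shape constrains $K_D$ poorly.

### BLI

The "2:1 heterogeneous" sensorgram model is implemented in its standard
interpretation: two independent 1:1 Langmuir surface-site classes, so
the response is a sum of two exponential phases with observed
association rate $k_{on,i}C + k_{off,i}$ per phase and affinities
$K_{D,i} = k_{off,i}/k_{on,i}$ by construction. `fit_bli_biphasic()`
fits all curves globally (shared rates and amplitudes across analyte
concentrations). Because the biphasic model is unidentifiable when one
amplitude vanishes, the nested 1:1 model is always fitted as well and
preferred, with a warning, when it already explains the data; the
second amplitude is then reported as exactly zero. Default design:
analyte at 12.5-100 uM, 300 s association, 300 s dissociation.

## Thermodynamic integration at desk scale

Relative binding free energies from alchemical simulations use a
thermodynamic cycle: the transformation A -> B is carried out once in
the bound state and once free in solvent, and
$\Delta\Delta G_{AB} = \Delta G_{bound} - \Delta G_{unbound}$.
Each leg integrates the Boltzmann average of
$\partial U/\partial\lambda$ over the coupling parameter:

$$\Delta G = \int_0^1 \left\langle \frac{\partial U}{\partial \lambda}
\right\rangle_\lambda d\lambda
\approx \sum_i w_i \left\langle \frac{\partial U}{\partial\lambda}
\right\rangle_{\lambda_i}.$$

The 12-window $\lambda$ scheme used in practice is the 12-point
Gauss-Legendre rule mapped to $[0,1]$ with weights normalised to sum
to 1. `gauss_legendre_schedule()` generates the rule for any order from
1 to 64 by the Golub-Welsch eigenvalue method rather than hard-coding
tables; mirror symmetry is enforced by averaging the two half-spectra
(the eigensolver treats each pair independently), and the order-12 rule
reproduces the published node/weight list at five decimals. Only six
weights are ever listed for twelve windows because the rule is
mirror-symmetric.

```{r}
gauss_legendre_schedule(12)
```

Since explicit-solvent molecular dynamics is far outside a desk-scale
package, the estimator is exercised on analytic toy alchemical systems
(`toy_alchemical_system()`): each end state is a per-coordinate
quadratic potential $\tfrac12 a x^2 + c x + e$, linearly interpolated in
$\lambda$, so every intermediate ensemble is Gaussian and both
$\langle\partial U/\partial\lambda\rangle_\lambda$ and the end-to-end
$\Delta G$ have closed forms (`exact_dudl_mean()`, `exact_deltaG()`).
For the stiffness morph $k_A \to k_B$,
$\Delta G = \tfrac{kT}{2}\ln(k_B/k_A)$. Window averages are sampled by
random-walk Metropolis (`sample_dudl()`): the proposal width starts at
$2.4\sqrt{kT/a(\lambda)}$, is tuned towards 40% acceptance during
burn-in (default: an extra 20% of the production steps, discarded) and
then frozen; a warning flags tuned acceptance outside $[0.1, 0.9]$.
Standard errors divide the sample variance by an effective sample size
from the initial-positive-sequence autocorrelation estimator. Per-window
seeds are derived deterministically from one root seed, so full runs are
bit-reproducible and the caller's RNG state is never disturbed.

```{r}
cyc <- run_ti(toy_alchemical_system("harmonic_stiffness", list(k = 1), list(k = 4)),
              toy_alchemical_system("harmonic_stiffness", list(k = 1), list(k = 2)),
              n_steps = 1500, seed = 5)
cyc
0.5 * log(4) - 0.5 * log(2)   # exact
```

Replica exchange between $\lambda$ windows, softcore treatment of
vanishing atoms and charge-correction schemes belong to the
explicit-solvent setting and are deliberately out of scope; independent
windows with burn-in stand in for the divergent equilibration of real
TI protocols. Cycle objects can also carry externally computed legs
(e.g. simulation-scale estimates); `assemble_cycle()` then only performs
the subtraction and error quadrature, never recomputation.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical designs* of the assays with
one root seed and deterministic per-stream child seeds:

* `generate_gel_timecourses()`: triplicates at 0/10/50/250 uM on a
  0-120 min grid, Gaussian noise (sd 0.02) added to band *intensities*
  before truncation at zero and renormalisation, mimicking densitometry.
  The truncation biases mean fractions near the 0/1 boundary by up to
  $\sigma/\sqrt{2\pi}\approx 0.008$; unbiasedness checks therefore apply
  away from the boundary (all species at least 3 sd from 0).
* `generate_kobs_series()`: multiplicative log-normal noise on the
  hyperbolic model; the default concentration ladder
  {0, 0.5, 1, 2, 5, 10, 25, 50} uM spans a low-micromolar $K_i$ (the
  exact experimental ladder is not part of the assay description).
* `generate_dose_response()`: 11 log-spaced concentrations from 0.25 uM
  to 1 mM (the FRET design) with additive percent noise.
* `generate_itc()` / `generate_bli()`: the forward models above with
  additive Gaussian noise.

They do not emulate image-level gel artefacts, radiolabel decay,
baseline drift, mass-transport limitation in BLI, or inter-day batch
effects -- so passing recovery tests demonstrates estimator correctness
under the assumed error models, not robustness to every failure mode of
real instruments.

## Problem sizes

The test-suite simulation studies use 100 seeds for gel-noise recovery,
200 simulated experiments for $K_i$ interval coverage, 40 seeds for
noisy ITC recovery, and 5000 Metropolis samples per window (12 windows)
for the TI oracle check; these sizes give the quoted medians and
coverages stable second digits while keeping a full run in tens of
seconds.

## Known limitations

* The kinetic model is strictly irreversible and unbranched; lariat
  pathways and spliced-exon reopening are handled only as dose-response
  readouts, not mechanistically.
* The ITC model assumes a single site class and a constant blank
  offset; competitive or multi-site titrations are out of scope.
* The BLI "2:1" interpretation (two independent site classes) is the
  standard one, but vendor software implements proprietary variants;
  exact parameter agreement with instrument reports is not guaranteed.
* Delta-method errors on $\Delta\Delta G$ are first order; published
  uncertainties propagated by other (unstated) schemes can differ.
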