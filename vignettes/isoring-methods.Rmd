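---
title: "Methods: isodesmic assembly with preferential ring closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isodesmic assembly with preferential ring closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoring)
```

## The model

`isoring` models the self-assembly of a ring-forming protein (the
motivating case is full-length human RAD52, monomer mass 48.4 kDa) as
**isodesmic growth with preferential cyclization**. Two assumptions
define it:

1. *Noncooperative chain growth.* Every monomer-addition step shares one
   dissociation constant $K_d$, so open chains follow the geometric law
   $c_{open}(n) = K_d\,(c_1/K_d)^n$ with $c_1$ the free monomer
   concentration. There is no nucleus and no length-dependent bond
   energy.
2. *Elastic ring closure.* An open $n$-mer can close into a ring by
   forming one extra bond without adding a subunit. The closure
   equilibrium is
   $$K_c(n) = K_c^\circ\,
   \exp\!\left[-\tfrac12\left(\frac{n-n_o}{\sigma_{ring}}\right)^2\right],$$
   a Gaussian in the ring size: the polymer has a preferred curvature
   giving an optimal protomer number $n_o$, and deviations cost Hookean
   bending energy $E_b = \tfrac12((n-n_o)/\sigma_{ring})^2$ in units of
   $k_BT$ ($\sigma_{ring}^{-2}$ is proportional to the effective bending
   stiffness). Ring species are $c_{ring}(n) = K_c(n)\,c_{open}(n)$.

All energies are expressed in $k_BT$; temperature never enters
numerically. The free-energy gain of closing the optimal ring is
$\Delta G_{ring} = k_BT \ln K_c^\circ$ (`ring_closure_energy()`).

Given a total protomer concentration the package inverts the mass
balance $\sum_n n\,(c_{open}(n)+c_{ring}(n)) = c_{total}$ for $c_1$.
The left side is strictly increasing in $c_1$ and the root is bracketed
by $[0, c_{total}]$, so a bisection root-finder followed by Newton
polishing is guaranteed to converge; solved distributions satisfy the
mass balance to better than $10^{-9}$ relative (tested).

This model reproduces a condensation-like phase behaviour: below a
critical concentration almost all material is in monomers and short
oligomers (the "gas" pool), above it the ring pool (the "liquid"
reservoir) grows nearly linearly while the short pool stays almost
constant. The package quantifies the transition two ways: the
**maximum-curvature critical concentration** (second derivative of the
ring pool versus total concentration) and the **empirical linear model**
$c_{ring} = (c_{protomer}-c_{crit})/n_{avg}$ fitted above the onset,
whose intercept-derived $c_{crit}$ should match the short-pool plateau.

### Parameters and defaults

| parameter | meaning | unit | reference value |
|---|---|---|---|
| `kd` | isodesmic step dissociation constant | nM | 14 |
| `kc0` | ring-closure amplitude $K_c^\circ$ | — | $1.9\times10^6$ |
| `n_opt` | optimal ring protomer number | protomers | 10.8 |
| `sigma_ring` | SD of the ring-size Gaussian | protomers | 0.79 |
| `n_max` | largest tracked oligomer | protomers | 25 |
| `n_ring_min` | smallest ring allowed | protomers | 3 |

The reference values (`rad52_params()`) are the published global-fit
results for full-length RAD52. `n_max = 25` keeps the truncation error
of the size sum far below $10^{-9}$ of total mass at these parameters
(the Gaussian makes rings beyond ~14 protomers vanishingly rare, and
open chains decay geometrically); `n_ring_min = 3` merely excludes
geometrically impossible rings — $K_c(3)$ is already
$<10^{-14}K_c^\circ$, so its exact value is irrelevant. Pool windows
default to sizes 1–4 (short) and 8–12 (rings), the windows used in the
underlying study; both are arguments everywhere they appear.

## Measurement model: histogram deconvolution

Mass photometry yields one calibrated mass per landing event. The
instrument resolution grows linearly with mass; `sd_calibration`
stores that line together with the detection window (default 40 kDa –
7 MDa). Oligomer abundances are obtained by fitting a sum of Gaussians
to the binned event histogram (default 4 kDa bins):

* candidate centers are integer multiples of the monomer mass. For a
  $k$-component fit the $k$ *most populated* multiples (by
  nearest-multiple event counts) receive components, so empty
  intermediate sizes (pentamers–heptamers are rare when rings dominate)
  do not consume components before the ring sizes are covered.
* centers may move at most `center_tol` monomer masses (default 0.2)
  from their multiple. Observed mass offsets of genuine oligomer peaks
  are below ~0.05 monomer masses, while a loose bound lets the strongly
  overlapping ring components (peak spacing ≈ 1.7 SD at ring masses)
  slide collectively and smear the per-size allocation; 0.2 is tight
  enough to stop the smearing and loose enough for real offsets, and
  any value below 0.5 keeps the size assignment unambiguous.
* each SD is parameterized as a fraction in $(0,1]$ of the calibration
  prediction *at the component's current center*, so the
  instrument-resolution upper bound holds exactly by construction while
  narrower peaks (a species with fixed stoichiometry can be narrower
  than heterogeneous calibration standards) remain allowed.
* amplitudes are full-Gaussian event counts and the model integrates
  each Gaussian over each bin. Because bins start at the detection
  floor but areas are full-Gaussian, events lost below 40 kDa are
  implicitly restored — without this restoration a 48.4 kDa monomer
  peak loses ~17% of its events and the downstream $K_d$ collapses
  (verified on synthetic data).
* the component count minimizes $AIC = N\ln(RSS/N) + 2p$ ($p = 3k$
  free parameters, $N$ bins); ties break toward fewer components.
  After selection, peaks holding $<2\%$ of the fitted area are removed
  and fractions renormalized. Peaks heavier than `n_max` monomers are
  labelled ring clusters and excluded from concentration tables.

Counts convert to species concentrations assuming equal per-particle
landing probability: $c_i = f_i S$ with $f_i$ the retained area
fractions and $S$ fixed by $\sum_i n_i c_i = c_{nominal}$. No
mass-dependent landing correction is applied; if landing rates are
mass-dependent in a given instrument this is a systematic error the
user must assess.

## Global fit

`isoring_fit()` minimizes weighted squared residuals between observed
per-size species concentrations and the model's $c_{open}(n) +
c_{ring}(n)$ (a mass measurement cannot distinguish an open $n$-mer
from its ring) jointly over all concentrations, using
Levenberg–Marquardt on $(\log K_d, \log K_c^\circ, n_o, \log
\sigma_{ring})$ with box bounds. Starts: a moment-style, data-driven
guess ($K_d$ from $c_1^2/c_2$, $n_o$ from the ring-region mode,
$K_c^\circ$ from the ring/open ratio), the user's `init` if any, and
seeded random multistarts (default 10) — the joint objective has a
competing shallow basin (small $K_d$, very broad ring Gaussian) that
purely random starting occasionally falls into, and the data-driven
start reliably lands in the physical basin.

Weighting defaults to equal weights. An inverse-count ("Poisson")
scheme is available, but for deconvolution-derived tables the dominant
error is the allocation noise between overlapping ring components,
which is far super-Poissonian; on synthetic ground truth inverse-count
weighting over-trusts low-count rows and biases $K_d$ low by ~10%,
while equal weights recover it to within a few percent.

Uncertainties come from a nonparametric bootstrap over replicate
readings (default 200 resamples, seeded; case-resampling of replicates
within each concentration, refitting from the point estimate). With
`nboot = 0` asymptotic errors from the final Jacobian are reported
instead.

## Synthetic data

The generator draws each landing event's species with probability
proportional to its species (particle) concentration, adds Gaussian
noise with the calibration SD at the true mass, and discards (without
replacement) events below the detection floor — emulating a 60-s
reading of a dilute sample with independent landings. Defaults match
the study conditions: titrations at {10, 25, 50, 100, 200} nM, 4
replicate readings, 2000 events drawn per reading, 48.4 kDa monomer,
noise law $sd(m) = 0.04m + 7$ kDa (chosen once so that a 25.3 kDa
protein has ≈8 kDa SD, consistent with reported instrument behaviour),
40 kDa floor. An optional ring-cluster contaminant fraction exercises
the 2% pruning rule. Hill binding curves and single-exponential
annealing courses are generated with additive Gaussian noise.

What the generator does *not* emulate: surface crowding or depletion
over a reading, mass-dependent landing probabilities, day-to-day
calibration drift, DNA-bound mass shifts, and >1.5 MDa aggregates.
Passing recovery tests therefore demonstrate the statistical soundness
of the estimator chain under the stated noise model, not robustness to
those instrument systematics.

## Numerical choices

* Free-monomer inversion: `uniroot` at tolerance
  $\varepsilon^{0.75}$ plus ≤4 Newton steps; species laws are evaluated
  in log space with a cap so that trial $c_1 > K_d$ at large `n_max`
  cannot overflow.
* Critical concentration: central second differences on a log-spaced
  grid (default 400 points, 0.1–50 nM; non-uniform-spacing formula).
  The result is stable to within 10% under grid refinement (tested);
  `kc0 = 0` has no ring phase and errors out.
* Degenerate inputs: flat binding curves, all-zero ring pools,
  rank-deficient empirical fits and single-concentration global fits
  raise errors; a negative fitted $c_{crit}$ is returned but flagged.
* AIC ties (differences $<10^{-9}$) resolve to the smaller component
  count.
* Hill and annealing fits run on log-parameter scales, making
  positivity unconditional; both are scale-equivariant (tested).

## Problem sizes

The shipped tests and the acceptance script use the study-scale
titration (5 concentrations × 4 replicates × 2000 events ≈ 40,000
events per pipeline run), 5000-event fixtures for deconvolution
round-trips, 100 seeded curves for the Hill-recovery property, and
20 seeded bimodal fixtures for the AIC consistency check.

## Known limitations

* Ring–ring clusters are detected and labelled but not modelled
  thermodynamically; their protomer mass is excluded from titration
  tables, slightly inflating other species via the mass-balance
  normalization when clusters are abundant.
* Species below the 2% area threshold are unobservable by construction;
  at low concentrations this removes trimer/tetramer rows entirely
  rather than reporting noisy small values.
* The per-size allocation among heavily overlapping ring peaks remains
  the dominant error source; $\sigma_{ring}$ is recovered with a small
  upward bias (~0.05–0.1 protomers at study scale) even with the
  tightened center bounds.
* Whether plotted "oligomer concentrations" are species or
  protomer-weighted quantities is a modelling choice; the package uses
  species (particle) concentrations throughout, with protomer weighting
  applied only inside mass balances.
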