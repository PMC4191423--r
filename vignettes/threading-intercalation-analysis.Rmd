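---
title: "Force-clamp analysis of DNA threading intercalation"
author: "threadclamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-clamp analysis of DNA threading intercalation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threadclamp)
```

## The experiment and the model

Threading intercalators are bulky ligands that must pass part of their
structure between DNA base pairs before the aromatic moiety can stack
inside the duplex. The threading step requires a large, transient DNA
deformation, which makes both association and dissociation extremely slow
— slow enough that conventional stretching curves never equilibrate. The
measurement this package analyses instead holds a single DNA molecule
(typically bacteriophage lambda DNA, 48,502 bp) at constant force `F` in a
ligand solution of concentration `C` and records the per-base-pair
extension `L(t)` as intercalation elongates the molecule.

The analysis chain rests on four model components.

**Single-exponential relaxation.** At constant force the extension relaxes
as

    L(t) = L(0) + [L_eq - L(0)] (1 - exp(-k_total t)),

with a net rate `k_total = k_on + k_off`, the sum of the pseudo-first-order
threading-on rate and the threading-off rate. `fitRelaxation()` fits
`(L0, L_eq, k_total)` by Levenberg–Marquardt least squares, parameterising
the rate on the log scale because it spans decades across conditions.

**Extension mixture and occupancy.** The partially bound molecule behaves
as a linear mixture of bare DNA and the ligand-saturated complex, so the
fractional saturation at equilibrium is

    theta(F, C) = [L_eq(F,C) - L_DNA(F)] / [L_sat(F) - L_DNA(F)].

`L_DNA(F)` and `L_sat(F)` are extensible worm-like chains (WLC). We use the
extensible Marko–Siggia interpolation solved numerically for the extension
(`wlcExtension()`), not the Odijk high-force expansion, because the
saturated complex has a persistence length near 1.6 nm, far outside the
regime where the high-force expansion is accurate at tens of pN.

**McGhee–von Hippel isotherm.** A ligand occluding `n` contiguous base
pairs binds a one-dimensional lattice with overlap exclusion. In the
fractional-saturation convention `theta = n * nu` (with `nu` ligands per
base pair) the non-cooperative isotherm reads

    theta = (C / Kd) * n (1 - theta)^n / (1 - theta + theta/n)^(n-1).

Substituting `theta = n nu` recovers the textbook `nu/C` form with
intrinsic association constant `1/Kd`, so the two statements are
algebraically identical; we work in the saturation convention because that
is what the extension measures. `mvhCoverage()` solves the isotherm by
bracketed root finding (the residual is monotone, so the root on
`[0, 1)` is unique), and `fitIsotherm()` fits `(Kd, n)` per force, with
real-valued `n` because the fitted site size varies continuously with
force.

**Bell force dependence.** Binding elongates DNA, so force tilts the free
energy landscape: `Kd(F) = Kd(0) exp(-F dx_eq / kT)` while
`k_on/off(F) = k_on/off(0) exp(+x_on/off F / kT)`. `bellFit()` performs
these fits in log space (linear regression of `ln value` on `F`). The paper
behind this design does not state its regression space; we chose log space
because the multiplicative scatter of rate estimates spanning decades is
approximately homoscedastic there, and a cross-validation test confirms
log-space and direct nonlinear fits agree within one standard error on low
noise data.

Three independent routes to the per-ligand equilibrium elongation fall out
of the chain and are all reported by `deriveThermodynamics()`:

1. the Bell-fit distance of `Kd(F)`;
2. the force average of `n(F) * [L_sat(F) - L_DNA(F)]`;
3. `x_on - x_off` from the rate fits.

The same function converts the depression of the zero-force association
rate below the diffusion limit into the threading free energy
`G_thread = kT ln(k_dif / k_a(0))`, with `k_dif = 1e9 /M/s` by default
(configurable), and reports the zero-force residence half-life
`ln(2)/k_off(0)`. Note the half-life implied by a zero-force off rate of
order 1e-3 /s is tens of minutes; claims of multi-hour residence for such
ligands refer to different conditions, and the package reports the computed
number without reconciling the two.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| temperature | K | 294.15 | measurement temperature (21 C); sets kT = 4.061 pN nm used in every Bell exponent |
| bare DNA WLC | nm, pN | Lp 50, S 1000, L0 0.34 | standard B-DNA elasticity |
| saturated WLC | nm, pN | Lp 1.6, S 598, L0 0.45 | fitted elasticity of the saturated complex; contour chosen so the high-force rise matches 0.34 nm plus the per-ligand elongation shared over ~1.7 bp |
| force ceiling | pN | 65 | stays below the overstretching transition; inputs above are rejected, not clamped |
| satThreshold | – | 0.95 | occupancy above which the top-concentration plateau is taken as L_sat directly |
| k_dif | /M/s | 1e9 | diffusion-limited association rate |
| bootstrap resamples | – | 500 (small fits) | residual bootstrap for uncertainties |

All lengths are per base pair; multiply by the construct length for total
extensions.

## The synthetic generator and the lattice oracle

Because no public trace data accompany the experiment, validation rests on
two generators with known truth.

`simulateTrace()` draws the deterministic kernel
`L(t) = L_DNA + theta_eq (1 - e^{-k_total t}) (L_sat - L_DNA)` with
`k_total = k_a(F) C + k_off(F)` from Bell-model truth rates and `theta_eq`
from the McGhee–von Hippel isotherm at the implied
`Kd(F) = k_off(F)/k_a(F)`, then adds i.i.d. Gaussian noise (default
1e-4 nm/bp, about 5 nm over a lambda construct, matching stated instrument
resolution) at 200 ms sampling for 5/k_total (at least 10 samples). This
"MvH-target" kernel mirrors the analysis's own mixed use of an exclusion
isotherm with two-state kinetics; it is exactly self-consistent only at
`n = 1`. The default truth is the fitted parameter set of the reference
experiment: `k_a(0) = 1.01e4 /M/s`, `k_off(0) = 4.44e-4 /s` (implied
`Kd(0) = 44 nM`), `x_on = 0.33 nm`, `x_off = 0.14 nm`, site size falling
linearly from 3.7 bp at 10 pN to 1.7 bp at 60 pN (clamped outside; the
force dependence of `n` is an input schedule, not an emergent property,
because no generative model for it exists).

Two choices exist for the saturated extension. The default, `satModel =
"elongation"`, sets `L_sat(F) = L_DNA(F) + dx_eq / n(F)`: the per-ligand
elongation is force-independent, so route 2 above is exact by construction
and all three routes must agree on synthetic data. The alternative,
`satModel = "wlc"`, draws `L_sat(F)` from the saturated-complex WLC
(Lp 1.6 nm, S 598 pN); it reproduces the measured elasticity but makes the
implied per-ligand elongation force-dependent. Real data sit between the
two idealisations — indeed the experimental routes disagree slightly
(0.19 vs 0.23 nm), which the analysis reports without reconciling.

What the generator deliberately omits: the ~2 s force ramp before
recording (analysis treats the first sample as t = 0 and leaves `L(0)`
free), drift and 1/f instrument noise, bead Brownian motion, sequence
heterogeneity and AT preference, and any multi-exponential character.
Passing recovery tests therefore demonstrates the estimators are unbiased
and correctly calibrated under the stated noise model, not that real traces
are single-exponential — that is an experimental finding, not a package
claim.

`gillespieLattice()` is an independent stochastic oracle: a continuous-time
simulation of ligand footprints (integer `n`) binding a finite lattice with
exclusion, whose late-window time-averaged coverage must match the closed
form isotherm. It shares no numerics with `mvhCoverage()` and also
quantifies the bias of the two-state rate split under exclusion: the
isotherm fit allows real-valued `n` but the oracle is inherently integer,
and the mismatch is part of what the oracle is for.

## Numerical choices and degenerate inputs

- WLC inversion: bracketed `uniroot` on the relative extension, polished by
  Newton steps to 1e-10 relative; non-convergence signals invalid
  parameters rather than returning a guess.
- Isotherm solving: `uniroot` to 1e-13 on `[0, 1 - 1e-12]`; `C = 0`
  short-circuits to zero.
- All nonlinear fits are multistart (site size over `n0 = 1..5`,
  persistence length over four decades) with the best residual winning;
  bootstrap refits restart from the point estimate.
- Occupancies pushed outside `[0, 1]` by noise are clamped and counted
  (`nClamped` attribute, pipeline warning); inconsistent elasticity
  (`L_sat <= L_DNA`) is an error.
- Flat traces (plateau within 3 noise SD of the start) are rejected as "no
  detectable binding"; short traces (< 2/k_total) are fitted but flagged
  unconverged.
- Degenerate designs error early: fewer than 4 titration points or a
  concentration span under 10x, fewer than 3 Bell forces or a span under
  20 pN, single-concentration rate regressions.
- Zero-concentration rate splitting uses the explicit limit
  `k_on = 0, k_off = k_total`; `k_off` is computed as `k_total - k_on` so
  the sum identity is exact in floating point.

## Pipeline design decisions

The per-force saturated extension is under-determined when the titration
never quite saturates. The pipeline makes this deterministic with a
two-regime rule: it first fits `(Kd, n, L_sat)` jointly to `L_eq(C)`; if
the fitted occupancy of the highest concentration exceeds `satThreshold`
(default 0.95) it switches to using that plateau directly as `L_sat` and
refits `(Kd, n)` alone. Under the default truth the top concentration
(150 nM) reaches only ~0.77–0.95 occupancy depending on force, so the
joint branch is the one normally exercised.

Per-force isotherm fits are independent (matching the original analysis);
a global fit tying `Kd(F)` to the Bell form would be an extension and is
not enabled. Residuals are unweighted by default because the source
analysis states no weighting; inverse-variance weighting is available via
`weighted = TRUE`.

Uncertainties for the small-sample fits (isotherm, Bell, WLC; a handful of
points each) come from seeded residual bootstraps, default 500 resamples.
For relaxation fits the package defaults to the asymptotic least-squares
covariance: each trace carries thousands of samples at high signal-to-noise
under the default conditions, where the asymptotic and bootstrap intervals
coincide; `nBoot` switches any fit to the bootstrap. The Bell fit of the
per-force on/off rates is evaluated at a reference concentration (default
5 nM, nearest available), matching how the transition distances are usually
quoted; the association-rate fit uses all concentrations through the
per-force slopes.

Problem sizes used in the shipped validation: the end-to-end recovery runs
6 forces x 7 concentrations x 2 replicates (84 traces, ~7e5 samples), the
lattice oracle checks use 100–360 sites with 6–8 replicate runs per
footprint, and bootstraps use 200–500 resamples. These choices keep the
whole suite within a couple of minutes on one core while leaving every
recovery comfortably inside its 3-standard-error acceptance band.

## A worked example

```{r example, eval = FALSE}
grid <- simulateGrid(makeTruth(), seq(20, 60, 20), c(5, 25, 50, 150),
                     seed = 3)
report <- runPipeline(grid$traces, pipelineConfig(seed = 1))
report
report@thermo
```

## Known limitations

- Equations splitting `k_total` into `k_on` and `k_off` through `Kd` are
  exact for a two-state system; under footprint exclusion with `n > 1`
  they are an approximation. The package applies them as the field does
  and provides the lattice oracle to quantify the bias.
- The relaxation model is strictly single-exponential; multi-exponential
  bulk-solution behaviour is out of scope by design.
- The lattice oracle cannot represent fractional site sizes.
- Cooperativity (the omega parameter of the full exclusion isotherm) is
  not modelled.
- No instrument model: trap stiffness, bead displacement and the force
  feedback servo are outside the package; inputs are assumed to be
  calibrated per-base-pair extensions at known constant force.
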