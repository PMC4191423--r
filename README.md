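# threadclamp

Analysis of constant-force single-molecule DNA stretching experiments on
slow **threading intercalators** — ligands that must push part of their
structure between base pairs before they can stack inside the duplex, and
whose on/off kinetics are consequently measured in minutes to hours. The
package is written for single-molecule biophysicists who record
force-clamp extension traces (optical tweezers or similar) of DNA in
ligand solution and want the full quantitative characterisation: binding
affinity, site size, force-dependent kinetics, transition-state
distances, complex elasticity and the free-energy cost of the threading
deformation.

## The model

At constant force `F` and ligand concentration `C`, the per-base-pair
extension relaxes single-exponentially,

    L(t) = L(0) + [L_eq − L(0)] (1 − e^(−k_total t)),    k_total = k_on + k_off

toward an equilibrium that is a mixture of bare DNA and the saturated
complex, `L_eq = (1 − Θ) L_DNA(F) + Θ L_sat(F)`, with both states modelled
as extensible worm-like chains. The equilibrium occupancy follows the
non-cooperative McGhee–von Hippel isotherm for a ligand occluding `n`
base pairs,

    Θ = (C/K_d) · n (1 − Θ)^n / (1 − Θ + Θ/n)^(n−1),

fitted per force for `(K_d, n)`. Force dependences are Bell exponentials:
`K_d(F) = K_d(0) e^(−F Δx_eq / kT)` and
`k_on/off(F) = k_on/off(0) e^(+x_on/off F / kT)`, giving the equilibrium
elongation per bound ligand by three independent routes (Bell fit of
`K_d(F)`; force average of `n(F)·ΔL_sat(F)`; `x_on − x_off`). The
depression of the zero-force association rate below the diffusion limit
yields the threading free energy
`G_thread = kT ln(k_dif / k_a(0))`.

A self-consistent synthetic trace generator (`simulateTrace`,
`simulateGrid`) and an independent Gillespie footprint-exclusion lattice
simulator (`gillespieLattice`) make every stage testable by parameter
recovery without experimental data.

## Worked example

```r
library(threadclamp)

grid   <- simulateGrid(makeTruth(), seq(20, 60, 20), c(5, 25, 50, 150),
                       seed = 3)
report <- runPipeline(grid$traces, pipelineConfig(seed = 1))
report
#> AnalysisReport: 12 trace fits, 12 equilibrium points, 3 isotherm fits
#>   Kd(0) = 43.92 nM, dxEq = 0.19 nm
#>   G_thread = 11.5 kBT
#>   warnings: 2

report@kaBell
#> BellFit[k_a]: value(0) = 10106, distance = 0.33 nm (3 points)

report@thermo
#> DerivedThermodynamics:
#>   dxEq routes (nm): kd_bell = 0.19, site_size = 0.19, rate_split = 0.19
#>   G_thread = 11.5 kBT = 6.72 kcal/mol
#>   zero-force half-life = 0.434 h
```

Reading the output: the extrapolated zero-force dissociation constant is
43.9 nM and each bound ligand lengthens the duplex by 0.19 nm at
equilibrium, consistently across all three routes. The fitted zero-force
association rate (1.01e4 /M/s) sits five orders of magnitude below the
diffusion limit, i.e. only ~1 in 10^5 diffusive encounters threads; that
corresponds to a threading deformation free energy of 11.5 kT
(6.7 kcal/mol). The zero-force residence half-life implied by the fitted
off rate is about 26 minutes. The truth parameters behind `makeTruth()`
are recovered within their bootstrap uncertainties — which is the point:
run the same pipeline on your own trace CSVs (`readTraceDir`, then
`runPipeline`) to get the same report for real data.

Traces are CSV files (`time_s,extension_nm_per_bp`) with a JSON sidecar
(`force_pN`, `concentration_nM`, …); see `?readTrace`. A thin
command-line wrapper lives in `inst/scripts/threadclamp-pipeline.R`.

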