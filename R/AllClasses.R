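#' @import methods
NULL

# Boltzmann constant in pN nm / K
.kB <- 0.0138065
# Avogadro's number (1/mol)
.NA <- 6.02214076e23
# thermal calorie, J/kcal
.J_PER_KCAL <- 4184

#' Experimental conditions
#'
#' Temperature, construct length and bare base-pair rise shared by all
#' calculations. The thermal energy slot is derived from the temperature at
#' construction (kB = 0.0138065 pN nm / K) and validated against it.
#'
#' @slot temperature absolute temperature in kelvin.
#' @slot thermalEnergy kB * temperature, in pN nm.
#' @slot bpCount number of base pairs in the construct.
#' @slot contourPerBp bare-DNA contour length per base pair, nm.
#' @export
setClass("Conditions",
  representation(
    temperature = "numeric",
    thermalEnergy = "numeric",
    bpCount = "numeric",
    contourPerBp = "numeric"
  )
)

setValidity("Conditions", function(object) {
  msgs <- character()
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msgs <- c(msgs, "temperature must be a single positive value (kelvin)")
  kt <- .kB * object@temperature
  if (abs(object@thermalEnergy - kt) > 1e-6 * kt)
    msgs <- c(msgs, "thermalEnergy must equal 0.0138065 * temperature")
  if (length(object@bpCount) != 1L || object@bpCount <= 0)
    msgs <- c(msgs, "bpCount must be positive")
  if (length(object@contourPerBp) != 1L || object@contourPerBp <= 0)
    msgs <- c(msgs, "contourPerBp must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Worm-like-chain elasticity parameters
#'
#' Extensible worm-like chain parameters for one polymer state (bare DNA or
#' the ligand-saturated complex).
#'
#' @slot persistenceLength nm; the continuum chain model is rejected below
#'   0.5 nm.
#' @slot stretchModulus enthalpic stretch modulus, pN.
#' @slot contourPerBp contour length per base pair, nm.
#' @export
setClass("WLCParams",
  representation(
    persistenceLength = "numeric",
    stretchModulus = "numeric",
    contourPerBp = "numeric"
  )
)

setValidity("WLCParams", function(object) {
  msgs <- character()
  if (!all(c(object@persistenceLength, object@stretchModulus,
             object@contourPerBp) > 0))
    msgs <- c(msgs, "all WLC parameters must be strictly positive")
  if (length(object@persistenceLength) &&
      object@persistenceLength < 0.5)
    msgs <- c(msgs, "persistenceLength below 0.5 nm: continuum WLC rejected")
  if (length(msgs)) msgs else TRUE
})

#' Fitted worm-like-chain parameters
#'
#' A [WLCParams-class] augmented with uncertainties from [fitWLC()].
#'
#' @slot se named standard errors of the fitted parameters.
#' @slot cov covariance matrix of the fitted parameters.
#' @slot nPoints number of (force, extension) points fitted.
#' @slot residualNorm root-mean-square residual, nm/bp.
#' @export
setClass("WLCFit",
  contains = "WLCParams",
  representation(
    se = "numeric",
    cov = "matrix",
    nPoints = "integer",
    residualNorm = "numeric"
  )
)

#' A constant-force extension recording
#'
#' One force-clamp trace: per-base-pair extension sampled in time while the
#' applied force and ligand concentration are held constant.
#'
#' @slot times seconds, strictly increasing; the first recorded sample is
#'   time zero of the analysis.
#' @slot extensions nm per base pair, same length as `times`.
#' @slot force applied force, pN, in (0, 65].
#' @slot concentration ligand concentration, nM.
#' @slot label free-text identifier.
#' @slot meta list of provenance fields carried through the CSV/JSON sidecar
#'   round trip.
#' @export
setClass("ForceClampTrace",
  representation(
    times = "numeric",
    extensions = "numeric",
    force = "numeric",
    concentration = "numeric",
    label = "character",
    meta = "list"
  )
)

setValidity("ForceClampTrace", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@extensions))
    msgs <- c(msgs, "times and extensions must have the same length")
  if (length(object@times) >= 2L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(object@force) != 1L || object@force <= 0 || object@force > 65)
    msgs <- c(msgs, "force must lie in (0, 65] pN")
  if (length(object@concentration) != 1L || object@concentration < 0)
    msgs <- c(msgs, "concentration must be non-negative (nM)")
  if (length(object@extensions) &&
      (any(object@extensions <= 0) || any(object@extensions >= 0.7)))
    msgs <- c(msgs, "extensions must lie in (0, 0.7) nm/bp")
  if (length(msgs)) msgs else TRUE
})

#' Single-exponential relaxation fit of a trace
#'
#' Result of [fitRelaxation()]: L(t) = L0 + (Leq - L0) (1 - exp(-kTotal t)).
#'
#' @slot L0 extension at time zero, nm/bp.
#' @slot Leq equilibrium extension, nm/bp.
#' @slot kTotal net relaxation rate, 1/s.
#' @slot se named standard errors for (L0, Leq, kTotal).
#' @slot cov covariance matrix.
#' @slot rSquared coefficient of determination.
#' @slot residAutocorr TRUE when lag-1 residual autocorrelation exceeds the
#'   white-noise band (model misfit indicator).
#' @slot converged TRUE when the trace spans at least 2 / kTotal so the
#'   plateau is constrained by data rather than extrapolation.
#' @slot nObs number of samples.
#' @slot force,concentration copied from the source trace.
#' @export
setClass("RelaxationFit",
  representation(
    L0 = "numeric",
    Leq = "numeric",
    kTotal = "numeric",
    se = "numeric",
    cov = "matrix",
    rSquared = "numeric",
    residAutocorr = "logical",
    converged = "logical",
    nObs = "integer",
    force = "numeric",
    concentration = "numeric"
  )
)

setValidity("RelaxationFit", function(object) {
  if (object@kTotal <= 0) "kTotal must be positive" else TRUE
})

#' On/off rates split from a net relaxation rate
#'
#' Result of [splitRates()]. Slots are parallel vectors, one element per
#' (force, concentration) condition; the sum identity
#' kOn + kOff == kTotal holds exactly.
#'
#' @slot force pN.
#' @slot concentration nM.
#' @slot kOn pseudo-first-order threading-on rate, 1/s.
#' @slot kOff threading-off rate, 1/s.
#' @slot kTotal source net rate, 1/s.
#' @slot se named list with optional kOn/kOff standard errors.
#' @export
setClass("RateSet",
  representation(
    force = "numeric",
    concentration = "numeric",
    kOn = "numeric",
    kOff = "numeric",
    kTotal = "numeric",
    se = "list"
  )
)

setValidity("RateSet", function(object) {
  bad <- abs(object@kOn + object@kOff - object@kTotal) >
    1e-12 * pmax(object@kTotal, .Machine$double.xmin)
  if (any(bad)) "kOn + kOff must equal kTotal to 1e-12 relative" else TRUE
})

#' McGhee-von Hippel isotherm fit at one force
#'
#' @slot force pN.
#' @slot Kd equilibrium dissociation constant, nM.
#' @slot n binding site size, bp (real-valued, >= 1).
#' @slot Lsat saturated extension used/fitted, nm/bp (NA when occupancies
#'   were supplied directly).
#' @slot se named standard errors (bootstrap).
#' @slot cov covariance of (Kd, n).
#' @slot nPoints number of titration points.
#' @slot residualNorm root-mean-square residual (occupancy units).
#' @slot nonIdentifiable TRUE when the relative Kd standard error exceeds
#'   100 percent.
#' @export
setClass("IsothermFit",
  representation(
    force = "numeric",
    Kd = "numeric",
    n = "numeric",
    Lsat = "numeric",
    se = "numeric",
    cov = "matrix",
    nPoints = "integer",
    residualNorm = "numeric",
    nonIdentifiable = "logical"
  )
)

setValidity("IsothermFit", function(object) {
  msgs <- character()
  if (object@Kd <= 0) msgs <- c(msgs, "Kd must be positive")
  if (object@n < 1) msgs <- c(msgs, "site size n must be >= 1")
  if (nrow(object@cov) == 2L) {
    if (max(abs(object@cov - t(object@cov))) > 1e-8 * max(1, abs(object@cov)))
      msgs <- c(msgs, "covariance must be symmetric")
    if (any(eigen(object@cov, symmetric = TRUE,
                  only.values = TRUE)$values < -1e-8))
      msgs <- c(msgs, "covariance must be positive semidefinite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Site-size route to the per-ligand elongation
#'
#' Result of [deltaXFromSiteSize()]: per-force dxEq = n(F) * dLsat(F) and
#' its force average.
#'
#' @slot perForce data.frame with columns force, n, dLsat, deltaX.
#' @slot mean force-averaged per-ligand elongation, nm.
#' @slot se standard error of the force average, nm.
#' @export
setClass("SiteSizeElongation",
  representation(perForce = "data.frame", mean = "numeric", se = "numeric")
)

setValidity("SiteSizeElongation", function(object) {
  dx <- object@perForce$deltaX
  if (any(dx <= 0) || any(dx >= 0.5))
    "per-force elongations must lie in (0, 0.5) nm" else TRUE
})

#' Bell-model exponential force-dependence fit
#'
#' Fit of value(F) = value(0) exp(+/- x F / kT) in log space. The distance
#' sign convention is positive when force facilitates the process (rates
#' grow, Kd shrinks).
#'
#' @slot quantity one of "Kd", "k_on", "k_off", "k_a".
#' @slot zeroForceValue extrapolated zero-force value (nM, 1/s or 1/M/s).
#' @slot distance transition (or equilibrium) distance, nm.
#' @slot se named standard errors (bootstrap) for zeroForceValue and
#'   distance.
#' @slot cov covariance of (log zeroForceValue, distance).
#' @slot nPoints number of (force, value) points.
#' @export
setClass("BellFit",
  representation(
    quantity = "character",
    zeroForceValue = "numeric",
    distance = "numeric",
    se = "numeric",
    cov = "matrix",
    nPoints = "integer"
  )
)

setValidity("BellFit", function(object) {
  msgs <- character()
  if (object@zeroForceValue <= 0)
    msgs <- c(msgs, "zeroForceValue must be positive")
  if (abs(object@distance) >= 1)
    msgs <- c(msgs, "|distance| must be below 1 nm")
  if (!object@quantity %in% c("Kd", "k_on", "k_off", "k_a"))
    msgs <- c(msgs, "quantity must be Kd, k_on, k_off or k_a")
  if (length(msgs)) msgs else TRUE
})

#' Derived equilibrium and threading thermodynamics
#'
#' Result of [deriveThermodynamics()]: the per-ligand equilibrium elongation
#' by its three routes, the threading free energy from the depression of the
#' association rate below the diffusion limit, and the zero-force residence
#' half-life.
#'
#' @slot deltaXRoutes named numeric: `kd_bell` (Bell fit of Kd(F)),
#'   `site_size` (n * dLsat force average), `rate_split` (x_on - x_off);
#'   NA where a route's inputs were not supplied.
#' @slot routesAgree TRUE when all available routes agree pairwise within
#'   25 percent relative.
#' @slot gThreadKT threading free energy in units of kB T.
#' @slot gThreadKcal the same in kcal/mol at the configured temperature.
#' @slot kDif assumed diffusion-limited association rate, 1/M/s.
#' @slot kA0 zero-force association rate used, 1/M/s.
#' @slot halfLifeZeroForce zero-force residence half-life ln(2)/k_off(0),
#'   seconds (NA without an off-rate fit).
#' @slot conditions the [Conditions-class] used for unit conversions.
#' @export
setClass("DerivedThermodynamics",
  representation(
    deltaXRoutes = "numeric",
    routesAgree = "logical",
    gThreadKT = "numeric",
    gThreadKcal = "numeric",
    kDif = "numeric",
    kA0 = "numeric",
    halfLifeZeroForce = "numeric",
    conditions = "Conditions"
  )
)

#' Linear concentration dependence of a rate at one force
#'
#' Result of [associationRate()]: weighted regression of a rate on ligand
#' concentration. For the on rate the slope is the bimolecular association
#' rate k_a(F); for the off rate the slope should be consistent with zero.
#'
#' @slot force pN.
#' @slot quantity "kOn" or "kOff".
#' @slot slope per molar per second.
#' @slot intercept per second.
#' @slot se named standard errors of slope and intercept.
#' @slot cov covariance matrix.
#' @slot interceptZero TRUE when the intercept is within two standard
#'   errors of zero.
#' @slot slopeZero TRUE when the slope is within two standard errors of
#'   zero.
#' @slot nPoints number of concentrations.
#' @export
setClass("AssociationFit",
  representation(
    force = "numeric",
    quantity = "character",
    slope = "numeric",
    intercept = "numeric",
    se = "numeric",
    cov = "matrix",
    interceptZero = "logical",
    slopeZero = "logical",
    nPoints = "integer"
  )
)

#' Generating truth for synthetic force-clamp data
#'
#' A self-consistent parameter set for [simulateTrace()],
#' [simulateGrid()] and [gillespieLattice()]. The force-dependent rates are
#' Bell exponentials k_a(F) = kA0 exp(xOn F / kT) and
#' k_off(F) = kOff0 exp(xOff F / kT); the implied dissociation constant
#' Kd(F) = k_off(F)/k_a(F) feeds the McGhee-von Hippel equilibrium target.
#'
#' @slot kA0 zero-force bimolecular association rate, 1/M/s.
#' @slot kOff0 zero-force off rate, 1/s.
#' @slot xOn,xOff forward and reverse transition distances, nm
#'   (xOn > xOff > 0).
#' @slot siteSizeFn function force (pN) -> site size n (bp, >= 1).
#' @slot perLigandElongation equilibrium elongation per bound ligand, nm.
#' @slot bareWLC,satWLC [WLCParams-class] for bare DNA and the saturated
#'   complex.
#' @slot satModel "elongation" (L_sat = L_dna + dx/n(F)) or "wlc" (L_sat
#'   from satWLC).
#' @slot noiseSd i.i.d. Gaussian measurement noise, nm/bp.
#' @slot sampleInterval s.
#' @slot durationFactor trace duration in multiples of 1/k_total.
#' @slot conditions [Conditions-class].
#' @export
setClass("TruthParams",
  representation(
    kA0 = "numeric",
    kOff0 = "numeric",
    xOn = "numeric",
    xOff = "numeric",
    siteSizeFn = "function",
    perLigandElongation = "numeric",
    bareWLC = "WLCParams",
    satWLC = "WLCParams",
    satModel = "character",
    noiseSd = "numeric",
    sampleInterval = "numeric",
    durationFactor = "numeric",
    conditions = "Conditions"
  )
)

setValidity("TruthParams", function(object) {
  msgs <- character()
  if (object@kA0 <= 0 || object@kOff0 <= 0)
    msgs <- c(msgs, "zero-force rates must be positive")
  if (!(object@xOn > object@xOff))
    msgs <- c(msgs, "xOn must exceed xOff (binding must be force-facilitated)")
  if (object@xOff <= 0)
    msgs <- c(msgs, "xOff must be positive")
  nf <- try(vapply(c(1, 10, 30, 60, 65), object@siteSizeFn, numeric(1)),
            silent = TRUE)
  if (inherits(nf, "try-error") || any(nf < 1))
    msgs <- c(msgs, "siteSizeFn must return n >= 1 over (0, 65] pN")
  if (object@perLigandElongation <= 0)
    msgs <- c(msgs, "perLigandElongation must be positive")
  if (!object@satModel %in% c("elongation", "wlc"))
    msgs <- c(msgs, "satModel must be 'elongation' or 'wlc'")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be non-negative")
  if (object@sampleInterval <= 0 || object@durationFactor <= 0)
    msgs <- c(msgs, "sampleInterval and durationFactor must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory of the stochastic lattice simulator
#'
#' Event-resolved state of the Gillespie footprint-exclusion simulation.
#' Ligand footprints of `footprint` contiguous base pairs never overlap,
#' so boundCounts * footprint <= nSites at all times.
#'
#' @slot times event times, s (first element 0).
#' @slot boundCounts number of bound ligands after each event.
#' @slot nSites lattice length, bp.
#' @slot footprint integer site size used by the simulation, bp.
#' @slot extensions per-bp extension after each event, nm/bp.
#' @slot coverage time-averaged late-window fractional saturation
#'   (footprint * bound / nSites).
#' @slot force,concentration simulated condition.
#' @export
setClass("LatticeTrajectory",
  representation(
    times = "numeric",
    boundCounts = "numeric",
    nSites = "integer",
    footprint = "integer",
    extensions = "numeric",
    coverage = "numeric",
    force = "numeric",
    concentration = "numeric"
  )
)

setValidity("LatticeTrajectory", function(object) {
  if (any(object@boundCounts * object@footprint > object@nSites))
    "bound footprints exceed the lattice" else TRUE
})

#' Pipeline configuration
#'
#' Options controlling [runPipeline()]. The seed governs every stochastic
#' step (bootstraps) and is recorded in the report.
#'
#' @slot conditions [Conditions-class].
#' @slot bareWLC bare-DNA elasticity used for L_dna(F).
#' @slot satThreshold fitted occupancy of the highest-concentration
#'   condition above which its plateau is taken as L_sat directly; below
#'   it L_sat is fitted jointly with (Kd, n).
#' @slot nBootTrace bootstrap resamples for relaxation fits (0 = asymptotic
#'   covariance).
#' @slot nBootIsotherm bootstrap resamples for isotherm fits.
#' @slot nBootBell bootstrap resamples for Bell fits.
#' @slot refConcentration concentration (nM) at which the per-force on/off
#'   Bell fits are evaluated (nearest available is used).
#' @slot kDif diffusion-limited association rate, 1/M/s.
#' @slot weighted use inverse-variance weights in isotherm/Bell fits.
#' @slot seed integer RNG seed.
#' @export
setClass("PipelineConfig",
  representation(
    conditions = "Conditions",
    bareWLC = "WLCParams",
    satThreshold = "numeric",
    nBootTrace = "integer",
    nBootIsotherm = "integer",
    nBootBell = "integer",
    refConcentration = "numeric",
    kDif = "numeric",
    weighted = "logical",
    seed = "integer"
  )
)

#' Full analysis report
#'
#' Output of [runPipeline()]. Stages that could not run (degraded inputs)
#' leave their slot as NULL and add a warning string.
#'
#' @slot relaxation data.frame of per-trace relaxation fits.
#' @slot equilibrium data.frame of per-(force, concentration) equilibrium
#'   points: Leq, kTotal, theta and uncertainties.
#' @slot satTable data.frame of per-force L_sat with its source
#'   ("plateau" or "joint").
#' @slot satWLC [WLCFit-class] of L_sat(F), or NULL.
#' @slot isotherms named list of [IsothermFit-class], one per force.
#' @slot rates data.frame of split on/off rates per condition.
#' @slot associations named list of [AssociationFit-class] per force.
#' @slot kdBell,onBell,offBell,kaBell [BellFit-class] or NULL.
#' @slot siteSize [SiteSizeElongation-class] or NULL.
#' @slot thermo [DerivedThermodynamics-class] or NULL.
#' @slot warnings character vector of stage warnings.
#' @slot config the [PipelineConfig-class] used.
#' @export
setClass("AnalysisReport",
  representation(
    relaxation = "data.frame",
    equilibrium = "data.frame",
    satTable = "data.frame",
    satWLC = "ANY",
    isotherms = "list",
    rates = "data.frame",
    associations = "list",
    kdBell = "ANY",
    onBell = "ANY",
    offBell = "ANY",
    kaBell = "ANY",
    siteSize = "ANY",
    thermo = "ANY",
    warnings = "character",
    config = "PipelineConfig"
  )
)
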