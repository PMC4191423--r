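#' @include AllClasses.R
NULL

#' Accessors for threadclamp objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object from this package.
#' @return the corresponding scalar or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("thermalEnergy", function(x) standardGeneric("thermalEnergy"))
#' @rdname accessors
#' @export
setGeneric("temperatureK", function(x) standardGeneric("temperatureK"))
#' @rdname accessors
#' @export
setGeneric("bpCount", function(x) standardGeneric("bpCount"))
#' @rdname accessors
#' @export
setGeneric("contourPerBp", function(x) standardGeneric("contourPerBp"))
#' @rdname accessors
#' @export
setGeneric("persistenceLength", function(x) standardGeneric("persistenceLength"))
#' @rdname accessors
#' @export
setGeneric("stretchModulus", function(x) standardGeneric("stretchModulus"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("extensions", function(x) standardGeneric("extensions"))
#' @rdname accessors
#' @export
setGeneric("appliedForce", function(x) standardGeneric("appliedForce"))
#' @rdname accessors
#' @export
setGeneric("ligandConcentration", function(x) standardGeneric("ligandConcentration"))
#' @rdname accessors
#' @export
setGeneric("totalRate", function(x) standardGeneric("totalRate"))
#' @rdname accessors
#' @export
setGeneric("equilibriumExtension", function(x) standardGeneric("equilibriumExtension"))
#' @rdname accessors
#' @export
setGeneric("onRate", function(x) standardGeneric("onRate"))
#' @rdname accessors
#' @export
setGeneric("offRate", function(x) standardGeneric("offRate"))
#' @rdname accessors
#' @export
setGeneric("dissociationConstant", function(x) standardGeneric("dissociationConstant"))
#' @rdname accessors
#' @export
setGeneric("siteSize", function(x) standardGeneric("siteSize"))
#' @rdname accessors
#' @export
setGeneric("zeroForceValue", function(x) standardGeneric("zeroForceValue"))
#' @rdname accessors
#' @export
setGeneric("transitionDistance", function(x) standardGeneric("transitionDistance"))
#' @rdname accessors
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))
#' @rdname accessors
#' @export
setGeneric("latticeCoverage", function(x) standardGeneric("latticeCoverage"))

setMethod("thermalEnergy", "Conditions", function(x) x@thermalEnergy)
setMethod("temperatureK", "Conditions", function(x) x@temperature)
setMethod("bpCount", "Conditions", function(x) x@bpCount)
setMethod("contourPerBp", "Conditions", function(x) x@contourPerBp)
setMethod("contourPerBp", "WLCParams", function(x) x@contourPerBp)
setMethod("persistenceLength", "WLCParams", function(x) x@persistenceLength)
setMethod("stretchModulus", "WLCParams", function(x) x@stretchModulus)

setMethod("traceTimes", "ForceClampTrace", function(x) x@times)
setMethod("extensions", "ForceClampTrace", function(x) x@extensions)
setMethod("appliedForce", "ForceClampTrace", function(x) x@force)
setMethod("ligandConcentration", "ForceClampTrace", function(x) x@concentration)
#' @rdname accessors
#' @export
setMethod("length", "ForceClampTrace", function(x) length(x@times))

setMethod("totalRate", "RelaxationFit", function(x) x@kTotal)
setMethod("equilibriumExtension", "RelaxationFit", function(x) x@Leq)
setMethod("appliedForce", "RelaxationFit", function(x) x@force)
setMethod("ligandConcentration", "RelaxationFit", function(x) x@concentration)
setMethod("stdErrors", "RelaxationFit", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("coef", "RelaxationFit", function(object)
  c(L0 = object@L0, Leq = object@Leq, kTotal = object@kTotal))
#' @rdname accessors
#' @export
setMethod("vcov", "RelaxationFit", function(object) object@cov)

setMethod("onRate", "RateSet", function(x) x@kOn)
setMethod("offRate", "RateSet", function(x) x@kOff)
setMethod("totalRate", "RateSet", function(x) x@kTotal)
setMethod("appliedForce", "RateSet", function(x) x@force)
setMethod("ligandConcentration", "RateSet", function(x) x@concentration)

setMethod("dissociationConstant", "IsothermFit", function(x) x@Kd)
setMethod("siteSize", "IsothermFit", function(x) x@n)
setMethod("appliedForce", "IsothermFit", function(x) x@force)
setMethod("stdErrors", "IsothermFit", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("coef", "IsothermFit", function(object)
  c(Kd = object@Kd, n = object@n))
#' @rdname accessors
#' @export
setMethod("vcov", "IsothermFit", function(object) object@cov)

setMethod("zeroForceValue", "BellFit", function(x) x@zeroForceValue)
setMethod("transitionDistance", "BellFit", function(x) x@distance)
setMethod("stdErrors", "BellFit", function(x) x@se)

setMethod("persistenceLength", "WLCFit", function(x) x@persistenceLength)
setMethod("stdErrors", "WLCFit", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("coef", "WLCFit", function(object)
  c(persistenceLength = object@persistenceLength,
    stretchModulus = object@stretchModulus,
    contourPerBp = object@contourPerBp))

setMethod("latticeCoverage", "LatticeTrajectory", function(x) x@coverage)

setMethod("show", "Conditions", function(object) {
  cat("Conditions: ", object@temperature, " K (kT = ",
      format(object@thermalEnergy, digits = 5), " pN nm), ",
      object@bpCount, " bp, ", object@contourPerBp, " nm/bp\n", sep = "")
})

setMethod("show", "WLCParams", function(object) {
  cat("Extensible WLC: Lp = ", format(object@persistenceLength, digits = 4),
      " nm, S = ", format(object@stretchModulus, digits = 4),
      " pN, L0 = ", format(object@contourPerBp, digits = 4), " nm/bp\n",
      sep = "")
})

setMethod("show", "WLCFit", function(object) {
  callNextMethod()
  cat("  se: ", paste(names(object@se),
      format(object@se, digits = 3), sep = " = ", collapse = ", "),
      "  (", object@nPoints, " points, rms ",
      format(object@residualNorm, digits = 3), ")\n", sep = "")
})

setMethod("show", "ForceClampTrace", function(object) {
  cat("ForceClampTrace '", object@label, "': ", length(object@times),
      " samples, F = ", object@force, " pN, C = ", object@concentration,
      " nM, t = [", format(min(object@times), digits = 4), ", ",
      format(max(object@times), digits = 4), "] s\n", sep = "")
})

setMethod("show", "RelaxationFit", function(object) {
  cat("RelaxationFit (F = ", object@force, " pN, C = ",
      object@concentration, " nM): L0 = ",
      format(object@L0, digits = 5), ", Leq = ",
      format(object@Leq, digits = 5), " nm/bp, kTotal = ",
      format(object@kTotal, digits = 4), " 1/s, R2 = ",
      format(object@rSquared, digits = 4),
      if (!object@converged) "  [UNCONVERGED]" else "", "\n", sep = "")
})

setMethod("show", "IsothermFit", function(object) {
  cat("IsothermFit at ", object@force, " pN: Kd = ",
      format(object@Kd, digits = 4), " nM, n = ",
      format(object@n, digits = 4), " bp",
      if (object@nonIdentifiable) "  [NON-IDENTIFIABLE]" else "",
      "\n", sep = "")
})

setMethod("show", "BellFit", function(object) {
  cat("BellFit[", object@quantity, "]: value(0) = ",
      format(object@zeroForceValue, digits = 4), ", distance = ",
      format(object@distance, digits = 3), " nm (", object@nPoints,
      " points)\n", sep = "")
})

setMethod("show", "RateSet", function(object) {
  cat("RateSet with", length(object@kOn), "conditions\n")
  print(data.frame(force = object@force,
                   concentration = object@concentration,
                   kOn = object@kOn, kOff = object@kOff))
})

setMethod("show", "AssociationFit", function(object) {
  cat("AssociationFit[", object@quantity, "] at ", object@force,
      " pN: slope = ", format(object@slope, digits = 4),
      " 1/M/s, intercept = ", format(object@intercept, digits = 3),
      " 1/s\n", sep = "")
})

setMethod("show", "SiteSizeElongation", function(object) {
  cat("Site-size route: dxEq = ", format(object@mean, digits = 3),
      " +/- ", format(object@se, digits = 2), " nm over ",
      nrow(object@perForce), " forces\n", sep = "")
})

setMethod("show", "DerivedThermodynamics", function(object) {
  cat("DerivedThermodynamics:\n  dxEq routes (nm): ",
      paste(names(object@deltaXRoutes),
            format(object@deltaXRoutes, digits = 3),
            sep = " = ", collapse = ", "), "\n",
      "  G_thread = ", format(object@gThreadKT, digits = 4), " kBT = ",
      format(object@gThreadKcal, digits = 3), " kcal/mol\n",
      "  zero-force half-life = ",
      format(object@halfLifeZeroForce / 3600, digits = 3), " h\n", sep = "")
})

setMethod("show", "TruthParams", function(object) {
  kd0 <- object@kOff0 / object@kA0 * 1e9
  cat("TruthParams: kA0 = ", format(object@kA0, digits = 4),
      " 1/M/s, kOff0 = ", format(object@kOff0, digits = 4),
      " 1/s  (implied Kd(0) = ", format(kd0, digits = 4), " nM)\n",
      "  xOn = ", object@xOn, " nm, xOff = ", object@xOff,
      " nm (dxEq = ", format(object@xOn - object@xOff, digits = 3),
      " nm), satModel = ", object@satModel, "\n", sep = "")
})

setMethod("show", "LatticeTrajectory", function(object) {
  cat("LatticeTrajectory: N = ", object@nSites, " bp, footprint = ",
      object@footprint, " bp, ", length(object@times),
      " events, late-window coverage = ",
      format(object@coverage, digits = 4), "\n", sep = "")
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport:", nrow(object@relaxation), "trace fits,",
      nrow(object@equilibrium), "equilibrium points,",
      length(object@isotherms), "isotherm fits\n")
  if (!is.null(object@kdBell))
    cat("  Kd(0) = ", format(object@kdBell@zeroForceValue, digits = 4),
        " nM, dxEq = ", format(object@kdBell@distance, digits = 3),
        " nm\n", sep = "")
  if (!is.null(object@thermo))
    cat("  G_thread = ", format(object@thermo@gThreadKT, digits = 4),
        " kBT\n", sep = "")
  if (length(object@warnings))
    cat("  warnings:", length(object@warnings), "\n")
})
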