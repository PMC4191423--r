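#' @include AllClasses.R
NULL

#' Construct experimental conditions
#'
#' Defaults describe the reference experiment: 21 C, a single lambda-DNA
#' construct of 48502 bp, 0.34 nm base-pair rise. The thermal energy is
#' derived (kB * T, 4.061 pN nm at 294.15 K) and used in every Bell
#' exponent.
#'
#' @param temperature kelvin.
#' @param bpCount base pairs in the construct.
#' @param contourPerBp bare contour length per base pair, nm.
#' @return a [Conditions-class] object.
#' @examples
#' cond <- Conditions()
#' thermalEnergy(cond) # ~4.061 pN nm
#' @export
Conditions <- function(temperature = 294.15, bpCount = 48502,
                       contourPerBp = 0.34) {
  new("Conditions", temperature = temperature,
      thermalEnergy = .kB * temperature,
      bpCount = bpCount, contourPerBp = contourPerBp)
}

#' Construct worm-like-chain parameters
#'
#' @param persistenceLength nm (>= 0.5; the continuum model is rejected
#'   below that).
#' @param stretchModulus pN.
#' @param contourPerBp nm per base pair.
#' @return a [WLCParams-class] object.
#' @examples
#' bareDNA()      # standard B-DNA elasticity
#' WLCParams(1.6, 598, 0.34)
#' @export
WLCParams <- function(persistenceLength, stretchModulus, contourPerBp) {
  new("WLCParams", persistenceLength = persistenceLength,
      stretchModulus = stretchModulus, contourPerBp = contourPerBp)
}

#' @rdname WLCParams
#' @export
bareDNA <- function() WLCParams(50, 1000, 0.34)

#' Construct a force-clamp trace
#'
#' @param times sample times in seconds, strictly increasing; time zero is
#'   the first recorded sample (after the initial force ramp).
#' @param extensions per-base-pair extensions, nm/bp, in (0, 0.7).
#' @param force constant applied force, pN, in (0, 65].
#' @param concentration ligand concentration, nM.
#' @param label free-text identifier.
#' @param meta optional list of provenance fields.
#' @return a [ForceClampTrace-class] object.
#' @export
ForceClampTrace <- function(times, extensions, force, concentration,
                            label = "", meta = list()) {
  new("ForceClampTrace", times = as.numeric(times),
      extensions = as.numeric(extensions), force = force,
      concentration = concentration, label = label, meta = meta)
}

# relative extension z solving the extensible Marko-Siggia force balance
# F = (kT/Lp) * (1/(4(1-z)^2) - 1/4 + z); scalar force. Bracketed root
# polished by Newton to 1e-10 relative in z.
.msRelExtension <- function(force, kTLp) {
  f <- function(z) kTLp * (0.25 / (1 - z)^2 - 0.25 + z) - force
  r <- tryCatch(
    stats::uniroot(f, lower = 0, upper = 1 - 1e-12, tol = 1e-13,
                   maxiter = 2000),
    error = function(e) stop("WLC root solve failed (force = ", force,
                             " pN): invalid parameters", call. = FALSE))
  z <- r$root
  for (i in 1:50) {
    dz <- f(z) / (kTLp * (0.5 / (1 - z)^3 + 1))
    zNew <- min(max(z - dz, 0), 1 - 1e-12)
    if (abs(zNew - z) <= 1e-10 * max(z, 1e-6)) return(zNew)
    z <- zNew
  }
  stop("WLC root solve did not converge to 1e-10 relative", call. = FALSE)
}

#' Extensible worm-like-chain extension at a force
#'
#' Per-base-pair extension of the extensible Marko-Siggia interpolation,
#' solved numerically: the entropic force balance
#' F = (kT/Lp) (1/(4 (1 - x/L)^2) - 1/4 + x/L) is inverted for the relative
#' extension and the enthalpic stretch term F/S is added, so
#' x = L0 (z + F/S). Strictly increasing in force and approaching
#' L0 (1 + F/S) minus the entropic correction at high force.
#'
#' @param force pN; scalar or vector in (0, 65].
#' @param params [WLCParams-class].
#' @param conditions [Conditions-class] supplying kT.
#' @return per-bp extension(s), nm.
#' @examples
#' wlcExtension(10, bareDNA()) # ~0.325 nm/bp
#' @export
wlcExtension <- function(force, params, conditions = Conditions()) {
  stopifnot(is(params, "WLCParams"), is(conditions, "Conditions"))
  if (any(force <= 0) || any(force > 65))
    stop("force must lie in (0, 65] pN", call. = FALSE)
  kTLp <- thermalEnergy(conditions) / persistenceLength(params)
  z <- vapply(force, .msRelExtension, numeric(1), kTLp = kTLp)
  contourPerBp(params) * (z + force / stretchModulus(params))
}

#' Fit worm-like-chain elasticity to force-extension points
#'
#' Levenberg-Marquardt least squares of [wlcExtension()] to measured
#' (force, extension) pairs, with multistart over persistence-length
#' initialisations. Uncertainties come from a seeded residual bootstrap.
#'
#' @param points data.frame with columns `force` (pN) and `extension`
#'   (nm/bp); at least 4 points spanning at least 20 pN.
#' @param conditions [Conditions-class].
#' @param fixedContour optional contour length per bp to hold fixed; when
#'   NULL the contour is a third fitted parameter.
#' @param nBoot bootstrap resamples for the standard errors (default 500).
#' @param seed RNG seed for the bootstrap.
#' @return a [WLCFit-class].
#' @export
fitWLC <- function(points, conditions = Conditions(), fixedContour = NULL,
                   nBoot = 500, seed = 1) {
  stopifnot(is.data.frame(points),
            all(c("force", "extension") %in% names(points)))
  f <- points$force
  x <- points$extension
  if (length(unique(f)) < 2 || diff(range(f)) < 1e-9)
    stop("degenerate input: all forces equal", call. = FALSE)
  if (nrow(points) < 4)
    stop("underdetermined: need at least 4 (force, extension) points",
         call. = FALSE)
  if (diff(range(f)) < 20)
    stop("force range must span at least 20 pN", call. = FALSE)

  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                     ptol = 1e-14)
  fitOnce <- function(x, startAt = NULL) {
    starts <- if (is.null(startAt)) {
      lapply(c(1, 3, 10, 50), function(lp0)
        if (is.null(fixedContour))
          list(lp = lp0, s = 1000, l0 = max(x) * 1.02)
        else list(lp = lp0, s = 1000))
    } else list(as.list(startAt))
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        if (is.null(fixedContour))
          minpack.lm::nlsLM(
            x ~ wlcExtension(f, WLCParams(lp, s, l0), conditions),
            start = st,
            lower = c(0.5, 1, 0.05), upper = c(1000, 1e9, 0.7),
            control = ctrl)
        else
          minpack.lm::nlsLM(
            x ~ wlcExtension(f, WLCParams(lp, s, fixedContour),
                             conditions),
            start = st,
            lower = c(0.5, 1), upper = c(1000, 1e9), control = ctrl),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || deviance(fit) < deviance(best)))
        best <- fit
    }
    if (is.null(best)) stop("WLC fit failed to converge", call. = FALSE)
    best
  }

  fit <- fitOnce(x)
  est <- coef(fit)
  lp <- est[["lp"]]; s <- est[["s"]]
  l0 <- if (is.null(fixedContour)) est[["l0"]] else fixedContour
  pred <- wlcExtension(f, WLCParams(lp, s, l0), conditions)
  resid <- x - pred
  rms <- sqrt(mean(resid^2))

  nPar <- length(est)
  if (nBoot > 0) {
    boots <- withr::with_seed(seed, {
      replicate(nBoot, {
        xb <- pred + sample(resid, length(resid), replace = TRUE)
        tryCatch(coef(fitOnce(xb, startAt = est)),
                 error = function(e) rep(NA_real_, nPar))
      })
    })
    boots <- matrix(boots, nrow = nPar)
    se <- apply(boots, 1, stats::sd, na.rm = TRUE)
    cov <- stats::cov(t(boots), use = "complete.obs")
  } else {
    cov <- tryCatch(suppressWarnings(stats::vcov(fit)), error = function(e)
      matrix(NA_real_, nPar, nPar))
    se <- sqrt(pmax(diag(cov), 0))
  }
  nm <- c("persistenceLength", "stretchModulus",
          if (is.null(fixedContour)) "contourPerBp")
  names(se) <- nm
  dimnames(cov) <- list(nm, nm)
  new("WLCFit", persistenceLength = lp, stretchModulus = s,
      contourPerBp = l0, se = se, cov = cov,
      nPoints = nrow(points), residualNorm = rms)
}

#' Fractional occupancy from an equilibrium extension
#'
#' Theta = (Leq - Ldna) / (Lsat - Ldna), the bound-ligand-induced
#' elongation as a fraction of the saturated elongation at the same force.
#' Values pushed outside \\[0, 1\\] by measurement noise are clamped and the
#' number of clamping events is reported via the `"nClamped"` attribute and
#' a message.
#'
#' @param Leq equilibrium extension(s), nm/bp.
#' @param Ldna bare-DNA extension at the same force, nm/bp.
#' @param Lsat saturated-complex extension at the same force, nm/bp; must
#'   exceed `Ldna`.
#' @return occupancies in \\[0, 1\\] with attribute `nClamped`.
#' @export
fractionalOccupancy <- function(Leq, Ldna, Lsat) {
  if (any(Lsat <= Ldna))
    stop("inconsistent elasticity inputs: Lsat must exceed Ldna",
         call. = FALSE)
  theta <- (Leq - Ldna) / (Lsat - Ldna)
  nClamped <- sum(theta < 0 | theta > 1)
  if (nClamped > 0)
    message("fractionalOccupancy: clamped ", nClamped,
            " value(s) to [0, 1]")
  theta <- pmin(pmax(theta, 0), 1)
  attr(theta, "nClamped") <- nClamped
  theta
}

#' Mixture extension from an occupancy
#'
#' The equilibrium extension of a partially bound molecule as the linear
#' combination (1 - theta) Ldna + theta Lsat; the exact inverse of
#' [fractionalOccupancy()].
#'
#' @param theta occupancy in \\[0, 1\\].
#' @param Ldna,Lsat bare and saturated extensions at the same force, nm/bp.
#' @return extension(s), nm/bp.
#' @export
mixtureExtension <- function(theta, Ldna, Lsat) {
  if (any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]", call. = FALSE)
  (1 - theta) * Ldna + theta * Lsat
}
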