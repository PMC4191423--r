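#' @include kinetics.R isotherm.R bell.R io.R
NULL

#' Build a pipeline configuration
#'
#' @param conditions [Conditions-class].
#' @param bareWLC bare-DNA elasticity used to evaluate L_dna(F).
#' @param satThreshold occupancy above which the highest-concentration
#'   plateau is used directly as L_sat (default 0.95); otherwise L_sat is
#'   fitted jointly with (Kd, n).
#' @param nBootTrace,nBootIsotherm,nBootBell bootstrap resample counts per
#'   stage (0 = asymptotic errors).
#' @param refConcentration nM; the concentration (nearest available) at
#'   which the per-force on/off Bell fits are evaluated.
#' @param kDif diffusion-limited association rate, 1/M/s.
#' @param weighted inverse-variance weighting in isotherm/Bell fits.
#' @param seed integer seed governing all bootstraps.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(conditions = Conditions(), bareWLC = bareDNA(),
                           satThreshold = 0.95, nBootTrace = 0,
                           nBootIsotherm = 200, nBootBell = 500,
                           refConcentration = 5, kDif = 1e9,
                           weighted = FALSE, seed = 1) {
  new("PipelineConfig", conditions = conditions, bareWLC = bareWLC,
      satThreshold = satThreshold, nBootTrace = as.integer(nBootTrace),
      nBootIsotherm = as.integer(nBootIsotherm),
      nBootBell = as.integer(nBootBell),
      refConcentration = refConcentration, kDif = kDif,
      weighted = weighted, seed = as.integer(seed))
}

# joint (Kd, n, Lsat) fit of Leq(C) at one force, Ldna fixed
.fitIsothermLsat <- function(conc, leq, Ldna) {
  lsat0 <- max(leq) + 0.25 * (max(leq) - Ldna)
  pos <- conc > 0
  kd0 <- max(conc[pos][which.min(abs(leq[pos] - (Ldna + lsat0) / 2))],
             min(conc[pos]))
  best <- NULL
  for (n0 in 1:5) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        leq ~ Ldna + mvhCoverage(conc, exp(lKd), n) * (Lsat - Ldna),
        start = list(lKd = log(kd0), n = n0, Lsat = lsat0),
        lower = c(-25, 1, Ldna + 1e-6), upper = c(25, 50, 0.7),
        control = minpack.lm::nls.lm.control(maxiter = 150,
                                             ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best)))
      best <- fit
  }
  if (is.null(best))
    stop("joint (Kd, n, Lsat) fit failed to converge", call. = FALSE)
  cf <- coef(best)
  list(Kd = exp(cf[["lKd"]]), n = cf[["n"]], Lsat = cf[["Lsat"]])
}

#' Run the full force-clamp analysis pipeline
#'
#' Stage order: (1) single-exponential fit of every trace; (2) per-force
#' saturated extension L_sat(F) - taken from the highest-concentration
#' plateau when its fitted occupancy exceeds `satThreshold`, otherwise
#' fitted jointly with (Kd, n) - followed by a worm-like-chain fit of
#' L_sat(F); (3) occupancies from the extension mixture; (4) per-force
#' McGhee-von Hippel fits; (5) Bell fit of Kd(F); (6) on/off rate
#' splitting and per-force association-rate slopes; (7) Bell fits of the
#' rates; (8) derived thermodynamics. Stage failures abort downstream
#' stages and are reported as warnings, never silently skipped. With a
#' single force or fewer than three concentrations the report is degraded
#' (later stages NULL) with explanatory warnings. Deterministic given the
#' traces and the config seed.
#'
#' @param traces list of [ForceClampTrace-class] objects, or a directory
#'   path of trace CSVs with sidecars.
#' @param config a [PipelineConfig-class].
#' @return an [AnalysisReport-class].
#' @examples
#' g <- simulateGrid(makeTruth(), c(40, 60), c(10, 50, 150), seed = 3)
#' rep <- runPipeline(g$traces, pipelineConfig(nBootIsotherm = 0))
#' @export
runPipeline <- function(traces, config = pipelineConfig()) {
  stopifnot(is(config, "PipelineConfig"))
  if (is.character(traces)) traces <- readTraceDir(traces)
  if (!length(traces))
    stop("configuration error: no input traces", call. = FALSE)
  stopifnot(all(vapply(traces, is, logical(1), "ForceClampTrace")))
  warns <- character()
  cond <- config@conditions

  ## stage 1: relaxation fits
  relaxFits <- list()
  for (i in seq_along(traces)) {
    f <- tryCatch(fitRelaxation(traces[[i]], nBoot = config@nBootTrace,
                                seed = config@seed + i),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warns <- c(warns, paste0("trace ", i, " (",
                               traces[[i]]@label, "): ",
                               conditionMessage(f)))
    } else {
      if (!f@converged)
        warns <- c(warns, paste0("trace ", i, " (", traces[[i]]@label,
                                 "): unconverged (span < 2/kTotal)"))
      relaxFits[[length(relaxFits) + 1L]] <- f
    }
  }
  if (!length(relaxFits))
    stop("all relaxation fits failed; nothing to analyse", call. = FALSE)
  relax <- do.call(rbind, lapply(relaxFits, function(f)
    data.frame(force = f@force, concentration = f@concentration,
               L0 = f@L0, Leq = f@Leq, kTotal = f@kTotal,
               LeqSe = f@se[["Leq"]], kTotalSe = f@se[["kTotal"]],
               rSquared = f@rSquared, converged = f@converged)))

  ## aggregate replicates per (force, concentration)
  key <- interaction(relax$force, relax$concentration, drop = TRUE)
  agg <- do.call(rbind, lapply(split(relax, key), function(d) {
    r <- nrow(d)
    data.frame(force = d$force[1], concentration = d$concentration[1],
               Leq = mean(d$Leq),
               LeqSe = if (r > 1) stats::sd(d$Leq) / sqrt(r)
                       else d$LeqSe[1],
               kTotal = mean(d$kTotal),
               kTotalSe = if (r > 1) stats::sd(d$kTotal) / sqrt(r)
                          else d$kTotalSe[1],
               nTraces = r)
  }))
  agg <- agg[order(agg$force, agg$concentration), ]
  rownames(agg) <- NULL
  forces <- sort(unique(agg$force))

  ## stage 2: per-force L_sat
  satRows <- list()
  nClampedTotal <- 0L
  for (f in forces) {
    d <- agg[agg$force == f, ]
    Ldna <- wlcExtension(f, config@bareWLC, cond)
    if (length(unique(d$concentration)) < 4 ||
        {pc <- d$concentration[d$concentration > 0]
         max(pc) / min(pc) < 10}) {
      warns <- c(warns, paste0("force ", f,
                               " pN: too few concentrations for an ",
                               "isotherm; L_sat not determined"))
      next
    }
    joint <- tryCatch(.fitIsothermLsat(d$concentration, d$Leq, Ldna),
                      error = function(e) e)
    if (inherits(joint, "error")) {
      warns <- c(warns, paste0("force ", f, " pN: ",
                               conditionMessage(joint)))
      next
    }
    cmax <- max(d$concentration)
    thetaMax <- mvhCoverage(cmax, joint$Kd, joint$n)
    if (thetaMax > config@satThreshold) {
      lsat <- d$Leq[d$concentration == cmax][1]
      src <- "plateau"
    } else {
      lsat <- joint$Lsat
      src <- "joint"
    }
    satRows[[length(satRows) + 1L]] <-
      data.frame(force = f, Ldna = Ldna, Lsat = lsat, source = src)
  }
  satTable <- if (length(satRows)) do.call(rbind, satRows) else
    data.frame(force = numeric(), Ldna = numeric(), Lsat = numeric(),
               source = character())

  satWLC <- NULL
  if (nrow(satTable) >= 4 && diff(range(satTable$force)) >= 20) {
    satWLC <- tryCatch(
      fitWLC(data.frame(force = satTable$force,
                        extension = satTable$Lsat),
             cond, nBoot = min(config@nBootBell, 200L),
             seed = config@seed + 7L),
      error = function(e) {
        warns <<- c(warns, paste0("saturated WLC fit: ",
                                  conditionMessage(e)))
        NULL
      })
  } else {
    warns <- c(warns,
               "saturated WLC fit skipped: need >= 4 forces spanning 20 pN")
  }

  ## stage 3: occupancies
  agg$theta <- NA_real_
  agg$thetaSe <- NA_real_
  for (i in seq_len(nrow(satTable))) {
    f <- satTable$force[i]
    sel <- agg$force == f
    th <- suppressMessages(
      fractionalOccupancy(agg$Leq[sel], satTable$Ldna[i],
                          satTable$Lsat[i]))
    nClampedTotal <- nClampedTotal + attr(th, "nClamped")
    agg$theta[sel] <- as.numeric(th)
    agg$thetaSe[sel] <- agg$LeqSe[sel] /
      (satTable$Lsat[i] - satTable$Ldna[i])
  }
  if (nClampedTotal > 0)
    warns <- c(warns, paste0("occupancy clamped to [0, 1] for ",
                             nClampedTotal, " equilibrium point(s)"))

  ## stage 4: per-force isotherm fits
  isotherms <- list()
  for (i in seq_len(nrow(satTable))) {
    f <- satTable$force[i]
    d <- agg[agg$force == f & !is.na(agg$theta), ]
    fit <- tryCatch(
      fitIsotherm(data.frame(concentration = d$concentration,
                             theta = d$theta, sd = d$thetaSe),
                  force = f, nBoot = config@nBootIsotherm,
                  seed = config@seed + 100L + i,
                  weighted = config@weighted),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warns <- c(warns, paste0("isotherm at ", f, " pN: ",
                               conditionMessage(fit)))
      next
    }
    fit@Lsat <- satTable$Lsat[i]
    if (fit@nonIdentifiable)
      warns <- c(warns, paste0("isotherm at ", f,
                               " pN: non-identifiable Kd (rel. SE > 100%)"))
    isotherms[[as.character(f)]] <- fit
  }

  ## stage 5: Bell fit of Kd(F)
  kdBell <- NULL
  if (length(isotherms) >= 3) {
    kdPts <- data.frame(
      force = vapply(isotherms, appliedForce, numeric(1)),
      value = vapply(isotherms, dissociationConstant, numeric(1)),
      se = vapply(isotherms, function(x) x@se[["Kd"]], numeric(1)))
    kdBell <- tryCatch(
      bellFit(kdPts, "Kd", cond, nBoot = config@nBootBell,
              seed = config@seed + 200L, weighted = config@weighted),
      error = function(e) {
        warns <<- c(warns, paste0("Kd Bell fit: ", conditionMessage(e)))
        NULL
      })
  } else {
    warns <- c(warns, "Kd Bell fit skipped: need >= 3 forces")
  }

  ## stage 6: rate splitting and association rates
  rates <- data.frame()
  associations <- list()
  if (length(isotherms)) {
    rateRows <- list()
    for (f in names(isotherms)) {
      fv <- isotherms[[f]]@force
      d <- agg[agg$force == fv, ]
      rs <- splitRates(d$kTotal, isotherms[[f]]@Kd, d$concentration,
                       force = fv, kTotalSe = d$kTotalSe)
      rateRows[[f]] <- data.frame(force = rs@force,
                                  concentration = rs@concentration,
                                  kTotal = rs@kTotal, kOn = rs@kOn,
                                  kOff = rs@kOff,
                                  kOnSe = rs@se$kOn, kOffSe = rs@se$kOff)
      af <- tryCatch(associationRate(rs, "kOn",
                                     weighted = config@weighted),
                     error = function(e) e)
      if (inherits(af, "error")) {
        warns <- c(warns, paste0("association rate at ", f, " pN: ",
                                 conditionMessage(af)))
      } else {
        if (!af@interceptZero)
          warns <- c(warns, paste0("association fit at ", f,
                                   " pN: intercept not consistent with 0"))
        associations[[f]] <- af
      }
    }
    rates <- do.call(rbind, rateRows)
    rownames(rates) <- NULL
  }

  ## stage 7: Bell fits of the rates
  onBell <- offBell <- kaBell <- NULL
  if (nrow(rates) && length(unique(rates$force)) >= 3) {
    refC <- unique(rates$concentration)
    refC <- refC[which.min(abs(refC - config@refConcentration))]
    dref <- rates[rates$concentration == refC, ]
    onBell <- tryCatch(
      bellFit(data.frame(force = dref$force, value = dref$kOn,
                         se = dref$kOnSe),
              "k_on", cond, nBoot = config@nBootBell,
              seed = config@seed + 300L, weighted = config@weighted),
      error = function(e) {
        warns <<- c(warns, paste0("k_on Bell fit: ", conditionMessage(e)))
        NULL
      })
    offBell <- tryCatch(
      bellFit(data.frame(force = dref$force, value = dref$kOff,
                         se = dref$kOffSe),
              "k_off", cond, nBoot = config@nBootBell,
              seed = config@seed + 301L, weighted = config@weighted),
      error = function(e) {
        warns <<- c(warns, paste0("k_off Bell fit: ", conditionMessage(e)))
        NULL
      })
    if (length(associations) >= 3) {
      kaPts <- data.frame(
        force = vapply(associations, function(a) a@force, numeric(1)),
        value = vapply(associations, function(a) a@slope, numeric(1)),
        se = vapply(associations, function(a) a@se[["slope"]],
                    numeric(1)))
      kaBell <- tryCatch(
        bellFit(kaPts, "k_a", cond, nBoot = config@nBootBell,
                seed = config@seed + 302L, weighted = config@weighted),
        error = function(e) {
          warns <<- c(warns, paste0("k_a Bell fit: ", conditionMessage(e)))
          NULL
        })
    }
  } else {
    warns <- c(warns,
               "rate Bell fits skipped: need >= 3 forces with split rates")
  }

  ## stage 8: derived thermodynamics
  siteSizeRoute <- NULL
  if (length(isotherms) >= 2 && nrow(satTable) >= 2) {
    fs <- vapply(isotherms, appliedForce, numeric(1))
    sat <- satTable[match(fs, satTable$force), ]
    siteSizeRoute <- tryCatch(
      deltaXFromSiteSize(unname(isotherms),
                         data.frame(force = sat$force,
                                    dLsat = sat$Lsat - sat$Ldna)),
      error = function(e) {
        warns <<- c(warns, paste0("site-size route: ",
                                  conditionMessage(e)))
        NULL
      })
  }
  thermo <- NULL
  if (!is.null(kaBell)) {
    thermo <- tryCatch(
      deriveThermodynamics(kdBell = kdBell, onBell = onBell,
                           offBell = offBell, kaBell = kaBell,
                           siteSize = siteSizeRoute, kDif = config@kDif,
                           conditions = cond),
      error = function(e) {
        warns <<- c(warns, paste0("thermodynamics: ",
                                  conditionMessage(e)))
        NULL
      })
  } else {
    warns <- c(warns, "thermodynamics skipped: no k_a Bell fit")
  }

  new("AnalysisReport", relaxation = relax, equilibrium = agg,
      satTable = satTable, satWLC = satWLC, isotherms = isotherms,
      rates = rates, associations = associations, kdBell = kdBell,
      onBell = onBell, offBell = offBell, kaBell = kaBell,
      siteSize = siteSizeRoute, thermo = thermo, warnings = warns,
      config = config)
}
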