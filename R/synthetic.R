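#' @include core-model.R isotherm.R
NULL

# default site-size schedule: linear between (10 pN, 3.7 bp) and
# (60 pN, 1.7 bp), clamped outside that range
.defaultSiteSizeFn <- function(force) {
  n <- 3.7 + (force - 10) * (1.7 - 3.7) / 50
  pmin(pmax(n, 1.7), 3.7)
}

#' Build a self-consistent generating truth
#'
#' Assembles a [TruthParams-class] whose defaults reproduce the study
#' conditions of the reference experiment: zero-force association rate
#' 1.01e4 1/M/s, zero-force off rate 4.44e-4 1/s (implied Kd(0) ~44 nM),
#' forward/reverse transition distances 0.33/0.14 nm, site size falling
#' linearly from 3.7 bp at 10 pN to 1.7 bp at 60 pN, standard B-DNA bare
#' elasticity, saturated-complex elasticity Lp = 1.6 nm / S = 598 pN,
#' Gaussian measurement noise of 1e-4 nm/bp and 200 ms sampling.
#'
#' @param kA0 zero-force association rate, 1/M/s.
#' @param kOff0 zero-force off rate, 1/s.
#' @param xOn,xOff transition distances, nm; xOn must exceed xOff.
#' @param siteSizeFn function force -> site size; NULL for the default
#'   linear schedule.
#' @param perLigandElongation nm; NULL defaults to xOn - xOff.
#' @param bareWLC,satWLC [WLCParams-class] for the two states.
#' @param satModel "elongation" (default; L_sat(F) = L_dna(F) +
#'   perLigandElongation / n(F), so the site-size route is exact by
#'   construction) or "wlc" (L_sat(F) from `satWLC`).
#' @param noiseSd nm/bp.
#' @param sampleInterval s.
#' @param durationFactor trace length in multiples of 1/k_total.
#' @param conditions [Conditions-class].
#' @return a [TruthParams-class]; printing it logs the implied Kd(0) and
#'   dxEq.
#' @examples
#' makeTruth() # implied Kd(0) ~44 nM
#' @export
makeTruth <- function(kA0 = 1.01e4, kOff0 = 4.44e-4, xOn = 0.33,
                      xOff = 0.14, siteSizeFn = NULL,
                      perLigandElongation = NULL,
                      bareWLC = bareDNA(),
                      satWLC = WLCParams(1.6, 598, 0.45),
                      satModel = c("elongation", "wlc"),
                      noiseSd = 1e-4, sampleInterval = 0.2,
                      durationFactor = 5, conditions = Conditions()) {
  satModel <- match.arg(satModel)
  if (is.null(siteSizeFn)) siteSizeFn <- .defaultSiteSizeFn
  if (is.null(perLigandElongation)) perLigandElongation <- xOn - xOff
  new("TruthParams", kA0 = kA0, kOff0 = kOff0, xOn = xOn, xOff = xOff,
      siteSizeFn = siteSizeFn, perLigandElongation = perLigandElongation,
      bareWLC = bareWLC, satWLC = satWLC, satModel = satModel,
      noiseSd = noiseSd, sampleInterval = sampleInterval,
      durationFactor = durationFactor, conditions = conditions)
}

#' Force-dependent truth values implied by a generating parameter set
#'
#' Evaluates the Bell rates, implied dissociation constant, site size and
#' the bare/saturated extensions of a [TruthParams-class] at one or more
#' forces (and optionally a concentration, for the net rate).
#'
#' @param truth a [TruthParams-class].
#' @param force pN (vectorised).
#' @param concentration optional nM; adds kTotal and thetaEq columns.
#' @return data.frame with columns force, kA (1/M/s), kOff (1/s), Kd (nM),
#'   n (bp), Ldna, Lsat (nm/bp) and, given a concentration, kTotal (1/s)
#'   and thetaEq.
#' @export
truthAt <- function(truth, force, concentration = NULL) {
  stopifnot(is(truth, "TruthParams"))
  kT <- thermalEnergy(truth@conditions)
  kA <- truth@kA0 * exp(truth@xOn * force / kT)
  kOff <- truth@kOff0 * exp(truth@xOff * force / kT)
  kdNM <- kOff / kA * 1e9
  n <- vapply(force, truth@siteSizeFn, numeric(1))
  ldna <- wlcExtension(force, truth@bareWLC, truth@conditions)
  lsat <- if (truth@satModel == "elongation")
    ldna + truth@perLigandElongation / n
  else wlcExtension(force, truth@satWLC, truth@conditions)
  out <- data.frame(force = force, kA = kA, kOff = kOff, Kd = kdNM, n = n,
                    Ldna = ldna, Lsat = lsat)
  if (!is.null(concentration)) {
    out$concentration <- concentration
    out$kTotal <- kA * concentration * 1e-9 + kOff
    out$thetaEq <- mapply(function(kd, nn) mvhCoverage(concentration, kd, nn),
                          kdNM, n)
  }
  out
}

#' Simulate one force-clamp trace
#'
#' Deterministic relaxation kernel plus i.i.d. Gaussian noise. The
#' occupancy relaxes as theta(t) = thetaEq (1 - exp(-kTotal t)) with
#' kTotal = k_a(F) C + k_off(F) (Bell rates from the truth) and thetaEq
#' from the McGhee-von Hippel isotherm at the implied Kd(F) and n(F); the
#' extension is the worm-like-chain mixture
#' L(t) = L_dna(F) + theta(t) (L_sat(F) - L_dna(F)). Bit-reproducible for
#' a given seed.
#'
#' @param force pN in (0, 65].
#' @param concentration nM, >= 0.
#' @param truth a [TruthParams-class].
#' @param seed integer RNG seed for the measurement noise.
#' @return a [ForceClampTrace-class]; generation parameters are recorded
#'   in its `meta` slot.
#' @export
simulateTrace <- function(force, concentration, truth, seed = 1) {
  stopifnot(is(truth, "TruthParams"), length(force) == 1L,
            length(concentration) == 1L)
  if (force <= 0 || force > 65) stop("force must lie in (0, 65] pN",
                                     call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  tv <- truthAt(truth, force, concentration)
  # at least 10 samples even when the kinetics outrun the sampling clock
  duration <- max(truth@durationFactor / tv$kTotal,
                  9 * truth@sampleInterval)
  times <- seq(0, duration, by = truth@sampleInterval)
  theta <- tv$thetaEq * (1 - exp(-tv$kTotal * times))
  kernel <- tv$Ldna + theta * (tv$Lsat - tv$Ldna)
  noise <- if (truth@noiseSd > 0)
    withr::with_seed(seed, stats::rnorm(length(times), 0, truth@noiseSd))
  else 0
  ForceClampTrace(times, kernel + noise, force, concentration,
    label = sprintf("sim_F%gpN_C%gnM_seed%d", force, concentration, seed),
    meta = list(seed = seed, kTotal = tv$kTotal, thetaEq = tv$thetaEq,
                Ldna = tv$Ldna, Lsat = tv$Lsat, Kd = tv$Kd, n = tv$n,
                noiseSd = truth@noiseSd,
                temperature_K = temperatureK(truth@conditions),
                bp_count = bpCount(truth@conditions)))
}

#' Simulate a force-concentration grid of traces
#'
#' One trace per (force, concentration, replicate), each with its own
#' deterministic sub-seed, together with a tidy truth table recording the
#' per-condition generating values for recovery scoring.
#'
#' @param truth a [TruthParams-class].
#' @param forces pN.
#' @param concentrations nM.
#' @param replicates traces per condition.
#' @param seed integer master seed.
#' @return list with elements `traces` (list of
#'   [ForceClampTrace-class]) and `truthTable` (data.frame).
#' @examples
#' g <- simulateGrid(makeTruth(), c(40, 60), c(25, 150), seed = 2)
#' g$truthTable
#' @export
simulateGrid <- function(truth, forces, concentrations, replicates = 1,
                         seed = 1) {
  stopifnot(length(forces) >= 1, length(concentrations) >= 1,
            replicates >= 1)
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration = concentrations, force = forces)
  traces <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    subSeed <- (as.integer(seed) %% 65536L) * 32749L + i
    tr <- simulateTrace(grid$force[i], grid$concentration[i], truth,
                        seed = subSeed)
    traces[[i]] <- tr
    rows[[i]] <- cbind(truthAt(truth, grid$force[i], grid$concentration[i]),
                       replicate = grid$replicate[i], seed = subSeed)
  }
  list(traces = traces, truthTable = do.call(rbind, rows))
}

#' Gillespie simulation of footprint-exclusion lattice binding
#'
#' Independent stochastic oracle for the isotherm and the relaxation
#' kinetics: a one-dimensional lattice of `nSites` base pairs on which
#' ligands occupy `footprint` contiguous sites. Every position admitting a
#' full free footprint binds at rate k_a(F) C; every bound ligand unbinds
#' at rate k_off(F) (Bell rates from the truth). The per-bp extension is
#' L_dna(F) + bound * perLigandElongation / nSites. The late-window
#' time-averaged fractional saturation (footprint * bound / nSites over
#' the second half of the run) converges to [mvhCoverage()] at the implied
#' Kd(F).
#'
#' @param force pN.
#' @param concentration nM.
#' @param truth a [TruthParams-class].
#' @param footprint integer site size, bp (>= 1).
#' @param nSites lattice length; must be at least 100 * footprint.
#' @param tEnd simulated time, s; NULL defaults to 20 / (k_a C + k_off).
#' @param seed integer RNG seed.
#' @return a [LatticeTrajectory-class].
#' @export
gillespieLattice <- function(force, concentration, truth, footprint,
                             nSites = 100L * footprint, tEnd = NULL,
                             seed = 1) {
  stopifnot(is(truth, "TruthParams"))
  footprint <- as.integer(footprint)
  nSites <- as.integer(nSites)
  if (footprint < 1) stop("footprint must be a positive integer",
                          call. = FALSE)
  if (nSites < 100L * footprint)
    stop("lattice too short: need nSites >= 100 * footprint", call. = FALSE)
  tv <- truthAt(truth, force, concentration)
  kBind <- tv$kA * concentration * 1e-9 # per eligible position, 1/s
  kUn <- tv$kOff
  if (is.null(tEnd)) tEnd <- 20 / max(kBind + kUn, .Machine$double.xmin)

  withr::with_seed(seed, {
    covered <- logical(nSites)
    starts <- integer(0) # left ends of bound footprints
    times <- 0
    bound <- 0L
    tNow <- 0
    recT <- c(0); recB <- c(0L)
    repeat {
      free <- !covered
      # positions i where sites i..i+footprint-1 are all free
      if (footprint == 1L) {
        elig <- which(free)
      } else {
        cs <- cumsum(free)
        win <- cs[footprint:nSites] -
          c(0, cs[seq_len(nSites - footprint)])
        elig <- which(win == footprint)
      }
      rateB <- length(elig) * kBind
      rateU <- length(starts) * kUn
      total <- rateB + rateU
      if (total <= 0) break
      dt <- stats::rexp(1, total)
      if (tNow + dt > tEnd) break
      tNow <- tNow + dt
      if (stats::runif(1) < rateB / total) {
        i <- elig[sample.int(length(elig), 1L)]
        covered[i:(i + footprint - 1L)] <- TRUE
        starts <- c(starts, i)
      } else {
        j <- sample.int(length(starts), 1L)
        i <- starts[j]
        covered[i:(i + footprint - 1L)] <- FALSE
        starts <- starts[-j]
      }
      recT <- c(recT, tNow)
      recB <- c(recB, length(starts))
    }
    recT <- c(recT, tEnd)
    recB <- c(recB, recB[length(recB)])
    # time-averaged coverage over the late window [tEnd/2, tEnd]
    w0 <- tEnd / 2
    dtv <- diff(recT)
    mid <- recT[-length(recT)]
    keep <- (mid + dtv) > w0
    lo <- pmax(mid[keep], w0)
    hi <- (mid + dtv)[keep]
    bw <- recB[-length(recB)][keep]
    covg <- sum(bw * (hi - lo)) / (tEnd - w0) * footprint / nSites
    ext <- tv$Ldna + recB * truth@perLigandElongation / nSites
    new("LatticeTrajectory", times = recT, boundCounts = as.numeric(recB),
        nSites = nSites, footprint = footprint, extensions = ext,
        coverage = covg, force = force, concentration = concentration)
  })
}
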