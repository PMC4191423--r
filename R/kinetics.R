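#' @include core-model.R
NULL

#' Fit a single-exponential relaxation to a force-clamp trace
#'
#' Least squares of L(t) = L0 + (Leq - L0)(1 - exp(-kTotal t)) to one
#' constant-force recording. Initialisation: L0 from the first sample, Leq
#' from the mean of the last decile, kTotal from a log-linear regression of
#' the residual decay. A trace whose plateau rises less than three times
#' the measurement noise above its start carries no detectable binding
#' signal and is rejected. The fit is flagged unconverged when the trace
#' spans less than 2/kTotal, i.e. the plateau is extrapolated.
#'
#' @param trace a [ForceClampTrace-class] with at least 10 samples.
#' @param nBoot residual-bootstrap resamples for the uncertainties;
#'   0 (default) uses the asymptotic least-squares covariance.
#' @param seed RNG seed for the bootstrap.
#' @return a [RelaxationFit-class].
#' @examples
#' tr <- simulateTrace(40, 25, makeTruth(), seed = 7)
#' fitRelaxation(tr)
#' @export
fitRelaxation <- function(trace, nBoot = 0, seed = 1) {
  stopifnot(is(trace, "ForceClampTrace"))
  t <- trace@times - trace@times[1]
  y <- trace@extensions
  n <- length(y)
  if (n < 10)
    stop("need at least 10 samples to fit a relaxation", call. = FALSE)

  decile <- max(3L, ceiling(n / 10))
  plateau <- mean(y[(n - decile + 1L):n])
  start0 <- y[1]
  # high-frequency noise estimate, robust to the slow trend
  noiseSd <- stats::mad(diff(y)) / sqrt(2)
  if (plateau - start0 < 3 * max(noiseSd, .Machine$double.eps))
    stop("no detectable binding: plateau within 3 noise SD of start",
         call. = FALSE)

  # log-linear initial rate from the residual decay toward the plateau
  dy <- plateau - y
  ok <- dy > max(3 * noiseSd, 1e-12) & t < max(t) * 0.9
  k0 <- if (sum(ok) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(dy[ok]) ~ t[ok]))[2])
    if (is.finite(sl) && sl < 0) -sl else 2 / max(t)
  } else 2 / max(t)

  fitOnce <- function(y) {
    minpack.lm::nlsLM(
      y ~ L0 + (Leq - L0) * (1 - exp(-exp(lk) * t)),
      start = list(L0 = y[1], Leq = plateau, lk = log(k0)),
      control = minpack.lm::nls.lm.control(maxiter = 200,
                                           ftol = 1e-14, ptol = 1e-14))
  }
  fit <- fitOnce(y)
  est <- coef(fit)
  L0 <- est[["L0"]]; Leq <- est[["Leq"]]; k <- exp(est[["lk"]])
  pred <- L0 + (Leq - L0) * (1 - exp(-k * t))
  resid <- y - pred
  rss <- sum(resid^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)

  if (nBoot > 0) {
    boots <- withr::with_seed(seed, replicate(nBoot, {
      yb <- pred + sample(resid, n, replace = TRUE)
      cb <- tryCatch(coef(fitOnce(yb)),
                     error = function(e) rep(NA_real_, 3))
      c(cb[1], cb[2], exp(cb[3]))
    }))
    se <- apply(boots, 1, stats::sd, na.rm = TRUE)
    cov <- stats::cov(t(boots), use = "complete.obs")
  } else {
    vl <- tryCatch(suppressWarnings(stats::vcov(fit)),
                   error = function(e) matrix(NA_real_, 3, 3))
    J <- diag(c(1, 1, k)) # (L0, Leq, lk) -> (L0, Leq, k)
    cov <- J %*% vl %*% t(J)
    se <- sqrt(pmax(diag(cov), 0))
  }
  nm <- c("L0", "Leq", "kTotal")
  names(se) <- nm
  dimnames(cov) <- list(nm, nm)

  a1 <- if (n > 10) stats::cor(resid[-1], resid[-n]) else 0
  new("RelaxationFit", L0 = L0, Leq = Leq, kTotal = k, se = se, cov = cov,
      rSquared = r2, residAutocorr = is.finite(a1) && abs(a1) > 4 / sqrt(n),
      converged = max(t) >= 2 / k, nObs = as.integer(n),
      force = trace@force, concentration = trace@concentration)
}

#' Split a net relaxation rate into on and off rates
#'
#' For a two-state binding process relaxing at kTotal = kOn + kOff with
#' equilibrium constant Kd, kOn = kTotal / (1 + Kd/C) and
#' kOff = kTotal / (1 + C/Kd). kOff is computed as kTotal - kOn so the sum
#' identity holds exactly. At C = 0 the limit kOn = 0, kOff = kTotal is
#' used. Under footprint exclusion (n > 1) the split is the standard
#' two-state approximation.
#'
#' @param kTotal net relaxation rate(s), 1/s.
#' @param Kd dissociation constant(s), nM.
#' @param concentration ligand concentration(s), nM.
#' @param force optional force(s) (pN) recorded in the result.
#' @param kTotalSe optional standard error(s) of kTotal, propagated
#'   proportionally.
#' @return a [RateSet-class] (vectorised over its inputs).
#' @examples
#' splitRates(1.56e-3, Kd = 43.75, concentration = 5)
#' @export
splitRates <- function(kTotal, Kd, concentration, force = NA_real_,
                       kTotalSe = NULL) {
  if (any(kTotal <= 0) || any(Kd <= 0) || any(concentration < 0))
    stop("kTotal and Kd must be positive, concentration non-negative",
         call. = FALSE)
  m <- max(length(kTotal), length(Kd), length(concentration), length(force))
  kTotal <- rep_len(kTotal, m); Kd <- rep_len(Kd, m)
  concentration <- rep_len(concentration, m); force <- rep_len(force, m)
  kOn <- ifelse(concentration == 0, 0, kTotal / (1 + Kd / concentration))
  kOff <- kTotal - kOn
  se <- list()
  if (!is.null(kTotalSe)) {
    kTotalSe <- rep_len(kTotalSe, m)
    se <- list(kOn = kOn / kTotal * kTotalSe, kOff = kOff / kTotal * kTotalSe)
  }
  new("RateSet", force = force, concentration = concentration,
      kOn = kOn, kOff = kOff, kTotal = kTotal, se = se)
}

#' Concentration dependence of a rate at one force
#'
#' Weighted linear regression of a rate on ligand concentration. For the
#' on rate the slope is the bimolecular association rate k_a(F) (reported
#' in 1/M/s) and the intercept should be consistent with zero for a
#' bimolecular process; for the off rate the slope itself should be
#' consistent with zero.
#'
#' @param rates a [RateSet-class] at a single force (or a data.frame with
#'   columns force, concentration, kOn/kOff and optional kOnSe/kOffSe).
#' @param quantity "kOn" (default) or "kOff".
#' @param weighted use inverse-variance weights when standard errors are
#'   available.
#' @return an [AssociationFit-class].
#' @export
associationRate <- function(rates, quantity = c("kOn", "kOff"),
                            weighted = FALSE) {
  quantity <- match.arg(quantity)
  if (is(rates, "RateSet")) {
    df <- data.frame(force = rates@force, concentration = rates@concentration,
                     value = slot(rates, quantity))
    seName <- quantity
    if (length(rates@se)) df$se <- rates@se[[quantity]]
  } else {
    df <- data.frame(force = rates$force, concentration = rates$concentration,
                     value = rates[[quantity]])
    seCol <- paste0(quantity, "Se")
    if (!is.null(rates[[seCol]])) df$se <- rates[[seCol]]
  }
  fr <- unique(df$force[!is.na(df$force)])
  if (length(fr) > 1)
    stop("rates must all be at a single force", call. = FALSE)
  if (length(unique(df$concentration)) < 3)
    stop("underdetermined: need at least 3 distinct concentrations",
         call. = FALSE)
  w <- if (weighted && !is.null(df$se) && all(is.finite(df$se)) &&
           all(df$se > 0)) 1 / df$se^2 else NULL
  fit <- stats::lm(value ~ concentration, data = df, weights = w)
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))
  # concentration in nM -> slope per nM per s; report per M per s
  slope <- cf[["concentration"]] * 1e9
  intercept <- cf[["(Intercept)"]]
  se <- c(slope = sqrt(vc[2, 2]) * 1e9, intercept = sqrt(vc[1, 1]))
  cov <- vc * outer(c(1, 1e9), c(1, 1e9))
  dimnames(cov) <- list(c("intercept", "slope"), c("intercept", "slope"))
  if (quantity == "kOn" && slope <= 0)
    stop("fitted association rate is non-positive", call. = FALSE)
  new("AssociationFit",
      force = if (length(fr)) fr else NA_real_, quantity = quantity,
      slope = slope, intercept = intercept, se = se, cov = cov,
      interceptZero = abs(intercept) <= 2 * se[["intercept"]],
      slopeZero = abs(slope) <= 2 * se[["slope"]],
      nPoints = nrow(df))
}
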