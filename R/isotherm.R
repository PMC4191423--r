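#' @include core-model.R
NULL

# McGhee-von Hippel fixed-point residual for fractional saturation theta:
# theta = (C/Kd) * n (1-theta)^n / (1 - theta + theta/n)^(n-1)
.mvhResidual <- function(theta, cOverKd, n) {
  theta - cOverKd * n * (1 - theta)^n / (1 - theta + theta / n)^(n - 1)
}

#' McGhee-von Hippel equilibrium coverage
#'
#' Solves the non-cooperative McGhee-von Hippel isotherm for the fractional
#' saturation theta at a ligand concentration, written in the
#' extension-saturation convention theta = n * nu (nu = ligands per bp):
#' theta = (C/Kd) n (1-theta)^n / (1 - theta + theta/n)^(n-1).
#' The residual is monotone, so bracketed root finding on
#' \\[0, 1 - 1e-12\\] gives the unique solution to 1e-12 absolute. For
#' n = 1 this reduces to the Langmuir form C / (C + Kd).
#'
#' @param concentration nM; scalar or vector, >= 0 (zero short-circuits
#'   to 0).
#' @param Kd dissociation constant, nM (> 0).
#' @param n binding site size in bp; real-valued, >= 1.
#' @return coverage value(s) in \\[0, 1).
#' @examples
#' mvhCoverage(10, 10, 1)   # 0.5 (Langmuir)
#' mvhCoverage(50, 2.8, 1.7)
#' @export
mvhCoverage <- function(concentration, Kd, n) {
  if (any(concentration < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (Kd <= 0) stop("Kd must be positive", call. = FALSE)
  if (n < 1) stop("site size n must be >= 1", call. = FALSE)
  vapply(concentration, function(C) {
    if (C == 0) return(0)
    r <- stats::uniroot(.mvhResidual, lower = 0, upper = 1 - 1e-12,
                        tol = 1e-13, maxiter = 2000,
                        cOverKd = C / Kd, n = n)
    r$root
  }, numeric(1))
}

# internal: multistart MvH least squares on occupancies.
# Returns the nlsLM fit with parameters (lKd = log Kd, n).
.mvhFitOnce <- function(concentration, theta, weights = NULL,
                        startAt = NULL) {
  # initial Kd: concentration nearest half saturation, fallback median
  pos <- concentration > 0
  kd0 <- if (any(pos)) {
    i <- which.min(abs(theta[pos] - 0.5))
    max(concentration[pos][i], min(concentration[pos]))
  } else 1
  starts <- if (is.null(startAt))
    lapply(1:5, function(n0) list(lKd = log(kd0), n = n0))
  else list(as.list(startAt))
  best <- NULL
  args <- list(
    theta ~ mvhCoverage(concentration, exp(lKd), n),
    lower = c(-25, 1), upper = c(25, 50),
    control = minpack.lm::nls.lm.control(maxiter = 150,
                                         ftol = 1e-14, ptol = 1e-14))
  if (!is.null(weights)) args$weights <- weights
  for (st in starts) {
    args$start <- st
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best)))
      best <- fit
  }
  if (is.null(best)) stop("isotherm fit failed to converge", call. = FALSE)
  best
}

#' Fit the McGhee-von Hippel isotherm at one force
#'
#' Nonlinear least squares of [mvhCoverage()] over (Kd, n) to a titration
#' of fractional occupancies, with multistart over site-size
#' initialisations n = 1..5 (best residual wins) and a seeded residual
#' bootstrap for the uncertainties. A fit whose relative Kd standard error
#' exceeds 100 percent is flagged non-identifiable, not hidden.
#'
#' @param points data.frame with columns `concentration` (nM), `theta`
#'   and optionally `sd` (per-point occupancy uncertainty); at least 4
#'   concentrations spanning a factor of 10.
#' @param force pN, recorded in the result.
#' @param nBoot bootstrap resamples (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param weighted use 1/sd^2 weights (requires an `sd` column).
#' @return an [IsothermFit-class].
#' @export
fitIsotherm <- function(points, force, nBoot = 500, seed = 1,
                        weighted = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "theta") %in% names(points)))
  conc <- points$concentration
  theta <- points$theta
  pos <- conc[conc > 0]
  if (length(unique(conc)) < 4)
    stop("underdetermined: need at least 4 distinct concentrations",
         call. = FALSE)
  if (max(pos) / min(pos) < 10)
    stop("concentrations must span at least a factor of 10", call. = FALSE)
  w <- NULL
  if (weighted) {
    if (is.null(points$sd)) stop("weighted fit needs an sd column",
                                 call. = FALSE)
    w <- 1 / points$sd^2
  }
  fit <- .mvhFitOnce(conc, theta, w)
  est <- coef(fit)
  kd <- exp(est[["lKd"]]); nSize <- est[["n"]]
  pred <- mvhCoverage(conc, kd, nSize)
  resid <- theta - pred
  rms <- sqrt(mean(resid^2))

  if (nBoot > 0) {
    boots <- withr::with_seed(seed, replicate(nBoot, {
      tb <- pmin(pmax(pred + sample(resid, length(resid), replace = TRUE),
                      0), 1 - 1e-9)
      cb <- tryCatch(coef(.mvhFitOnce(conc, tb, w, startAt = est)),
                     error = function(e) c(lKd = NA_real_, n = NA_real_))
      c(exp(cb[["lKd"]]), cb[["n"]])
    }))
    se <- apply(boots, 1, stats::sd, na.rm = TRUE)
    cov <- stats::cov(t(boots), use = "complete.obs")
  } else {
    vl <- tryCatch(suppressWarnings(stats::vcov(fit)), error = function(e)
      matrix(NA_real_, 2, 2))
    # delta method from (lKd, n) to (Kd, n)
    J <- diag(c(kd, 1))
    cov <- J %*% vl %*% t(J)
    se <- sqrt(pmax(diag(cov), 0))
  }
  names(se) <- c("Kd", "n")
  dimnames(cov) <- list(c("Kd", "n"), c("Kd", "n"))
  nonId <- is.finite(se[["Kd"]]) && se[["Kd"]] / kd > 1
  new("IsothermFit", force = force, Kd = kd, n = nSize, Lsat = NA_real_,
      se = se, cov = cov, nPoints = nrow(points), residualNorm = rms,
      nonIdentifiable = nonId)
}

#' Per-ligand elongation from site sizes and saturated elongations
#'
#' The equilibrium elongation per bound ligand at each force as
#' dxEq(F) = n(F) * dLsat(F), where dLsat is the per-bp elongation of the
#' saturated complex over bare DNA, together with the force average and its
#' standard error.
#'
#' @param fits list of [IsothermFit-class] objects (one per force).
#' @param satElongations data.frame with columns `force` (pN) and `dLsat`
#'   (nm/bp); forces must match the fits exactly.
#' @return a [SiteSizeElongation-class].
#' @export
deltaXFromSiteSize <- function(fits, satElongations) {
  stopifnot(is.list(fits), is.data.frame(satElongations),
            all(c("force", "dLsat") %in% names(satElongations)))
  fF <- vapply(fits, appliedForce, numeric(1))
  if (length(fF) != nrow(satElongations) ||
      any(sort(fF) != sort(satElongations$force)))
    stop("mismatched force grids between fits and saturated elongations",
         call. = FALSE)
  ord <- match(satElongations$force, fF)
  n <- vapply(fits[ord], siteSize, numeric(1))
  dx <- n * satElongations$dLsat
  perForce <- data.frame(force = satElongations$force, n = n,
                         dLsat = satElongations$dLsat, deltaX = dx)
  m <- mean(dx)
  se <- if (length(dx) > 1) stats::sd(dx) / sqrt(length(dx)) else NA_real_
  new("SiteSizeElongation", perForce = perForce, mean = m, se = se)
}
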