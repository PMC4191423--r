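#' @include core-model.R
NULL

#' Bell-model exponential fit in force
#'
#' Linear regression of ln(value) on force. The slope times kT gives the
#' distance to the transition (or equilibrium) state along the pulling
#' coordinate, with the sign convention that the distance is positive when
#' force facilitates the process: rates grow with force
#' (value = value(0) exp(+x F / kT)) while the dissociation constant
#' shrinks (Kd = Kd(0) exp(-dxEq F / kT)). Fitting in log space treats the
#' multiplicative error of quantities spanning decades as homoscedastic.
#' Uncertainties come from a seeded residual bootstrap in log space.
#'
#' @param points data.frame with columns `force` (pN), `value` (> 0; nM
#'   for Kd, 1/s for rates, 1/M/s for k_a) and optionally `se`; at least
#'   3 distinct forces spanning at least 20 pN.
#' @param quantity one of "Kd", "k_on", "k_off", "k_a".
#' @param conditions [Conditions-class] supplying kT.
#' @param nBoot bootstrap resamples (default 500).
#' @param seed RNG seed for the bootstrap.
#' @param weighted use (value/se)^2 weights in log space.
#' @return a [BellFit-class].
#' @examples
#' f <- seq(10, 60, 10)
#' kd <- 44 * exp(-0.19 * f / thermalEnergy(Conditions()))
#' bellFit(data.frame(force = f, value = kd), "Kd")
#' @export
bellFit <- function(points, quantity = c("Kd", "k_on", "k_off", "k_a"),
                    conditions = Conditions(), nBoot = 500, seed = 1,
                    weighted = FALSE) {
  quantity <- match.arg(quantity)
  stopifnot(is.data.frame(points),
            all(c("force", "value") %in% names(points)))
  if (any(points$value <= 0))
    stop("non-positive values: log-space Bell fit undefined", call. = FALSE)
  if (length(unique(points$force)) < 3)
    stop("underdetermined: need at least 3 distinct forces", call. = FALSE)
  if (diff(range(points$force)) < 20)
    stop("force range must span at least 20 pN", call. = FALSE)
  kT <- thermalEnergy(conditions)
  sgn <- if (quantity == "Kd") -1 else 1
  w <- if (weighted && !is.null(points$se))
    (points$value / points$se)^2 else NULL

  fitOnce <- function(ly) {
    fit <- stats::lm(ly ~ points$force, weights = w)
    cf <- stats::coef(fit)
    c(a = cf[[1]], dist = sgn * cf[[2]] * kT)
  }
  ly <- log(points$value)
  est <- fitOnce(ly)
  pred <- est[["a"]] + sgn * est[["dist"]] / kT * points$force
  resid <- ly - pred

  if (nBoot > 0 && length(resid) > 3) {
    boots <- withr::with_seed(seed, replicate(nBoot, {
      fitOnce(pred + sample(resid, length(resid), replace = TRUE))
    }))
    se <- apply(boots, 1, stats::sd)
    cov <- stats::cov(t(boots))
  } else {
    fit <- stats::lm(ly ~ points$force, weights = w)
    vc <- suppressWarnings(stats::vcov(fit))
    J <- diag(c(1, sgn * kT))
    cov <- J %*% vc %*% t(J)
    se <- sqrt(pmax(diag(cov), 0))
  }
  nm <- c("logZeroForceValue", "distance")
  names(se) <- nm
  dimnames(cov) <- list(nm, nm)
  seOut <- c(zeroForceValue = exp(est[["a"]]) * se[["logZeroForceValue"]],
             distance = se[["distance"]])
  new("BellFit", quantity = quantity, zeroForceValue = exp(est[["a"]]),
      distance = est[["dist"]], se = seOut, cov = cov,
      nPoints = nrow(points))
}

#' Derive equilibrium and threading thermodynamics from the fitted routes
#'
#' Combines the Bell fits and the site-size analysis into the quantities
#' the force-clamp experiment is designed to deliver: the per-ligand
#' equilibrium elongation dxEq by its three routes (the Bell fit of Kd(F);
#' the force average of n(F) * dLsat(F); and x_on - x_off from the rate
#' fits), the threading free energy
#' G_thread = kT ln(k_dif / k_a(0)) implied by the depression of the
#' zero-force association rate below the diffusion limit, and the
#' zero-force residence half-life ln(2)/k_off(0).
#'
#' @param kdBell [BellFit-class] of Kd(F), or NULL.
#' @param onBell [BellFit-class] of the on rate (x_on), or NULL.
#' @param offBell [BellFit-class] of the off rate (x_off), or NULL.
#' @param kaBell [BellFit-class] of the association rate k_a(F); when NULL
#'   and `onBell` is tagged "k_a" that fit is used for G_thread.
#' @param siteSize [SiteSizeElongation-class] route, or NULL.
#' @param kDif diffusion-limited association rate, 1/M/s (default 1e9);
#'   must exceed the fitted k_a(0).
#' @param conditions [Conditions-class] for the kcal/mol conversion at the
#'   configured temperature.
#' @return a [DerivedThermodynamics-class].
#' @examples
#' ka <- bellFit(data.frame(force = c(20, 40, 60),
#'                          value = 1.01e4 * exp(0.31 * c(20, 40, 60) / 4.061)),
#'               "k_a", nBoot = 0)
#' deriveThermodynamics(kaBell = ka)
#' @export
deriveThermodynamics <- function(kdBell = NULL, onBell = NULL,
                                 offBell = NULL, kaBell = NULL,
                                 siteSize = NULL, kDif = 1e9,
                                 conditions = Conditions()) {
  routes <- c(kd_bell = NA_real_, site_size = NA_real_,
              rate_split = NA_real_)
  if (!is.null(kdBell)) {
    stopifnot(is(kdBell, "BellFit"), kdBell@quantity == "Kd")
    routes[["kd_bell"]] <- kdBell@distance
  }
  if (!is.null(siteSize)) {
    stopifnot(is(siteSize, "SiteSizeElongation"))
    routes[["site_size"]] <- siteSize@mean
  }
  if (!is.null(onBell) && !is.null(offBell))
    routes[["rate_split"]] <- onBell@distance - offBell@distance

  have <- routes[is.finite(routes)]
  agree <- if (length(have) >= 2) {
    all(abs(outer(have, have, "-")) <= 0.25 * mean(have))
  } else NA

  src <- if (!is.null(kaBell)) kaBell
         else if (!is.null(onBell) && onBell@quantity == "k_a") onBell
         else NULL
  if (is.null(src))
    stop("need an association-rate (k_a) Bell fit for G_thread",
         call. = FALSE)
  stopifnot(is(src, "BellFit"))
  kA0 <- src@zeroForceValue
  if (kDif < kA0)
    stop("nonphysical input: kDif must be at least the fitted k_a(0)",
         call. = FALSE)
  gKT <- log(kDif / kA0)
  # kBT in kcal/mol at the configured temperature
  kcalPerKT <- thermalEnergy(conditions) * 1e-21 * .NA / .J_PER_KCAL
  halfLife <- if (!is.null(offBell)) log(2) / offBell@zeroForceValue
              else NA_real_

  new("DerivedThermodynamics", deltaXRoutes = routes,
      routesAgree = agree, gThreadKT = gKT, gThreadKcal = gKT * kcalPerKT,
      kDif = kDif, kA0 = kA0, halfLifeZeroForce = halfLife,
      conditions = conditions)
}
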