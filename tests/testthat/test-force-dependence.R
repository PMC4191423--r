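kT <- thermalEnergy(Conditions())

test_that("Bell fits recover noiseless exponentials exactly", {
  f <- seq(10, 60, 10)
  kd <- bellFit(data.frame(force = f, value = 44 * exp(-0.19 * f / kT)),
                "Kd", nBoot = 0)
  expect_equal(zeroForceValue(kd), 44, tolerance = 1e-9)
  expect_equal(transitionDistance(kd), 0.19, tolerance = 1e-9)
  on <- bellFit(data.frame(force = f, value = 1.6e-4 * exp(0.33 * f / kT)),
                "k_on", nBoot = 0)
  expect_equal(transitionDistance(on), 0.33, tolerance = 1e-9)
  expect_error(bellFit(data.frame(force = c(10, 30), value = c(1, 2)),
                       "k_on"), "3 distinct")
  expect_error(bellFit(data.frame(force = f, value = -kd@zeroForceValue *
                                    seq_along(f)), "Kd"), "non-positive")
})

test_that("log-space and direct nonlinear exponential fits agree", {
  f <- seq(10, 60, 10)
  val <- withr::with_seed(13,
    44 * exp(-0.19 * f / kT) * exp(rnorm(length(f), 0, 0.03)))
  logFit <- bellFit(data.frame(force = f, value = val), "Kd",
                    nBoot = 300, seed = 6)
  # independent route: direct nonlinear least squares on the linear scale
  nlin <- minpack.lm::nlsLM(val ~ a * exp(-d * f / kT),
                            start = list(a = 40, d = 0.2))
  expect_lt(abs(transitionDistance(logFit) - coef(nlin)[["d"]]),
            max(stdErrors(logFit)[["distance"]], 1e-3))
  expect_lt(abs(zeroForceValue(logFit) - coef(nlin)[["a"]]),
            max(stdErrors(logFit)[["zeroForceValue"]], 0.5))
})

test_that("Bell fit of Kd agrees with the kOff/kA ratio route on
           synthetic truth", {
  truth <- makeTruth()
  tv <- truthAt(truth, paperForces())
  direct <- bellFit(data.frame(force = tv$force, value = tv$Kd), "Kd",
                    nBoot = 0)
  ratio <- tv$kOff / tv$kA * 1e9
  viaRatio <- bellFit(data.frame(force = tv$force, value = ratio), "Kd",
                      nBoot = 0)
  expect_equal(transitionDistance(direct), transitionDistance(viaRatio),
               tolerance = 1e-10)
  expect_equal(transitionDistance(direct), truth@xOn - truth@xOff,
               tolerance = 1e-10)
})

test_that("derived thermodynamics combines the three elongation routes
           and the threading free energy", {
  f <- seq(10, 60, 10)
  on <- bellFit(data.frame(force = f, value = 1.6e-4 * exp(0.33 * f / kT)),
                "k_on", nBoot = 0)
  off <- bellFit(data.frame(force = f, value = 1.4e-3 * exp(0.14 * f / kT)),
                 "k_off", nBoot = 0)
  ka <- bellFit(data.frame(force = f, value = 1.01e4 * exp(0.31 * f / kT)),
                "k_a", nBoot = 0)
  th <- deriveThermodynamics(onBell = on, offBell = off, kaBell = ka)
  expect_equal(th@deltaXRoutes[["rate_split"]], 0.19, tolerance = 1e-9)
  expect_equal(th@gThreadKT, log(1e9 / 1.01e4), tolerance = 1e-9)
  expect_equal(th@halfLifeZeroForce, log(2) / 1.4e-3, tolerance = 1e-6)
  # equal rates: zero threading cost
  th0 <- deriveThermodynamics(kaBell = ka, kDif = zeroForceValue(ka))
  expect_equal(th0@gThreadKT, 0)
  expect_error(deriveThermodynamics(kaBell = ka, kDif = 1e3),
               "nonphysical")
  expect_error(deriveThermodynamics(kdBell = NULL, onBell = on,
                                    offBell = off), "k_a")
})

test_that("the three elongation routes agree on self-consistent synthetic
           truth", {
  truth <- makeTruth()
  tv <- truthAt(truth, paperForces())
  kd <- bellFit(data.frame(force = tv$force, value = tv$Kd), "Kd",
                nBoot = 0)
  # pseudo-first-order on rate at 5 nM; off rate concentration-free
  on <- bellFit(data.frame(force = tv$force, value = tv$kA * 5e-9),
                "k_on", nBoot = 0)
  off <- bellFit(data.frame(force = tv$force, value = tv$kOff), "k_off",
                 nBoot = 0)
  ka <- bellFit(data.frame(force = tv$force, value = tv$kA), "k_a",
                nBoot = 0)
  fits <- lapply(seq_len(nrow(tv)), function(i)
    new("IsothermFit", force = tv$force[i], Kd = tv$Kd[i], n = tv$n[i],
        Lsat = tv$Lsat[i], se = c(Kd = 0.1, n = 0.1), cov = diag(2),
        nPoints = 8L, residualNorm = 0, nonIdentifiable = FALSE))
  ss <- deltaXFromSiteSize(fits,
    data.frame(force = tv$force, dLsat = tv$Lsat - tv$Ldna))
  th <- deriveThermodynamics(kdBell = kd, onBell = on, offBell = off,
                             kaBell = ka, siteSize = ss)
  expect_true(all(abs(th@deltaXRoutes - 0.19) < 0.01))
  expect_true(th@routesAgree)
})
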