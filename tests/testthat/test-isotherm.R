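test_that("coverage reduces to the Langmuir form for unit site size", {
  cGrid <- 10^seq(-2, 3, length.out = 25)
  expect_equal(mvhCoverage(cGrid, 10, 1), cGrid / (cGrid + 10),
               tolerance = 1e-10)
  expect_equal(mvhCoverage(10, 10, 1), 0.5, tolerance = 1e-10)
  expect_equal(mvhCoverage(0, 3, 2), 0)
})

test_that("coverage matches an independent bisection oracle for
           fractional site sizes", {
  for (case in list(c(2.8, 2.8, 1.7), c(10, 21, 3.7), c(150, 2.8, 1.7),
                    c(5, 44, 2.5))) {
    expect_equal(mvhCoverage(case[1], case[2], case[3]),
                 oracleMvH(case[1], case[2], case[3]),
                 tolerance = 1e-9)
  }
})

test_that("coverage is monotone in concentration and affinity and
           saturates", {
  withr::with_seed(21, {
    for (i in 1:20) {
      kd <- runif(1, 0.5, 100)
      n <- runif(1, 1, 5)
      cGrid <- sort(runif(8, 0.1, 500))
      th <- mvhCoverage(cGrid, kd, n)
      expect_true(all(diff(th) > 0))
      # tighter binding raises coverage
      expect_true(all(mvhCoverage(cGrid, kd / 2, n) > th))
      expect_true(all(th >= 0 & th < 1))
    }
  })
  expect_gt(mvhCoverage(1e7, 10, 2), 0.99)
})

test_that("isotherm fitting recovers generating parameters", {
  cGrid <- c(1, 2, 5, 10, 25, 50, 100, 150)
  # noiseless self-recovery
  pts <- data.frame(concentration = cGrid,
                    theta = mvhCoverage(cGrid, 21, 3.7))
  fit <- fitIsotherm(pts, force = 10, nBoot = 0)
  expect_equal(dissociationConstant(fit), 21, tolerance = 1e-6)
  expect_equal(siteSize(fit), 3.7, tolerance = 1e-6)
  expect_false(fit@nonIdentifiable)
  # noisy titration at 60 pN recovers (Kd = 2.8, n = 1.7) within 3 SE
  noisy <- do.call(rbind, lapply(1:3, function(r)
    data.frame(concentration = cGrid,
               theta = mvhCoverage(cGrid, 2.8, 1.7))))
  noisy$theta <- withr::with_seed(60,
    pmin(pmax(noisy$theta + rnorm(nrow(noisy), 0, 0.02), 0), 1 - 1e-9))
  nf <- fitIsotherm(noisy, force = 60, nBoot = 300, seed = 2)
  expect_lt(abs(dissociationConstant(nf) - 2.8), 3 * stdErrors(nf)[["Kd"]])
  expect_lt(abs(siteSize(nf) - 1.7), 3 * stdErrors(nf)[["n"]])
  # underdetermined designs error
  expect_error(fitIsotherm(pts[1:3, ], force = 10), "4 distinct")
  tight <- data.frame(concentration = c(10, 20, 30, 40),
                      theta = c(0.2, 0.3, 0.4, 0.5))
  expect_error(fitIsotherm(tight, force = 10), "factor of 10")
})

test_that("site-size route multiplies n into the saturated elongation", {
  mk <- function(force, Kd, n) new("IsothermFit", force = force, Kd = Kd,
    n = n, Lsat = NA_real_, se = c(Kd = 0.1, n = 0.1),
    cov = diag(2), nPoints = 8L, residualNorm = 0,
    nonIdentifiable = FALSE)
  fits <- list(mk(10, 21, 2), mk(60, 2.8, 2))
  sat <- data.frame(force = c(10, 60), dLsat = c(0.10, 0.10))
  out <- deltaXFromSiteSize(fits, sat)
  expect_equal(out@perForce$deltaX, c(0.20, 0.20))
  expect_equal(out@mean, 0.20)
  # mismatched grids rejected
  expect_error(deltaXFromSiteSize(fits,
    data.frame(force = c(10, 50), dLsat = c(0.1, 0.1))), "mismatch")
})

test_that("site-size route round-trips the generator truth", {
  truth <- makeTruth() # elongation model: n * dLsat constant by design
  tv <- truthAt(truth, paperForces())
  fits <- lapply(seq_len(nrow(tv)), function(i)
    new("IsothermFit", force = tv$force[i], Kd = tv$Kd[i], n = tv$n[i],
        Lsat = tv$Lsat[i], se = c(Kd = 0.1, n = 0.1), cov = diag(2),
        nPoints = 8L, residualNorm = 0, nonIdentifiable = FALSE))
  out <- deltaXFromSiteSize(fits,
    data.frame(force = tv$force, dLsat = tv$Lsat - tv$Ldna))
  expect_equal(out@mean, truth@perLigandElongation, tolerance = 0.02)
})
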