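test_that("conditions derive the thermal energy and reject bad inputs", {
  cond <- Conditions()
  expect_equal(thermalEnergy(cond), 0.0138065 * 294.15, tolerance = 1e-12)
  expect_equal(bpCount(cond), 48502)
  expect_error(Conditions(temperature = -1))
  expect_error(new("Conditions", temperature = 294.15, thermalEnergy = 5,
                   bpCount = 48502, contourPerBp = 0.34),
               "thermalEnergy")
})

test_that("WLC extension matches the high-force expansion and the
           enthalpic stretch term", {
  cond <- Conditions()
  # near-inextensible chain at 10 pN: entropic result ~0.325 nm/bp
  x <- wlcExtension(10, WLCParams(50, 1e9, 0.34), cond)
  expect_equal(x, oracleOdijk(10, 50, 0.34), tolerance = 3e-3)
  expect_equal(round(x, 3), 0.325)
  # entropic limit: extension vanishes as force -> 0+
  expect_lt(wlcExtension(1e-6, bareDNA(), cond), 1e-3)
  # finite vs infinite stretch modulus differ by F/S * L0 at high force
  for (f in c(10, 30, 60)) {
    dx <- wlcExtension(f, WLCParams(50, 1000, 0.34), cond) -
      wlcExtension(f, WLCParams(50, 1e9, 0.34), cond)
    expect_equal(dx, f / 1000 * 0.34, tolerance = 0.02)
  }
  expect_error(wlcExtension(70, bareDNA()), "65")
  expect_error(wlcExtension(0, bareDNA()), "65")
})

test_that("WLC extension is strictly monotone in force for random
           parameter draws", {
  cond <- Conditions()
  withr::with_seed(42, {
    for (i in 1:25) {
      p <- WLCParams(runif(1, 0.6, 100), runif(1, 200, 2000),
                     runif(1, 0.2, 0.5))
      ext <- wlcExtension(seq(0.5, 65, length.out = 40), p, cond)
      expect_true(all(diff(ext) > 0))
    }
  })
})

test_that("WLC fitting recovers generating parameters", {
  cond <- Conditions()
  truth <- WLCParams(1.6, 598, 0.34)
  pts <- data.frame(force = seq(10, 60, 10))
  pts$extension <- wlcExtension(pts$force, truth, cond)
  # noiseless self-recovery to 1e-6 relative
  fit <- fitWLC(pts, cond, fixedContour = 0.34, nBoot = 0)
  expect_equal(persistenceLength(fit), 1.6, tolerance = 1e-6)
  expect_equal(stretchModulus(fit), 598, tolerance = 1e-6)
  # 1% noise: recovery within 3 bootstrap SE
  noisy <- pts
  noisy$extension <- withr::with_seed(7,
    pts$extension * (1 + rnorm(nrow(pts), 0, 0.01)))
  nf <- fitWLC(noisy, cond, fixedContour = 0.34, nBoot = 300, seed = 11)
  expect_lt(abs(persistenceLength(nf) - 1.6),
            3 * stdErrors(nf)[["persistenceLength"]])
  # degenerate designs
  expect_error(fitWLC(pts[1:3, ], cond), "4")
  same <- data.frame(force = rep(30, 5), extension = rep(0.4, 5))
  expect_error(fitWLC(same, cond), "degenerate")
  narrow <- data.frame(force = c(10, 12, 14, 16),
                       extension = pts$extension[1:4])
  expect_error(fitWLC(narrow, cond), "20 pN")
})

test_that("occupancy and mixture extension are exact inverses", {
  expect_equal(fractionalOccupancy(0.34, 0.34, 0.46), 0,
               ignore_attr = TRUE)
  expect_equal(fractionalOccupancy(0.46, 0.34, 0.46), 1,
               ignore_attr = TRUE)
  expect_equal(fractionalOccupancy(0.40, 0.34, 0.46), 0.5,
               ignore_attr = TRUE)
  expect_error(fractionalOccupancy(0.4, 0.46, 0.34), "inconsistent")
  expect_equal(mixtureExtension(0, 0.34, 0.46), 0.34)
  expect_equal(mixtureExtension(1, 0.34, 0.46), 0.46)
  expect_error(mixtureExtension(1.2, 0.34, 0.46), "0, 1")
  # round-trip identity on both scales, to 1e-12
  withr::with_seed(5, {
    th <- runif(50)
    l <- mixtureExtension(th, 0.335, 0.47)
    expect_equal(as.numeric(fractionalOccupancy(l, 0.335, 0.47)), th,
                 tolerance = 1e-12, ignore_attr = TRUE)
    x <- runif(50, 0.335, 0.47)
    expect_equal(
      mixtureExtension(as.numeric(fractionalOccupancy(x, 0.335, 0.47)),
                       0.335, 0.47),
      x, tolerance = 1e-12)
  })
  # clamping is reported, not fatal
  expect_message(th <- fractionalOccupancy(0.47, 0.34, 0.46), "clamped")
  expect_equal(as.numeric(th), 1)
  expect_equal(attr(th, "nClamped"), 1L)
})

test_that("traces validate their physical ranges", {
  expect_error(ForceClampTrace(c(0, 1, 1), c(0.3, 0.3, 0.3), 10, 5),
               "increasing")
  expect_error(ForceClampTrace(0:2, c(0.3, 0.3, 0.3), 70, 5), "65")
  expect_error(ForceClampTrace(0:2, c(0.3, 0.8, 0.3), 10, 5), "0.7")
  tr <- ForceClampTrace(0:10 * 0.2, seq(0.34, 0.36, length.out = 11),
                        40, 25)
  expect_s4_class(tr, "ForceClampTrace")
  expect_equal(length(tr), 11L)
})
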