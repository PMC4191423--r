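test_that("relaxation fitting recovers a noiseless exponential exactly", {
  t <- seq(0, 2500, by = 0.2)
  y <- 0.335 + (0.365 - 0.335) * (1 - exp(-2e-3 * t))
  tr <- ForceClampTrace(t, y, force = 40, concentration = 25)
  fit <- fitRelaxation(tr)
  expect_equal(fit@L0, 0.335, tolerance = 1e-8)
  expect_equal(fit@Leq, 0.365, tolerance = 1e-8)
  expect_equal(totalRate(fit), 2e-3, tolerance = 1e-8)
  expect_true(fit@converged)
})

test_that("flat traces are rejected as carrying no binding signal", {
  t <- seq(0, 100, by = 0.2)
  y <- withr::with_seed(3, rep(0.35, length(t)) + rnorm(length(t), 0, 1e-4))
  expect_error(fitRelaxation(ForceClampTrace(t, y, 40, 25)),
               "no detectable binding")
  expect_error(fitRelaxation(ForceClampTrace(0:5, rep(0.3, 6) + 1e-3 * 0:5,
                                             40, 25)),
               "10 samples")
})

test_that("a generator trace is recovered within 3 SE and flags
           truncation", {
  truth <- makeTruth()
  tr <- simulateTrace(40, 5, truth, seed = 1)
  tv <- truthAt(truth, 40, 5)
  fit <- fitRelaxation(tr, nBoot = 200, seed = 4)
  expect_lt(abs(totalRate(fit) - tv$kTotal),
            3 * stdErrors(fit)[["kTotal"]])
  leqTrue <- tv$Ldna + tv$thetaEq * (tv$Lsat - tv$Ldna)
  expect_lt(abs(equilibriumExtension(fit) - leqTrue),
            3 * stdErrors(fit)[["Leq"]])
  # truncated trace (first quarter only) is flagged unconverged
  nCut <- ceiling(length(tr) * 0.08)
  cut <- ForceClampTrace(traceTimes(tr)[1:nCut], extensions(tr)[1:nCut],
                         appliedForce(tr), ligandConcentration(tr))
  expect_false(fitRelaxation(cut)@converged)
})

test_that("relaxation fitting is invariant to time origin and to 2x
           subsampling", {
  truth <- makeTruth()
  tr <- simulateTrace(30, 25, truth, seed = 9)
  fit <- fitRelaxation(tr)
  shifted <- ForceClampTrace(traceTimes(tr) + 137.5, extensions(tr),
                             appliedForce(tr), ligandConcentration(tr))
  fitS <- fitRelaxation(shifted)
  expect_equal(totalRate(fitS), totalRate(fit), tolerance = 1e-10)
  idx <- seq(1, length(tr), by = 2)
  sub <- ForceClampTrace(traceTimes(tr)[idx], extensions(tr)[idx],
                         appliedForce(tr), ligandConcentration(tr))
  fitSub <- fitRelaxation(sub)
  expect_lt(abs(totalRate(fitSub) - totalRate(fit)),
            max(stdErrors(fit)[["kTotal"]], stdErrors(fitSub)[["kTotal"]]))
})

test_that("rate splitting obeys its exact identities and matches the
           reference rates", {
  # symmetry at C = Kd
  rs <- splitRates(1e-3, Kd = 10, concentration = 10)
  expect_equal(onRate(rs), offRate(rs))
  expect_equal(onRate(rs), 5e-4)
  # zero-concentration limit handled explicitly
  rs0 <- splitRates(1e-3, Kd = 10, concentration = 0)
  expect_equal(onRate(rs0), 0)
  expect_equal(offRate(rs0), 1e-3)
  # reference split: kTotal = 1.56e-3 at 5 nM with Kd = 43.75 nM
  ref <- splitRates(1.56e-3, Kd = 43.75, concentration = 5)
  expect_equal(onRate(ref), 1.6e-4, tolerance = 1e-3)
  expect_equal(offRate(ref), 1.4e-3, tolerance = 1e-3)
  # sum identity exact over random inputs
  withr::with_seed(8, {
    k <- 10^runif(40, -4, 0); kd <- 10^runif(40, -1, 2)
    cc <- 10^runif(40, -1, 3)
    r <- splitRates(k, kd, cc)
    expect_equal(onRate(r) + offRate(r), k, tolerance = 1e-15)
  })
  expect_error(splitRates(-1, 10, 5), "positive")
})

test_that("association-rate regression extracts the bimolecular slope", {
  kT <- thermalEnergy(Conditions())
  kA30 <- 1.01e4 * exp(0.31 * 30 / kT) # ~9.98e4 1/M/s
  cc <- c(2, 5, 10, 25, 50, 150)
  rs <- splitRates(kA30 * cc * 1e-9 + 1.2e-3, Kd = 1.2e-3 / kA30 * 1e9,
                   concentration = cc, force = 30)
  af <- associationRate(rs)
  expect_equal(af@slope, kA30, tolerance = 1e-9)
  expect_equal(round(af@slope / 1e4, 1), 10.0) # ~9.98e4
  expect_true(af@interceptZero)
  # the off rate is concentration-independent: slope consistent with 0
  withr::with_seed(15, {
    koff <- 1.2e-3 * (1 + rnorm(length(cc), 0, 0.05))
    off <- associationRate(data.frame(force = 30, concentration = cc,
                                      kOn = NA, kOff = koff), "kOff")
    expect_lt(abs(off@slope), 3 * off@se[["slope"]])
  })
  expect_error(associationRate(splitRates(1e-3, 10, 5, force = 30)),
               "3 distinct")
})

test_that("fitted net rates on generator data equal kA(F) C + kOff(F)
           within 3 SE", {
  truth <- makeTruth()
  for (cond in list(c(40, 5), c(60, 50))) {
    tr <- simulateTrace(cond[1], cond[2], truth, seed = 31 + cond[1])
    fit <- fitRelaxation(tr, nBoot = 100, seed = 5)
    tv <- truthAt(truth, cond[1], cond[2])
    expect_lt(abs(totalRate(fit) - tv$kTotal),
              3 * stdErrors(fit)[["kTotal"]])
  }
})
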