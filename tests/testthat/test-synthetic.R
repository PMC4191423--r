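test_that("truth construction is self-consistent and rejects
           force-inhibited binding", {
  truth <- makeTruth()
  expect_equal(truth@kOff0 / truth@kA0 * 1e9, 43.96, tolerance = 1e-3)
  expect_equal(truth@perLigandElongation, truth@xOn - truth@xOff)
  expect_error(makeTruth(xOn = 0.14, xOff = 0.14), "xOn")
  expect_error(makeTruth(xOn = 0.1, xOff = 0.2), "xOn")
  # default site-size schedule: endpoints and clamping
  expect_equal(truth@siteSizeFn(10), 3.7)
  expect_equal(truth@siteSizeFn(60), 1.7)
  expect_equal(truth@siteSizeFn(5), 3.7)
  expect_equal(truth@siteSizeFn(65), 1.7)
})

test_that("noiseless traces equal the closed-form relaxation kernel", {
  truth <- makeTruth(noiseSd = 0)
  tr <- simulateTrace(40, 25, truth, seed = 1)
  tv <- truthAt(truth, 40, 25)
  t <- traceTimes(tr)
  expected <- tv$Ldna + tv$thetaEq * (1 - exp(-tv$kTotal * t)) *
    (tv$Lsat - tv$Ldna)
  expect_equal(extensions(tr), expected, tolerance = 1e-14)
  expect_equal(extensions(tr)[1], tv$Ldna, tolerance = 1e-14)
  # saturating concentration drives the plateau to Lsat
  sat <- simulateTrace(40, 5e5, truth, seed = 1)
  expect_gte(length(sat), 10L)
  expect_equal(max(extensions(sat)), tv$Lsat, tolerance = 1e-2)
})

test_that("trace generation is bit-reproducible under a fixed seed", {
  truth <- makeTruth()
  a <- simulateTrace(30, 10, truth, seed = 77)
  b <- simulateTrace(30, 10, truth, seed = 77)
  expect_identical(extensions(a), extensions(b))
  c <- simulateTrace(30, 10, truth, seed = 78)
  expect_false(identical(extensions(a), extensions(c)))
  g1 <- simulateGrid(truth, c(30, 60), c(5, 50), seed = 4)
  g2 <- simulateGrid(truth, c(30, 60), c(5, 50), seed = 4)
  expect_identical(lapply(g1$traces, extensions),
                   lapply(g2$traces, extensions))
  expect_identical(g1$truthTable, g2$truthTable)
})

test_that("grids carry one trace per condition with matching truth rows", {
  truth <- makeTruth()
  g <- simulateGrid(truth, c(20, 50), c(5, 25, 100), replicates = 2,
                    seed = 2)
  expect_length(g$traces, 12)
  expect_equal(nrow(g$truthTable), 12)
  single <- simulateGrid(truth, 30, 10, seed = 2)
  expect_length(single$traces, 1)
  got <- vapply(g$traces, appliedForce, numeric(1))
  expect_setequal(unique(got), c(20, 50))
})

test_that("lattice equilibrium matches the closed-form isotherm", {
  truth <- makeTruth()
  force <- 30
  # concentration near the force-adjusted Kd probes mid-coverage
  kd30 <- truthAt(truth, force)$Kd
  for (fp in 1:3) {
    covs <- vapply(1:8, function(r)
      latticeCoverage(gillespieLattice(force, kd30, truth, footprint = fp,
                                       nSites = 120L * fp,
                                       seed = 100 * fp + r)),
      numeric(1))
    mcSe <- sd(covs) / sqrt(length(covs))
    expect_lt(abs(mean(covs) - mvhCoverage(kd30, kd30, fp)),
              3 * max(mcSe, 5e-3))
  }
})

test_that("lattice limits behave: Langmuir at unit footprint, full
           coverage without unbinding", {
  truth <- makeTruth()
  kd30 <- truthAt(truth, 30)$Kd
  covs <- vapply(1:8, function(r)
    latticeCoverage(gillespieLattice(30, 3 * kd30, truth, footprint = 1,
                                     seed = 500 + r)), numeric(1))
  expect_lt(abs(mean(covs) - 0.75), 3 * max(sd(covs) / sqrt(8), 5e-3))
  # irreversible binding fills the lattice
  noOff <- makeTruth(kOff0 = 1e-30)
  full <- gillespieLattice(30, 50, noOff, footprint = 1, tEnd = 1e5,
                           seed = 9)
  expect_equal(latticeCoverage(full), 1, tolerance = 1e-6)
  expect_error(gillespieLattice(30, 50, truth, footprint = 3,
                                nSites = 150L), "100")
  # footprints never overlap
  traj <- gillespieLattice(30, 5 * kd30, truth, footprint = 2, seed = 12)
  expect_true(all(traj@boundCounts * 2 <= traj@nSites))
})

test_that("lattice relaxation rate is compatible with the two-state
           kernel at unit footprint", {
  truth <- makeTruth(kOff0 = 4.44e-4)
  tv <- truthAt(truth, 40, 50)
  traj <- gillespieLattice(40, 50, truth, footprint = 1, nSites = 400L,
                           seed = 21)
  # coverage at one net-rate time constant should be ~63% of equilibrium
  tc <- 1 / tv$kTotal
  idx <- findInterval(tc, traj@times)
  thEq <- mvhCoverage(50, tv$Kd, 1)
  expect_equal(traj@boundCounts[idx] / 400 / thEq, 1 - exp(-1),
               tolerance = 0.35)
})
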