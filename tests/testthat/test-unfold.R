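## a slightly jittered helix lifts the exact energy degeneracy of the ideal
## geometry so that bonds break over a range of E rather than in one step
jitteredHelix <- function(n = 12) {
  makeHelixStructure(HelixFixtureSpec(n), jitter_sd = 0.08, jitter_seed = 7)
}

test_that("energy-temperature map is affine, invertible and matches the
           reference conversions", {
  expect_equal(energyToTemperature(0), 26.85)
  expect_lt(abs(energyToTemperature(0.45) - 36), 0.3)
  expect_lt(abs(energyToTemperature(1.83) - 63.4), 0.3)
  expect_lt(abs(energyToTemperature(2.16) - 70.2), 0.3)
  E <- seq(0, 5, 0.25)
  expect_equal(temperatureToEnergy(energyToTemperature(E)), E)
  ## affine: equal increments in E give equal increments in T
  expect_equal(diff(energyToTemperature(E)), rep(5, length(E) - 1))
})

test_that("unfolding sweep obeys the global-index invariants", {
  tr <- simulateUnfolding(jitteredHelix())
  expect_true(all(diff(tr@phi) >= -1e-12))   # flexibility only grows
  expect_true(all(diff(tr@pi) <= 1e-12))     # giant cluster only shrinks
  expect_true(all(tr@sigma >= 0))
  expect_equal(tr@pi[1], 1)
  ## terminal state: all hydrogen bonds gone, indexes at their extremes
  last <- length(tr@energy)
  expect_equal(tr@pi[last], min(tr@pi))
  expect_equal(tr@phi[last], max(tr@phi))
  ## entropy returns toward zero once every body is independent
  expect_lt(tr@sigma[last], 1e-12)
  expect_gt(max(tr@sigma), tr@sigma[last])
})

test_that("cluster entropy vanishes at both extremes of clustering", {
  allOne <- new("RigidDecomposition", labels = rep(1L, 30),
                floppyModes = 0L, giantCluster = 1L)
  singletons <- new("RigidDecomposition", labels = 1:30,
                    floppyModes = 10L, giantCluster = 1L)
  expect_equal(clusterEntropy(allOne), 0)
  expect_equal(clusterEntropy(singletons), 0)
  ## entropy reflects disorder of the size distribution: a polydisperse
  ## split is disordered, a monodisperse one is not
  split21 <- new("RigidDecomposition", labels = rep(1:2, c(20, 10)),
                 floppyModes = 0L, giantCluster = 1L)
  w <- c(20, 10) / 30
  expect_equal(clusterEntropy(split21), -sum(w * log(w)))
  mono <- new("RigidDecomposition", labels = rep(1:2, each = 15),
              floppyModes = 0L, giantCluster = 1L)
  expect_equal(clusterEntropy(mono), 0)
})

test_that("transition detection finds single steps and flags trends", {
  mkTrace <- function(y) new("UnfoldingTrace",
    energy = seq(0, by = 0.1, length.out = length(y)),
    phi = seq(0, 1, length.out = length(y)), sigma = y,
    pi = rev(y) / max(y), decompositions = list(),
    network = buildNetwork(makeHelixStructure(HelixFixtureSpec(4))))
  step <- c(rep(0, 5), rep(1, 5))
  expect_equal(detectTransition(mkTrace(step), "sigma"), 0.5)
  expect_equal(detectTransition(mkTrace(step), "pi"), 0.5)
  lin <- seq(0, 1, length.out = 11)
  expect_true(is.na(detectTransition(mkTrace(lin), "sigma")))
  expect_true(is.na(detectTransition(mkTrace(rep(0.3, 8)), "sigma")))
  ## on the helix the entropy transition fires at or before the collapse
  tr <- simulateUnfolding(jitteredHelix())
  eSig <- detectTransition(tr, "sigma")
  ePi <- detectTransition(tr, "pi")
  expect_false(is.na(eSig) || is.na(ePi))
  expect_lte(eSig, ePi)
})

test_that("fuzzy ensembles are seeded, reproducible and degenerate at
           sigma_E = 0", {
  hx <- jitteredHelix(10)
  z <- fuzzyEnsemble(hx, n_topologies = 3, sigma_E = 0, seed = 1)
  expect_equal(z@sigmaSD, 0)
  expect_equal(z@piSD, 0)
  a <- fuzzyEnsemble(hx, n_topologies = 6, sigma_E = 0.2, seed = 11)
  b <- fuzzyEnsemble(hx, n_topologies = 6, sigma_E = 0.2, seed = 11)
  expect_equal(a@piTransitions, b@piTransitions)
  expect_equal(as.data.frame(a@profile), as.data.frame(b@profile))
  c <- fuzzyEnsemble(hx, n_topologies = 6, sigma_E = 0.2, seed = 12)
  expect_false(identical(a@piTransitions, c@piTransitions))
})

test_that("ensemble transition statistics are consistent with the
           single-topology sweep", {
  hx <- jitteredHelix(10)
  single <- detectTransition(simulateUnfolding(hx), "sigma")
  ens <- fuzzyEnsemble(hx, n_topologies = 50, sigma_E = 0.2, seed = 5)
  expect_gt(ens@sigmaSD, 0)
  expect_lt(abs(ens@sigmaMean - single), 2 * ens@sigmaSD + 1e-9)
  ## doubling the ensemble moves the mean by no more than about two
  ## standard errors of the smaller ensemble
  ens2 <- fuzzyEnsemble(hx, n_topologies = 100, sigma_E = 0.2, seed = 5)
  expect_lt(abs(ens2@piMean - ens@piMean), 2 * ens@piSD / sqrt(50) + 1e-9)
  expect_lt(abs(ens2@sigmaMean - ens@sigmaMean),
            2 * ens@sigmaSD / sqrt(50) + 1e-9)
})

test_that("local indexes separate rigid cores from floppy termini", {
  ## without hydrogen bonds nothing is ever rigid: P = R = 0 everywhere
  ext <- makeHelixStructure(HelixFixtureSpec(6, phi = 180, psi = 180))
  pext <- localIndexes(simulateUnfolding(ext, E_max = 1))
  expect_true(all(pext@P == 0))
  expect_true(all(pext@R == 0))
  ## helix: both termini leave the giant cluster below the central residues
  tr <- simulateUnfolding(jitteredHelix())
  prof <- localIndexes(tr)
  df <- as.data.frame(prof)
  central <- df[df$resid %in% 5:8, ]
  termini <- df[df$resid %in% c(1, 12), ]
  expect_lt(max(termini$P), min(central$P))
  expect_lt(max(termini$R), min(central$R))
  expect_true(all(df$F >= 0 & df$F <= 1))
})

test_that("weak-spot frequencies identify at least one nucleus per
           topology", {
  hx <- jitteredHelix(10)
  ens <- fuzzyEnsemble(hx, n_topologies = 20, sigma_E = 0.2, seed = 9)
  ok <- sum(!is.na(ens@piTransitions))
  expect_gt(ok, 0)
  ## every topology with a detected transition contributes >= 1 weak spot
  expect_gte(sum(ens@profile@F), ok / ens@nTopologies)
  expect_true(all(ens@profile@F <= 1))
})

test_that("structure annotation round-trips index values through PDB", {
  d <- withr::local_tempdir()
  hx <- jitteredHelix(8)
  prof <- localIndexes(simulateUnfolding(hx))
  paths <- annotateStructure(hx, prof, E_list = c(0.5, 2.0), index = "P",
                             dir = d)
  expect_equal(length(paths), 2)
  back <- readStructure(paths[1])
  pdb <- bio3d::read.pdb(paths[1], verbose = FALSE)
  perRes <- tapply(pdb$atom$b, back@atoms$resid, unique)
  expect_equal(as.numeric(perRes),
               round(prof@P[match(sort(unique(back@atoms$resid)),
                                  prof@resid)], 2),
               tolerance = 5e-3)
  ## the snapshot below the first bond loss equals the native annotation
  n1 <- readLines(paths[1]); n2 <- readLines(paths[2])
  expect_identical(substring(n1, 61, 66), substring(n2, 61, 66))
  ## residue mismatch is an error
  small <- new("ResidueProfile", resid = 1:3, P = c(0, 0, 0),
               R = c(0, 0, 0), F = c(0, 0, 0))
  expect_error(annotateStructure(hx, small, 0.5, "P", d), "cover")
})
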