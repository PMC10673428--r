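test_that("spectral mass center matches direct arithmetic and is intensive", {
  expect_equal(spectralCenter(SpectralTrace(500, 1)), 2.0)
  ## equal intensities at 400 and 500 nm: (1/400 + 1/500)/2 in nm^-1
  expect_equal(spectralCenter(SpectralTrace(c(400, 500), c(1, 1))), 2.25)
  set.seed(11)
  for (k in 1:20) {
    wl <- sort(runif(15, 300, 450))
    it <- runif(15, 0, 5)
    v <- spectralCenter(SpectralTrace(wl, it))
    expect_equal(spectralCenter(SpectralTrace(wl, 10 * it)), v)
    expect_gte(v, 1000 / max(wl))
    expect_lte(v, 1000 / min(wl))
  }
  expect_error(spectralCenter(SpectralTrace(c(400, 500), c(0, 0))), "> 0")
})

test_that("Hill model has the right midpoint and step limits", {
  for (n in c(0.5, 1, 2, 8))
    expect_equal(hillEval(4.2, 4.2, n, Xa = 3, Xb = 1), 2)
  ## n -> infinity approaches a two-level step
  expect_equal(hillEval(c(3.9, 4.1), 4, n = 1e4, Xa = 1, Xb = 0), c(1, 0),
               tolerance = 1e-12)
})

test_that("titration fitting recovers truth on exact and noisy data", {
  cv0 <- makeTitrationCurve(5.8, 1, 1, 0, seq(3, 9, 0.25), NoiseSpec(0))
  f0 <- fitTitration(cv0)
  expect_true(isConverged(f0))
  expect_equal(coef(f0)[["pKa"]], 5.8, tolerance = 1e-6)
  expect_equal(coef(f0)[["n"]], 1, tolerance = 1e-6)
  ## seeded noisy recovery inside the reported experimental uncertainty
  cv <- makeTitrationCurve(4.0, 1, 1, 0, seq(2, 8, 0.25),
                           NoiseSpec(0.02, seed = 1))
  f <- fitTitration(cv)
  expect_lt(abs(coef(f)[["pKa"]] - 4.0), 0.3)
  ## a constant signal is unidentifiable
  flat <- DenaturationCurve("pH", seq(2, 8, 1), rep(1, 7))
  expect_error(fitTitration(flat), "unidentifiable")
})

test_that("LEM Gibbs energy is linear with a sign flip at the midpoint", {
  expect_equal(lemGibbs(2, 1.5, 1.5), 0)
  expect_equal(lemGibbs(2, 1.5, 0), 3.0)
  expect_gt(lemGibbs(2, 1.5, 1.0), 0)
  expect_lt(lemGibbs(2, 1.5, 2.0), 0)
})

test_that("chemical fitting recovers truth and flags degenerate input", {
  cv <- makeChemicalCurve(2, 1.5, 1, 0, seq(0, 4, 0.1), 298.15, NoiseSpec(0))
  f <- fitChemical(cv)
  expect_true(isConverged(f))
  expect_equal(coef(f)[["m"]], 2, tolerance = 1e-6)
  expect_equal(coef(f)[["D_half"]], 1.5, tolerance = 1e-6)
  ## at the fitted midpoint the model equals the mean of the baselines
  est <- coef(f)
  dh <- est[["D_half"]]
  K <- exp(-est[["m"]] * (dh - dh) / (GAS_CONSTANT_KCAL * 298.15))
  mid <- ((est[["XN"]] + est[["sN"]] * dh) + (est[["XD"]] + est[["sD"]] * dh) *
            K) / (1 + K)
  expect_equal(mid, mean(c(est[["XN"]] + est[["sN"]] * dh,
                           est[["XD"]] + est[["sD"]] * dh)))
  ## apparent-parameter caveat is always attached
  expect_match(f@caveat, "irreversible")
  ## monotone linear input has no sigmoidal region
  lin <- DenaturationCurve("denaturant_M", seq(0, 4, 0.25),
                           seq(1, 0.5, length.out = 17),
                           temperatureK = 298.15)
  expect_false(isConverged(fitChemical(lin)))
})

test_that("thermal fitting recovers the reference CD midpoint", {
  ## dG(Tm) = 0 for any dCp in the Gibbs-Helmholtz expression
  for (dcp in c(0, 0.5, 1.5))
    expect_equal(transitionGibbs(TransitionParams(66, 60, dcp), 339.15), 0)
  gr <- seq(25, 80, 0.2)
  bl <- BaselineParams(1, -0.002, 0.1, -0.001)
  range0 <- diff(range(thermofluorSignal(TransitionParams(66, 60), bl, gr)))
  cv <- makeThermofluorTrace(TransitionParams(66, 60), bl, gr,
                             NoiseSpec(0.01 * range0, seed = 1))
  f <- fitThermal(cv)
  expect_true(isConverged(f))
  expect_lt(abs(coef(f)[["Tm"]] - 66), 1)
  ## flat curve flags rather than fits
  flat <- DenaturationCurve("temperature_C", gr, rep(1, length(gr)))
  expect_false(isConverged(fitThermal(flat)))
})

test_that("van't Hoff fit with fixed dCp agrees with a grid-search oracle", {
  gr <- seq(40, 85, 0.5)
  bl <- BaselineParams(1, 0, 0, 0)
  cv <- makeThermofluorTrace(TransitionParams(64, 70), bl, gr, NoiseSpec(0))
  f <- fitThermal(cv, fix_dCp = 0)
  ## coarse independent grid search over (Tm, dHm) with known flat baselines
  rss <- function(tm, dh) {
    pred <- thermofluorSignal(TransitionParams(tm, dh), bl, gr)
    sum((signalValues(cv) - pred)^2)
  }
  grid <- expand.grid(tm = seq(60, 68, 0.5), dh = seq(40, 100, 5))
  best <- grid[which.min(mapply(rss, grid$tm, grid$dh)), ]
  expect_lt(abs(coef(f)[["Tm"]] - best$tm), 0.5)
  expect_lt(abs(coef(f)[["dHm"]] - best$dh), 5)
  expect_equal(coef(f)[["dCp"]], 0)
})
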