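test_that("titration generator reproduces the Hill model at key points", {
  ## midpoint at pKa for any Hill coefficient
  for (n in c(0.5, 1, 3)) {
    cv <- makeTitrationCurve(4.0, n, Xa = 1, Xb = 0, grid = c(3, 4, 5))
    expect_equal(signalValues(cv)[2], 0.5)
  }
  ## acid limit
  cv <- makeTitrationCurve(4.0, 1, Xa = 1, Xb = 0, grid = c(1.0, 7))
  expect_equal(signalValues(cv)[1], 1, tolerance = 1e-3)
  ## direct arithmetic: pKa 4.7, pH 5.7 -> 10/(1 + 10)
  cv <- makeTitrationCurve(4.7, 1, Xa = 0, Xb = 1, grid = c(4.7, 5.7))
  expect_equal(signalValues(cv)[2], 10 / 11, tolerance = 1e-12)
})

test_that("seeded generation is bit-for-bit reproducible", {
  g <- seq(2, 8, 0.5)
  a <- makeTitrationCurve(4, 1, 1, 0, g, NoiseSpec(0.05, seed = 42))
  b <- makeTitrationCurve(4, 1, 1, 0, g, NoiseSpec(0.05, seed = 42))
  c <- makeTitrationCurve(4, 1, 1, 0, g, NoiseSpec(0.05, seed = 43))
  expect_identical(signalValues(a), signalValues(b))
  expect_false(identical(signalValues(a), signalValues(c)))
  ## generation does not disturb the caller's RNG stream
  set.seed(7); r1 <- rnorm(3)
  set.seed(7)
  invisible(makeTitrationCurve(4, 1, 1, 0, g, NoiseSpec(0.05, seed = 1)))
  expect_identical(rnorm(3), r1)
})

test_that("noiseless curves equal the model evaluation exactly", {
  g <- seq(2, 9, 0.25)
  cv <- makeTitrationCurve(5.2, 1.3, 2, 0.5, g, NoiseSpec(0))
  expect_identical(signalValues(cv), hillEval(g, 5.2, 1.3, 2, 0.5))
  tg <- seq(25, 90, 0.5)
  pr <- TransitionParams(66, 60)
  bl <- BaselineParams(1, -0.01, 0.2, -0.002)
  tr <- makeThermofluorTrace(pr, bl, tg, NoiseSpec(0))
  expect_identical(signalValues(tr), thermofluorSignal(pr, bl, tg))
  ## truth parameters always recorded
  expect_equal(curveMetadata(cv)$truth$pKa, 5.2)
  expect_equal(curveMetadata(tr)$truth$tm, 66)
})

test_that("thermogram generator obeys limits and conserves enthalpy", {
  expect_error(makeThermogram(list(), seq(25, 90, 1)), "1 and 2")
  ## zero enthalpy: flat zero curve
  tg <- makeThermogram(TransitionParams(60, 0), seq(25, 90, 0.5))
  expect_true(all(signalValues(tg) == 0))
  ## reference two-transition parameters integrate to the total enthalpy
  tg <- makeThermogram(list(TransitionParams(52.3, 55),
                            TransitionParams(69.8, 50)),
                       seq(10, 110, 0.05))
  x <- xValues(tg); y <- signalValues(tg)
  integral <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(integral, 105, tolerance = 0.005)
  expect_error(makeThermogram(TransitionParams(60, 50), c(30, 20, 40)),
               "increasing")
})

test_that("thermofluor generator matches the two-state populations", {
  pr <- TransitionParams(71.3, 120)
  flat <- BaselineParams(0, 0, 1, 0)
  ## K = 1 at Tm: midpoint of the baselines
  tr <- makeThermofluorTrace(pr, flat, c(25, 71.3, 90))
  expect_equal(signalValues(tr)[2], 0.5, tolerance = 1e-12)
  ## native limit far below Tm
  expect_equal(signalValues(tr)[1], 0, tolerance = 1e-6)
  ## unfolded population at 75 degC by direct scalar arithmetic
  dG <- 120 * (1 - 348.15 / 344.45)
  K <- exp(-dG / (1.9872e-3 * 348.15))
  tr75 <- makeThermofluorTrace(pr, flat, c(25, 75))
  expect_equal(signalValues(tr75)[2], K / (1 + K), tolerance = 1e-12)
})

test_that("chemical curve generator follows the linear extrapolation model", {
  cv <- makeChemicalCurve(2, 1.5, XN = 1, XD = 0, grid = c(0, 1.5, 6))
  expect_equal(signalValues(cv)[2], 0.5, tolerance = 1e-12)
  expect_equal(signalValues(cv)[3], 0, tolerance = 1e-3)  # denatured limit
  ## direct arithmetic at D = 2, T = 298.15 K
  cv2 <- makeChemicalCurve(2, 1.5, XN = 0, XD = 1, grid = c(0, 2),
                           temperatureK = 298.15)
  expect_equal(signalValues(cv2)[2],
               1 / (1 + exp(-1.0 / (0.0019872 * 298.15))),
               tolerance = 1e-6)
  expect_error(makeChemicalCurve(-1, 1.5, grid = c(0, 1)), "m must be")
  expect_error(makeChemicalCurve(2, 1.5, grid = c(-1, 0, 1)), ">= 0")
})

test_that("noise specification rejects invalid inputs", {
  expect_error(NoiseSpec(-0.1), ">= 0")
  expect_error(makeTitrationCurve(4, 1, 1, 0, numeric(0)), "empty")
})

test_that("helix fixture is deterministic and hydrogen-bondable", {
  hx1 <- makeHelixStructure(HelixFixtureSpec(12))
  hx2 <- makeHelixStructure(HelixFixtureSpec(12))
  expect_identical(hx1@atoms, hx2@atoms)
  hb <- detectHBonds(hx1)
  alpha <- hb[hb$donorRes - hb$acceptorRes == 4, ]
  expect_gte(nrow(alpha), 8)
  ## minimal allowed size is still a valid structure
  hx4 <- makeHelixStructure(HelixFixtureSpec(4))
  expect_s4_class(hx4, "MolecularStructure")
  expect_gte(nrow(detectHBonds(hx4)), 0)
  ## fully extended chain forms no backbone hydrogen bonds
  ext <- makeHelixStructure(HelixFixtureSpec(8, phi = 180, psi = 180))
  expect_equal(nrow(detectHBonds(ext)), 0)
  expect_error(HelixFixtureSpec(3), ">= 4")
})

test_that("curves round-trip through CSV with a JSON truth sidecar", {
  d <- withr::local_tempdir()
  cv <- makeTitrationCurve(4.5, 1, 1, 0, seq(2, 8, 0.5),
                           NoiseSpec(0.02, seed = 3))
  p <- file.path(d, "curve.csv")
  writeCurve(cv, p)
  back <- readCurve(p, "pH")
  expect_equal(xValues(back), xValues(cv))
  expect_equal(signalValues(back), signalValues(cv), tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$truth$pKa, 4.5)
  expect_equal(side$axis_kind, "pH")
})
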