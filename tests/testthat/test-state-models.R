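referenceDscParams <- function()
  list(TransitionParams(52.3, 55), TransitionParams(69.8, 50))

test_that("equilibrium constants follow the Gibbs-Helmholtz expression", {
  expect_equal(equilibriumK(TransitionParams(52.3, 55), 325.45), 1)
  ## scalar arithmetic oracle at 333.15 K
  dG <- 55 * (1 - 333.15 / 325.45)
  expect_equal(equilibriumK(TransitionParams(52.3, 55), 333.15),
               exp(-dG / (1.9872e-3 * 333.15)), tolerance = 1e-12)
  expect_equal(round(equilibriumK(TransitionParams(52.3, 55), 333.15), 1),
               7.1)
  ## zero enthalpy, zero dCp: K = 1 at every temperature
  expect_equal(equilibriumK(TransitionParams(50, 0), c(280, 320, 360)),
               rep(1, 3))
})

test_that("partition functions factorize and coincide in the K2 << K1 limit", {
  expect_equal(partitionTwoTransition(0, 0), 1)
  expect_equal(partitionTwoTransition(1, 1), 4)
  expect_equal(partitionThreeState(0, 5), 1)
  expect_equal(partitionThreeState(1, 1), 3)
  set.seed(5)
  K1 <- runif(50, 0, 20); K2 <- runif(50, 0, 20)
  expect_equal(partitionTwoTransition(K1, K2), (1 + K1) * (1 + K2))
  ## sequential and independent models agree when K2 is negligible
  expect_equal(partitionThreeState(K1, K2 * 1e-9),
               partitionTwoTransition(K1, K2 * 1e-9), tolerance = 1e-7)
})

test_that("populations are normalized, bounded and reproduce the reference maxima", {
  grid <- seq(25, 90, by = 0.01)
  pops <- statePopulations(referenceDscParams(), grid)
  df <- as.data.frame(pops)
  fr <- as.matrix(df[, -1])
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-12)
  ## native dominates far below the first transition
  expect_gt(df$native[1], 0.99)
  ## first intermediate peaks just under 80% near 60 degC
  i1max <- which.max(df$intermediate1)
  expect_lt(df$intermediate1[i1max], 0.80)
  expect_gt(df$intermediate1[i1max], 0.75)
  expect_lt(abs(df$temperature[i1max] - 60), 2)
  ## second intermediate never above 2%
  expect_lt(max(df$intermediate2), 0.02)
  ## with dCp = 0 the native fraction falls and the unfolded fraction rises
  expect_true(all(diff(df$native) <= 1e-12))
  expect_true(all(diff(df$unfolded) >= -1e-12))
})

test_that("average excess enthalpy matches its statistical-mechanics origin", {
  tr <- referenceDscParams()
  expect_equal(averageExcessEnthalpy(tr, 280), 0, tolerance = 1e-3)
  expect_equal(averageExcessEnthalpy(tr, 420), 105, tolerance = 1e-3)
  ## equals R T^2 d(ln Q)/dT by centered differences at random temperatures
  set.seed(9)
  lnQ <- function(tK) {
    K1 <- equilibriumK(tr[[1]], tK); K2 <- equilibriumK(tr[[2]], tK)
    log(partitionTwoTransition(K1, K2))
  }
  for (tK in runif(10, 300, 360)) {
    h <- 1e-3
    numeric <- GAS_CONSTANT_KCAL * tK^2 * (lnQ(tK + h) - lnQ(tK - h)) / (2 * h)
    expect_equal(averageExcessEnthalpy(tr, tK), numeric, tolerance = 1e-6)
  }
})

test_that("analytic heat capacity integrates and differentiates consistently", {
  tr <- referenceDscParams()
  ## zero enthalpies give an identically zero thermogram
  z <- excessHeatCapacity(list(TransitionParams(52, 0),
                               TransitionParams(70, 0)), seq(25, 90, 0.5))
  expect_true(all(signalValues(z) == 0))
  ## quadrature conservation: integral equals dH1 + dH2 with dCp = 0
  tg <- excessHeatCapacity(tr, seq(0, 130, 0.02))
  x <- xValues(tg); y <- signalValues(tg)
  expect_equal(sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2), 105,
               tolerance = 0.01)
  ## closed form equals centered differences of the average enthalpy
  tK <- seq(300, 360, 2.5)
  h <- 1e-4
  numeric <- (averageExcessEnthalpy(tr, tK + h) -
                averageExcessEnthalpy(tr, tK - h)) / (2 * h)
  analytic <- signalValues(excessHeatCapacity(tr, kelvinToCelsius(tK)))
  expect_equal(analytic, numeric, tolerance = 1e-6)
  ## also with nonzero dCp
  tr2 <- list(TransitionParams(52.3, 55, 0.4), TransitionParams(69.8, 50, 0.6))
  numeric2 <- (averageExcessEnthalpy(tr2, tK + h) -
                 averageExcessEnthalpy(tr2, tK - h)) / (2 * h)
  analytic2 <- signalValues(excessHeatCapacity(tr2, kelvinToCelsius(tK)))
  expect_equal(analytic2, numeric2, tolerance = 1e-6)
})

test_that("specific unfolding enthalpy normalizes by molecular mass", {
  ## reference ratio: 105 kcal/mol over the implied mass gives 9.4 cal/g
  mw <- 1000 * 105 / 9.4
  expect_equal(specificUnfoldingEnthalpy(55, 50, mw), 9.4)
  expect_equal(specificUnfoldingEnthalpy(0, 0, 12000), 0)
  expect_equal(specificUnfoldingEnthalpy(30, 40, 10000),
               2 * specificUnfoldingEnthalpy(15, 20, 10000))
  expect_error(specificUnfoldingEnthalpy(55, 50, 0), "> 0")
})
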