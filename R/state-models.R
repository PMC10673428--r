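## Equilibrium statistical-thermodynamic models: the two-state thermal-shift
## model and the two-transition DSC model with state populations, analytic
## excess heat capacity and the sequential three-state comparison model.

#' Gibbs energy and equilibrium constant of one unfolding transition
#'
#' For a transition with melting temperature Tm, enthalpy dH(Tm) and
#' heat-capacity change dCp, the Gibbs energy at temperature T (kelvin) is
#'
#'   dG(T) = dH(Tm) (1 - T/Tm) + dCp (T - Tm - T log(T/Tm))
#'
#' (equivalently dG = dH(1 - T/Tm) - dCp (Tm - T + T log(T/Tm))) and the
#' conformational equilibrium constant is K(T) = exp(-dG/(R T)) with
#' R = 1.9872e-3 kcal mol^-1 K^-1.
#'
#' @param params a [TransitionParams-class] object.
#' @param tempK temperature(s) in kelvin (> 0).
#' @return numeric vector: Gibbs energy in kcal mol^-1, or the
#'   dimensionless equilibrium constant.
#' @examples
#' equilibriumK(TransitionParams(tm = 52.3, dH = 55), 333.15)  # ~7.1
#' @export
transitionGibbs <- function(params, tempK) {
  stopifnot(is(params, "TransitionParams"), all(tempK > 0))
  tmK <- celsiusToKelvin(params@tm)
  params@dH * (1 - tempK / tmK) +
    params@dCp * (tempK - tmK - tempK * log(tempK / tmK))
}

#' @rdname transitionGibbs
#' @export
equilibriumK <- function(params, tempK) {
  exp(-transitionGibbs(params, tempK) / (GAS_CONSTANT_KCAL * tempK))
}

#' Partition functions of the two-transition and three-state models
#'
#' The two-transition model treats the protein as two energetic domains that
#' unfold independently: Q = 1 + K1 + K2 + K1 K2 = (1 + K1)(1 + K2), with
#' states native, intermediate 1 (domain 1 unfolded), intermediate 2
#' (domain 2 unfolded) and unfolded. The sequential three-state model has
#' Q = 1 + K1 + K1 K2. The two coincide when K2 is negligible relative to
#' K1 (widely separated transitions).
#'
#' @param K1,K2 non-negative equilibrium constants (vectorized).
#' @return numeric partition function values.
#' @export
partitionTwoTransition <- function(K1, K2) {
  stopifnot(all(K1 >= 0), all(K2 >= 0))
  1 + K1 + K2 + K1 * K2
}

#' @rdname partitionTwoTransition
#' @export
partitionThreeState <- function(K1, K2) {
  stopifnot(all(K1 >= 0), all(K2 >= 0))
  1 + K1 + K1 * K2
}

## internal: per-temperature state table for either model.
## Returns list(weights = matrix, enthalpies = matrix, dHdT = matrix) with
## one column per state; temperature-dependent dH_i when dCp != 0.
stateTable <- function(transitions, tempK, model = c("two_transition",
                                                     "three_state")) {
  model <- match.arg(model)
  stopifnot(length(transitions) == 2L)
  p1 <- transitions[[1]]; p2 <- transitions[[2]]
  K1 <- equilibriumK(p1, tempK); K2 <- equilibriumK(p2, tempK)
  H1 <- p1@dH + p1@dCp * (tempK - celsiusToKelvin(p1@tm))
  H2 <- p2@dH + p2@dCp * (tempK - celsiusToKelvin(p2@tm))
  one <- rep(1, length(tempK)); zero <- rep(0, length(tempK))
  if (model == "two_transition") {
    w <- cbind(native = one, i1 = K1, i2 = K2, u = K1 * K2)
    H <- cbind(zero, H1, H2, H1 + H2)
    dHdT <- cbind(zero, one * p1@dCp, one * p2@dCp, one * (p1@dCp + p2@dCp))
  } else {
    w <- cbind(native = one, i1 = K1, u = K1 * K2)
    H <- cbind(zero, H1, H1 + H2)
    dHdT <- cbind(zero, one * p1@dCp, one * (p1@dCp + p2@dCp))
  }
  list(weights = w, enthalpies = H, dHdT = dHdT)
}

#' Equilibrium state populations of the two-transition model
#'
#' Populations on a temperature grid: native = 1/Q, intermediate 1 = K1/Q,
#' intermediate 2 = K2/Q, unfolded = K1 K2 / Q with
#' Q = 1 + K1 + K2 + K1 K2.
#'
#' @param transitions list of two [TransitionParams-class] objects
#'   (transition 1 and 2; sorted by Tm internally for labeling only, the
#'   model is symmetric).
#' @param grid increasing temperature grid in degrees Celsius.
#' @return a [StatePopulations-class] object.
#' @examples
#' pops <- statePopulations(list(TransitionParams(52.3, 55),
#'                               TransitionParams(69.8, 50)),
#'                          seq(25, 90, by = 0.5))
#' max(as.data.frame(pops)$intermediate1)  # just under 0.8
#' @export
statePopulations <- function(transitions, grid) {
  grid <- checkGrid(grid, "temperature grid")
  tempK <- celsiusToKelvin(grid)
  st <- stateTable(transitions, tempK, "two_transition")
  Q <- rowSums(st$weights)
  new("StatePopulations", temperature = grid,
      native = st$weights[, 1] / Q,
      intermediate1 = st$weights[, 2] / Q,
      intermediate2 = st$weights[, 3] / Q,
      unfolded = st$weights[, 4] / Q)
}

#' Average excess enthalpy and analytic excess heat capacity
#'
#' The average excess enthalpy relative to the native state is
#' \eqn{\langle \Delta H \rangle = R T^2 \, \partial \ln Q / \partial T
#' = P_1 \Delta H_1 + P_2 \Delta H_2 + P_{12} (\Delta H_1 + \Delta H_2)},
#' and the excess molar heat capacity is its temperature derivative,
#' evaluated here in closed form as the Boltzmann variance of the state
#' enthalpies plus the population-weighted dCp terms:
#'
#'   Cp(T) = Var(H)/(R T^2) + sum_s P_s dCp_s.
#'
#' With dCp = 0 the thermogram integrates exactly to dH1 + dH2.
#'
#' @inheritParams statePopulations
#' @param tempK temperature(s) in kelvin.
#' @param model `"two_transition"` (default) or `"three_state"`.
#' @return `averageExcessEnthalpy`: numeric kcal mol^-1;
#'   `excessHeatCapacity`: a [Thermogram-class].
#' @export
averageExcessEnthalpy <- function(transitions, tempK,
                                  model = "two_transition") {
  st <- stateTable(transitions, tempK, model)
  Q <- rowSums(st$weights)
  rowSums(st$weights * st$enthalpies) / Q
}

#' @rdname averageExcessEnthalpy
#' @export
excessHeatCapacity <- function(transitions, grid, model = "two_transition") {
  grid <- checkGrid(grid, "temperature grid")
  tempK <- celsiusToKelvin(grid)
  Thermogram(grid, excessCpValues(transitions, tempK, model))
}

## internal vectorized Cp evaluation (kelvin input), shared with the fitters.
excessCpValues <- function(transitions, tempK, model = "two_transition") {
  st <- stateTable(transitions, tempK, model)
  Q <- rowSums(st$weights)
  meanH <- rowSums(st$weights * st$enthalpies) / Q
  meanH2 <- rowSums(st$weights * st$enthalpies^2) / Q
  varH <- pmax(meanH2 - meanH^2, 0)
  meanDcp <- rowSums(st$weights * st$dHdT) / Q
  varH / (GAS_CONSTANT_KCAL * tempK^2) + meanDcp
}

#' Two-state thermal-shift (thermofluor) signal model
#'
#' The observed fluorescence is the population-weighted sum of the native
#' and unfolded intrinsic signals, each a linear function of temperature:
#' F(T) = P_N F_N(T) + P_U F_U(T) with F_N = aN + bN T, F_U = aU + bU T,
#' P_U = K/(1+K) and K from the Gibbs-Helmholtz expression of
#' [transitionGibbs()].
#'
#' @param params a [TransitionParams-class].
#' @param baselines a [BaselineParams-class]; baselines are linear in the
#'   Celsius temperature.
#' @param tC temperature(s) in degrees Celsius.
#' @return numeric fluorescence signal.
#' @export
thermofluorSignal <- function(params, baselines, tC) {
  K <- equilibriumK(params, celsiusToKelvin(tC))
  pU <- K / (1 + K)
  fN <- baselines@aN + baselines@bN * tC
  fU <- baselines@aU + baselines@bU * tC
  (1 - pU) * fN + pU * fU
}

#' Specific unfolding enthalpy per gram
#'
#' Combines the enthalpies of the two calorimetric transitions and
#' normalizes by molecular weight: 1000 (dH1 + dH2) / MW, in cal g^-1 with
#' dH in kcal mol^-1 and MW in g mol^-1. A packing-density style comparator
#' between proteins; the molecular weight must be supplied explicitly.
#'
#' @param dH1,dH2 transition enthalpies, kcal mol^-1.
#' @param MW molecular weight, g mol^-1 (> 0).
#' @return numeric, cal g^-1.
#' @export
specificUnfoldingEnthalpy <- function(dH1, dH2, MW) {
  if (!is.numeric(MW) || any(MW <= 0)) stop("MW must be > 0")
  1000 * (dH1 + dH2) / MW
}
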