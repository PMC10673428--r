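## Synthetic-data generators: every input the analysis pipeline consumes can
## be produced here, from the stated signal models plus additive seeded
## Gaussian noise, with the generating truth parameters stored in metadata.

#' Noise specification for synthetic curves
#'
#' Additive, homoscedastic Gaussian measurement noise. The same seed always
#' produces bit-identical output. `sd = NA` requests the module default:
#' 1% of the noiseless signal range for curves and 0.2 kcal mol^-1 K^-1 for
#' thermograms.
#'
#' @param sd standard deviation in signal units (>= 0, or NA for default).
#' @param seed integer RNG seed (NULL leaves the RNG state untouched).
#' @return a list with class `NoiseSpec`.
#' @export
NoiseSpec <- function(sd = NA_real_, seed = NULL) {
  if (!is.na(sd) && sd < 0) stop("noise sd must be >= 0")
  structure(list(sd = sd, seed = seed), class = "NoiseSpec")
}

## resolve a NoiseSpec default against the noiseless signal
resolveSd <- function(noise, y, default = 0.01 * diff(range(y))) {
  if (is.na(noise$sd)) default else noise$sd
}

#' Generate a synthetic pH titration curve
#'
#' Evaluates the Hill titration model (see [hillEval()]) on a pH grid and
#' adds seeded Gaussian noise. Both protonated and deprotonated species
#' contribute to the signal; `Xa` is the acidic-limit signal, `Xb` the
#' basic-limit signal, `pKa` the apparent midpoint and `n` the Hill
#' coefficient.
#'
#' @param pKa apparent midpoint, pH units.
#' @param n Hill coefficient (> 0).
#' @param Xa,Xb acidic / basic intrinsic signals.
#' @param grid strictly increasing pH values.
#' @param noise a [NoiseSpec()].
#' @return a [DenaturationCurve-class] with truth parameters in metadata.
#' @examples
#' cv <- makeTitrationCurve(4.0, 1, 1, 0, seq(2, 8, 0.25),
#'                          NoiseSpec(0.02, seed = 1))
#' @export
makeTitrationCurve <- function(pKa, n = 1, Xa = 1, Xb = 0, grid,
                               noise = NoiseSpec(0)) {
  grid <- checkGrid(grid, "pH grid")
  y <- hillEval(grid, pKa = pKa, n = n, Xa = Xa, Xb = Xb)
  sd <- resolveSd(noise, y)
  DenaturationCurve("pH", grid, addNoise(y, sd, noise$seed),
    metadata = list(truth = list(pKa = pKa, n = n, Xa = Xa, Xb = Xb),
                    noise_sd = sd, seed = noise$seed,
                    model = "hill_titration"))
}

#' Generate a synthetic DSC thermogram
#'
#' Evaluates the analytic excess molar heat capacity of the one- or
#' two-transition equilibrium model ([excessHeatCapacity()]) on a
#' temperature grid and adds seeded Gaussian noise (default sd
#' 0.2 kcal mol^-1 K^-1). A single transition is padded internally with a
#' zero-enthalpy partner so the same two-transition machinery applies.
#'
#' @param transitions list of one or two [TransitionParams-class] objects.
#' @param grid strictly increasing temperatures, degrees Celsius.
#' @param noise a [NoiseSpec()].
#' @return a [Thermogram-class] with truth parameters in metadata.
#' @export
makeThermogram <- function(transitions, grid, noise = NoiseSpec(0)) {
  if (is(transitions, "TransitionParams")) transitions <- list(transitions)
  if (length(transitions) < 1L || length(transitions) > 2L)
    stop("between 1 and 2 transitions are required")
  grid <- checkGrid(grid, "temperature grid")
  tr <- transitions
  if (length(tr) == 1L) tr <- c(tr, list(TransitionParams(tm = 150, dH = 0)))
  y <- excessCpValues(tr, celsiusToKelvin(grid))
  sd <- resolveSd(noise, y, default = 0.2)
  Thermogram(grid, addNoise(y, sd, noise$seed),
    metadata = list(
      truth = lapply(transitions, function(p)
        list(tm = p@tm, dH = p@dH, dCp = p@dCp)),
      noise_sd = sd, seed = noise$seed, model = "two_transition_dsc"))
}

#' Generate a synthetic thermal-shift (thermofluor) trace
#'
#' Evaluates the two-state fluorescence model [thermofluorSignal()] with
#' linear native/unfolded baselines and adds seeded Gaussian noise (default
#' sd 1% of the signal range).
#'
#' @param params a [TransitionParams-class] (Tm, dH, dCp).
#' @param baselines a [BaselineParams-class].
#' @param grid strictly increasing temperatures, degrees Celsius.
#' @param noise a [NoiseSpec()].
#' @return a [DenaturationCurve-class] with truth parameters in metadata.
#' @export
makeThermofluorTrace <- function(params, baselines, grid,
                                 noise = NoiseSpec(0)) {
  grid <- checkGrid(grid, "temperature grid")
  y <- thermofluorSignal(params, baselines, grid)
  sd <- resolveSd(noise, y)
  DenaturationCurve("temperature_C", grid, addNoise(y, sd, noise$seed),
    metadata = list(
      truth = list(tm = params@tm, dH = params@dH, dCp = params@dCp,
                   aN = baselines@aN, bN = baselines@bN,
                   aU = baselines@aU, bU = baselines@bU),
      noise_sd = sd, seed = noise$seed, model = "thermofluor_two_state"))
}

#' Generate a synthetic chemical denaturation curve
#'
#' Two-state model with the linear extrapolation model (LEM) Gibbs energy
#' dG = m ([D]_1/2 - [D]): the signal is
#' (XN + XD exp(-dG/RT)) / (1 + exp(-dG/RT)). Baselines are flat here;
#' [fitChemical()] additionally estimates baseline slopes.
#'
#' @param m LEM slope, kcal mol^-1 M^-1 (> 0).
#' @param D_half midpoint denaturant concentration, M.
#' @param XN,XD native / denatured intrinsic signals.
#' @param grid strictly increasing denaturant concentrations, M (>= 0).
#' @param temperatureK kelvin temperature of the experiment.
#' @param noise a [NoiseSpec()].
#' @return a [DenaturationCurve-class] with truth parameters in metadata.
#' @export
makeChemicalCurve <- function(m, D_half, XN = 1, XD = 0, grid,
                              temperatureK = 298.15, noise = NoiseSpec(0)) {
  if (m <= 0) stop("m must be > 0")
  grid <- checkGrid(grid, "denaturant grid")
  if (any(grid < 0)) stop("denaturant concentrations must be >= 0")
  K <- exp(-lemGibbs(m, D_half, grid) / (GAS_CONSTANT_KCAL * temperatureK))
  y <- (XN + XD * K) / (1 + K)
  sd <- resolveSd(noise, y)
  DenaturationCurve("denaturant_M", grid, addNoise(y, sd, noise$seed),
    temperatureK = temperatureK,
    metadata = list(truth = list(m = m, D_half = D_half, XN = XN, XD = XD),
                    noise_sd = sd, seed = noise$seed, model = "lem_two_state"))
}

#' Write and read synthetic curves as CSV with a JSON truth sidecar
#'
#' `writeCurve()` writes a two-column CSV (`x`, `signal`) and, when truth
#' parameters are present in the metadata, a JSON sidecar `<path>.json`
#' recording them together with the axis kind and noise settings.
#'
#' @param curve a [DenaturationCurve-class] or [Thermogram-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  df <- data.frame(x = xValues(curve), signal = signalValues(curve))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  md <- curveMetadata(curve)
  if (length(md)) {
    side <- c(list(axis_kind = axisKind(curve)), md)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
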