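## Constructors, accessors and show methods for the core containers.

#' Construct a DenaturationCurve
#'
#' @param axisKind `"pH"`, `"denaturant_M"` or `"temperature_C"`.
#' @param x strictly increasing abscissa.
#' @param signal measured signal, same length as `x`.
#' @param temperatureK kelvin temperature of a chemical denaturation
#'   (ignored for other axis kinds).
#' @param metadata list of annotations (truth parameters, provenance).
#' @return a [DenaturationCurve-class] object.
#' @export
DenaturationCurve <- function(axisKind, x, signal, temperatureK = NA_real_,
                              metadata = list()) {
  new("DenaturationCurve", axisKind = axisKind, x = as.numeric(x),
      signal = as.numeric(signal), temperatureK = as.numeric(temperatureK),
      metadata = metadata)
}

#' Construct a Thermogram
#'
#' @param temperature strictly increasing grid in degrees Celsius.
#' @param excessCp excess molar heat capacity, kcal mol^-1 K^-1.
#' @param metadata list of annotations.
#' @return a [Thermogram-class] object.
#' @export
Thermogram <- function(temperature, excessCp, metadata = list()) {
  new("Thermogram", temperature = as.numeric(temperature),
      excessCp = as.numeric(excessCp), metadata = metadata)
}

#' Construct a SpectralTrace
#'
#' @param wavelength wavelengths in nm.
#' @param intensity fluorescence intensities (arbitrary units).
#' @return a [SpectralTrace-class] object.
#' @export
SpectralTrace <- function(wavelength, intensity) {
  new("SpectralTrace", wavelength = as.numeric(wavelength),
      intensity = as.numeric(intensity))
}

#' Construct TransitionParams
#'
#' @param tm melting temperature, degrees Celsius.
#' @param dH unfolding enthalpy at `tm`, kcal mol^-1.
#' @param dCp heat-capacity change, kcal mol^-1 K^-1 (default 0).
#' @return a [TransitionParams-class] object.
#' @export
TransitionParams <- function(tm, dH, dCp = 0) {
  new("TransitionParams", tm = as.numeric(tm), dH = as.numeric(dH),
      dCp = as.numeric(dCp))
}

#' Construct BaselineParams
#'
#' @param aN,bN intercept and slope of the native baseline versus
#'   temperature in degrees Celsius.
#' @param aU,bU intercept and slope of the unfolded baseline.
#' @return a [BaselineParams-class] object.
#' @export
BaselineParams <- function(aN, bN, aU, bU) {
  new("BaselineParams", aN = as.numeric(aN), bN = as.numeric(bN),
      aU = as.numeric(aU), bU = as.numeric(bU))
}

## --- generics --------------------------------------------------------------

#' Accessors for curve-like objects
#'
#' `xValues()` returns the abscissa, `signalValues()` the measured ordinate,
#' `axisKind()` the abscissa kind, and `curveMetadata()` the annotation list.
#'
#' @param object a [DenaturationCurve-class] or [Thermogram-class].
#' @return numeric vector, character scalar or list, respectively.
#' @aliases xValues signalValues axisKind curveMetadata
#' @export
setGeneric("xValues", function(object) standardGeneric("xValues"))

#' @rdname xValues
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))

#' @rdname xValues
#' @export
setGeneric("axisKind", function(object) standardGeneric("axisKind"))

#' @rdname xValues
#' @export
setGeneric("curveMetadata", function(object) standardGeneric("curveMetadata"))

#' @rdname xValues
setMethod("xValues", "DenaturationCurve", function(object) object@x)
#' @rdname xValues
setMethod("signalValues", "DenaturationCurve", function(object) object@signal)
#' @rdname xValues
setMethod("axisKind", "DenaturationCurve", function(object) object@axisKind)
#' @rdname xValues
setMethod("curveMetadata", "DenaturationCurve", function(object) object@metadata)

#' @rdname xValues
setMethod("xValues", "Thermogram", function(object) object@temperature)
#' @rdname xValues
setMethod("signalValues", "Thermogram", function(object) object@excessCp)
#' @rdname xValues
setMethod("axisKind", "Thermogram", function(object) "temperature_C")
#' @rdname xValues
setMethod("curveMetadata", "Thermogram", function(object) object@metadata)

#' Extract fitted coefficients and standard errors
#'
#' @param object an [UnfoldingFit-class] result.
#' @param ... ignored.
#' @return named numeric vector.
#' @export
setMethod("coef", "UnfoldingFit", function(object, ...) object@coefficients)

#' @rdname coef-UnfoldingFit-method
#' @aliases standardErrors
#' @export
setGeneric("standardErrors", function(object) standardGeneric("standardErrors"))

#' @rdname coef-UnfoldingFit-method
setMethod("standardErrors", "UnfoldingFit", function(object) object@se)

#' @rdname coef-UnfoldingFit-method
#' @aliases isConverged
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname coef-UnfoldingFit-method
setMethod("isConverged", "UnfoldingFit", function(object) object@converged)

## --- show methods ----------------------------------------------------------

setMethod("show", "DenaturationCurve", function(object) {
  cat(sprintf("DenaturationCurve (%s): %d points, x in [%.3g, %.3g]\n",
              object@axisKind, length(object@x),
              min(object@x), max(object@x)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "Thermogram", function(object) {
  cat(sprintf("Thermogram: %d points, %.1f-%.1f degC, peak Cp %.3g kcal/mol/K\n",
              length(object@temperature), min(object@temperature),
              max(object@temperature), max(object@excessCp)))
})

setMethod("show", "UnfoldingFit", function(object) {
  cat(sprintf("%s (%s)\n", class(object),
              if (object@converged) "converged" else "NOT converged"))
  est <- object@coefficients
  se <- object@se[names(est)]
  for (nm in names(est))
    cat(sprintf("  %-8s %12.5g  (se %.3g)\n", nm, est[[nm]], se[[nm]]))
  if (length(object@caveat)) cat("  caveat:", object@caveat, "\n")
})

setMethod("show", "MolecularStructure", function(object) {
  cat(sprintf("MolecularStructure: %d atoms, %d residues, %d covalent bonds\n",
              nrow(object@atoms), length(unique(object@atoms$resid)),
              nrow(object@bonds)))
})

setMethod("show", "ConstraintNetwork", function(object) {
  tb <- table(object@edges$type)
  cat(sprintf("ConstraintNetwork: %d bodies; edges: %s\n", object@nBodies,
              paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                    collapse = ", ")))
})

setMethod("show", "UnfoldingTrace", function(object) {
  cat(sprintf(
    "UnfoldingTrace: %d energy steps in [%.2f, %.2f] kcal/mol\n",
    length(object@energy), min(object@energy), max(object@energy)))
  cat(sprintf("  phi %.3f -> %.3f; pi %.3f -> %.3f; max sigma %.3f\n",
              object@phi[1], utils::tail(object@phi, 1), object@pi[1],
              utils::tail(object@pi, 1), max(object@sigma)))
})

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d topologies\n", object@nTopologies))
  cat(sprintf("  sigma transition: %.3f +/- %.3f kcal/mol\n",
              object@sigmaMean, object@sigmaSD))
  cat(sprintf("  pi transition:    %.3f +/- %.3f kcal/mol\n",
              object@piMean, object@piSD))
})

#' Convert trace and profile objects to data frames
#'
#' @param x an [UnfoldingTrace-class] or [ResidueProfile-class].
#' @param ... ignored.
#' @return a base data.frame.
#' @export
setMethod("as.data.frame", "UnfoldingTrace", function(x, ...) {
  data.frame(energy = x@energy, temperature_C = energyToTemperature(x@energy),
             phi = x@phi, sigma = x@sigma, pi = x@pi)
})

#' @rdname as.data.frame-UnfoldingTrace-method
#' @export
setMethod("as.data.frame", "ResidueProfile", function(x, ...) {
  data.frame(resid = x@resid, P = x@P, R = x@R, F = x@F)
})

#' @rdname as.data.frame-UnfoldingTrace-method
#' @export
setMethod("as.data.frame", "StatePopulations", function(x, ...) {
  data.frame(temperature = x@temperature, native = x@native,
             intermediate1 = x@intermediate1, intermediate2 = x@intermediate2,
             unfolded = x@unfolded)
})
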