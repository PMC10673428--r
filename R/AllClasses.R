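#' @import methods
NULL

## ---------------------------------------------------------------------------
## Measured-curve containers
## ---------------------------------------------------------------------------

#' DenaturationCurve: ordered observations of a spectroscopic signal
#'
#' Holds one denaturation curve: a strictly increasing abscissa (pH,
#' denaturant concentration in M, or temperature in degrees Celsius) with the
#' measured signal, plus free-form metadata. Synthetic curves generated by
#' this package store their generating ("truth") parameters in `metadata`
#' so that recovery tests can assert against them.
#'
#' @slot axisKind one of `"pH"`, `"denaturant_M"`, `"temperature_C"`.
#' @slot x numeric, strictly increasing abscissa.
#' @slot signal numeric, same length as `x`.
#' @slot temperatureK scalar kelvin temperature at which a chemical
#'   denaturation was measured (`NA` for other axis kinds).
#' @slot metadata list of free-form annotations.
#' @exportClass DenaturationCurve
setClass("DenaturationCurve",
  representation(axisKind = "character", x = "numeric", signal = "numeric",
                 temperatureK = "numeric", metadata = "list"),
  prototype(temperatureK = NA_real_, metadata = list()))

setValidity("DenaturationCurve", function(object) {
  msg <- character()
  if (!object@axisKind %in% c("pH", "denaturant_M", "temperature_C"))
    msg <- c(msg, "axisKind must be pH, denaturant_M or temperature_C")
  if (length(object@x) != length(object@signal))
    msg <- c(msg, "x and signal must have equal length")
  if (length(object@x) > 1L && any(diff(object@x) <= 0))
    msg <- c(msg, "x must be strictly increasing")
  if (anyNA(object@x) || anyNA(object@signal))
    msg <- c(msg, "x and signal must not contain NA")
  if (length(msg)) msg else TRUE
})

#' SpectralTrace: one emission spectrum
#'
#' Wavelengths (nm) with fluorescence intensities, the input of
#' [spectralCenter()].
#'
#' @slot wavelength numeric nm, > 0.
#' @slot intensity numeric, >= 0, same length.
#' @exportClass SpectralTrace
setClass("SpectralTrace",
  representation(wavelength = "numeric", intensity = "numeric"))

setValidity("SpectralTrace", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@intensity))
    msg <- c(msg, "wavelength and intensity must have equal length")
  if (any(object@wavelength <= 0)) msg <- c(msg, "wavelengths must be > 0")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Thermogram: excess molar heat capacity versus temperature
#'
#' @slot temperature numeric, strictly increasing grid in degrees Celsius.
#' @slot excessCp numeric, excess molar heat capacity in kcal mol^-1 K^-1.
#' @slot metadata list of free-form annotations (truth parameters for
#'   synthetic thermograms).
#' @exportClass Thermogram
setClass("Thermogram",
  representation(temperature = "numeric", excessCp = "numeric",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("Thermogram", function(object) {
  msg <- character()
  if (length(object@temperature) != length(object@excessCp))
    msg <- c(msg, "temperature and excessCp must have equal length")
  if (length(object@temperature) > 1L && any(diff(object@temperature) <= 0))
    msg <- c(msg, "temperature grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Thermodynamic parameter containers
## ---------------------------------------------------------------------------

#' TransitionParams: thermodynamic parameters of one unfolding transition
#'
#' @slot tm melting temperature in degrees Celsius.
#' @slot dH unfolding enthalpy at `tm`, kcal mol^-1 (>= 0).
#' @slot dCp heat-capacity change, kcal mol^-1 K^-1.
#' @exportClass TransitionParams
setClass("TransitionParams",
  representation(tm = "numeric", dH = "numeric", dCp = "numeric"),
  prototype(dCp = 0))

setValidity("TransitionParams", function(object) {
  msg <- character()
  if (length(object@tm) != 1L || !is.finite(object@tm))
    msg <- c(msg, "tm must be a finite scalar")
  if (length(object@dH) != 1L || object@dH < 0)
    msg <- c(msg, "dH must be a scalar >= 0")
  if (length(object@dCp) != 1L || !is.finite(object@dCp))
    msg <- c(msg, "dCp must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' BaselineParams: linear native/unfolded signal baselines
#'
#' Intercepts and slopes of the native and unfolded signals as linear
#' functions of temperature in degrees Celsius: F_N(T) = aN + bN*T and
#' F_U(T) = aU + bU*T.
#'
#' @slot aN,bN,aU,bU numeric scalars (free parameters, no constraints).
#' @exportClass BaselineParams
setClass("BaselineParams",
  representation(aN = "numeric", bN = "numeric",
                 aU = "numeric", bU = "numeric"))

#' StatePopulations: equilibrium populations of the four-state model
#'
#' Populations of native, two intermediates and unfolded states on a
#' temperature grid; rows sum to one.
#'
#' @slot temperature numeric grid in degrees Celsius.
#' @slot native,intermediate1,intermediate2,unfolded numeric fractions in
#'   `[0, 1]`, each the same length as `temperature`.
#' @exportClass StatePopulations
setClass("StatePopulations",
  representation(temperature = "numeric", native = "numeric",
                 intermediate1 = "numeric", intermediate2 = "numeric",
                 unfolded = "numeric"))

setValidity("StatePopulations", function(object) {
  n <- length(object@temperature)
  fr <- cbind(object@native, object@intermediate1,
              object@intermediate2, object@unfolded)
  msg <- character()
  if (nrow(fr) != n) msg <- c(msg, "population lengths must match grid")
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12))
    msg <- c(msg, "populations must lie in [0, 1]")
  if (any(abs(rowSums(fr) - 1) > 1e-12))
    msg <- c(msg, "populations must sum to 1 at every temperature")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Fit results
## ---------------------------------------------------------------------------

#' Virtual parent of all fit-result classes
#'
#' All fits report point estimates, standard errors, a convergence flag,
#' diagnostics and a caveat string. Denaturations of the kind this package
#' models are typically irreversible, so the reported parameters are
#' *apparent* values and each fit carries an explicit irreversibility caveat;
#' no Gibbs energy of folding is derived from chemical fits.
#'
#' @slot coefficients named numeric vector of point estimates.
#' @slot se named numeric vector of standard errors (NA if unavailable).
#' @slot converged logical scalar.
#' @slot diagnostics list (residual variance, iterations, messages).
#' @slot caveat character, human-readable caveats attached to the result.
#' @exportClass UnfoldingFit
setClass("UnfoldingFit",
  representation("VIRTUAL", coefficients = "numeric", se = "numeric",
                 converged = "logical", diagnostics = "list",
                 caveat = "character"),
  prototype(diagnostics = list(), caveat = character()))

#' @rdname UnfoldingFit-class
#' @exportClass TitrationFit
setClass("TitrationFit", contains = "UnfoldingFit")

#' @rdname UnfoldingFit-class
#' @exportClass ChemicalFit
setClass("ChemicalFit", contains = "UnfoldingFit")

#' @rdname UnfoldingFit-class
#' @exportClass ThermalFit
setClass("ThermalFit", contains = "UnfoldingFit")

#' DscFit: result of a multi-transition thermogram deconvolution
#'
#' @slot model `"two_transition"` or `"three_state"`.
#' @slot populations the [StatePopulations-class] computed from the fitted
#'   parameters on the thermogram grid.
#' @exportClass DscFit
setClass("DscFit", contains = "UnfoldingFit",
  representation(model = "character", populations = "StatePopulations"))

## ---------------------------------------------------------------------------
## Structures and rigidity
## ---------------------------------------------------------------------------

#' MolecularStructure: atoms plus covalent bonds
#'
#' A minimal single-chain, single-model structure: one row per atom with
#' element, PDB atom name, 1-based residue index, chain id and coordinates in
#' angstroms, plus a two-column covalent bond list (atom row indices).
#'
#' @slot atoms data.frame with columns `element`, `name`, `resid`, `chain`,
#'   `x`, `y`, `z`.
#' @slot bonds data.frame with integer columns `i`, `j` referencing rows of
#'   `atoms`.
#' @exportClass MolecularStructure
setClass("MolecularStructure",
  representation(atoms = "data.frame", bonds = "data.frame"))

setValidity("MolecularStructure", function(object) {
  msg <- character()
  need <- c("element", "name", "resid", "chain", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else if (!all(is.finite(object@atoms$x) & is.finite(object@atoms$y) &
                is.finite(object@atoms$z)))
    msg <- c(msg, "coordinates must be finite")
  if (nrow(object@bonds)) {
    if (!all(c("i", "j") %in% names(object@bonds)))
      msg <- c(msg, "bonds must have columns i, j")
    else if (any(object@bonds$i < 1) || any(object@bonds$j > nrow(object@atoms)) ||
             any(object@bonds$j < 1) || any(object@bonds$i > nrow(object@atoms)))
      msg <- c(msg, "bond indices must reference valid atoms")
  }
  if (length(msg)) msg else TRUE
})

#' ConstraintNetwork: body-and-bar network for rigidity analysis
#'
#' Atoms are rigid bodies with six degrees of freedom; interactions are typed
#' multi-bar edges. Covalent bonds and hydrogen bonds place five bars
#' (leaving one dihedral degree of freedom), hydrophobic tethers two.
#' Hydrogen-bond edges carry the bond energy so they can be diluted during a
#' simulated unfolding.
#'
#' @slot nBodies integer number of bodies (atoms).
#' @slot edges data.frame with columns `i`, `j` (body indices), `type`
#'   (`"covalent"`, `"hbond"`, `"tether"`), `bars` (2 or 5) and `energy`
#'   (kcal mol^-1, NA for non-H-bond edges).
#' @slot bodyResid integer residue index of each body (for per-residue
#'   indexes).
#' @slot bodyName character atom name of each body.
#' @exportClass ConstraintNetwork
setClass("ConstraintNetwork",
  representation(nBodies = "integer", edges = "data.frame",
                 bodyResid = "integer", bodyName = "character"))

setValidity("ConstraintNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (!all(c("i", "j", "type", "bars", "energy") %in% names(e)))
      msg <- c(msg, "edges must have columns i, j, type, bars, energy")
    else {
      if (any(e$i < 1 | e$i > object@nBodies | e$j < 1 | e$j > object@nBodies))
        msg <- c(msg, "edge endpoints must reference valid bodies")
      if (!all(e$bars %in% c(2L, 5L)))
        msg <- c(msg, "bar multiplicity must be 2 or 5")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RigidDecomposition: output of the pebble game
#'
#' @slot labels integer rigid-cluster label per body (labels partition the
#'   bodies; singletons allowed).
#' @slot floppyModes integer count of internal floppy modes (>= 0).
#' @slot giantCluster integer label of the largest rigid cluster.
#' @exportClass RigidDecomposition
setClass("RigidDecomposition",
  representation(labels = "integer", floppyModes = "integer",
                 giantCluster = "integer"))

setValidity("RigidDecomposition", function(object) {
  msg <- character()
  if (object@floppyModes < 0) msg <- c(msg, "floppy modes must be >= 0")
  if (anyNA(object@labels)) msg <- c(msg, "labels must not contain NA")
  if (length(msg)) msg else TRUE
})

#' UnfoldingTrace: global flexibility indexes along the energy coordinate
#'
#' The reaction coordinate E (kcal mol^-1, >= 0) increases as hydrogen bonds
#' weaker than E are removed. Phi is the floppy mode density (non-decreasing
#' in E), Sigma the cluster configuration entropy (>= 0, near zero at both
#' ends of the process) and Pi the rigidity order parameter (fraction of the
#' initial giant rigid cluster still in a common rigid cluster,
#' non-increasing in E).
#'
#' @slot energy numeric, increasing grid of E values.
#' @slot phi,sigma,pi numeric indexes per grid point.
#' @slot decompositions list of [RigidDecomposition-class] per grid point.
#' @slot network the E = 0 [ConstraintNetwork-class] the sweep started from.
#' @exportClass UnfoldingTrace
setClass("UnfoldingTrace",
  representation(energy = "numeric", phi = "numeric", sigma = "numeric",
                 pi = "numeric", decompositions = "list",
                 network = "ConstraintNetwork"))

setValidity("UnfoldingTrace", function(object) {
  msg <- character()
  n <- length(object@energy)
  if (length(object@phi) != n || length(object@sigma) != n ||
      length(object@pi) != n)
    msg <- c(msg, "phi, sigma, pi must match the energy grid length")
  if (n > 1L && any(diff(object@energy) <= 0))
    msg <- c(msg, "energy grid must be increasing")
  if (any(object@phi < -1e-9 | object@phi > 1 + 1e-9))
    msg <- c(msg, "phi must lie in [0, 1]")
  if (any(object@pi < -1e-9 | object@pi > 1 + 1e-9))
    msg <- c(msg, "pi must lie in [0, 1]")
  if (any(object@sigma < -1e-9)) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ResidueProfile: per-residue local flexibility indexes
#'
#' P (percolation index) is the energy at which a residue's C-alpha leaves
#' the giant rigid cluster; R (rigidity index) the mean energy at which the
#' residue's backbone constraints segregate from their rigid cluster; F the
#' frequency (over an ensemble) with which the residue hosts the earliest
#' newly-flexible constraint at the rigidity-order-parameter transition.
#'
#' @slot resid integer residue indexes.
#' @slot P,R numeric energies in kcal mol^-1.
#' @slot F numeric frequencies in `[0, 1]`.
#' @exportClass ResidueProfile
setClass("ResidueProfile",
  representation(resid = "integer", P = "numeric", R = "numeric",
                 F = "numeric"))

setValidity("ResidueProfile", function(object) {
  n <- length(object@resid)
  msg <- character()
  if (length(object@P) != n || length(object@R) != n || length(object@F) != n)
    msg <- c(msg, "P, R, F must match resid length")
  if (any(object@F < -1e-12 | object@F > 1 + 1e-12))
    msg <- c(msg, "F must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EnsembleResult: fuzzy-ensemble simulated unfolding summary
#'
#' @slot nTopologies integer, number of perturbed network topologies.
#' @slot sigmaTransitions,piTransitions numeric per-topology transition
#'   energies (kcal mol^-1; NA where no transition was detected).
#' @slot sigmaMean,sigmaSD,piMean,piSD numeric scalars.
#' @slot profile mean [ResidueProfile-class] over the ensemble.
#' @slot traces list of per-topology [UnfoldingTrace-class] objects (possibly
#'   empty if not retained).
#' @exportClass EnsembleResult
setClass("EnsembleResult",
  representation(nTopologies = "integer",
                 sigmaTransitions = "numeric", piTransitions = "numeric",
                 sigmaMean = "numeric", sigmaSD = "numeric",
                 piMean = "numeric", piSD = "numeric",
                 profile = "ResidueProfile", traces = "list"),
  prototype(traces = list()))

setValidity("EnsembleResult", function(object) {
  msg <- character()
  if (object@nTopologies < 1L) msg <- c(msg, "nTopologies must be >= 1")
  sds <- c(object@sigmaSD, object@piSD)
  if (any(!is.na(sds) & sds < 0)) msg <- c(msg, "SDs must be >= 0")
  if (length(msg)) msg else TRUE
})
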