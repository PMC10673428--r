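## Simulated thermal unfolding of a constraint network: hydrogen bonds are
## removed from the weakest to the strongest along an increasing energy
## coordinate E (kcal/mol, default step 0.1), and the rigidity of each
## intermediate network is decomposed with the pebble game. Global indexes:
## Phi (floppy mode density), Sigma (cluster configuration entropy), Pi
## (rigidity order parameter). The network only changes at the discrete
## bond-strength thresholds, so decompositions are computed once per
## distinct bond set and mapped back onto the energy grid.

#' Linear map between the dilution energy and temperature
#'
#' The reaction coordinate E (kcal mol^-1, positive, increasing during
#' unfolding) maps to temperature through the affine relation
#' T(K) = 300 + 20 E, returned in degrees Celsius; `temperatureToEnergy()`
#' is the exact inverse.
#'
#' @param E energy in kcal mol^-1 (>= 0).
#' @param tC temperature in degrees Celsius.
#' @return numeric vector.
#' @examples
#' energyToTemperature(0)     # 26.85
#' energyToTemperature(0.45)  # 35.85, ~36 degC
#' energyToTemperature(1.83)  # 63.45 degC
#' @export
energyToTemperature <- function(E) {
  stopifnot(all(E >= 0, na.rm = TRUE))
  kelvinToCelsius(300 + 20 * E)
}

#' @rdname energyToTemperature
#' @export
temperatureToEnergy <- function(tC) (celsiusToKelvin(tC) - 300) / 20

#' Simulated thermal unfolding of a structure's constraint network
#'
#' Sweeps the energy coordinate from 0 to `E_max` in steps of `step`
#' (default 0.1 kcal mol^-1). At each E the network retains covalent bonds,
#' tethers and the hydrogen bonds with |E_HB| >= E, and the pebble game
#' reports: Phi, the floppy mode density (non-decreasing in E); Sigma, the
#' mass-weighted cluster configuration entropy (near zero when a single
#' giant cluster exists and again when all bodies are independent); and Pi,
#' the fraction of the E = 0 giant rigid cluster's bodies still sharing a
#' common rigid cluster (non-increasing in E).
#'
#' @param structure a [MolecularStructure-class].
#' @param E_max top of the energy sweep (default: just past the strongest
#'   hydrogen bond).
#' @param step energy step, kcal mol^-1 (> 0).
#' @param hbonds optional precomputed (possibly perturbed) hydrogen-bond
#'   table from [detectHBonds()].
#' @param tethers optional precomputed tether table.
#' @return an [UnfoldingTrace-class].
#' @export
simulateUnfolding <- function(structure, E_max = NULL, step = 0.1,
                              hbonds = NULL, tethers = NULL) {
  stopifnot(is(structure, "MolecularStructure"), step > 0)
  if (is.null(hbonds)) hbonds <- detectHBonds(structure)
  if (is.null(tethers)) tethers <- detectTethers(structure)
  strengths <- abs(hbonds$energy)
  if (is.null(E_max))
    E_max <- if (length(strengths)) ceiling(max(strengths) / step + 1) * step
             else 10 * step
  grid <- seq(0, E_max, by = step)
  net0 <- buildNetwork(structure, 0, hbonds = hbonds, tethers = tethers)
  n <- net0@nBodies
  ## kept-bond count per grid point; identical counts = identical network
  kept <- vapply(grid, function(E) sum(strengths >= E), integer(1))
  ## evaluate from the sparsest network down, inserting bonds incrementally
  st <- newPebbleState(n)
  base <- net0@edges[net0@edges$type != "hbond", , drop = FALSE]
  if (nrow(base))
    for (k in seq_len(nrow(base)))
      psInsertEdge(st, base$i[k], base$j[k], base$bars[k])
  hb <- net0@edges[net0@edges$type == "hbond", , drop = FALSE]
  hb <- hb[order(abs(hb$energy), decreasing = TRUE), , drop = FALSE]  # strongest first
  decos <- vector("list", length(grid))
  inserted <- 0L
  prevKept <- -1L
  for (gi in rev(seq_along(grid))) {
    nk <- kept[gi]
    if (nk == prevKept) { decos[[gi]] <- decos[[gi + 1L]]; next }
    while (inserted < nk) {
      inserted <- inserted + 1L
      psInsertEdge(st, hb$i[inserted], hb$j[inserted], hb$bars[inserted])
    }
    cur <- rbind(base[, c("i", "j")], hb[seq_len(inserted), c("i", "j")])
    labels <- psClusters(st, uniquePairs(
      data.frame(i = cur$i, j = cur$j)))
    decos[[gi]] <- decompositionFromLabels(labels, sum(st$pebbles) - 6L)
    prevKept <- nk
  }
  ref <- which(decos[[1L]]@labels == decos[[1L]]@giantCluster)
  phi <- vapply(decos, floppyModeDensity, numeric(1), nBodies = n)
  sigma <- vapply(decos, clusterEntropy, numeric(1))
  piv <- vapply(decos, giantClusterOverlap, numeric(1), reference = ref)
  new("UnfoldingTrace", energy = grid, phi = phi, sigma = sigma, pi = piv,
      decompositions = decos, network = net0)
}

#' Detect the phase-transition energy of a global index
#'
#' For the rigidity order parameter the transition is the energy of the
#' largest single-step drop; for the cluster configuration entropy, of the
#' largest single-step rise. Ties resolve to the lowest energy. A flat
#' trace, a trace with no step in the expected direction, or a perfectly
#' linear trend (no single step stands out) has no transition and returns
#' `NA`.
#'
#' @param trace an [UnfoldingTrace-class].
#' @param index `"sigma"` or `"pi"`.
#' @return transition energy in kcal mol^-1, or `NA_real_` when none.
#' @export
detectTransition <- function(trace, index = c("sigma", "pi")) {
  index <- match.arg(index)
  y <- if (index == "sigma") trace@sigma else trace@pi
  d <- diff(y)
  if (index == "pi") d <- -d          # look for the largest drop
  if (!length(d) || max(d) <= 0) return(NA_real_)
  ## a perfectly uniform trend (linear trace) has no single-step transition
  if (length(d) > 2 && stats::sd(d) < 1e-12) return(NA_real_)
  trace@energy[which.max(d) + 1L]
}

#' Fuzzy-ensemble simulated unfolding
#'
#' De-biases the single-topology analysis by running the unfolding over an
#' ensemble of network topologies generated from one structure: each
#' hydrogen bond's energy is perturbed by seeded Gaussian noise of standard
#' deviation `sigma_E` (kcal mol^-1), mimicking non-covalent constraints
#' randomly breaking or forming in the native state; perturbed bonds whose
#' energy becomes unfavorable (>= 0) are dropped for that topology. The
#' per-index transition energies are reported as mean over the
#' topologies with standard deviation, together with the ensemble-averaged
#' per-residue profile of [localIndexes()].
#'
#' @param structure a [MolecularStructure-class].
#' @param n_topologies number of perturbed topologies (>= 1).
#' @param sigma_E Gaussian energy perturbation sd, kcal mol^-1 (>= 0).
#' @param seed integer root seed; the same seed gives an identical result.
#' @param step,E_max passed to [simulateUnfolding()].
#' @param keep_traces retain the per-topology traces in the result.
#' @return an [EnsembleResult-class].
#' @export
fuzzyEnsemble <- function(structure, n_topologies = 500, sigma_E = 0.2,
                          seed = 1L, step = 0.1, E_max = NULL,
                          keep_traces = FALSE) {
  stopifnot(n_topologies >= 1, sigma_E >= 0)
  hb0 <- detectHBonds(structure)
  tet <- detectTethers(structure)
  if (is.null(E_max)) {
    top <- if (nrow(hb0)) max(abs(hb0$energy)) + 4 * sigma_E else 10 * step
    E_max <- ceiling(top / step + 1) * step
  }
  traces <- vector("list", n_topologies)
  sigE <- piE <- rep(NA_real_, n_topologies)
  for (t in seq_len(n_topologies)) {
    hb <- hb0
    if (sigma_E > 0 && nrow(hb)) {
      hb$energy <- withSeed(deriveSeed(seed, paste0("topology", t)),
                            hb$energy + stats::rnorm(nrow(hb), sd = sigma_E))
      hb <- hb[hb$energy < 0, , drop = FALSE]
    }
    tr <- simulateUnfolding(structure, E_max = E_max, step = step,
                            hbonds = hb, tethers = tet)
    traces[[t]] <- tr
    sigE[t] <- detectTransition(tr, "sigma")
    piE[t] <- detectTransition(tr, "pi")
  }
  prof <- localIndexes(traces)
  new("EnsembleResult", nTopologies = as.integer(n_topologies),
      sigmaTransitions = sigE, piTransitions = piE,
      sigmaMean = mean(sigE, na.rm = TRUE),
      sigmaSD = stats::sd(sigE[!is.na(sigE)]),
      piMean = mean(piE, na.rm = TRUE),
      piSD = stats::sd(piE[!is.na(piE)]),
      profile = prof, traces = if (keep_traces) traces else list())
}

#' Per-residue local flexibility indexes over one or more unfolding runs
#'
#' For each completed run: the percolation index P of a residue is the
#' lowest energy at which its C-alpha body leaves the giant rigid cluster
#' (0 if never part of it); the rigidity index R is the mean over the
#' residue's backbone constraint edges of the energy at which each edge's
#' endpoints stop sharing a rigid cluster; the weak-spot frequency F is the
#' fraction of runs in which the residue hosts (as donor or acceptor) the
#' weakest hydrogen bond removed at the run's rigidity-order-parameter
#' transition step. P and R are averaged over the runs.
#'
#' @param traces an [UnfoldingTrace-class] or list of them (one per
#'   topology).
#' @return a [ResidueProfile-class].
#' @export
localIndexes <- function(traces) {
  if (is(traces, "UnfoldingTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  net <- traces[[1]]@network
  resids <- sort(unique(net@bodyResid))
  nres <- length(resids)
  Pacc <- Racc <- matrix(NA_real_, length(traces), nres)
  Fcount <- rep(0, nres)
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    decos <- tr@decompositions
    grid <- tr@energy
    ref <- which(decos[[1]]@labels == decos[[1]]@giantCluster)
    for (ri in seq_along(resids)) {
      r <- resids[ri]
      ca <- which(tr@network@bodyResid == r & tr@network@bodyName == "CA")[1]
      Pacc[ti, ri] <- percolationEnergy(decos, grid, ref, ca)
      Racc[ti, ri] <- rigidityEnergy(decos, grid, tr@network, r)
    }
    ## weak spot at the Pi transition: the weakest bond removed in that step
    eStar <- detectTransition(tr, "pi")
    if (!is.na(eStar)) {
      hb <- tr@network@edges[tr@network@edges$type == "hbond", , drop = FALSE]
      s <- abs(hb$energy)
      gone <- which(s < eStar & s >= eStar - diff(grid[1:2]))
      if (length(gone)) {
        weakest <- gone[which.min(s[gone])]
        hosts <- unique(net@bodyResid[c(hb$i[weakest], hb$j[weakest])])
        Fcount[match(hosts, resids)] <- Fcount[match(hosts, resids)] + 1
      }
    }
  }
  new("ResidueProfile", resid = as.integer(resids),
      P = colMeans(Pacc), R = colMeans(Racc),
      F = Fcount / length(traces))
}

## lowest grid E at which body `ca` is no longer in the cluster holding the
## plurality of the reference set (0 if outside at E = 0; capped at max E)
percolationEnergy <- function(decos, grid, ref, ca) {
  if (is.na(ca)) return(0)
  for (gi in seq_along(grid)) {
    lab <- decos[[gi]]@labels
    tab <- table(lab[ref])
    giantLab <- as.integer(names(tab)[which.max(tab)])
    if (lab[ca] != giantLab) return(grid[gi])
  }
  grid[length(grid)]
}

## mean segregation energy of the residue's backbone covalent edges
rigidityEnergy <- function(decos, grid, net, r) {
  bb <- which(net@bodyResid == r & net@bodyName %in% c("N", "CA", "C"))
  e <- net@edges
  sel <- e$type == "covalent" & (e$i %in% bb | e$j %in% bb)
  if (!any(sel)) return(0)
  ei <- e$i[sel]; ej <- e$j[sel]
  segE <- vapply(seq_along(ei), function(k) {
    for (gi in seq_along(grid)) {
      lab <- decos[[gi]]@labels
      if (lab[ei[k]] != lab[ej[k]]) return(grid[gi])
    }
    grid[length(grid)]
  }, numeric(1))
  mean(segE)
}

#' Annotate a structure series with a per-residue index
#'
#' Writes one PDB snapshot per requested energy with the chosen local index
#' (`P` or `R`) in the B-factor column of every atom of each residue. The
#' index values themselves do not depend on the snapshot energy (the energy
#' is recorded in the file name), so any monotone color mapping applied
#' downstream is preserved across the series.
#'
#' @param structure a [MolecularStructure-class].
#' @param profile a [ResidueProfile-class] over the same residues.
#' @param E_list energies labeling the snapshots.
#' @param index `"P"` or `"R"`.
#' @param dir output directory.
#' @return character vector of written file paths, invisibly.
#' @export
annotateStructure <- function(structure, profile, E_list, index = c("P", "R"),
                              dir = ".") {
  index <- match.arg(index)
  stopifnot(is(structure, "MolecularStructure"),
            is(profile, "ResidueProfile"))
  resids <- unique(structure@atoms$resid)
  if (!all(resids %in% profile@resid))
    stop("profile does not cover all residues of the structure")
  vals <- slot(profile, index)[match(structure@atoms$resid, profile@resid)]
  paths <- character(length(E_list))
  for (k in seq_along(E_list)) {
    paths[k] <- file.path(dir, sprintf("annotated_%s_E%.2f.pdb", index,
                                       E_list[k]))
    writeStructure(structure, paths[k], bfactor = vals)
  }
  invisible(paths)
}
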