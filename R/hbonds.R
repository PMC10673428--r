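## Hydrogen-bond and hydrophobic-tether detection, and body-and-bar network
## construction.
##
## Hydrogen-bond energies use a Mayo-style distance-and-angle potential of
## the kind used throughout the rigidity-analysis lineage:
##
##   E_HB = V0 * [5 (d0/d)^12 - 6 (d0/d)^10] * cos^2(theta) * exp(-(pi-theta)^6)
##
## with d the donor-acceptor distance, theta the donor-H-acceptor angle, and
## the constants tabulated below. Only favorable candidates (E_HB < 0)
## within the geometric gates are retained.
##
##   constant              value      meaning
##   HB_V0                 8 kcal/mol well depth scale
##   HB_D0                 2.8 A      optimal donor-acceptor distance
##   HB_DIST_CUTOFF        3.6 A      maximum donor-acceptor distance
##   HB_ANGLE_MIN          90 deg     minimum donor-H-acceptor angle
##   TETHER_VDW C/S        1.85/1.95 A united-atom van der Waals radii
##                                    (implicit hydrogens on C and S)
##   TETHER_SLACK          0.25 A     added to the radii sum
##   TETHER_MIN_SEP        2          minimum residue separation

HB_V0 <- 8
HB_D0 <- 2.8
HB_DIST_CUTOFF <- 3.6
HB_ANGLE_MIN <- pi / 2
TETHER_VDW <- c(C = 1.85, S = 1.95)
TETHER_SLACK <- 0.25
TETHER_MIN_SEP <- 2L

## Mayo-style energy for one donor/hydrogen/acceptor triple; angle term is
## dropped when hydrogen coordinates are unavailable (distance_only mode).
hbondEnergy <- function(d_da, theta = NULL) {
  radial <- HB_V0 * (5 * (HB_D0 / d_da)^12 - 6 * (HB_D0 / d_da)^10)
  if (is.null(theta)) return(radial)
  if (theta < HB_ANGLE_MIN) return(0)
  radial * cos(theta)^2 * exp(-(pi - theta)^6)
}

#' Detect backbone hydrogen bonds in a structure
#'
#' Scores all donor (N-H) / acceptor (O) pairs within the distance gate with
#' a Mayo-style distance-and-angle potential (constants documented in the
#' package source and in the vignette) and returns the favorable bonds
#' (E_HB < 0) sorted from weakest to strongest. Donors are nitrogen atoms
#' with a covalently bonded hydrogen; acceptors are oxygen atoms. A
#' structure without polar atoms yields an empty table, not an error.
#'
#' @param structure a [MolecularStructure-class].
#' @param distance_only score with the radial term only (for structures
#'   without hydrogens; donors are then all N atoms).
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom row
#'   indices; `hydrogen` NA in distance-only mode), `donorRes`,
#'   `acceptorRes`, `energy` (kcal mol^-1, negative).
#' @export
detectHBonds <- function(structure, distance_only = FALSE) {
  stopifnot(is(structure, "MolecularStructure"))
  at <- structure@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  acceptors <- which(at$element == "O")
  if (distance_only) {
    donors <- which(at$element == "N")
    hyd <- rep(NA_integer_, length(donors))
  } else {
    bonded <- rbind(as.matrix(structure@bonds),
                    as.matrix(structure@bonds)[, 2:1, drop = FALSE])
    donors <- integer(); hyd <- integer()
    for (i in which(at$element == "N")) {
      hs <- bonded[bonded[, 1] == i, 2]
      hs <- hs[at$element[hs] == "H"]
      for (h in hs) { donors <- c(donors, i); hyd <- c(hyd, h) }
    }
  }
  out <- list()
  for (k in seq_along(donors)) {
    d <- donors[k]
    for (a in acceptors) {
      if (at$resid[a] == at$resid[d]) next
      dda <- vnorm(xyz[a, ] - xyz[d, ])
      if (dda > HB_DIST_CUTOFF || dda < 1.5) next
      th <- if (is.na(hyd[k])) NULL else
        angle3(xyz[d, ], xyz[hyd[k], ], xyz[a, ])
      e <- hbondEnergy(dda, th)
      if (e < 0)
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = hyd[k], acceptor = a,
          donorRes = at$resid[d], acceptorRes = at$resid[a], energy = e)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), donorRes = integer(),
                      acceptorRes = integer(), energy = numeric()))
  res <- do.call(rbind, out)
  res[order(res$energy, decreasing = TRUE), , drop = FALSE]  # weakest first
}

#' Detect hydrophobic tethers
#'
#' Carbon/sulfur atom pairs from residues at least `TETHER_MIN_SEP` apart
#' whose distance is below the sum of their van der Waals radii plus
#' 0.25 angstrom. Tethers contribute two bars to the constraint network and
#' are never diluted during the simulated unfolding.
#'
#' @param structure a [MolecularStructure-class].
#' @return data.frame with columns `i`, `j` (atom rows), `distance`.
#' @export
detectTethers <- function(structure) {
  stopifnot(is(structure, "MolecularStructure"))
  at <- structure@atoms
  cand <- which(at$element %in% names(TETHER_VDW))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  out <- list()
  if (length(cand) > 1L) {
    for (a in seq_len(length(cand) - 1L)) {
      i <- cand[a]
      for (b in seq(a + 1L, length(cand))) {
        j <- cand[b]
        if (abs(at$resid[i] - at$resid[j]) < TETHER_MIN_SEP) next
        cutoff <- TETHER_VDW[[at$element[i]]] + TETHER_VDW[[at$element[j]]] +
          TETHER_SLACK
        dd <- vnorm(xyz[i, ] - xyz[j, ])
        if (dd <= cutoff)
          out[[length(out) + 1L]] <- data.frame(i = i, j = j, distance = dd)
      }
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  do.call(rbind, out)
}

#' Build the body-and-bar constraint network at energy cutoff E
#'
#' Atoms become rigid bodies with six degrees of freedom. Covalent bonds
#' always contribute five bars, hydrophobic tethers always two; a hydrogen
#' bond contributes five bars if and only if its strength satisfies
#' |E_HB| >= E, so increasing E dilutes the network from the weakest bond
#' to the strongest.
#'
#' @param structure a [MolecularStructure-class].
#' @param E energy cutoff, kcal mol^-1 (>= 0).
#' @param hbonds,tethers optional precomputed tables from [detectHBonds()] /
#'   [detectTethers()] (recomputed when NULL).
#' @return a [ConstraintNetwork-class].
#' @export
buildNetwork <- function(structure, E = 0, hbonds = NULL, tethers = NULL) {
  stopifnot(is(structure, "MolecularStructure"), E >= 0)
  at <- structure@atoms
  if (is.null(hbonds)) hbonds <- detectHBonds(structure)
  if (is.null(tethers)) tethers <- detectTethers(structure)
  keep <- abs(hbonds$energy) >= E
  cov <- structure@bonds
  edges <- rbind(
    if (nrow(cov)) data.frame(i = cov$i, j = cov$j, type = "covalent",
                              bars = 5L, energy = NA_real_),
    if (any(keep)) data.frame(
      ## five bars between donor and acceptor heavy atoms
      i = hbonds$donor[keep], j = hbonds$acceptor[keep], type = "hbond",
      bars = 5L, energy = hbonds$energy[keep]),
    if (nrow(tethers)) data.frame(i = tethers$i, j = tethers$j,
                                  type = "tether", bars = 2L,
                                  energy = NA_real_))
  if (is.null(edges))
    edges <- data.frame(i = integer(), j = integer(), type = character(),
                        bars = integer(), energy = numeric())
  new("ConstraintNetwork", nBodies = nrow(at), edges = edges,
      bodyResid = as.integer(at$resid), bodyName = as.character(at$name))
}
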