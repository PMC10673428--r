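## Deterministic poly-alanine structure fixture built from ideal internal
## geometry, the stand-in input for the rigidity module. Constants below are
## standard literature values for peptide backbone geometry:
##
##   bond lengths (angstrom)      bond angles (degrees)
##   N-CA   1.458                 C(-1)-N-CA  121.7
##   CA-C   1.525                 N-CA-C      111.2
##   C-N    1.329                 CA-C-N(+1)  116.2
##   C=O    1.231                 CA-C-O      120.8
##   CA-CB  1.521                 N-CA-CB     110.4
##   N-H    1.010                 omega       180 (trans)
##
## The amide hydrogen is placed in the peptide plane along the outward
## bisector of the N-C(i-1) and N-CA bonds; the first residue carries no
## amide hydrogen (free N terminus).

HELIX_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521, b_n_h = 1.010,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.4)

#' Specification of an ideal helical peptide fixture
#'
#' @param n_residues number of residues (>= 4).
#' @param phi,psi backbone dihedrals in degrees; the default (-57, -47) is
#'   the ideal alpha helix. (180, 180) gives a fully extended chain with no
#'   backbone hydrogen bonds.
#' @param include_backbone_H place amide hydrogens (needed by the
#'   hydrogen-bond detector).
#' @return a list with class `HelixFixtureSpec`.
#' @export
HelixFixtureSpec <- function(n_residues, phi = -57, psi = -47,
                             include_backbone_H = TRUE) {
  if (n_residues < 4) stop("n_residues must be >= 4")
  structure(list(n_residues = as.integer(n_residues), phi = phi, psi = psi,
                 include_backbone_H = isTRUE(include_backbone_H)),
            class = "HelixFixtureSpec")
}

#' Build an ideal poly-alanine helix (or extended chain)
#'
#' Constructs a poly-alanine backbone (N, H, CA, CB, C, O per residue) by
#' internal-coordinate chain extension with the ideal geometry documented in
#' the package source, entirely deterministic. With the default alpha-helical
#' dihedrals the i -> i+4 backbone hydrogen bonds are detectable by
#' [detectHBonds()].
#'
#' @param spec a [HelixFixtureSpec()].
#' @param jitter_sd optional coordinate jitter (angstrom, default 0) applied
#'   with `jitter_seed`; useful to lift the exact degeneracy of the ideal
#'   geometry, in which all hydrogen bonds have identical energy.
#' @param jitter_seed integer seed for the jitter.
#' @return a [MolecularStructure-class] with covalent bonds populated.
#' @examples
#' hx <- makeHelixStructure(HelixFixtureSpec(12))
#' @export
makeHelixStructure <- function(spec, jitter_sd = 0, jitter_seed = 1L) {
  stopifnot(inherits(spec, "HelixFixtureSpec"))
  g <- HELIX_GEOM
  d2r <- pi / 180
  n <- spec$n_residues
  phi <- spec$phi * d2r; psi <- spec$psi * d2r; omega <- pi
  ## backbone N, CA, C positions by NeRF chain extension
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  ## first C placed in the xy plane at the ideal N-CA-C angle
  th <- pi - g$a_n_ca_c * d2r
  C[[1]] <- CA[[1]] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- placeAtom(N[[i]], CA[[i]], C[[i]], g$b_c_n,
                            g$a_ca_c_n * d2r, psi)
    CA[[i + 1]] <- placeAtom(CA[[i]], C[[i]], N[[i + 1]], g$b_n_ca,
                             g$a_c_n_ca * d2r, omega)
    C[[i + 1]] <- placeAtom(C[[i]], N[[i + 1]], CA[[i + 1]], g$b_ca_c,
                            g$a_n_ca_c * d2r, phi)
  }
  rows <- list()
  addRow <- function(name, element, resid, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      element = element, name = name, resid = resid, chain = "A",
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    addRow("N", "N", i, N[[i]])
    if (spec$include_backbone_H && i > 1) {
      ## outward bisector of N-C(i-1) and N-CA
      u <- -(unitv(C[[i - 1]] - N[[i]]) + unitv(CA[[i]] - N[[i]]))
      addRow("H", "H", i, N[[i]] + g$b_n_h * unitv(u))
    }
    addRow("CA", "C", i, CA[[i]])
    ## CB on the tetrahedral direction out of the N-CA-C plane (L chirality)
    un <- unitv(N[[i]] - CA[[i]]); uc <- unitv(C[[i]] - CA[[i]])
    bis <- -unitv(un + uc); perp <- unitv(crossp(uc, un))
    ## rotate off the bisector until the N-CA-CB angle hits its ideal value
    cosb <- sum(un * bis)
    gama <- acos(max(-1, min(1, cos(g$a_n_ca_cb * d2r) / cosb)))
    addRow("CB", "C", i, CA[[i]] +
             g$b_ca_cb * unitv(cos(gama) * bis + sin(gama) * perp))
    addRow("C", "C", i, C[[i]])
    ## carbonyl O anti to the next N (psi + pi about the CA-C axis)
    addRow("O", "O", i, placeAtom(N[[i]], CA[[i]], C[[i]], g$b_c_o,
                                  g$a_ca_c_o * d2r, psi + pi))
  }
  atoms <- do.call(rbind, rows)
  if (jitter_sd > 0) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz <- withSeed(jitter_seed,
                    xyz + stats::rnorm(length(xyz), sd = jitter_sd))
    atoms[, c("x", "y", "z")] <- xyz
  }
  st <- new("MolecularStructure", atoms = atoms,
            bonds = data.frame(i = integer(), j = integer()))
  st@bonds <- backboneBonds(atoms)
  validObject(st)
  st
}

## covalent bonds of the poly-alanine fixture, derived from atom names
backboneBonds <- function(atoms) {
  idx <- function(resid, name) {
    w <- which(atoms$resid == resid & atoms$name == name)
    if (length(w)) w[1] else NA_integer_
  }
  bonds <- list()
  add <- function(i, j) if (!is.na(i) && !is.na(j))
    bonds[[length(bonds) + 1L]] <<- c(i, j)
  for (r in unique(atoms$resid)) {
    add(idx(r, "N"), idx(r, "H"))
    add(idx(r, "N"), idx(r, "CA"))
    add(idx(r, "CA"), idx(r, "CB"))
    add(idx(r, "CA"), idx(r, "C"))
    add(idx(r, "C"), idx(r, "O"))
    add(idx(r, "C"), idx(r + 1, "N"))
  }
  if (!length(bonds)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, bonds)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}
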