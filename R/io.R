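## Shared I/O: curve CSV/TSV reading and PDB structure reading/writing.
## PDB records go through bio3d; covalent bonds are inferred from covalent
## radii (below) unless CONECT records are present, which take precedence.

COVALENT_RADII <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.02)
COVALENT_SLACK <- 0.40

#' Read a two-column denaturation curve from CSV/TSV
#'
#' Accepts comma-, tab- or whitespace-separated files with two numeric
#' columns (x, signal), with or without a header line. Rows are sorted by
#' ascending x; duplicated x values and non-numeric rows are errors.
#'
#' @param path file path.
#' @param axis_kind `"pH"`, `"denaturant_M"` or `"temperature_C"`.
#' @param temperatureK kelvin temperature (required downstream for chemical
#'   fits).
#' @return a [DenaturationCurve-class].
#' @export
readCurve <- function(path, axis_kind, temperatureK = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  hasHeader <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), if (sep == ",") "," else "\\s+")[[1]][1])))
  df <- utils::read.table(path, sep = sep, header = hasHeader,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns (x, signal)")
  x <- suppressWarnings(as.numeric(df[[1]]))
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(x) || anyNA(y)) stop("non-numeric rows in ", path)
  if (length(x) < 4L) stop("at least 4 points are required")
  if (anyDuplicated(x))
    stop("duplicated x value: ", x[duplicated(x)][1])
  o <- order(x)
  DenaturationCurve(axis_kind, x[o], y[o], temperatureK = temperatureK,
                    metadata = list(source = path))
}

#' Read a single-model PDB structure
#'
#' Parses ATOM records with bio3d. Multi-model files, altLoc markers and
#' insertion codes are rejected with a clear error. Covalent bonds come
#' from CONECT records when present; otherwise they are inferred from
#' interatomic distances against the sum of covalent radii plus 0.4
#' angstrom (radii documented in the package source).
#'
#' @param path PDB file path.
#' @return a [MolecularStructure-class].
#' @export
readStructure <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing PDB file: ", path)
  lines <- readLines(path)
  if (sum(grepl("^MODEL ", lines)) > 1L)
    stop("multi-model PDB files are not supported")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  marked <- function(v) any(!is.na(v) & nzchar(trimws(v)))
  if (marked(at$alt) || marked(at$insert))
    stop("altLoc/insertion codes are not supported")
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z))
    stop("missing coordinates in ", path)
  elem <- trimws(at$elesy)
  noel <- !nzchar(elem)
  elem[noel] <- substr(gsub("[0-9]", "", trimws(at$elety[noel])), 1, 1)
  atoms <- data.frame(element = elem, name = trimws(at$elety),
                      resid = as.integer(at$resno),
                      chain = as.character(at$chain),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  conect <- parseConect(lines, at$eleno)
  bonds <- if (nrow(conect)) conect else inferBonds(atoms)
  st <- new("MolecularStructure", atoms = atoms, bonds = bonds)
  validObject(st)
  st
}

## CONECT records -> bond table in atom row indices (precedence over
## distance inference); serial numbers are mapped through eleno.
parseConect <- function(lines, eleno) {
  cl <- grep("^CONECT", lines, value = TRUE)
  if (!length(cl))
    return(data.frame(i = integer(), j = integer()))
  out <- list()
  for (ln in cl) {
    ids <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)),
                                                "\\s+")[[1]]))
    ids <- ids[!is.na(ids)]
    if (length(ids) < 2L) next
    a <- match(ids[1], eleno)
    for (b in match(ids[-1], eleno))
      if (!is.na(a) && !is.na(b) && a < b)
        out[[length(out) + 1L]] <- c(a, b)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- unique(do.call(rbind, out))
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

## distance-based covalent bond inference
inferBonds <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- COVALENT_RADII[atoms$element]
  r[is.na(r)] <- 0.77
  n <- nrow(atoms)
  out <- list()
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    hit <- which(d <= r[i] + r[(i + 1):n] + COVALENT_SLACK & d > 0.4)
    for (j in hit)
      out[[length(out) + 1L]] <- c(i, i + j)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

#' Write a structure as a minimal single-model PDB
#'
#' ATOM records with 1-based residue numbering, occupancy 1.0 and the
#' supplied B-factors (default 0.0), via bio3d.
#'
#' @param structure a [MolecularStructure-class].
#' @param path output path.
#' @param bfactor numeric per-atom B-factors (recycled if scalar).
#' @return `path`, invisibly.
#' @export
writeStructure <- function(structure, path, bfactor = 0) {
  at <- structure@atoms
  n <- nrow(at)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resid, resid = rep("ALA", n),
                   eleno = seq_len(n), elety = at$name,
                   chain = at$chain, o = rep(1, n),
                   b = rep_len(bfactor, n), elesy = at$element)
  invisible(path)
}
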