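## (6,6) pebble game for body-and-bar networks.
##
## Each body carries six pebbles (degrees of freedom). A bar between bodies
## u and v is independent iff seven pebbles can be gathered on {u, v}; an
## accepted bar consumes one pebble and is oriented away from the body that
## paid it. Redundant bars are recorded but consume nothing. The total
## number of free pebbles equals 6 n - rank of the body-bar rigidity
## matroid; internal floppy modes are the free pebbles minus the six trivial
## rigid-body motions. Two bodies belong to the same rigid cluster iff no
## seventh pebble can be gathered on the pair (mutual rigidity, which for
## body-bar frameworks is an equivalence relation), so the rigid clusters
## are read out by pair tests on the network edges followed by a union-find.

newPebbleState <- function(n) {
  e <- new.env(parent = emptyenv())
  e$n <- as.integer(n)
  e$pebbles <- rep(6L, n)
  e$dir <- matrix(0L, n, n)   # dir[u, v] = bars oriented u -> v
  e$redundant <- 0L
  e
}

## Move one free pebble onto u or v if possible (path search along the
## orientation DAG with path reversal); returns TRUE on success.
psGather <- function(st, u, v) {
  n <- st$n
  visited <- logical(n)
  parent <- integer(n)
  stack <- c(u, v)
  visited[c(u, v)] <- TRUE
  parent[c(u, v)] <- 0L
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    succ <- which(st$dir[x, ] > 0L & !visited)
    for (w in succ) {
      visited[w] <- TRUE
      parent[w] <- x
      if (st$pebbles[w] > 0L) {
        ## reverse the path w -> ... -> root, moving the pebble to the root
        st$pebbles[w] <- st$pebbles[w] - 1L
        cur <- w
        while (parent[cur] != 0L) {
          p <- parent[cur]
          st$dir[p, cur] <- st$dir[p, cur] - 1L
          st$dir[cur, p] <- st$dir[cur, p] + 1L
          cur <- p
        }
        st$pebbles[cur] <- st$pebbles[cur] + 1L
        return(TRUE)
      }
      stack <- c(stack, w)
    }
  }
  FALSE
}

## Insert `bars` parallel bars between u and v; returns number accepted.
psInsertEdge <- function(st, u, v, bars) {
  acc <- 0L
  for (b in seq_len(bars)) {
    ok <- TRUE
    while (st$pebbles[u] + st$pebbles[v] < 7L) {
      if (!psGather(st, u, v)) { ok <- FALSE; break }
    }
    if (!ok) { st$redundant <- st$redundant + (bars - b + 1L); break }
    if (st$pebbles[u] > 0L) {
      st$pebbles[u] <- st$pebbles[u] - 1L
      st$dir[u, v] <- st$dir[u, v] + 1L
    } else {
      st$pebbles[v] <- st$pebbles[v] - 1L
      st$dir[v, u] <- st$dir[v, u] + 1L
    }
    acc <- acc + 1L
  }
  acc
}

## TRUE iff u and v are mutually rigid (a seventh pebble cannot be freed).
psRigidPair <- function(st, u, v) {
  if (u == v) return(TRUE)
  while (st$pebbles[u] + st$pebbles[v] < 7L) {
    if (!psGather(st, u, v)) return(TRUE)
  }
  FALSE
}

## Rigid-cluster labels from pair tests over the given undirected edge list
## (two-column matrix of unique body pairs). Union-find; labels are
## canonicalized to the smallest body index in each cluster.
psClusters <- function(st, pairs) {
  n <- st$n
  if (nrow(pairs)) storage.mode(pairs) <- "integer"
  parent <- seq_len(n)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      u <- pairs[k, 1]; v <- pairs[k, 2]
      if (findRoot(u) != findRoot(v) && psRigidPair(st, u, v)) {
        ru <- findRoot(u); rv <- findRoot(v)
        parent[max(ru, rv)] <- min(ru, rv)
      }
    }
  }
  vapply(seq_len(n), findRoot, integer(1))
}

## unique undirected body pairs of a ConstraintNetwork edge table
uniquePairs <- function(edges) {
  if (!nrow(edges)) return(matrix(integer(), 0, 2))
  a <- pmin(edges$i, edges$j); b <- pmax(edges$i, edges$j)
  unique(cbind(a, b))
}

#' Pebble-game rigid-cluster decomposition of a constraint network
#'
#' Runs the (6,6) pebble game on a body-and-bar network: every body has six
#' degrees of freedom, every bar removes one when independent. Returns the
#' rigid-cluster partition (mutual-rigidity equivalence classes), the count
#' of internal floppy modes (free pebbles minus the six trivial rigid-body
#' motions) and the label of the giant (largest) cluster. The decomposition
#' is independent of body input order and of the order in which edges are
#' presented.
#'
#' @param network a [ConstraintNetwork-class].
#' @return a [RigidDecomposition-class].
#' @examples
#' ## a chain of 4 bodies joined by 5-bar edges has 3 internal floppy modes
#' net <- new("ConstraintNetwork", nBodies = 4L,
#'            edges = data.frame(i = 1:3, j = 2:4, type = "covalent",
#'                               bars = 5L, energy = NA_real_),
#'            bodyResid = 1:4, bodyName = rep("X", 4))
#' pebbleGame(net)@floppyModes  # 3
#' @export
pebbleGame <- function(network) {
  stopifnot(is(network, "ConstraintNetwork"))
  n <- network@nBodies
  if (n < 1L) stop("network must contain at least one body")
  st <- newPebbleState(n)
  e <- network@edges
  if (nrow(e)) {
    ## deterministic insertion order
    e <- e[order(e$i, e$j, e$type), , drop = FALSE]
    for (k in seq_len(nrow(e)))
      psInsertEdge(st, e$i[k], e$j[k], e$bars[k])
  }
  labels <- psClusters(st, uniquePairs(e))
  decompositionFromLabels(labels, sum(st$pebbles) - 6L)
}

decompositionFromLabels <- function(labels, floppy) {
  sizes <- table(labels)
  big <- as.integer(names(sizes)[which.max(sizes)])
  new("RigidDecomposition", labels = as.integer(labels),
      floppyModes = as.integer(max(floppy, 0L)), giantCluster = big)
}

#' Global flexibility indexes of one decomposition
#'
#' `floppyModeDensity()` is the floppy mode count over the total internal
#' degrees of freedom 6n - 6. `clusterEntropy()` is the mass-weighted
#' Shannon entropy of the rigid-cluster *size distribution*,
#' \eqn{\Sigma = -\sum_s w_s \log w_s} with \eqn{w_s = s\, n_s / N} summed
#' over the distinct sizes s (n_s clusters of size s, N bodies): zero when
#' a single cluster holds all bodies, zero again when every body is a
#' singleton, and more generally zero for any monodisperse decomposition —
#' it measures the disorder of the size distribution, which peaks while a
#' polydisperse mixture of cluster sizes coexists at the rigidity
#' transition. `giantClusterOverlap()` is the fraction of a reference body
#' set still sharing one rigid cluster (the rigidity order parameter when
#' the reference is the giant cluster of the intact network).
#'
#' @param decomposition a [RigidDecomposition-class].
#' @param nBodies number of bodies.
#' @param reference integer vector of body indices (for the overlap).
#' @return numeric scalar.
#' @export
floppyModeDensity <- function(decomposition, nBodies) {
  if (nBodies < 2L) return(0)
  decomposition@floppyModes / (6 * nBodies - 6)
}

#' @rdname floppyModeDensity
#' @export
clusterEntropy <- function(decomposition) {
  sz <- as.integer(table(decomposition@labels))
  N <- sum(sz)
  ## group clusters by size s: w_s = s * n_s / N
  tab <- table(sz)
  s <- as.integer(names(tab)); ns <- as.integer(tab)
  w <- s * ns / N
  -sum(w * log(w))
}

#' @rdname floppyModeDensity
#' @export
giantClusterOverlap <- function(decomposition, reference) {
  if (!length(reference)) return(0)
  max(table(decomposition@labels[reference])) / length(reference)
}
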