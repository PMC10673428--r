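## Independent generic-rigidity oracle for body-bar networks.
##
## Each body b gets a 6-vector (v, w) of instantaneous velocity and angular
## velocity; a bar with generic endpoints a (on body u) and e (on body v)
## constrains the relative velocity along the bar direction:
##   v_u . d + w_u . (a x d) - v_v . d - w_v . (e x d) = 0,  d = a - e.
## The number of internal floppy modes is the nullity of the stacked
## constraint matrix minus the six trivial rigid-body motions.

oracleCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## edges: data.frame(i, j, bars); returns the rigidity matrix rows
oracleMatrix <- function(n, edges) {
  rows <- list()
  for (k in seq_len(nrow(edges))) {
    u <- edges$i[k]; v <- edges$j[k]
    for (b in seq_len(edges$bars[k])) {
      a <- stats::runif(3, -10, 10)
      e <- stats::runif(3, -10, 10)
      d <- a - e
      row <- numeric(6 * n)
      row[(6 * u - 5):(6 * u)] <- c(d, oracleCross(a, d))
      row[(6 * v - 5):(6 * v)] <- -c(d, oracleCross(e, d))
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

## internal floppy modes = 6n - rank - 6
oracleFloppyModes <- function(n, edges) {
  if (!nrow(edges)) return(6L * n - 6L)
  m <- oracleMatrix(n, edges)
  6L * n - qr(m, tol = 1e-9)$rank - 6L
}

## TRUE iff bodies u, v are mutually rigid: six extra generic bars between
## them add no rank
oracleRigidPair <- function(n, edges, u, v) {
  extra <- data.frame(i = rep(u, 6), j = rep(v, 6), bars = 1L)
  r0 <- if (nrow(edges)) qr(oracleMatrix(n, edges), tol = 1e-9)$rank else 0L
  r1 <- qr(oracleMatrix(n, rbind(edges[, c("i", "j", "bars")], extra)),
           tol = 1e-9)$rank
  r1 == r0
}

## random small body-bar test network as a ConstraintNetwork
randomNetwork <- function(n, nEdges, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  pick <- sample(nrow(pairs), min(nEdges, nrow(pairs)))
  data.frame(i = pairs[pick, 1], j = pairs[pick, 2],
             type = sample(c("covalent", "tether"), length(pick),
                           replace = TRUE),
             bars = sample(c(2L, 5L), length(pick), replace = TRUE),
             energy = NA_real_)
}

asNetwork <- function(n, edges) {
  new("ConstraintNetwork", nBodies = as.integer(n), edges = edges,
      bodyResid = seq_len(n), bodyName = rep("X", n))
}
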