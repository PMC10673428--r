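## small hand-built structure: two residues, donor N-H on residue 2
## pointing at a carbonyl O on residue 1, at a controllable N...O distance
tinyDonorAcceptor <- function(dNO) {
  atoms <- data.frame(
    element = c("C", "O", "N", "H", "C"),
    name = c("C", "O", "N", "H", "CA"),
    resid = c(1L, 1L, 5L, 5L, 5L),
    chain = "A",
    x = c(-1.23, 0, dNO, dNO - 1.01, dNO + 1.0),
    y = c(0.5, 0, 0, 0, 1.1),
    z = 0)
  new("MolecularStructure", atoms = atoms,
      bonds = data.frame(i = c(1L, 3L, 3L), j = c(2L, 4L, 5L)))
}

test_that("hydrogen-bond energies respond to geometry as documented", {
  ## a 5 angstrom donor-acceptor pair is beyond the cutoff
  expect_equal(nrow(detectHBonds(tinyDonorAcceptor(5.0))), 0)
  ## inside the cutoff the pair is favorable
  hb <- detectHBonds(tinyDonorAcceptor(2.9))
  expect_equal(nrow(hb), 1)
  expect_lt(hb$energy, 0)
  ## energy strictly decreases as the distance approaches the optimum
  e <- vapply(seq(3.55, 2.85, by = -0.1),
              function(d) detectHBonds(tinyDonorAcceptor(d))$energy[1],
              numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("helix hydrogen bonds are i -> i+4 and sorted weakest first", {
  hb <- detectHBonds(makeHelixStructure(HelixFixtureSpec(12)))
  strong <- hb[hb$energy < -1, ]
  expect_true(all(strong$donorRes - strong$acceptorRes == 4))
  expect_equal(nrow(strong), 8)
  expect_true(all(diff(hb$energy) <= 0))  # weakest (closest to 0) first
})

test_that("hydrophobic tethers obey cutoff and residue-separation rules", {
  ext <- makeHelixStructure(HelixFixtureSpec(8, phi = 180, psi = 180))
  expect_equal(nrow(detectTethers(ext)), 0)
  ## two CB carbons 3.9 apart from residues 1 and 6: within 1.85+1.85+0.25
  mk <- function(d, r2) {
    atoms <- data.frame(element = "C", name = "CB", resid = c(1L, r2),
                        chain = "A", x = c(0, d), y = 0, z = 0)
    new("MolecularStructure", atoms = atoms,
        bonds = data.frame(i = integer(), j = integer()))
  }
  expect_equal(nrow(detectTethers(mk(3.9, 6L))), 1)
  expect_equal(nrow(detectTethers(mk(4.0, 6L))), 0)  # beyond 3.95 cutoff
  ## adjacent residues are excluded at any distance
  expect_equal(nrow(detectTethers(mk(3.0, 2L))), 0)
})

test_that("network dilution removes hydrogen bonds monotonically", {
  hx <- makeHelixStructure(HelixFixtureSpec(10))
  hb <- detectHBonds(hx)
  net0 <- buildNetwork(hx, 0)
  expect_equal(sum(net0@edges$type == "hbond"), nrow(hb))
  ## above the strongest bond only covalent and tether edges remain
  netTop <- buildNetwork(hx, max(abs(hb$energy)) + 0.1)
  expect_equal(sum(netTop@edges$type == "hbond"), 0)
  expect_equal(sum(netTop@edges$type == "covalent"), nrow(hx@bonds))
  ## edge count versus E is non-increasing and matches direct enumeration
  Es <- seq(0, 8, by = 0.25)
  counts <- vapply(Es, function(E)
    sum(buildNetwork(hx, E, hbonds = hb)@edges$type == "hbond"), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts, vapply(Es, function(E) sum(abs(hb$energy) >= E),
                              integer(1)))
  expect_error(buildNetwork(hx, -0.5), "E >= 0")
})

test_that("pebble game handles canonical small networks", {
  one <- asNetwork(1, data.frame(i = integer(), j = integer(),
                                 type = character(), bars = integer(),
                                 energy = numeric()))
  d1 <- pebbleGame(one)
  expect_equal(d1@floppyModes, 0L)
  expect_equal(length(unique(d1@labels)), 1)
  ## chain of N bodies joined by 5-bar edges: one dihedral per bond
  for (N in c(2, 5, 9)) {
    chain <- asNetwork(N, data.frame(i = 1:(N - 1), j = 2:N,
                                     type = "covalent", bars = 5L,
                                     energy = NA_real_))
    expect_equal(pebbleGame(chain)@floppyModes, N - 1L)
  }
  ## two bodies joined by 7 bars (5 + 2): a single rigid cluster
  pair <- asNetwork(2, data.frame(i = c(1L, 1L), j = c(2L, 2L),
                                  type = c("covalent", "tether"),
                                  bars = c(5L, 2L), energy = NA_real_))
  d <- pebbleGame(pair)
  expect_equal(length(unique(d@labels)), 1)
  expect_equal(d@floppyModes, 0L)
})

test_that("pebble-game floppy modes match the rigidity-matrix rank oracle
           on random small networks", {
  set.seed(2024)
  cases <- 0L
  for (rep in 1:110) {
    n <- sample(3:12, 1)
    edges <- randomNetwork(n, sample(2:(2 * n), 1), seed = 5000 + rep)
    got <- pebbleGame(asNetwork(n, edges))@floppyModes
    want <- oracleFloppyModes(n, edges)
    expect_equal(got, want,
                 label = sprintf("floppy modes, case %d (n=%d)", rep, n))
    cases <- cases + 1L
  }
  expect_gte(cases, 100L)
})

test_that("rigid-cluster labels agree with the rank oracle pair test", {
  for (rep in 1:12) {
    n <- sample(4:9, 1)
    edges <- randomNetwork(n, sample(3:(2 * n), 1), seed = 900 + rep)
    labels <- pebbleGame(asNetwork(n, edges))@labels
    for (k in seq_len(nrow(edges))) {
      u <- edges$i[k]; v <- edges$j[k]
      expect_equal(labels[u] == labels[v],
                   oracleRigidPair(n, edges, u, v),
                   label = sprintf("pair (%d,%d) rep %d", u, v, rep))
    }
  }
})

test_that("decomposition is invariant under body permutation", {
  n <- 8
  edges <- randomNetwork(n, 12, seed = 77)
  base <- pebbleGame(asNetwork(n, edges))
  set.seed(3)
  for (rep in 1:5) {
    perm <- sample(n)
    pedges <- edges
    pedges$i <- perm[edges$i]; pedges$j <- perm[edges$j]
    pd <- pebbleGame(asNetwork(n, pedges))
    expect_equal(pd@floppyModes, base@floppyModes)
    ## same partition up to relabeling
    expect_equal(unname(split(seq_len(n), pd@labels[perm])[
      order(vapply(split(seq_len(n), pd@labels[perm]), min, integer(1)))]),
      unname(split(seq_len(n), base@labels)[
        order(vapply(split(seq_len(n), base@labels), min, integer(1)))]))
  }
})
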