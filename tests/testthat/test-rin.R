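two_ca_structure <- function(d) {
  structure(list(
    id = "pair",
    residues = data.frame(resno = c(1L, 2L), resname = "ALA", atom = "CA",
                          element = "C", x = c(0, d), y = 0, z = 0,
                          stringsAsFactors = FALSE),
    ligands = list()), class = "Structure")
}

test_that("the 7 Angstrom edge rule is sharp and weights equal distances", {
  g1 <- build_rin(two_ca_structure(6.9))
  expect_equal(igraph::ecount(g1), 1L)
  expect_equal(igraph::E(g1)$weight, 6.9)
  g2 <- build_rin(two_ca_structure(7.1))
  expect_equal(igraph::ecount(g2), 0L)
})

test_that("edge sets equal an all-pairs distance scan on random chains", {
  for (seed in 1:4) {
    ch <- make_chain(50, seed = seed)
    g <- build_rin(ch, cutoff = 7.0)
    ca <- ca_coords(ch)
    el <- igraph::as_edgelist(g)
    got <- sort(paste(pmin(as.integer(el[, 1]), as.integer(el[, 2])),
                      pmax(as.integer(el[, 1]), as.integer(el[, 2]))))
    want <- c()
    for (i in 1:49) for (j in (i + 1):50) {
      if (sqrt(sum((ca[i, ] - ca[j, ])^2)) <= 7.0)
        want <- c(want, paste(i, j))
    }
    expect_equal(got, sort(want))
  }
})

test_that("raising the cutoff only adds edges and shortens paths", {
  ch <- make_chain(40, seed = 9)
  g7 <- build_rin(ch, 7); g9 <- build_rin(ch, 9)
  e7 <- apply(igraph::as_edgelist(g7), 1, paste, collapse = "-")
  e9 <- apply(igraph::as_edgelist(g9), 1, paste, collapse = "-")
  expect_true(all(e7 %in% e9))
  p7 <- rin_shortest_paths(g7, 1, 40)
  p9 <- rin_shortest_paths(g9, 1, 40)
  if (p7$reachable) expect_lte(p9$length, p7$length)
})

test_that("betweenness matches hand values and exhaustive enumeration", {
  # path network A-B-C: middle vertex carries the single shortest path
  A <- matrix(NA_real_, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  g <- adjacency_to_rin(A)
  b <- rin_betweenness(g)
  expect_equal(unname(b), c(0, 1, 0))

  # complete unit-weight network: nothing is intermediate
  K <- matrix(1, 5, 5); diag(K) <- NA
  expect_equal(unname(rin_betweenness(adjacency_to_rin(K))), rep(0, 5))

  # random 8-node weighted networks vs exhaustive path enumeration
  set.seed(10)
  for (rep in 1:25) {
    A <- random_network(sample(4:8, 1))
    if (all(is.na(A))) next
    got <- rin_betweenness(adjacency_to_rin(A))
    expect_equal(unname(got), oracle_betweenness(A), tolerance = 1e-9)
  }
})

test_that("shortest paths match Floyd-Warshall and break ties deterministically", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    A <- random_network(n, p_edge = 0.6)
    if (all(is.na(A))) next
    g <- adjacency_to_rin(A)
    D <- oracle_floyd_warshall(A)
    res <- rin_shortest_paths(g, seq_len(n), n)
    for (r in seq_len(nrow(res))) {
      s <- as.integer(res$source[r])
      if (res$reachable[r]) expect_equal(res$length[r], D[s, n],
                                         tolerance = 1e-9)
      else expect_true(is.infinite(D[s, n]))
    }
  }

  # tie-break: two equal-length routes, fewer nodes wins; then lexicographic
  A <- matrix(NA_real_, 4, 4)
  A[1, 4] <- A[4, 1] <- 2.0            # direct, 2 nodes
  A[1, 2] <- A[2, 1] <- 1.0; A[2, 4] <- A[4, 2] <- 1.0  # via 2, same length
  g <- adjacency_to_rin(A)
  expect_equal(rin_shortest_paths(g, 1, 4)$path, "1-4")
  A2 <- matrix(NA_real_, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 1; A2[2, 4] <- A2[4, 2] <- 1
  A2[1, 3] <- A2[3, 1] <- 1; A2[3, 4] <- A2[4, 3] <- 1
  expect_equal(rin_shortest_paths(adjacency_to_rin(A2), 1, 4)$path, "1-2-4")
  expect_error(rin_shortest_paths(g, 99, 1), "unknown residue")
})

test_that("a rigid transform changes neither edges, betweenness nor path lengths", {
  ch <- make_chain(30, seed = 12)
  g <- build_rin(ch)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ch2 <- ch
  xyz <- as.matrix(ch2$residues[, c("x", "y", "z")]) %*% R
  ch2$residues$x <- xyz[, 1] + 11; ch2$residues$y <- xyz[, 2] - 4
  ch2$residues$z <- xyz[, 3] + 2
  g2 <- build_rin(ch2)
  expect_equal(igraph::as_edgelist(g2), igraph::as_edgelist(g))
  expect_equal(igraph::E(g2)$weight, igraph::E(g)$weight, tolerance = 1e-3)
  expect_equal(rin_betweenness(g2), rin_betweenness(g), tolerance = 1e-9)
})

test_that("nucleotide contacts equal a brute-force all-atom scan", {
  s <- read_structure(fixture_pdb_text(with_ligand = TRUE), chain = "A")
  got <- nucleotide_contacts(s, cutoff = 6.5)
  res <- s$residues
  lig <- s$ligands[[1]]$atoms
  want <- c()
  for (rn in unique(res$resno)) {
    ra <- res[res$resno == rn, ]
    hit <- FALSE
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(lig))) {
      d <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                       as.numeric(lig[j, c("x", "y", "z")]))^2))
      if (d <= 6.5) hit <- TRUE
    }
    if (hit) want <- c(want, rn)
  }
  expect_equal(got, sort(want))
  expect_error(nucleotide_contacts(s, het_codes = "GTP"), "no ligand")

  # a single planted residue 3.0 A from the ligand is the only contact
  fx <- make_complex_fixture("hydrogen_bond", seed = 1)
  st <- fx$structure
  st$ligands[[1]]$het_code <- "GDP"
  got2 <- nucleotide_contacts(st, cutoff = 4.0)
  expect_equal(got2, 1L)
})

test_that("center-of-mass distances respect symmetry and trivial cases", {
  one <- structure(list(
    id = "one",
    residues = data.frame(resno = 1L, resname = "GLY", atom = "CA",
                          element = "C", x = 2, y = 3, z = 4,
                          stringsAsFactors = FALSE),
    ligands = list()), class = "Structure")
  expect_equal(unname(center_of_mass_distances(one)), 0)

  # symmetric dimer of identical halves: mirror residues are equidistant
  half <- make_chain(10, seed = 13)$residues
  mirr <- half
  mirr$x <- -mirr$x
  mirr$resno <- mirr$resno + 10L
  dimer <- structure(list(id = "dimer", residues = rbind(half, mirr),
                          ligands = list()), class = "Structure")
  d <- center_of_mass_distances(dimer)
  expect_equal(unname(d[as.character(1:10)]), unname(d[as.character(11:20)]),
               tolerance = 1e-9)
  expect_error(center_of_mass_distances(dimer, residues = 99), "unknown")
})
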