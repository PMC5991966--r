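# Independent oracles used across the suite. These deliberately re-derive
# every quantity by brute force (enumeration, dense DP, numerical
# minimization) without touching the package's implementation paths.

# --- rigid superposition: numerical minimizer over rotations ----------------

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# brute-force minimum RMSD: coarse random-quaternion grid, then Nelder-Mead
# refinement of the best starts (translation handled by centering)
oracle_min_rmsd <- function(P, Q, n_grid = 4000L) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  }
  qs <- matrix(rnorm(4L * n_grid), ncol = 4L)
  vals <- apply(qs, 1L, f)
  best <- order(vals)[1:5]
  res <- vapply(best, function(i) {
    stats::optim(qs[i, ], f, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1))
  min(res)
}

# --- graphs: exhaustive path enumeration ------------------------------------

# all simple paths between two nodes of a weighted adjacency matrix
enumerate_paths <- function(A, from, to) {
  n <- nrow(A)
  out <- list()
  walk <- function(path, total) {
    v <- path[length(path)]
    if (v == to) { out[[length(out) + 1L]] <<- list(path = path, w = total);
      return(invisible()) }
    for (u in seq_len(n)) {
      if (!is.na(A[v, u]) && !(u %in% path)) walk(c(path, u), total + A[v, u])
    }
  }
  walk(from, 0)
  out
}

# normalized betweenness by exhaustive shortest-path counting
oracle_betweenness <- function(A, tol = 1e-9) {
  n <- nrow(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    paths <- enumerate_paths(A, s, t)
    if (length(paths) == 0L) next
    w <- vapply(paths, `[[`, numeric(1), "w")
    short <- paths[w <= min(w) + tol]
    sigma <- length(short)
    inner <- unlist(lapply(short, function(p)
      p$path[-c(1L, length(p$path))]))
    for (v in seq_len(n)) bc[v] <- bc[v] + sum(inner == v) / sigma
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# all-pairs shortest path lengths (Floyd-Warshall)
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- A
  D[is.na(D)] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# random weighted geometric-ish network as an adjacency matrix (NA = no edge)
random_network <- function(n, p_edge = 0.5) {
  A <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (runif(1) < p_edge) A[i, j] <- A[j, i] <- round(runif(1, 1, 10), 3)
  }
  A
}

adjacency_to_rin <- function(A) {
  n <- nrow(A)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  idx <- which(!is.na(A) & upper.tri(A), arr.ind = TRUE)
  if (nrow(idx)) g <- igraph::add_edges(g, as.vector(t(idx)),
                                        weight = A[idx])
  g
}

# --- alignment: exhaustive affine-gap DP ------------------------------------

# global affine-gap alignment score; a gap of length L costs open + L * ext
# (the same convention as the package's aligner)
oracle_nw_score <- function(a, b, open = 10, ext = 0.5,
                            submat = "BLOSUM62") {
  S <- get(data(list = submat, package = "Biostrings",
                envir = environment()))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # last column pair aligned
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (a against -)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1L] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- S[av[i], bv[j]]
    M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                             X[i, j + 1L] - ext)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                             Y[i + 1L, j] - ext)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# --- misc -------------------------------------------------------------------

# Amari index of a permutation/scaling ambiguity between mixing estimates
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(P / apply(P, 2, max)) - 1)
  (r + c) / (2 * n * (n - 1))
}

# neighborhood-preservation (trustworthiness) of an embedding
trustworthiness <- function(X, Y, k) {
  n <- nrow(X)
  DX <- as.matrix(dist(X)); DY <- as.matrix(dist(Y))
  total <- 0
  for (i in seq_len(n)) {
    rank_hi <- order(DX[i, -i])
    hi_ids <- seq_len(n)[-i][rank_hi]
    lo_ids <- seq_len(n)[-i][order(DY[i, -i])][seq_len(k)]
    ranks <- match(lo_ids, hi_ids)
    total <- total + sum(pmax(ranks - k, 0))
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

# tiny handwritten PDB fixture: three residues (SER, GLY, LEU), optionally a
# GDP-like hetero group and a water
fixture_pdb_text <- function(with_ligand = FALSE) {
  l <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   SER A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   SER A   1       3.100   1.600   0.500  1.00  0.00           O",
    "ATOM      5  OG  SER A   1       1.900  -1.000   1.000  1.00  0.00           O",
    "ATOM      6  N   GLY A   2       1.400   2.400  -0.600  1.00  0.00           N",
    "ATOM      7  CA AGLY A   2       1.800   3.800  -0.700  0.60  0.00           C",
    "ATOM      8  CA BGLY A   2       1.900   3.900  -0.800  0.40  0.00           C",
    "ATOM      9  C   GLY A   2       0.900   4.700   0.100  1.00  0.00           C",
    "ATOM     10  O   GLY A   2       0.000   4.200   0.800  1.00  0.00           O",
    "ATOM     11  N   LEU A   3       1.100   6.000   0.000  1.00  0.00           N",
    "ATOM     12  CA  LEU A   3       0.300   7.000   0.700  1.00  0.00           C",
    "ATOM     13  CB  LEU A   3       0.900   8.400   0.500  1.00  0.00           C",
    "ATOM     14  C   LEU A   3      -1.100   7.000   0.100  1.00  0.00           C",
    "ATOM     15  O   LEU A   3      -1.400   6.300  -0.900  1.00  0.00           O")
  if (with_ligand) l <- c(l,
    "HETATM   16  PB  GDP A 201       5.000   5.000   5.000  1.00  0.00           P",
    "HETATM   17  O1B GDP A 201       6.200   5.500   5.400  1.00  0.00           O",
    "HETATM   18  C1* GDP A 201       4.400   6.300   4.400  1.00  0.00           C",
    "HETATM   19  O   HOH A 301       9.000   9.000   9.000  1.00  0.00           O")
  c(l, "TER", "END")
}
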