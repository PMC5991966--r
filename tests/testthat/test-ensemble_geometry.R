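test_that("Kabsch superposition recovers identity and planted rotations", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  self <- kabsch_superpose(P, P)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- P %*% R
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(P, Q, subset = 1:2), "subset")
  # collinear subset is degenerate
  L <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(L, L + 1), "degenerate")
})

test_that("Kabsch matches a numerical rotation-space minimizer on random pairs", {
  set.seed(2)
  for (rep in 1:10) {
    P <- matrix(rnorm(30), ncol = 3)
    Q <- matrix(rnorm(30), ncol = 3)
    k <- kabsch_superpose(P, Q)$rmsd
    o <- oracle_min_rmsd(P, Q, n_grid = 1500L)
    expect_lt(abs(k - o), 1e-3)
    expect_lte(k, o + 1e-9)   # Kabsch is the true optimum
  }
})

test_that("superposition rmsd is invariant under a common rigid transform", {
  set.seed(3)
  P <- matrix(rnorm(30), ncol = 3)
  Q <- matrix(rnorm(30), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  shift <- c(5, -3, 2)
  moved <- kabsch_superpose(sweep(P %*% R, 2, shift, `+`),
                            sweep(Q %*% R, 2, shift, `+`))$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("ensemble superposition collapses rigid copies and never increases core RMSD", {
  gen <- make_ensemble(ensemble_spec(m = 30, n = 8, n_clusters = 1,
                                     mode_sds = numeric(0), sigma = 0,
                                     seed = 11))
  al <- superpose_ensemble(gen$ensemble)
  expect_lt(max(pairwise_rmsd(al)), 1e-6)

  # pre-aligned input is unchanged
  al2 <- superpose_ensemble(al)
  expect_equal(al2$coords, al$coords, tolerance = 1e-9)

  # random noisy ensembles: mean core RMSD to the mean must not increase
  gen2 <- make_ensemble(ensemble_spec(m = 25, n = 10, n_clusters = 2,
                                      sigma = 0.5, seed = 12))
  core_rmsd <- function(ens) {
    mu <- colMeans(ens$coords)
    mean(sqrt(rowMeans((sweep(ens$coords, 2, mu))^2 %*%
                         kronecker(diag(25), rep(1, 3)))))
  }
  before <- core_rmsd(gen2$ensemble)
  after <- core_rmsd(superpose_ensemble(gen2$ensemble))
  expect_lte(after, before + 1e-9)
})

test_that("the invariant core keeps rigid residues and drops noisy ones", {
  # all-identical ensemble: the core is everything
  gen0 <- make_ensemble(ensemble_spec(m = 35, n = 6, n_clusters = 1,
                                      mode_sds = numeric(0), sigma = 0,
                                      seed = 21))
  expect_equal(as.integer(find_invariant_core(gen0$ensemble, floor_size = 5)),
               1:35)

  # floor = m means no iteration
  expect_equal(as.integer(find_invariant_core(gen0$ensemble, floor_size = 35)),
               1:35)

  # residues 1-10 rigid, 11-20 with large independent noise -> core in 1-10
  set.seed(22)
  base <- allostruct:::xyz_row(ca_coords(make_chain(20, seed = 23)))
  X <- t(replicate(8, base))
  noisy_cols <- as.vector(vapply(11:20, function(i) (3 * i - 2):(3 * i),
                                 integer(3)))
  X[, noisy_cols] <- X[, noisy_cols] + rnorm(length(X[, noisy_cols]), sd = 4)
  rownames(X) <- paste0("m", 1:8)
  ens <- allostruct:::new_ensemble_matrix(paste0("m", 1:8), 1:20, X)
  core <- find_invariant_core(ens, v_stop = 0.5, floor_size = 4)
  expect_true(all(core <= 10))
  expect_gte(length(core), 4)
})

test_that("RMSF has a closed form for isotropic noise and vanishes when rigid", {
  gen0 <- make_ensemble(ensemble_spec(m = 20, n = 5, n_clusters = 1,
                                      mode_sds = numeric(0), sigma = 0,
                                      seed = 31))
  al0 <- superpose_ensemble(gen0$ensemble)
  expect_lt(max(ensemble_rmsf(al0)), 1e-6)

  # one residue with isotropic sigma noise, others fixed: RMSF ~ sigma*sqrt(3)
  set.seed(32)
  m <- 5; n <- 2000; sigma <- 0.8
  base <- allostruct:::xyz_row(ca_coords(make_chain(m, seed = 33)))
  X <- matrix(base, n, 3 * m, byrow = TRUE)
  X[, 7:9] <- X[, 7:9] + rnorm(3 * n, sd = sigma)
  ens <- allostruct:::new_ensemble_matrix(paste0("m", 1:n), 1:m, X)
  r <- ensemble_rmsf(ens)   # already aligned by construction
  expect_equal(unname(r[3]), sigma * sqrt(3), tolerance = 0.05)
  expect_lt(max(r[-3]), 1e-9)

  # doubling the ensemble leaves RMSF unchanged
  ens2 <- allostruct:::new_ensemble_matrix(paste0("m", 1:(2 * n)), 1:m,
                                           rbind(X, X))
  expect_equal(ensemble_rmsf(ens2), r, tolerance = 1e-12)
})

test_that("pairwise RMSD matches the direct per-pair formula", {
  gen <- make_ensemble(ensemble_spec(m = 15, n = 6, n_clusters = 2,
                                     sigma = 0.4, seed = 41))
  al <- superpose_ensemble(gen$ensemble)
  sub <- c(2, 5, 9, 14)
  D <- pairwise_rmsd(al, sub)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (a in 1:5) for (b in (a + 1):6) {
    pa <- matrix(al$coords[a, ], ncol = 3, byrow = TRUE)[sub, ]
    pb <- matrix(al$coords[b, ], ncol = 3, byrow = TRUE)[sub, ]
    expect_equal(D[a, b], sqrt(mean(rowSums((pa - pb)^2))), tolerance = 1e-12)
  }
  # duplicated members have zero off-diagonal distance
  X <- al$coords; X[2, ] <- X[1, ]
  al2 <- allostruct:::new_ensemble_matrix(al$ids, al$frame, X)
  expect_equal(pairwise_rmsd(al2)[1, 2], 0)
})

test_that("hierarchical clustering recovers planted groups and exact clustroids", {
  # two far-separated groups
  set.seed(51)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), ncol = 2),
               matrix(rnorm(10, 20, 0.1), ncol = 2))
  D <- as.matrix(dist(pts))
  cm <- hierarchical_cluster(D, k = 2)
  expect_equal(length(unique(cm$labels[1:5])), 1L)
  expect_equal(length(unique(cm$labels[6:10])), 1L)
  expect_false(cm$labels[1] == cm$labels[6])

  # k = n gives singletons, each its own clustroid
  cm_n <- hierarchical_cluster(D, k = 10)
  expect_equal(sort(unname(cm_n$labels)), 1:10)
  expect_setequal(cm_n$clustroids, rownames(D))

  # k = 1: clustroid minimizes total distance (exhaustive scan)
  cm_1 <- hierarchical_cluster(D, k = 1)
  expect_equal(cm_1$clustroids,
               rownames(D)[which.min(colSums(D))],
               ignore_attr = TRUE)

  # clustroid optimality within every cluster, scanned exhaustively
  gen <- make_ensemble(ensemble_spec(m = 20, n = 12, n_clusters = 3,
                                     sigma = 0.3, seed = 52))
  Dm <- pairwise_rmsd(superpose_ensemble(gen$ensemble))
  cm3 <- hierarchical_cluster(Dm, k = 3)
  for (cl in unique(cm3$labels)) {
    ids <- names(cm3$labels)[cm3$labels == cl]
    tot <- colSums(Dm[ids, ids, drop = FALSE])
    expect_equal(min(tot), tot[cm3$clustroids[cl]], ignore_attr = TRUE)
  }
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2), k = 1),
               "symmetric")
})
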