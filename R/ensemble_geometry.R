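# Ensemble coordinate matrices, rigid-body superposition, flexibility and
# distance analysis, hierarchical clustering with clustroid representatives.

#' Build the ensemble C-alpha coordinate matrix
#'
#' One row per ensemble member, columns are the C-alpha coordinates
#' (x1, y1, z1, x2, ...) over a shared residue frame.
#'
#' @param structures List of `Structure` objects.
#' @param frame Residue frame (from [common_residue_frame()]); computed if
#'   `NULL`.
#' @return An `EnsembleMatrix`: list with `ids`, `frame` and the `n x 3m`
#'   numeric matrix `coords`.
#' @export
ensemble_matrix <- function(structures, frame = NULL) {
  if (is.null(frame)) frame <- common_residue_frame(structures)
  coords <- t(vapply(structures, function(s) {
    as.vector(t(ca_coords(s, frame)))
  }, numeric(3L * length(frame))))
  ids <- vapply(structures, function(s) s$id, character(1))
  rownames(coords) <- ids
  new_ensemble_matrix(ids, frame, coords)
}

new_ensemble_matrix <- function(ids, frame, coords) {
  stopifnot(nrow(coords) >= 2L, ncol(coords) == 3L * length(frame),
            all(is.finite(coords)))
  structure(list(ids = ids, frame = as.integer(frame), coords = coords),
            class = "EnsembleMatrix")
}

#' @export
print.EnsembleMatrix <- function(x, ...) {
  cat("EnsembleMatrix:", nrow(x$coords), "members x",
      length(x$frame), "residues\n")
  invisible(x)
}

n_members  <- function(ens) nrow(ens$coords)
n_residues <- function(ens) length(ens$frame)

# reshape one 3m row to an m x 3 matrix
row_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)
xyz_row <- function(m) as.vector(t(m))

#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares optimal rotation + translation of `mobile` onto `reference`
#' computed on a residue subset, by singular value decomposition of the
#' cross-covariance with the usual determinant correction so the result is a
#' proper rotation.
#'
#' @param mobile,reference Numeric vectors of length 3m (or m x 3 matrices).
#' @param subset Residue positions (into the m residues) used for the fit;
#'   default all.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3) and
#'   `rmsd` over the subset. The fitted coordinates of a point x are
#'   `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, subset = NULL) {
  P <- if (is.matrix(mobile)) mobile else row_xyz(mobile)
  Q <- if (is.matrix(reference)) reference else row_xyz(reference)
  stopifnot(nrow(P) == nrow(Q))
  if (is.null(subset)) subset <- seq_len(nrow(P))
  if (length(subset) < 3L) stop("superposition subset needs >= 3 points")
  Ps <- P[subset, , drop = FALSE]
  Qs <- Q[subset, , drop = FALSE]
  cp <- colMeans(Ps); cq <- colMeans(Qs)
  Pc <- sweep(Ps, 2, cp); Qc <- sweep(Qs, 2, cq)
  # degenerate subsets (coincident or collinear points) have rank < 2
  if (qr(Pc)$rank < 2L || qr(Qc)$rank < 2L)
    stop("degenerate (collinear or coincident) superposition subset")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.vector(cq - cp %*% R), rmsd = rmsd)
}

apply_rigid <- function(coords_m3, fit) {
  sweep(coords_m3 %*% fit$rotation, 2, fit$translation, `+`)
}

#' Superpose every ensemble member on a core subset
#'
#' All members are rigid-fitted onto the first member using the core residues,
#' followed by one refinement pass onto the resulting mean structure. The
#' procedure is deterministic.
#'
#' @param ensemble An `EnsembleMatrix`.
#' @param core Residue positions defining the reference (fit) subset;
#'   default all residues.
#' @return A superposed `EnsembleMatrix`.
#' @export
superpose_ensemble <- function(ensemble, core = NULL) {
  X <- ensemble$coords
  m <- n_residues(ensemble)
  if (is.null(core)) core <- seq_len(m)
  fit_all_to <- function(X, ref) {
    t(apply(X, 1L, function(row) {
      fit <- kabsch_superpose(row_xyz(row), ref, core)
      xyz_row(apply_rigid(row_xyz(row), fit))
    }))
  }
  X1 <- fit_all_to(X, row_xyz(X[1L, ]))
  Xm <- fit_all_to(X1, row_xyz(colMeans(X1)))
  dimnames(Xm) <- dimnames(X)
  new_ensemble_matrix(ensemble$ids, ensemble$frame, Xm)
}

# per-residue scatter-ellipsoid volume (product of principal axis lengths, in
# cubic Angstrom) across the aligned ensemble
residue_scatter_volume <- function(aligned) {
  X <- aligned$coords
  m <- n_residues(aligned)
  vapply(seq_len(m), function(i) {
    pos <- X[, (3L * i - 2L):(3L * i), drop = FALSE]
    ev <- eigen(stats::cov(pos), symmetric = TRUE, only.values = TRUE)$values
    prod(sqrt(pmax(ev, 0)))
  }, numeric(1))
}

#' Find the structurally invariant core of an ensemble
#'
#' Iterative trimming: superpose all members on the current core, measure each
#' core residue's positional scatter as the volume of its scatter ellipsoid
#' (product of the principal axes of the positional covariance), drop the most
#' variable residue, and repeat until every core residue scatters less than
#' `v_stop` or the core has shrunk to `floor_size` residues.
#'
#' @param ensemble An `EnsembleMatrix` with at least 3 members.
#' @param v_stop Stop threshold on the maximum scatter volume (cubic Angstrom).
#' @param floor_size Minimum core size; default `max(30, ceiling(0.4 * m))`.
#' @return Sorted residue positions (into the frame) forming the core, with
#'   attribute `max_volume`.
#' @export
find_invariant_core <- function(ensemble, v_stop = 1.0, floor_size = NULL) {
  m <- n_residues(ensemble)
  if (n_members(ensemble) < 3L) stop("need >= 3 members to find a core")
  if (is.null(floor_size)) floor_size <- max(30L, ceiling(0.4 * m))
  floor_size <- max(3L, floor_size)
  if (m < floor_size) stop("core floor ", floor_size, " unreachable: only ",
                           m, " residues in frame")
  core <- seq_len(m)
  repeat {
    aligned <- superpose_ensemble(ensemble, core)
    vol <- residue_scatter_volume(aligned)[core]
    if (max(vol) <= v_stop || length(core) <= floor_size) {
      out <- sort(core)
      attr(out, "max_volume") <- max(vol)
      return(out)
    }
    core <- core[-which.max(vol)]
  }
}

#' Per-residue root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` over a superposed ensemble.
#'
#' @param aligned A superposed `EnsembleMatrix`.
#' @return Numeric vector (Angstrom), named by residue number.
#' @export
ensemble_rmsf <- function(aligned) {
  X <- aligned$coords
  D <- sweep(X, 2, colMeans(X))
  m <- n_residues(aligned)
  sq <- D^2
  r <- vapply(seq_len(m), function(i) {
    sqrt(mean(rowSums(sq[, (3L * i - 2L):(3L * i), drop = FALSE])))
  }, numeric(1))
  names(r) <- aligned$frame
  r
}

#' Pairwise C-alpha RMSD matrix over a residue subset
#'
#' Deviations are measured in the shared superposed frame (no per-pair
#' refitting), matching how region-wise dendrograms are built from one common
#' superposition.
#'
#' @param aligned A superposed `EnsembleMatrix`.
#' @param subset Residue positions (default all).
#' @return Symmetric n x n matrix (Angstrom) with zero diagonal.
#' @export
pairwise_rmsd <- function(aligned, subset = NULL) {
  m <- n_residues(aligned)
  if (is.null(subset)) subset <- seq_len(m)
  if (length(subset) == 0L) stop("empty residue subset")
  cols <- as.vector(vapply(subset, function(i) (3L * i - 2L):(3L * i),
                           integer(3)))
  X <- aligned$coords[, cols, drop = FALSE]
  n <- nrow(X)
  D <- as.matrix(stats::dist(X)) / sqrt(length(subset))
  dimnames(D) <- list(aligned$ids, aligned$ids)
  D
}

#' Agglomerative clustering with clustroid representatives
#'
#' Hierarchical clustering of a distance matrix cut to `k` clusters. Each
#' cluster is represented by its clustroid: the member minimizing the summed
#' distance to all other members of its cluster (ties broken by list order).
#'
#' @param distances Symmetric non-negative distance matrix with zero diagonal.
#' @param k Number of clusters (1..n).
#' @param linkage `hclust` linkage method; default `"average"`.
#' @return A `ClusterModel` list: `labels` (named), `linkage`, `merge_tree`
#'   (the `hclust` object) and `clustroids` (one member id per cluster).
#' @export
hierarchical_cluster <- function(distances, k, linkage = "average") {
  D <- as.matrix(distances)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(D < -1e-12))
    stop("distances must be a symmetric non-negative matrix")
  n <- nrow(D)
  stopifnot(k >= 1L, k <= n)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("m", seq_len(n))
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- stats::cutree(tree, k = k)
  names(labels) <- rownames(D)
  clustroids <- vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    tot <- colSums(D[idx, idx, drop = FALSE])
    names(idx)[which.min(tot)]
  }, character(1))
  structure(list(labels = labels, linkage = linkage, merge_tree = tree,
                 clustroids = clustroids),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat("ClusterModel:", length(unique(x$labels)), "clusters (",
      x$linkage, "linkage ); clustroids:",
      paste(x$clustroids, collapse = ", "), "\n")
  invisible(x)
}
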