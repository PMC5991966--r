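# Synthetic-data generators with recorded ground truth: C-alpha chains and
# ensembles with planted clusters/modes/correlations, toy protein-ligand
# complexes with planted interactions, and docking score tables. Every
# generator is deterministic for a fixed seed.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

# palette covering donors/acceptors, charges, aromatics and apolar sidechains
.chain_palette <- c("ALA", "SER", "LEU", "VAL", "LYS", "GLU", "ASP", "ARG",
                    "ASN", "PHE", "TYR", "THR", "GLY", "ILE", "MET")

#' Generate a self-avoiding C-alpha chain
#'
#' Random walk with 3.8 Angstrom virtual bonds and a 3.0 Angstrom clash floor
#' between non-bonded residues (rejection sampling). Each residue carries
#' minimal backbone dummy atoms (N, C, O) and a CB (except glycine) so that
#' center-of-mass and interaction-profiling operations have atoms to work on.
#'
#' @param m Number of residues (>= 3).
#' @param seed Integer seed.
#' @param bond Virtual C-alpha bond length (Angstrom).
#' @param clash_floor Minimum non-bonded C-alpha separation (Angstrom).
#' @return A `Structure`.
#' @export
make_chain <- function(m, seed, bond = 3.8, clash_floor = 3.0) {
  if (m < 3L) stop("m must be >= 3")
  with_seed(seed, {
    ca <- matrix(NA_real_, m, 3)
    ca[1, ] <- c(0, 0, 0)
    for (i in seq(2L, m)) {
      repeat {
        u <- stats::rnorm(3)
        cand <- ca[i - 1L, ] + bond * u / sqrt(sum(u^2))
        if (i == 2L) { ca[i, ] <- cand; break }
        d2 <- colSums((t(ca[seq_len(i - 2L), , drop = FALSE]) - cand)^2)
        if (all(d2 >= clash_floor^2)) { ca[i, ] <- cand; break }
      }
    }
    resnames <- sample(.chain_palette, m, replace = TRUE)
    rows <- list()
    for (i in seq_len(m)) {
      dir <- if (i < m) ca[i + 1L, ] - ca[i, ] else ca[i, ] - ca[i - 1L, ]
      dir <- dir / sqrt(sum(dir^2))
      perp <- c(-dir[2], dir[1], 0)
      if (sum(perp^2) < 1e-6) perp <- c(1, 0, 0)
      perp <- perp / sqrt(sum(perp^2))
      add <- function(atom, element, xyz)
        data.frame(resno = i, resname = resnames[i], atom = atom,
                   element = element, x = xyz[1], y = xyz[2], z = xyz[3],
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- add("N", "N", ca[i, ] - 1.45 * dir)
      rows[[length(rows) + 1L]] <- add("CA", "C", ca[i, ])
      rows[[length(rows) + 1L]] <- add("C", "C", ca[i, ] + 1.52 * dir)
      rows[[length(rows) + 1L]] <- add("O", "O",
                                       ca[i, ] + 1.52 * dir + 1.23 * perp)
      if (resnames[i] != "GLY")
        rows[[length(rows) + 1L]] <- add("CB", "C", ca[i, ] + 1.53 * perp)
    }
    structure(list(id = sprintf("synthetic_chain_m%d_s%d", m, seed),
                   residues = do.call(rbind, rows), ligands = list()),
              class = "Structure")
  })
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Default synthetic-ensemble specification
#'
#' The defaults emulate a crystal-structure ensemble of the kind analyzed
#' here: 27 members over 160 residues, three conformational families whose
#' between-family displacement (3 Angstrom per-residue RMS) is ten times the
#' within-family coordinate noise (0.3 Angstrom), plus two soft collective
#' modes. Members are handed out with random rigid transforms applied, so the
#' superposition step is always exercised.
#'
#' @param m,n Residues and members.
#' @param n_clusters Number of planted conformational families.
#' @param separation Per-residue RMS displacement between family means
#'   (Angstrom).
#' @param mode_sds Standard deviations of the planted collective modes.
#' @param sigma Isotropic per-coordinate noise (Angstrom).
#' @param seed Integer seed (mandatory).
#' @return An `EnsembleSpec` list.
#' @export
ensemble_spec <- function(m = 160L, n = 27L, n_clusters = 3L,
                          separation = 3.0, mode_sds = c(1.0, 0.6),
                          sigma = 0.3, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_clusters >= 1L, sigma >= 0)
  list(m = as.integer(m), n = as.integer(n),
       n_clusters = as.integer(n_clusters), separation = separation,
       mode_sds = mode_sds, sigma = sigma, seed = as.integer(seed))
}

#' Generate a synthetic conformational ensemble with known ground truth
#'
#' Each member is the base chain plus its family (cluster) mean displacement,
#' plus contributions along planted collective modes, plus isotropic noise; a
#' random rigid transform is then applied to every member.
#'
#' @param spec An [ensemble_spec()].
#' @return List with `ensemble` (an `EnsembleMatrix`) and `truth` (labels,
#'   cluster means, mode vectors/scores, noise level, pre-transform
#'   coordinates).
#' @export
make_ensemble <- function(spec) {
  with_seed(spec$seed, {
    base <- xyz_row(ca_coords(make_chain(spec$m, seed = spec$seed + 1L)))
    p <- 3L * spec$m
    cmeans <- matrix(0, spec$n_clusters, p)
    if (spec$n_clusters > 1L) {
      for (cl in seq_len(spec$n_clusters)) {
        v <- stats::rnorm(p)
        cmeans[cl, ] <- v / sqrt(sum(v^2)) * spec$separation * sqrt(spec$m)
      }
    }
    modes <- lapply(spec$mode_sds, function(sd) {
      v <- stats::rnorm(p)
      list(vector = v / sqrt(sum(v^2)), sd = sd)
    })
    labels <- rep(seq_len(spec$n_clusters), length.out = spec$n)
    labels <- sample(labels)
    scores <- matrix(stats::rnorm(spec$n * length(modes)), spec$n)
    X <- matrix(0, spec$n, p)
    for (t in seq_len(spec$n)) {
      x <- base + cmeans[labels[t], ]
      for (j in seq_along(modes))
        x <- x + scores[t, j] * modes[[j]]$sd * modes[[j]]$vector
      X[t, ] <- x + stats::rnorm(p, sd = spec$sigma)
    }
    aligned_truth <- X
    for (t in seq_len(spec$n)) {
      R <- random_rotation()
      shift <- stats::runif(3, -20, 20)
      X[t, ] <- xyz_row(sweep(row_xyz(X[t, ]) %*% R, 2, shift, `+`))
    }
    ids <- sprintf("syn_%02d", seq_len(spec$n))
    rownames(X) <- ids
    list(ensemble = new_ensemble_matrix(ids, seq_len(spec$m), X),
         truth = list(labels = labels, cluster_means = cmeans,
                      modes = modes, mode_scores = scores,
                      sigma = spec$sigma, pre_transform = aligned_truth))
  })
}

#' Generate an ensemble with planted pairwise motion correlations
#'
#' Residue displacements share one spatial direction and their amplitudes are
#' drawn from a multivariate normal whose correlation matrix carries the
#' requested pairwise values, so the population DCCM entry for a planted pair
#' (i, j) equals rho exactly.
#'
#' @param m Residues.
#' @param pairs Data frame with columns `i`, `j`, `rho` (|rho| <= 1).
#' @param n Members.
#' @param seed Integer seed.
#' @param amplitude Displacement standard deviation (Angstrom).
#' @return List with `ensemble` (aligned `EnsembleMatrix`) and `truth`
#'   (the planted correlation matrix).
#' @export
make_correlated_ensemble <- function(m, pairs, n, seed, amplitude = 1.0) {
  stopifnot(all(abs(pairs$rho) <= 1), all(pairs$i != pairs$j),
            all(c(pairs$i, pairs$j) <= m))
  S <- diag(m)
  for (r in seq_len(nrow(pairs))) {
    S[pairs$i[r], pairs$j[r]] <- S[pairs$j[r], pairs$i[r]] <- pairs$rho[r]
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("correlation specification is not positive definite")
  # symmetric square root tolerates rho = +/-1 (positive semi-definite)
  ch <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*%
    t(ev$vectors)
  with_seed(seed, {
    base <- xyz_row(ca_coords(make_chain(m, seed = seed + 1L)))
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    A <- matrix(stats::rnorm(n * m), n) %*% ch * amplitude
    X <- matrix(base, n, 3L * m, byrow = TRUE)
    for (i in seq_len(m)) {
      cols <- (3L * i - 2L):(3L * i)
      X[, cols] <- X[, cols] + outer(A[, i], u)
    }
    ids <- sprintf("cor_%04d", seq_len(n))
    rownames(X) <- ids
    list(ensemble = new_ensemble_matrix(ids, seq_len(m), X),
         truth = list(correlation = S, direction = u))
  })
}

# residue templates used by the complex fixtures; each sits in its own local
# frame with the interaction partner expected along +y
.fixture_residue <- function(resname, resno, origin) {
  at <- function(atom, element, dx, dy, dz)
    data.frame(resno = resno, resname = resname, atom = atom,
               element = element, x = origin[1] + dx, y = origin[2] + dy,
               z = origin[3] + dz, stringsAsFactors = FALSE)
  base <- rbind(at("N", "N", -1.45, 0, 0), at("CA", "C", 0, 0, 0),
                at("C", "C", 1.52, 0, 0), at("O", "O", 2.2, -1.0, 0))
  side <- switch(resname,
    SER = at("OG", "O", 0, 1.4, 0),
    LEU = rbind(at("CB", "C", 0, 1.53, 0), at("CD1", "C", 0, 3.0, 0)),
    GLU = rbind(at("CB", "C", 0, 1.53, 0), at("CG", "C", 0, 2.9, 0),
                at("CD", "C", 0, 4.2, 0), at("OE1", "O", -1.0, 5.0, 0),
                at("OE2", "O", 1.0, 5.0, 0)),
    PHE = rbind(at("CB", "C", 0, 1.53, 0), at("CG", "C", 0, 2.9, 0),
                at("CD1", "C", -1.2, 3.6, 0), at("CD2", "C", 1.2, 3.6, 0),
                at("CE1", "C", -1.2, 5.0, 0), at("CE2", "C", 1.2, 5.0, 0),
                at("CZ", "C", 0, 5.7, 0)),
    NULL)
  rbind(base, side)
}

#' Build a toy protein-ligand complex with planted interactions
#'
#' Constructs a minimal complex containing exactly the requested interaction
#' at a planted distance, with all other atom pairs safely outside every
#' profiler cutoff. `kind = "mixed"` plants one interaction of each type on
#' residues spaced 20 Angstrom apart.
#'
#' @param kind One of `"hydrogen_bond"`, `"salt_bridge"`, `"hydrophobic"`,
#'   `"pi_cation"`, `"mixed"`.
#' @param seed Integer seed (adds a <= 0.02 Angstrom jitter that never
#'   crosses a cutoff).
#' @param distance Planted interaction distance (Angstrom); defaults per
#'   kind to 2.9 / 4.0 / 3.6 / 5.0. Pass e.g. 5.6 to plant a just-over-cutoff
#'   salt bridge.
#' @return List with `structure`, `pose` (ligand group) and `truth` (data
#'   frame of planted interactions; zero rows when the planted distance is
#'   beyond its cutoff).
#' @export
make_complex_fixture <- function(kind = c("hydrogen_bond", "salt_bridge",
                                          "hydrophobic", "pi_cation", "mixed"),
                                 seed = 1L, distance = NULL) {
  kind <- match.arg(kind)
  defaults <- c(hydrogen_bond = 2.9, salt_bridge = 4.0, hydrophobic = 3.6,
                pi_cation = 5.0)
  cutoffs <- c(hydrogen_bond = 3.5, salt_bridge = 5.5, hydrophobic = 4.0,
               pi_cation = 6.0)
  kinds <- if (kind == "mixed") names(defaults) else kind
  with_seed(seed, {
    res_rows <- list(); lig_rows <- list(); truth <- list()
    for (s in seq_along(kinds)) {
      k <- kinds[s]
      d <- if (!is.null(distance) && kind != "mixed") distance else defaults[[k]]
      origin <- c(20 * (s - 1L), 0, 0)
      lig_at <- function(atom, element, dx, dy, dz)
        data.frame(atom = atom, element = element, x = origin[1] + dx,
                   y = origin[2] + dy, z = origin[3] + dz,
                   stringsAsFactors = FALSE)
      if (k == "hydrogen_bond") {
        res_rows[[s]] <- .fixture_residue("SER", s, origin)
        lig_rows[[s]] <- rbind(lig_at(paste0("O", s), "O", 0, 1.4 + d, 0),
                               lig_at(paste0("C", s), "C", 0, 2.8 + d, 0))
        planted <- data.frame(type = "hydrogen_bond", residue = s,
                              distance = d)
      } else if (k == "salt_bridge") {
        res_rows[[s]] <- .fixture_residue("GLU", s, origin)
        lig_rows[[s]] <- rbind(lig_at(paste0("N", s), "N", 0, 5.0 + d, 0),
                               lig_at(paste0("C", s), "C", 0, 5.0 + d, 1.47))
        planted <- data.frame(type = "salt_bridge", residue = s,
                              distance = d)
      } else if (k == "hydrophobic") {
        res_rows[[s]] <- .fixture_residue("LEU", s, origin)
        lig_rows[[s]] <- lig_at(paste0("C", s), "C", 0, 3.0 + d, 0)
        planted <- data.frame(type = "hydrophobic", residue = s,
                              distance = d)
      } else {
        res_rows[[s]] <- .fixture_residue("PHE", s, origin)
        centroid_y <- mean(c(2.9, 3.6, 3.6, 5.0, 5.0, 5.7))
        lig_rows[[s]] <- lig_at(paste0("N", s), "N", 0, centroid_y, d)
        planted <- data.frame(type = "pi_cation", residue = s, distance = d)
      }
      if (planted$distance <= cutoffs[[k]])
        truth[[length(truth) + 1L]] <- planted
    }
    residues <- do.call(rbind, res_rows)
    pose_atoms <- do.call(rbind, lig_rows)
    structure_out <- structure(
      list(id = paste0("complex_", kind), residues = residues,
           ligands = list(list(het_code = "LIG", atoms = pose_atoms))),
      class = "Structure")
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(type = character(0), residue = integer(0),
                 distance = numeric(0))
    list(structure = structure_out,
         pose = list(het_code = "LIG", atoms = pose_atoms),
         truth = truth_df)
  })
}

#' Generate a synthetic docking score table with known ranking
#'
#' @param n_ligands Number of ligands (>= 1).
#' @param energy_range Vina-style free-energy range (kcal/mol, negative).
#' @param count_range Interaction-count range (integers).
#' @param seed Integer seed.
#' @param file Optional path; the table is written as CSV when given.
#' @return List with `table` (data frame), `csv` (the text lines) and
#'   `truth` (ligand ids in ground-truth weighted-score order, computed by
#'   direct arithmetic).
#' @export
make_screen_table <- function(n_ligands, energy_range = c(-10, -2),
                              count_range = c(0L, 8L), seed = 1L,
                              file = NULL) {
  stopifnot(n_ligands >= 1L)
  with_seed(seed, {
    df <- data.frame(
      ligand = sprintf("SYN%05d", sample.int(99999L, n_ligands)),
      target = "synthetic_target",
      site = sample(c("site1", "site2"), n_ligands, replace = TRUE),
      energy = round(stats::runif(n_ligands, energy_range[1],
                                  energy_range[2]), 1),
      n_interactions = sample(seq(count_range[1], count_range[2]),
                              n_ligands, replace = TRUE),
      stringsAsFactors = FALSE)
    # ground-truth ranking by direct formula
    mm <- function(v) if (diff(range(v)) == 0) rep(1, length(v)) else
      (v - min(v)) / diff(range(v))
    sc <- 0.8 * mm(-df$energy) + 0.2 * mm(df$n_interactions)
    truth <- df$ligand[order(-sc, df$energy, df$ligand)]
    lines <- c(paste(names(df), collapse = ","),
               apply(df, 1L, paste, collapse = ","))
    if (!is.null(file)) writeLines(lines, file)
    list(table = df, csv = lines, truth = truth)
  })
}

#' Convert ensemble members to C-alpha-only Structures
#'
#' @param ensemble An `EnsembleMatrix`.
#' @return List of `Structure` objects (one per member, CA atoms only).
#' @export
ensemble_structures <- function(ensemble) {
  lapply(seq_len(n_members(ensemble)), function(t) {
    xyz <- row_xyz(ensemble$coords[t, ])
    structure(list(
      id = ensemble$ids[t],
      residues = data.frame(resno = ensemble$frame, resname = "ALA",
                            atom = "CA", element = "C",
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE),
      ligands = list()), class = "Structure")
  })
}
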