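# Docking-hit ingestion, geometric protein-ligand interaction profiling, the
# 80/20 weighted re-score, site assignment and Lipinski rule-of-five checks.

#' Allosteric site definitions for Rab11
#'
#' Residue contacts made by top-scoring ligands at the two pockets flanking
#' helix 102-112: site 1 (near the nucleotide site) and site 2 (distal).
#'
#' @return List of two `SiteDefinition`s (`name`, `residues`).
#' @export
rab11_sites <- function() {
  list(
    site1 = list(name = "site1",
                 residues = c(19L, 20L, 74L, 77L, 97L, 101L, 104L, 107L,
                              108L, 111L, 112L)),
    site2 = list(name = "site2",
                 residues = c(103L, 106L, 109L, 110L, 113L, 115L, 116L,
                              117L, 118L, 119L, 146L, 147L, 148L, 149L,
                              171L, 175L))
  )
}

#' H-Ras allosteric pocket definitions
#'
#' Pocket p2 (near the nucleotide site) and pocket p3 (alpha3-loop7 region),
#' the H-Ras counterparts of Rab11 site 1 and site 2.
#'
#' @return List of two `SiteDefinition`s.
#' @export
hras_pockets <- function() {
  list(
    p2 = list(name = "p2", residues = c(61:65, 90:95)),
    p3 = list(name = "p3", residues = c(97L, 101L, 107:111, 136:140, 161:166))
  )
}

#' Load a docking score table
#'
#' Reads a CSV/TSV with columns `ligand`, `target`, `site`, `energy` (an
#' optional `n_interactions` column is carried through). Duplicate
#' (ligand, target, site) rows are collapsed to the lowest-energy record.
#'
#' @param table Path to a delimited file, or a data frame.
#' @return Data frame of screen records, one per (ligand, target, site).
#' @export
load_scores <- function(table) {
  if (is.character(table)) {
    first <- readLines(table, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(table, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE)
  } else df <- as.data.frame(table)
  need <- c("ligand", "target", "site", "energy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty score table")
  df$energy <- suppressWarnings(as.numeric(df$energy))
  if (anyNA(df$energy)) stop("unparsable energy value(s)")
  key <- paste(df$ligand, df$target, df$site, sep = "|")
  ord <- order(key, df$energy)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- geometric interaction profiler -----------------------------------------

# covalent-bond inference by heavy-atom distance (shared threshold for C-N,
# C-O, C-C bonds; crystal structures carry no explicit connectivity)
.bond_max <- 1.8

atom_xyz <- function(df) as.matrix(df[, c("x", "y", "z")])

# apolar carbons: carbon atoms with no covalently bonded N/O in the same group
apolar_carbons <- function(atoms) {
  el <- toupper(atoms$element)
  xyz <- atom_xyz(atoms)
  is_c <- el == "C"
  is_no <- el %in% c("N", "O")
  out <- rep(FALSE, nrow(atoms))
  for (i in which(is_c)) {
    d2 <- colSums((t(xyz[is_no, , drop = FALSE]) - xyz[i, ])^2)
    out[i] <- !any(d2 <= .bond_max^2)
  }
  out
}

# aromatic/planar 5- or 6-membered rings in a ligand's bond graph
ligand_rings <- function(atoms) {
  heavy <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  n <- nrow(heavy)
  if (n < 5L) return(list())
  xyz <- atom_xyz(heavy)
  D <- as.matrix(stats::dist(xyz))
  A <- D <= .bond_max & upper.tri(D)
  edges <- which(A, arr.ind = TRUE)
  if (nrow(edges) < 5L) return(list())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(edges))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, edges[k, ]))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = edges[k, 1],
                                                  to = edges[k, 2]))
    p <- as.integer(sp$vpath[[1]])
    if (length(p) %in% c(5L, 6L)) {
      key <- paste(sort(p), collapse = "-")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- colMeans(xyz[p, , drop = FALSE])
      }
    }
  }
  rings
}

.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

#' Geometric protein-ligand interaction profile
#'
#' Detects interactions between a protein chain and a ligand pose by distance
#' rules (hydrogen positions are not required, so no angle criteria):
#' \itemize{
#'   \item hydrogen bond: protein N/O to ligand N/O heavy atoms <= 3.5 A;
#'   \item hydrophobic: apolar carbon to apolar carbon <= 4.0 A;
#'   \item salt bridge: opposite charge-group centers <= 5.5 A (Lys NZ,
#'     Arg CZ, Asp/Glu carboxylate midpoints; ligand nitrogens as cations and
#'     ligand carboxylate midpoints as anions);
#'   \item pi-cation: cation to aromatic ring centroid <= 6.0 A.
#' }
#'
#' @param structure A `Structure` (the protein).
#' @param pose A ligand group (`het_code` + `atoms` data frame) as produced by
#'   [read_structure()].
#' @param cutoffs Named list overriding the defaults
#'   `list(hbond = 3.5, hydrophobic = 4.0, salt_bridge = 5.5, pi_cation = 6.0)`.
#' @return Data frame (`InteractionSet`): `type`, `residue`, `ligand_atom`,
#'   `distance`; zero rows if no interaction.
#' @export
profile_interactions <- function(structure, pose, cutoffs = list()) {
  cut <- utils::modifyList(
    list(hbond = 3.5, hydrophobic = 4.0, salt_bridge = 5.5, pi_cation = 6.0),
    cutoffs)
  la <- pose$atoms[toupper(pose$atoms$element) != "H", , drop = FALSE]
  if (nrow(la) == 0L) stop("ligand pose has no heavy atoms")
  res <- structure$residues
  res <- res[toupper(res$element) != "H", , drop = FALSE]
  lxyz <- atom_xyz(la)
  pxyz <- atom_xyz(res)
  rec <- function(type, residue, ligand_atom, distance)
    data.frame(type = type, residue = residue, ligand_atom = ligand_atom,
               distance = round(distance, 3), stringsAsFactors = FALSE)
  out <- list()

  # hydrogen bonds: N/O vs N/O
  pi <- which(toupper(res$element) %in% c("N", "O"))
  li <- which(toupper(la$element) %in% c("N", "O"))
  for (i in pi) for (j in li) {
    d <- sqrt(sum((pxyz[i, ] - lxyz[j, ])^2))
    if (d <= cut$hbond)
      out[[length(out) + 1L]] <- rec("hydrogen_bond", res$resno[i],
                                     la$atom[j], d)
  }

  # hydrophobic: apolar C vs apolar C
  pc <- which(apolar_carbons(res))
  lc <- which(apolar_carbons(la))
  for (i in pc) for (j in lc) {
    d <- sqrt(sum((pxyz[i, ] - lxyz[j, ])^2))
    if (d <= cut$hydrophobic)
      out[[length(out) + 1L]] <- rec("hydrophobic", res$resno[i],
                                     la$atom[j], d)
  }

  # charged-group centers
  prot_charges <- protein_charge_centers(res)
  lig_charges <- ligand_charge_centers(la)
  for (p in prot_charges) for (l in lig_charges) {
    if (p$sign * l$sign < 0) {
      d <- sqrt(sum((p$xyz - l$xyz)^2))
      if (d <= cut$salt_bridge)
        out[[length(out) + 1L]] <- rec("salt_bridge", p$resno, l$label, d)
    }
  }

  # pi-cation: protein cation vs ligand ring, ligand cation vs protein ring
  prot_rings <- protein_rings(res)
  lig_rings <- ligand_rings(pose$atoms)
  for (p in prot_charges) {
    if (p$sign > 0) for (rc in lig_rings) {
      d <- sqrt(sum((p$xyz - rc)^2))
      if (d <= cut$pi_cation)
        out[[length(out) + 1L]] <- rec("pi_cation", p$resno, "ring", d)
    }
  }
  for (l in lig_charges) {
    if (l$sign > 0) for (r in prot_rings) {
      d <- sqrt(sum((l$xyz - r$xyz)^2))
      if (d <= cut$pi_cation)
        out[[length(out) + 1L]] <- rec("pi_cation", r$resno, l$label, d)
    }
  }

  if (length(out) == 0L)
    return(data.frame(type = character(0), residue = integer(0),
                      ligand_atom = character(0), distance = numeric(0)))
  do.call(rbind, out)
}

protein_charge_centers <- function(res) {
  out <- list()
  for (rn in unique(res$resno)) {
    r <- res[res$resno == rn, , drop = FALSE]
    nm <- r$resname[1]
    if (nm == "LYS" && "NZ" %in% r$atom)
      out[[length(out) + 1L]] <- list(resno = rn, sign = +1,
        xyz = as.numeric(r[r$atom == "NZ", c("x", "y", "z")]))
    if (nm == "ARG" && "CZ" %in% r$atom)
      out[[length(out) + 1L]] <- list(resno = rn, sign = +1,
        xyz = as.numeric(r[r$atom == "CZ", c("x", "y", "z")]))
    if (nm == "ASP" && all(c("OD1", "OD2") %in% r$atom))
      out[[length(out) + 1L]] <- list(resno = rn, sign = -1,
        xyz = colMeans(atom_xyz(r[r$atom %in% c("OD1", "OD2"), ])))
    if (nm == "GLU" && all(c("OE1", "OE2") %in% r$atom))
      out[[length(out) + 1L]] <- list(resno = rn, sign = -1,
        xyz = colMeans(atom_xyz(r[r$atom %in% c("OE1", "OE2"), ])))
  }
  out
}

protein_rings <- function(res) {
  out <- list()
  for (rn in unique(res$resno)) {
    r <- res[res$resno == rn, , drop = FALSE]
    ring <- .ring_atoms[[r$resname[1]]]
    if (!is.null(ring) && all(ring %in% r$atom))
      out[[length(out) + 1L]] <- list(
        resno = rn, xyz = colMeans(atom_xyz(r[r$atom %in% ring, ])))
  }
  out
}

ligand_charge_centers <- function(la) {
  out <- list()
  el <- toupper(la$element)
  xyz <- atom_xyz(la)
  for (j in which(el == "N"))
    out[[length(out) + 1L]] <- list(sign = +1, label = la$atom[j],
                                    xyz = xyz[j, ])
  # carboxylate-like anions: a carbon covalently bonded to two oxygens
  for (j in which(el == "C")) {
    d2 <- colSums((t(xyz) - xyz[j, ])^2)
    ox <- which(el == "O" & d2 <= .bond_max^2)
    if (length(ox) >= 2L)
      out[[length(out) + 1L]] <- list(sign = -1, label = la$atom[j],
        xyz = colMeans(xyz[ox[1:2], , drop = FALSE]))
  }
  out
}

# --- weighted re-scoring ------------------------------------------------------

#' Weighted 80/20 re-score of screening records
#'
#' Within the supplied record list, the (negated) binding free energy and the
#' interaction count are min-max normalized to [0, 1] (a constant column
#' normalizes to 1.0) and combined as
#' `score = 0.8 * energy_term + 0.2 * interaction_term`. Records are ranked
#' by descending score; ties are broken by lower energy, then ligand id.
#'
#' @param records Data frame with `ligand`, `energy` and `n_interactions`
#'   (and any other columns, carried through).
#' @return The records with `weighted_score` and `rank` columns, ordered by
#'   rank.
#' @export
weighted_score <- function(records) {
  df <- as.data.frame(records)
  if (nrow(df) == 0L) stop("no records to score")
  if (!("n_interactions" %in% names(df)) || anyNA(df$n_interactions))
    stop("every record needs an interaction count")
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(1, length(v)) else (v - r[1]) / diff(r)
  }
  e_hat <- minmax(-df$energy)
  i_hat <- minmax(df$n_interactions)
  df$weighted_score <- 0.8 * e_hat + 0.2 * i_hat
  ord <- order(-df$weighted_score, df$energy, df$ligand)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Assign a docked pose to a binding site
#'
#' The pose is assigned to the site whose residues contribute the most heavy
#' atoms within `cutoff` Angstrom of any pose heavy atom; ties go to site 1;
#' if neither site is within range the pose is `"unassigned"`.
#'
#' @param structure A `Structure`.
#' @param pose A ligand group.
#' @param sites List of two `SiteDefinition`s (default [rab11_sites()]).
#' @param cutoff Heavy-atom proximity cutoff (Angstrom).
#' @return Site name, with per-site atom counts in attribute `counts`.
#' @export
assign_site <- function(structure, pose, sites = rab11_sites(),
                        cutoff = 4.5) {
  la <- pose$atoms[toupper(pose$atoms$element) != "H", , drop = FALSE]
  if (nrow(la) == 0L) stop("ligand pose has no heavy atoms")
  lxyz <- atom_xyz(la)
  res <- structure$residues
  res <- res[toupper(res$element) != "H", , drop = FALSE]
  counts <- vapply(sites, function(s) {
    sub <- res[res$resno %in% s$residues, , drop = FALSE]
    if (nrow(sub) == 0L) return(0L)
    sxyz <- atom_xyz(sub)
    near <- vapply(seq_len(nrow(sxyz)), function(i) {
      any(colSums((t(lxyz) - sxyz[i, ])^2) <= cutoff^2)
    }, logical(1))
    sum(near)
  }, integer(1))
  names(counts) <- vapply(sites, `[[`, character(1), "name")
  label <- if (all(counts == 0L)) "unassigned" else names(counts)[which.max(counts)]
  attr(label, "counts") <- counts
  label
}

#' Lipinski rule-of-five evaluation
#'
#' Violations are counted against: donors <= 5, acceptors <= 10,
#' molecular mass < 500 g/mol, logP <= 5. A compound passes with at most one
#' violation.
#'
#' @param donors,acceptors Hydrogen-bond donor/acceptor group counts.
#' @param mass Molecular mass (g/mol).
#' @param logp Octanol-water partition coefficient.
#' @return List with `violations` and logical `pass`.
#' @export
lipinski <- function(donors, acceptors, mass, logp) {
  stopifnot(donors >= 0, acceptors >= 0, mass > 0)
  v <- sum(donors > 5, acceptors > 10, mass >= 500, logp > 5)
  list(violations = v, pass = v <= 1L)
}
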