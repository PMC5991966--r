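# Residue interaction networks: C-alpha contact graphs with distance-weighted
# edges, betweenness centrality, deterministic shortest paths, nucleotide
# contacts and center-of-mass distances.

# standard atomic masses for the elements found in protein/ligand records
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                  S = 32.06, SE = 78.971, F = 18.998, CL = 35.45,
                  BR = 79.904, I = 126.904, MG = 24.305, ZN = 65.38,
                  FE = 55.845, NA. = 22.99, K = 39.098, CA = 40.078,
                  BE = 9.012)

element_mass <- function(element) {
  m <- .atomic_mass[toupper(element)]
  m[is.na(m)] <- 12.011   # unknown elements counted as carbon-like
  unname(m)
}

#' Build the residue interaction network of a structure
#'
#' Residues are nodes; an undirected edge joins two residues iff their
#' C-alpha to C-alpha Euclidean distance is within `cutoff` Angstrom. Each
#' edge carries the geometric distance (rounded to 3 decimals) as its weight.
#'
#' @param structure A `Structure` with at least 2 C-alpha residues.
#' @param cutoff Contact threshold in Angstrom (default 7.0).
#' @return An `igraph` graph whose vertex names are residue numbers, with a
#'   `cutoff` graph attribute.
#' @export
build_rin <- function(structure, cutoff = 7.0) {
  ca <- ca_coords(structure)
  n <- nrow(ca)
  if (n < 2L) stop("need at least 2 C-alpha residues")
  D <- as.matrix(stats::dist(ca))
  idx <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(ca))
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(idx)),
                           weight = round(D[idx], 3))
  }
  g <- igraph::set_graph_attr(g, "cutoff", cutoff)
  g
}

#' Betweenness centrality of network residues
#'
#' Weighted-shortest-path betweenness normalized by `(N-1)(N-2)/2`, the number
#' of vertex pairs in an undirected network.
#'
#' @param network An `igraph` residue interaction network.
#' @return Named numeric vector (residue numbers).
#' @export
rin_betweenness <- function(network) {
  if (igraph::vcount(network) == 0L) stop("empty network")
  igraph::betweenness(network, directed = FALSE,
                      weights = igraph::E(network)$weight,
                      normalized = TRUE)
}

#' Deterministic shortest paths between residue sets
#'
#' For every (source, target) pair the minimum-total-weight path is reported.
#' Among equally short paths, ties are broken by fewer nodes and then by the
#' lexicographically smallest residue-number sequence, so results are
#' reproducible. Unreachable pairs are flagged rather than dropped.
#'
#' @param network An `igraph` residue interaction network.
#' @param sources,targets Residue numbers (must be network nodes).
#' @return Data frame with one row per pair: `source`, `target`, `length`
#'   (Angstrom, `NA` if unreachable), `n_nodes`, `reachable`, `path`
#'   (residue numbers joined by `"-"`).
#' @export
rin_shortest_paths <- function(network, sources, targets) {
  nodes <- igraph::V(network)$name
  miss <- setdiff(as.character(c(sources, targets)), nodes)
  if (length(miss)) stop("unknown residue(s): ", paste(miss, collapse = ", "))
  w <- igraph::E(network)$weight
  out <- list()
  for (s in as.character(sources)) {
    for (t in as.character(targets)) {
      if (s == t) {
        out[[length(out) + 1L]] <- data.frame(
          source = s, target = t, length = 0, n_nodes = 1L,
          reachable = TRUE, path = s, stringsAsFactors = FALSE)
        next
      }
      sp <- suppressWarnings(
        igraph::all_shortest_paths(network, from = s, to = t, weights = w))
      paths <- sp$vpaths
      if (length(paths) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          source = s, target = t, length = NA_real_, n_nodes = NA_integer_,
          reachable = FALSE, path = NA_character_, stringsAsFactors = FALSE)
        next
      }
      seqs <- lapply(paths, function(p) as.integer(igraph::V(network)$name[p]))
      nn <- lengths(seqs)
      cand <- which(nn == min(nn))
      if (length(cand) > 1L) {       # lexicographic residue-number sequence
        keys <- vapply(seqs[cand], function(sq)
          paste(sprintf("%06d", sq), collapse = ","), character(1))
        cand <- cand[order(keys)]
      }
      best <- seqs[[cand[1L]]]
      len <- path_length(network, best)
      out[[length(out) + 1L]] <- data.frame(
        source = s, target = t, length = len, n_nodes = length(best),
        reachable = TRUE, path = paste(best, collapse = "-"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

path_length <- function(network, resno_seq) {
  ids <- match(as.character(resno_seq), igraph::V(network)$name)
  total <- 0
  for (i in seq_len(length(ids) - 1L)) {
    e <- igraph::get_edge_ids(network, c(ids[i], ids[i + 1L]))
    if (e == 0L) stop("path step ", resno_seq[i], "-", resno_seq[i + 1L],
                      " is not an edge")
    total <- total + igraph::E(network)$weight[e]
  }
  total
}

#' Residues in contact with a bound nucleotide
#'
#' Residues with any heavy atom within `cutoff` Angstrom of any heavy atom of
#' a bound nucleotide ligand (GDP/GTP or a non-hydrolyzable analog).
#'
#' @param structure A `Structure`.
#' @param het_codes Ligand codes accepted as the nucleotide.
#' @param cutoff Heavy-atom contact distance (Angstrom).
#' @return Sorted integer vector of residue numbers.
#' @export
nucleotide_contacts <- function(structure,
                                het_codes = c("GDP", "GNP", "GSP", "GTP"),
                                cutoff = 4.0) {
  ligs <- Filter(function(l) l$het_code %in% het_codes, structure$ligands)
  if (length(ligs) == 0L)
    stop("no ligand with code in {", paste(het_codes, collapse = ", "), "}")
  lig_xyz <- do.call(rbind, lapply(ligs, function(l) {
    a <- l$atoms[toupper(l$atoms$element) != "H", , drop = FALSE]
    as.matrix(a[, c("x", "y", "z")])
  }))
  res <- structure$residues
  res <- res[toupper(res$element) != "H", , drop = FALSE]
  pxyz <- as.matrix(res[, c("x", "y", "z")])
  # squared-distance test against every ligand heavy atom
  hit <- rep(FALSE, nrow(pxyz))
  for (j in seq_len(nrow(lig_xyz))) {
    d2 <- (pxyz[, 1] - lig_xyz[j, 1])^2 + (pxyz[, 2] - lig_xyz[j, 2])^2 +
      (pxyz[, 3] - lig_xyz[j, 3])^2
    hit <- hit | d2 <= cutoff^2
  }
  sort(unique(res$resno[hit]))
}

#' Distance of residues to the protein center of mass
#'
#' The center of mass is computed over all polypeptide atoms (ligands
#' excluded) with standard atomic masses; the reported distance is from each
#' residue's C-alpha to that center.
#'
#' @param structure A `Structure`.
#' @param residues Residue numbers (default: all).
#' @return Named numeric vector of distances (Angstrom).
#' @export
center_of_mass_distances <- function(structure, residues = NULL) {
  res <- structure$residues
  mass <- element_mass(res$element)
  com <- colSums(as.matrix(res[, c("x", "y", "z")]) * mass) / sum(mass)
  ca <- ca_coords(structure, residues)
  d <- sqrt(colSums((t(ca) - com)^2))
  names(d) <- rownames(ca)
  d
}

#' Export a residue interaction network
#'
#' Writes the network as GraphML and/or an edge-list TSV
#' (`res_i`, `res_j`, `distance`).
#'
#' @param network An `igraph` residue interaction network.
#' @param graphml,tsv Output paths (either may be `NULL`).
#' @return Invisibly, the edge-list data frame.
#' @export
write_rin <- function(network, graphml = NULL, tsv = NULL) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(res_i = el[, 1], res_j = el[, 2],
                   distance = igraph::E(network)$weight,
                   stringsAsFactors = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(network, graphml, format = "graphml")
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
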