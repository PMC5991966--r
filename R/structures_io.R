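#' @importFrom stats cor cutree dist hclust prcomp rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

# Standard amino-acid three-letter codes. MSE (selenomethionine) is read as MET
# so that sequence-level operations see a standard residue.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.water_codes <- c("HOH", "DOD", "WAT", "H2O")

#' Read one protein chain from PDB-format text
#'
#' Parses ATOM/HETATM records of a single chain into a `Structure`: an ordered
#' set of amino-acid residues (each with exactly one C-alpha) plus any
#' non-water hetero groups (nucleotides, ions, small molecules) as ligands.
#'
#' Alternate locations are resolved per atom to the highest-occupancy copy,
#' ties going to altloc "A". Waters are discarded. Residues carrying insertion
#' codes are excluded (they cannot be placed in the shared residue frame), as
#' are residues without a C-alpha. Selenomethionine (MSE) is renamed MET.
#'
#' @param pdb A path to a PDB file or a character vector of PDB-format lines
#'   (a single string with embedded newlines also works).
#' @param chain Single chain identifier, e.g. `"A"`.
#' @return An object of class `Structure`: a list with elements `id`,
#'   `residues` (data frame with one row per atom: `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`) and `ligands` (list of hetero groups, each with
#'   `het_code` and an `atoms` data frame).
#' @export
read_structure <- function(pdb, chain) {
  stopifnot(is.character(chain), length(chain) == 1L, nchar(chain) == 1L)
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    id <- sub("\\.(pdb|ent)$", "", basename(pdb))
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
    id <- "structure"
  }
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no ATOM/HETATM records in input")
  atoms <- data.frame(
    record  = trimws(substr(lines, 1, 6)),
    atom    = trimws(substr(lines, 13, 16)),
    alt     = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    resno   = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode   = substr(lines, 27, 27),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no such chain: ", chain)
  atoms <- atoms[!(atoms$resname %in% .water_codes), , drop = FALSE]
  atoms$occ[is.na(atoms$occ)] <- 1
  # infer element from atom name when the element column is blank
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[0-9']", "", atoms$atom[blank]), 1, 1)
  atoms$resname[atoms$resname == "MSE"] <- "MET"

  # altloc resolution: per (residue, atom name) keep highest occupancy, tie -> 'A'
  key <- paste(atoms$resno, atoms$icode, atoms$resname, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt != "A", atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$resno, atoms$atom), , drop = FALSE]

  is_aa <- atoms$resname %in% .aa3
  prot <- atoms[is_aa & atoms$icode == " ", , drop = FALSE]
  # drop residues without a C-alpha
  has_ca <- unique(prot$resno[prot$atom == "CA"])
  prot <- prot[prot$resno %in% has_ca, , drop = FALSE]
  if (nrow(prot) == 0L) stop("chain ", chain, " has no C-alpha residues")
  prot <- prot[order(prot$resno), , drop = FALSE]
  rownames(prot) <- NULL

  het <- atoms[!is_aa, , drop = FALSE]
  ligands <- list()
  if (nrow(het) > 0L) {
    grp <- split(het, paste(het$resname, het$resno))
    ligands <- unname(lapply(grp, function(g) {
      list(het_code = g$resname[1],
           atoms = g[, c("atom", "element", "x", "y", "z"), drop = FALSE])
    }))
  }
  structure(
    list(id = paste0(id, "_", chain),
         residues = prot[, c("resno", "resname", "atom", "element",
                             "x", "y", "z"), drop = FALSE],
         ligands = ligands),
    class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure", x$id, "-", length(unique(x$residues$resno)), "residues,",
      length(x$ligands), "ligand group(s)\n")
  invisible(x)
}

#' Write a Structure back to PDB-format text
#'
#' @param structure A `Structure`.
#' @param file Optional path; if `NULL` the lines are returned invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_structure <- function(structure, file = NULL) {
  res <- structure$residues
  fmt <- function(record, i, a, resname, resno, x, y, z, element) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, i, ifelse(nchar(a) < 4, paste0(" ", a), a), "",
            resname, "A", resno, "", x, y, z, 1, 0, element)
  }
  n <- nrow(res)
  lines <- fmt("ATOM", seq_len(n), res$atom, res$resname, res$resno,
               res$x, res$y, res$z, res$element)
  i <- n
  for (lig in structure$ligands) {
    la <- lig$atoms
    lines <- c(lines, fmt("HETATM", i + seq_len(nrow(la)), la$atom,
                          lig$het_code, 9000L, la$x, la$y, la$z, la$element))
    i <- i + nrow(la)
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' C-alpha coordinates of a Structure
#'
#' @param structure A `Structure`.
#' @param resno Optional residue numbers to extract (default: all, in order).
#' @return Matrix with one row per residue and columns x, y, z; rownames are
#'   residue numbers.
#' @export
ca_coords <- function(structure, resno = NULL) {
  res <- structure$residues
  ca <- res[res$atom == "CA", , drop = FALSE]
  if (!is.null(resno)) {
    miss <- setdiff(resno, ca$resno)
    if (length(miss)) stop("unknown residue(s): ", paste(miss, collapse = ", "))
    ca <- ca[match(resno, ca$resno), , drop = FALSE]
  }
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Residue numbers resolved (with C-alpha) in every ensemble member
#'
#' Members of a crystallographic ensemble differ in which residues are
#' resolved; all coordinate matrices are built over the common frame.
#'
#' @param structures List of `Structure` objects (at least two).
#' @return Integer vector of residue numbers, ascending (`ResidueFrame`).
#' @export
common_residue_frame <- function(structures) {
  stopifnot(length(structures) >= 2L)
  sets <- lapply(structures, function(s) unique(s$residues$resno[s$residues$atom == "CA"]))
  frame <- Reduce(intersect, sets)
  if (length(frame) == 0L) stop("empty residue-frame intersection")
  sort(as.integer(frame))
}

#' Define a named contiguous sequence region
#'
#' @param name Region label, e.g. `"switch2"`.
#' @param start,end First and last residue number (inclusive).
#' @return A `RegionDef` list.
#' @export
region_def <- function(name, start, end) {
  stopifnot(start <= end)
  structure(list(name = name, start = as.integer(start), end = as.integer(end)),
            class = "RegionDef")
}

#' Positions of a region's residues within a residue frame
#'
#' @param frame Integer vector of residue numbers (a `ResidueFrame`).
#' @param region A `RegionDef`.
#' @param zero_based Return 0-based positions (default `FALSE`: R-style 1-based).
#' @return Integer positions into the frame ordering.
#' @export
select_region <- function(frame, region, zero_based = FALSE) {
  idx <- which(frame >= region$start & frame <= region$end)
  if (length(idx) == 0L)
    stop("region ", region$name, " [", region$start, "-", region$end,
         "] does not overlap the residue frame")
  if (zero_based) idx - 1L else idx
}

#' Canonical Rab11 sequence regions
#'
#' Switch 1 (E39-V46), switch 2 (A68-A79), interswitch (E47-T67), the P-loop
#' (G18-S25) and the RabF/RabSF family and subfamily motifs, in author
#' (deposited) residue numbering.
#'
#' @return Named list of `RegionDef` objects.
#' @export
rab11_regions <- function() {
  list(
    ploop       = region_def("ploop", 18, 25),
    switch1     = region_def("switch1", 39, 46),
    interswitch = region_def("interswitch", 47, 67),
    switch2     = region_def("switch2", 68, 79),
    rabf1       = region_def("rabf1", 44, 48),
    rabf2       = region_def("rabf2", 61, 65),
    rabf3       = region_def("rabf3", 71, 77),
    rabf4       = region_def("rabf4", 80, 84),
    rabsf1      = region_def("rabsf1", 8, 13),
    rabsf2      = region_def("rabsf2", 25, 42),
    rabsf3      = region_def("rabsf3", 100, 122)
  )
}

#' Fetch a PDB entry into a local cache (requires network)
#'
#' Downloads `<id>.pdb` from RCSB into `cache_dir` unless already present.
#' Offline environments can pre-populate the cache by any other means; all
#' readers only look at the cache directory.
#'
#' @param id 4-character PDB identifier.
#' @param cache_dir Directory for cached files.
#' @return Path to the cached file.
#' @export
fetch_pdb <- function(id, cache_dir = "pdb_cache") {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(toupper(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}

#' Fetch a UniProt sequence into a local cache (requires network)
#'
#' @param accession UniProt accession, e.g. `"P62491"`.
#' @param cache_dir Directory for cached FASTA files.
#' @return Path to the cached file.
#' @export
fetch_uniprot <- function(accession, cache_dir = "seq_cache") {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(accession, ".fasta"))
  if (!file.exists(dest)) {
    url <- paste0("https://rest.uniprot.org/uniprotkb/", accession, ".fasta")
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}
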