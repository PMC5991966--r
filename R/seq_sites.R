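# Global pairwise alignment, percent identity, and identity over binding-site
# residue sub-selections.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Global pairwise protein alignment (affine gaps)
#'
#' Needleman-Wunsch global alignment with an affine gap model, by default
#' BLOSUM62 with gap open 10 and gap extension 0.5 (a gap of length L costs
#' `open + L * extend`). `X` denotes a masked/unknown residue. Traceback is
#' deterministic.
#'
#' @param seqA,seqB Protein sequences (plain strings).
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return An `AlignmentResult` list: `alignedA`, `alignedB` (gapped strings
#'   of equal length), `score`, `matrix`, `gap_open`, `gap_extend`.
#' @export
global_align <- function(seqA, seqB, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  check_protein(seqA); check_protein(seqB)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  out <- list(alignedA = as.character(Biostrings::alignedPattern(aln)),
              alignedB = as.character(Biostrings::alignedSubject(aln)),
              score = Biostrings::score(aln),
              matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
  stopifnot(nchar(out$alignedA) == nchar(out$alignedB),
            gsub("-", "", out$alignedA) == toupper(seqA),
            gsub("-", "", out$alignedB) == toupper(seqB))
  class(out) <- "AlignmentResult"
  out
}

check_protein <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nchar(s) > 0L)
  ch <- unique(strsplit(toupper(s), "")[[1]])
  bad <- setdiff(ch, .aa_alphabet)
  if (length(bad)) stop("invalid residue character(s): ",
                        paste(bad, collapse = ", "))
  invisible(TRUE)
}

aln_columns <- function(alignment) {
  a <- strsplit(alignment$alignedA, "")[[1]]
  b <- strsplit(alignment$alignedB, "")[[1]]
  data.frame(a = a, b = b,
             # residue number within each ungapped input sequence
             resA = cumsum(a != "-") * (a != "-"),
             resB = cumsum(b != "-") * (b != "-"),
             stringsAsFactors = FALSE)
}

identity_over <- function(cols) {
  both <- cols$a != "-" & cols$b != "-"
  if (!any(both)) stop("no mutually non-gap alignment columns")
  # X is an unknown residue: never counted as an identity
  ident <- cols$a == cols$b & cols$a != "X"
  100 * sum(ident & both) / sum(both)
}

#' Percent identity of a pairwise alignment
#'
#' `100 * identical columns / mutually non-gap columns`.
#'
#' @param alignment An `AlignmentResult`.
#' @return Percentage in [0, 100].
#' @export
percent_identity <- function(alignment) {
  identity_over(aln_columns(alignment))
}

#' Percent identity over a residue sub-selection
#'
#' Identity computed only over alignment columns whose residue number in
#' sequence A belongs to `positionsA` (e.g. the binding-site contact
#' residues), using the same mutually-non-gap denominator as
#' [percent_identity()].
#'
#' @param alignment An `AlignmentResult`.
#' @param positionsA Residue numbers in the ungapped sequence A. If sequence A
#'   does not start at residue 1 of the author numbering, pass
#'   `offsetA` = (author number of the first residue) - 1.
#' @param offsetA Author-numbering offset of sequence A (default 0).
#' @return Percentage in [0, 100].
#' @export
site_identity <- function(alignment, positionsA, offsetA = 0L) {
  if (length(positionsA) == 0L) stop("empty position set")
  cols <- aln_columns(alignment)
  keep <- cols$resA > 0 & (cols$resA + offsetA) %in% positionsA
  if (!any(keep)) stop("no alignment column matches the requested positions")
  identity_over(cols[keep, , drop = FALSE])
}

#' Pairwise percent-identity matrix
#'
#' @param sequences Named character vector or named list of sequences.
#' @param ... Passed to [global_align()].
#' @return Symmetric percentage matrix with 100 on the diagonal.
#' @export
identity_matrix <- function(sequences, ...) {
  seqs <- unlist(sequences)
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  M <- diag(100, n)
  dimnames(M) <- list(names(seqs), names(seqs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pid <- percent_identity(global_align(seqs[[i]], seqs[[j]], ...))
    M[i, j] <- M[j, i] <- pid
  }
  M
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (first word of each header).
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  out
}

#' One-letter sequence of a Structure
#'
#' @param structure A `Structure`.
#' @return Single string over the resolved residues, in residue order.
#' @export
structure_sequence <- function(structure) {
  res <- structure$residues
  ca <- res[res$atom == "CA", , drop = FALSE]
  paste(ifelse(ca$resname %in% names(.aa321), .aa321[ca$resname], "X"),
        collapse = "")
}
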