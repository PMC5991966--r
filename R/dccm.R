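# Dynamical cross-correlation matrices over a superposed ensemble.

#' Dynamical cross-correlation matrix
#'
#' For residues i, j with displacement vectors about the ensemble mean,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`. Values are in
#' [-1, 1] with unit diagonal. Residues with zero fluctuation produce
#' undefined entries, which are reported as 0 and flagged in the
#' `zero_fluctuation` attribute rather than raising an error.
#'
#' @param aligned A superposed `EnsembleMatrix` with at least 3 members.
#' @return An m x m `DCCMatrix` (dimnames = residue numbers) with attributes
#'   `frame` and `zero_fluctuation`.
#' @export
compute_dccm <- function(aligned) {
  if (n_members(aligned) < 3L) stop("need >= 3 members for a DCCM")
  X <- aligned$coords
  n <- nrow(X)
  m <- n_residues(aligned)
  D <- sweep(X, 2, colMeans(X))
  ix <- seq(1L, 3L * m, by = 3L)
  S <- (crossprod(D[, ix, drop = FALSE]) +
        crossprod(D[, ix + 1L, drop = FALSE]) +
        crossprod(D[, ix + 2L, drop = FALSE])) / n
  v <- diag(S)
  zero <- v <= .Machine$double.eps * max(v, 1)
  denom <- sqrt(outer(v, v))
  C <- S / denom
  C[!is.finite(C)] <- 0
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C)[!zero] <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(aligned$frame, aligned$frame)
  attr(C, "frame") <- aligned$frame
  attr(C, "zero_fluctuation") <- aligned$frame[zero]
  class(C) <- c("DCCMatrix", "matrix")
  C
}

#' Cross-correlation statistics between two sequence regions
#'
#' Summarizes the DCCM block between `regionA` and `regionB` (mean, min, max
#' over all residue pairs of the cross submatrix).
#'
#' @param dccm A `DCCMatrix`.
#' @param regionA,regionB `RegionDef` objects (residue numbers in the frame).
#' @return List with `mean`, `min`, `max` and the block dimensions.
#' @export
region_correlation <- function(dccm, regionA, regionB) {
  frame <- attr(dccm, "frame")
  ia <- select_region(frame, regionA)
  ib <- select_region(frame, regionB)
  block <- unclass(dccm)[ia, ib, drop = FALSE]
  list(mean = mean(block), min = min(block), max = max(block),
       n_pairs = length(block))
}

#' Write a DCCM as CSV (matrix) and long-form TSV
#'
#' @param dccm A `DCCMatrix`.
#' @param csv,tsv Output paths (either may be `NULL`).
#' @return Invisibly, the long-form data frame.
#' @export
write_dccm <- function(dccm, csv = NULL, tsv = NULL) {
  M <- unclass(dccm)
  attr(M, "frame") <- NULL
  attr(M, "zero_fluctuation") <- NULL
  if (!is.null(csv)) utils::write.csv(M, csv, row.names = TRUE)
  long <- data.frame(
    res_i = rep(rownames(M), times = ncol(M)),
    res_j = rep(colnames(M), each = nrow(M)),
    C = as.vector(M))
  if (!is.null(tsv))
    utils::write.table(long, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(long)
}
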