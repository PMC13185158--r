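## Needleman-Wunsch global alignment against a user-supplied symmetric
## substitution matrix. The DP runs in compiled code; this file owns matrix
## construction, IO in the NCBI square-table dialect, and the S4 wrapper.

#' Build a simple match/mismatch substitution matrix
#'
#' @param alphabet symbols the matrix covers; default nucleotide
#'   `{A,C,G,T,N}`.
#' @param match score for identical symbols (default `+1`).
#' @param mismatch score for differing symbols (default `-3`, mirroring the
#'   discontinuous-MEGABLAST match/mismatch ratio of 1/-3 used to seed the
#'   repository searches).
#' @return A symmetric numeric matrix with `alphabet` dimnames.
#' @export
makeSubstitutionMatrix <- function(alphabet = c("A", "C", "G", "T", "N"),
                                   match = 1, mismatch = -3) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

#' Read a substitution matrix in the NCBI square-table dialect
#'
#' Whitespace-delimited square table with a header row of symbols and the
#' same symbols leading each row; `#` comment lines are skipped.
#'
#' @param path file path.
#' @return A symmetric numeric matrix.
#' @export
readSubstitutionMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, comment.char = "#",
                    check.names = FALSE, row.names = 1)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop("substitution matrix must be square with matching row/column symbols")
  if (any(abs(m - t(m)) > 1e-9)) stop("substitution matrix must be symmetric")
  m
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under a symmetric substitution matrix with an
#' affine gap model; a gap of length L costs `gapOpen + (L - 1) * gapExtend`,
#' so equal open and extend penalties (the default) give the linear model.
#' Traceback ties are resolved deterministically as diagonal > up > left.
#'
#' @param a,b sequences of the same kind (character or `XString`).
#' @param subMatrix symmetric scoring matrix with symbol dimnames; by default
#'   [makeSubstitutionMatrix()] (match +1 / mismatch -3).
#' @param gapOpen,gapExtend negative gap penalties; defaults -2/-2 (linear).
#'
#' @return A [GlobalAlignment-class] object.
#' @examples
#' aln <- needlemanWunsch("GAT", "CAT")
#' alignmentScore(aln)  # -1: one mismatch (-3) + two matches (+1 each)
#' @export
needlemanWunsch <- function(a, b, subMatrix = makeSubstitutionMatrix(),
                            gapOpen = -2, gapExtend = gapOpen) {
  a <- toupper(as.character(a)[1]); b <- toupper(as.character(b)[1])
  if (!nzchar(a) || !nzchar(b)) stop("both sequences must be non-empty")
  if (gapOpen > 0 || gapExtend > 0) stop("gap penalties must be <= 0")
  alphabet <- rownames(subMatrix)
  if (is.null(alphabet) || !identical(alphabet, colnames(subMatrix)))
    stop("subMatrix needs identical row and column symbol names")
  res <- .nw_align(a, b, subMatrix, alphabet, gapOpen, gapExtend)
  new("GlobalAlignment",
      alignedA = res$aligned_a, alignedB = res$aligned_b,
      score = res$score, identityPercent = res$identity_percent)
}
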