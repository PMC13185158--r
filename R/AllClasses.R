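## Central S4 containers. Sequence payloads live in Biostrings XStringSet
## objects; tabular results are plain data.frames so they round-trip through
## the TSV report files unchanged.

#' SeqRepository: a reference-anchored variant repository
#'
#' Holds one reference sequence plus an ordered set of member sequences of
#' the same kind (nucleotide CDSs or proteins), with per-member provenance
#' metadata (free-text source and a non-negative mining-cycle index).
#'
#' @slot reference a length-1 [Biostrings::XStringSet] holding the reference;
#'   its name is the reference id.
#' @slot members an [Biostrings::XStringSet] of member sequences, names are
#'   unique ids.
#' @slot kind `"nucleotide"` or `"protein"`.
#' @slot meta `data.frame` with columns `id`, `source`, `cycle`, one row per
#'   member, in member order.
#'
#' @seealso [SeqRepository()], [readFastaRepository()]
#' @exportClass SeqRepository
setClass("SeqRepository",
  slots = c(
    reference = "XStringSet",
    members   = "XStringSet",
    kind      = "character",
    meta      = "data.frame"
  )
)

.NUC_ALPHABET  <- c("A", "C", "G", "T", "N")
.PROT_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V", "*")

.checkAlphabet <- function(seqs, kind) {
  allowed <- if (kind == "nucleotide") .NUC_ALPHABET else .PROT_ALPHABET
  for (i in seq_along(seqs)) {
    chars <- strsplit(as.character(seqs[[i]]), "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad)) {
      return(sprintf("sequence '%s': illegal character '%s' at position %d",
                     names(seqs)[i], chars[bad[1]], bad[1]))
    }
  }
  TRUE
}

setValidity("SeqRepository", function(object) {
  msgs <- character()
  if (length(object@reference) != 1L)
    msgs <- c(msgs, "reference must contain exactly one sequence")
  if (!object@kind %in% c("nucleotide", "protein"))
    msgs <- c(msgs, "kind must be 'nucleotide' or 'protein'")
  ids <- names(object@members)
  if (length(object@members)) {
    if (is.null(ids) || any(!nzchar(ids)))
      msgs <- c(msgs, "all members must be named")
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate member id: '%s'",
                              ids[duplicated(ids)][1]))
    if (names(object@reference) %in% ids)
      msgs <- c(msgs, "reference id duplicated among members")
  }
  if (any(width(object@reference) == 0L) || any(width(object@members) == 0L))
    msgs <- c(msgs, "sequences must be non-empty")
  ok <- .checkAlphabet(object@reference, object@kind)
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  ok <- .checkAlphabet(object@members, object@kind)
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (nrow(object@meta) != length(object@members))
    msgs <- c(msgs, "meta must have one row per member")
  if (length(msgs)) msgs else TRUE
})

#' MutationProfile: reference-anchored mutation calls for one sequence
#'
#' One row per mismatching comparable position between a query CDS and the
#' reference, with base-change class (transition/transversion/ambiguous),
#' codon-level effect (silent/missense/nonsense/ambiguous), and region label.
#'
#' @slot seqId query sequence id.
#' @slot refId reference sequence id.
#' @slot mutations `data.frame` with columns `pos_nt`, `ref_base`, `alt_base`,
#'   `change_class`, `codon_index`, `effect`, `ref_aa`, `alt_aa`, `region`.
#' @slot identityPercent percent of matching comparable (non-gap) aligned
#'   positions.
#' @slot totalMutationPercent mutations per comparable position, in percent.
#' @slot perLinePercent per 60-nt-line mutation percentages (last line uses
#'   its true length).
#' @slot basePreference named fraction of mutations whose substituted base is
#'   A/C/G/T.
#' @slot refLength reference CDS length (nt).
#' @slot lineLen line length used for `perLinePercent`.
#' @slot frameshifted `TRUE` when the pairwise alignment contained a gap run
#'   whose length was not a multiple of 3 (codon effects downstream are then
#'   reported as `"ambiguous"`).
#'
#' @exportClass MutationProfile
setClass("MutationProfile",
  slots = c(
    seqId = "character",
    refId = "character",
    mutations = "data.frame",
    identityPercent = "numeric",
    totalMutationPercent = "numeric",
    perLinePercent = "numeric",
    basePreference = "numeric",
    refLength = "integer",
    lineLen = "integer",
    frameshifted = "logical"
  )
)

setValidity("MutationProfile", function(object) {
  need <- c("pos_nt", "ref_base", "alt_base", "change_class", "codon_index",
            "effect", "ref_aa", "alt_aa", "region")
  if (!all(need %in% names(object@mutations)))
    return("mutations table is missing required columns")
  if (length(object@perLinePercent) != ceiling(object@refLength / object@lineLen))
    return("per-line vector length must be ceiling(refLength / lineLen)")
  if (object@identityPercent < 0 || object@identityPercent > 100)
    return("identityPercent out of [0, 100]")
  TRUE
})

#' GlobalAlignment: a Needleman-Wunsch pairwise global alignment
#'
#' @slot alignedA,alignedB equal-length gapped strings (gap = `-`); removing
#'   the gaps recovers the input sequences.
#' @slot score optimal global alignment score.
#' @slot identityPercent matches over comparable (both-ungapped) columns,
#'   in percent.
#'
#' @exportClass GlobalAlignment
setClass("GlobalAlignment",
  slots = c(
    alignedA = "character",
    alignedB = "character",
    score = "numeric",
    identityPercent = "numeric"
  )
)

setValidity("GlobalAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  TRUE
})

#' StandardCurve: a linear colorimetric calibration model
#'
#' Ordinary least-squares fit of absorbance on concentration, with the
#' residual standard deviation, the limit of detection `LOD = 3.3 * sigma / S`,
#' and the mean absolute percentage error of the back-predicted standards.
#'
#' @slot slope absorbance per (ug/mL); must be positive.
#' @slot intercept absorbance at zero concentration.
#' @slot sigma residual standard deviation of the response (n - 2 denominator),
#'   or a user-supplied blank-replicate SD.
#' @slot lod limit of detection in ug/mL, `3.3 * sigma / slope`.
#' @slot mape mean absolute percentage error over back-predicted standards.
#' @slot range detection range (min, max) of the standards, ug/mL.
#' @slot n number of calibration points.
#'
#' @exportClass StandardCurve
setClass("StandardCurve",
  slots = c(
    slope = "numeric",
    intercept = "numeric",
    sigma = "numeric",
    lod = "numeric",
    mape = "numeric",
    range = "numeric",
    n = "integer"
  )
)

setValidity("StandardCurve", function(object) {
  if (object@slope <= 0) return("slope must be positive")
  if (abs(object@lod - 3.3 * object@sigma / object@slope) > 1e-9 * (1 + object@lod))
    return("lod must equal 3.3 * sigma / slope")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "SeqRepository", function(object) {
  cat(sprintf("SeqRepository of %d %s member(s)\n",
              length(object@members), object@kind))
  cat(sprintf("  reference: %s (%d %s)\n", names(object@reference),
              width(object@reference),
              if (object@kind == "nucleotide") "nt" else "aa"))
  if (length(object@members)) {
    shown <- head(names(object@members), 5L)
    cat("  members:   ", paste(shown, collapse = ", "),
        if (length(object@members) > 5L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "MutationProfile", function(object) {
  cat(sprintf("MutationProfile: %s vs %s\n", object@seqId, object@refId))
  cat(sprintf("  %d mutation(s), identity %.2f%%, total %.3f%%%s\n",
              nrow(object@mutations), object@identityPercent,
              object@totalMutationPercent,
              if (object@frameshifted) " [frameshifted]" else ""))
  if (nrow(object@mutations)) {
    eff <- table(object@mutations$effect)
    cat("  effects:   ", paste(names(eff), eff, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf("GlobalAlignment (score %.4g, identity %.2f%%)\n",
              object@score, object@identityPercent))
  a <- object@alignedA; b <- object@alignedB
  if (nchar(a) > 60) {
    a <- paste0(substr(a, 1, 57), "...")
    b <- paste0(substr(b, 1, 57), "...")
  }
  cat(" ", a, "\n ", b, "\n", sep = "")
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: y = %.6g x + %.6g  (n = %d)\n",
              object@slope, object@intercept, object@n))
  cat(sprintf("  sigma %.6g, LOD %.4g ug/mL, MAPE %.3g%%, range %g-%g ug/mL\n",
              object@sigma, object@lod, object@mape,
              object@range[1], object@range[2]))
})
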