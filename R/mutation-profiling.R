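## Reference-anchored mutation calling and composition statistics.
## Coordinates are 1-based, intervals closed. Mutations involving N are
## classified "ambiguous" and excluded from the transition/transversion and
## base-preference tallies.

.asChars <- function(x) strsplit(toupper(as.character(x)[1]), "", fixed = TRUE)[[1]]

.PURINES <- c("A", "G")

.changeClass <- function(ref, alt) {
  ifelse(ref == "N" | alt == "N", "ambiguous",
    ifelse((ref %in% .PURINES) == (alt %in% .PURINES), "transition", "transversion"))
}

#' Nucleotide composition summary
#'
#' Exact base counts and GC/AT percentages, `gc = 100 * (G + C) / (A + C + G + T)`;
#' N bases are counted but excluded from the percentage denominator.
#'
#' @param seq a nucleotide sequence (character, `DNAString`) or a
#'   `DNAStringSet` for a multi-row summary.
#' @return A `data.frame` with columns `id`, `a`, `c`, `g`, `t`, `n`,
#'   `gc_percent`, `at_percent`.
#' @examples
#' composition("ATGC")$gc_percent  # 50
#' @export
composition <- function(seq) {
  if (is(seq, "DNAStringSet")) {
    rows <- lapply(seq_along(seq), function(i) {
      r <- composition(seq[[i]])
      r$id <- if (!is.null(names(seq))) names(seq)[i] else as.character(i)
      r
    })
    return(do.call(rbind, rows))
  }
  chars <- .asChars(seq)
  counts <- vapply(c("A", "C", "G", "T", "N"), function(b) sum(chars == b), 0L)
  informative <- sum(counts[c("A", "C", "G", "T")])
  if (informative == 0L) stop("sequence has no informative (non-N) bases")
  if (sum(counts) != length(chars)) stop("non-nucleotide characters in sequence")
  data.frame(
    id = NA_character_,
    a = counts[["A"]], c = counts[["C"]], g = counts[["G"]], t = counts[["T"]],
    n = counts[["N"]],
    gc_percent = 100 * (counts[["G"]] + counts[["C"]]) / informative,
    at_percent = 100 * (counts[["A"]] + counts[["T"]]) / informative,
    stringsAsFactors = FALSE
  )
}

#' Active-domain region table with envelope flanks
#'
#' The envelope of an active domain is not delimited explicitly in the
#' annotation source, so it is constructed as fixed-width flanks on either
#' side of each domain interval (clipped to the CDS).
#'
#' @param domains `data.frame` with columns `name`, `start`, `end`
#'   (1-based nt, closed).
#' @param refLength reference CDS length in nt.
#' @param envelopeWidth flank width in nt (default 30).
#' @return `data.frame` with columns `name`, `start_nt`, `end_nt`, `class`.
#' @export
regionTable <- function(domains, refLength, envelopeWidth = 30L) {
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  rows <- list()
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      name = d$name, start_nt = d$start, end_nt = d$end,
      class = "active_domain", stringsAsFactors = FALSE)
    lf <- c(max(1L, d$start - envelopeWidth), d$start - 1L)
    rf <- c(d$end + 1L, min(refLength, d$end + envelopeWidth))
    if (lf[1] <= lf[2])
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(d$name, "_env5"), start_nt = lf[1], end_nt = lf[2],
        class = "envelope", stringsAsFactors = FALSE)
    if (rf[1] <= rf[2])
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(d$name, "_env3"), start_nt = rf[1], end_nt = rf[2],
        class = "envelope", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.assignRegion <- function(pos, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(rep("other", length(pos)))
  out <- rep("other", length(pos))
  for (cls in c("envelope", "active_domain")) {  # domain applied last: wins
    sub <- regions[regions$class == cls, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      out[pos >= sub$start_nt[i] & pos <= sub$end_nt[i]] <- cls
  }
  out
}

#' Call reference-anchored nucleotide mutations
#'
#' Compares a query CDS against the reference position by position. Unequal
#' lengths are first globally aligned ([needlemanWunsch()]); gap columns are
#' excluded from the comparable positions. One mutation is reported per
#' mismatching comparable position; the codon effect is computed by
#' translating the reference codon and the query-projected codon in the
#' reference frame. If the alignment contains a gap run whose length is not a
#' multiple of 3, the reading frame is lost from that point on and codon
#' effects at and beyond it are flagged `"ambiguous"`.
#'
#' @param reference,query nucleotide sequences (character or `DNAString`);
#'   the reference length must be a multiple of 3.
#' @param regions optional region table (see [regionTable()]), columns
#'   `name`, `start_nt`, `end_nt`, `class`.
#' @param refId,seqId ids recorded on the profile (default: names).
#' @param lineLen line length for the per-line mutation percentages.
#' @param subMatrix,gapOpen,gapExtend alignment parameters for the
#'   unequal-length case.
#'
#' @return A [MutationProfile-class] object.
#' @examples
#' p <- callMutations(c(ref = "ATGGCGCTG"), c(q = "ATGGTGCTG"))
#' mutations(p)  # pos 5 C->T, transition, missense A->V
#' @export
callMutations <- function(reference, query, regions = NULL,
                          refId = NULL, seqId = NULL, lineLen = 60L,
                          subMatrix = makeSubstitutionMatrix(),
                          gapOpen = -2, gapExtend = gapOpen) {
  if (is.null(refId)) refId <- if (!is.null(names(reference))) names(reference)[1] else "reference"
  if (is.null(seqId)) seqId <- if (!is.null(names(query))) names(query)[1] else "query"
  refC <- .asChars(reference)
  qryC <- .asChars(query)
  if (length(qryC) == 0L || !nzchar(paste(qryC, collapse = "")))
    stop("empty query sequence")
  if (length(refC) %% 3L != 0L)
    stop("reference CDS length must be a multiple of 3")
  refLen <- length(refC)

  frameshifted <- FALSE
  fsFrom <- Inf  # first reference position at/after which frame is lost
  if (length(qryC) == length(refC)) {
    proj <- qryC  # query projected onto reference coordinates
    comparable <- rep(TRUE, refLen)
  } else {
    aln <- needlemanWunsch(paste(refC, collapse = ""), paste(qryC, collapse = ""),
                           subMatrix = subMatrix, gapOpen = gapOpen,
                           gapExtend = gapExtend)
    aChars <- .asChars(aln@alignedA)
    bChars <- .asChars(aln@alignedB)
    refPos <- cumsum(aChars != "-")
    proj <- rep("-", refLen)
    keep <- aChars != "-"
    proj[refPos[keep]] <- bChars[keep]
    comparable <- proj != "-"
    ## gap runs in either row; frame lost where a run length is not 0 mod 3
    gapRun <- function(gapped) {
      r <- rle(gapped == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      idx <- which(r$values & r$lengths %% 3L != 0L)
      if (!length(idx)) return(Inf)
      ## reference coordinate where the first frame-breaking run begins
      col <- starts[idx[1]]
      p <- refPos[col]
      if (p == 0L) 1L else p
    }
    fsFrom <- min(gapRun(aChars), gapRun(bChars))
    frameshifted <- is.finite(fsFrom)
  }

  mism <- which(comparable & proj != refC)
  nComparable <- sum(comparable)
  nMatch <- sum(comparable & proj == refC)

  refAAfull <- .translateChars(refC)
  mk <- function(pos) {
    ci <- (pos - 1L) %/% 3L + 1L
    cstart <- (ci - 1L) * 3L + 1L
    refCodon <- refC[cstart:(cstart + 2L)]
    altCodon <- proj[cstart:(cstart + 2L)]
    refB <- refC[pos]; altB <- proj[pos]
    cls <- .changeClass(refB, altB)
    if (pos >= fsFrom || any(altCodon == "-") || any(altCodon == "N") ||
        any(refCodon == "N")) {
      eff <- "ambiguous"; altAA <- NA_character_
    } else {
      altAA <- .translateChars(altCodon)
      refAA <- refAAfull[ci]
      eff <- if (altAA == "*" && refAA != "*") "nonsense"
             else if (altAA == refAA) "silent" else "missense"
    }
    if (cls == "ambiguous") eff <- "ambiguous"
    data.frame(pos_nt = pos, ref_base = refB, alt_base = altB,
               change_class = cls, codon_index = ci, effect = eff,
               ref_aa = refAAfull[ci], alt_aa = altAA,
               stringsAsFactors = FALSE)
  }
  mut <- if (length(mism)) do.call(rbind, lapply(mism, mk)) else
    data.frame(pos_nt = integer(), ref_base = character(),
               alt_base = character(), change_class = character(),
               codon_index = integer(), effect = character(),
               ref_aa = character(), alt_aa = character(),
               stringsAsFactors = FALSE)
  mut$region <- .assignRegion(mut$pos_nt, regions)

  informative <- mut$change_class != "ambiguous"
  basePref <- vapply(c("A", "C", "G", "T"),
                     function(b) if (sum(informative)) sum(mut$alt_base[informative] == b) / sum(informative) else 0,
                     0)

  nLines <- as.integer(ceiling(refLen / lineLen))
  lineOf <- (mut$pos_nt - 1L) %/% lineLen + 1L
  lineLenVec <- rep(lineLen, nLines)
  if (nLines > 0L) lineLenVec[nLines] <- refLen - (nLines - 1L) * lineLen
  perLine <- vapply(seq_len(nLines),
                    function(i) 100 * sum(lineOf == i) / lineLenVec[i], 0)

  new("MutationProfile",
      seqId = seqId, refId = refId, mutations = mut,
      identityPercent = if (nComparable) 100 * nMatch / nComparable else 0,
      totalMutationPercent = if (nComparable) 100 * length(mism) / nComparable else 0,
      perLinePercent = perLine,
      basePreference = basePref,
      refLength = as.integer(refLen),
      lineLen = as.integer(lineLen),
      frameshifted = frameshifted)
}

#' Locate premature stop codons
#'
#' @param query a nucleotide CDS; length must be a multiple of 3.
#' @return Integer codon indices of in-frame stop codons strictly before the
#'   terminal codon.
#' @examples
#' prematureStops("ATGTAAGCGTGA")  # 2
#' @export
prematureStops <- function(query) {
  chars <- .asChars(query)
  if (length(chars) %% 3L != 0L)
    stop(sprintf("CDS length not divisible by 3 (remainder %d)",
                 length(chars) %% 3L))
  aa <- .translateChars(chars)
  idx <- which(aa == "*")
  idx[idx < length(aa)]
}

#' Per-line mutation percentages
#'
#' Element i is `100 * (mutations in line i) / (line length)`, the last line
#' using its true length.
#'
#' @param profile a [MutationProfile-class].
#' @param lineLen positive line length in nt (default 60).
#' @return Numeric vector of length `ceiling(refLength / lineLen)`.
#' @export
perLineRates <- function(profile, lineLen = 60L) {
  if (!is.numeric(lineLen) || lineLen < 1) stop("lineLen must be positive")
  lineLen <- as.integer(lineLen)
  refLen <- profile@refLength
  nLines <- as.integer(ceiling(refLen / lineLen))
  lineOf <- (mutations(profile)$pos_nt - 1L) %/% lineLen + 1L
  lens <- rep(lineLen, nLines)
  if (nLines > 0L) lens[nLines] <- refLen - (nLines - 1L) * lineLen
  vapply(seq_len(nLines), function(i) 100 * sum(lineOf == i) / lens[i], 0)
}

#' Flatten mutation profiles to a report table
#'
#' @param profiles a list of [MutationProfile-class] objects.
#' @return `data.frame` with columns `seq_id`, `pos`, `ref`, `alt`, `class`,
#'   `effect`, `region` (the TSV report layout).
#' @export
profileTable <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    m <- mutations(p)
    if (!nrow(m)) return(NULL)
    data.frame(seq_id = p@seqId, pos = m$pos_nt, ref = m$ref_base,
               alt = m$alt_base, class = m$change_class, effect = m$effect,
               region = m$region, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seq_id = character(), pos = integer(), ref = character(),
                      alt = character(), class = character(),
                      effect = character(), region = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
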