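## Hotspot and mismatch-motif mining across a profiled repository.
## A hotspot is one exact nucleotide change (pos, alt) shared by at least
## `minShare` sequences. A motif is a canonicalized group of nearby
## substitutions -- (offsets from the leftmost member, substituted bases) --
## recurring across sequences, with gap-constrained greedy grouping.

#' Find mutational hotspots
#'
#' Counts, over all profiles, how many distinct sequences carry each exact
#' silent or missense change `(pos, alt)` and reports those shared by at
#' least `minShare` sequences (inclusive).
#'
#' @param profiles non-empty list of [MutationProfile-class] objects against
#'   the same reference.
#' @param minShare minimum number of sequences sharing the change
#'   (default 4).
#' @return `data.frame` with columns `pos_nt`, `alt_base`, `effect`,
#'   `support`, sorted by support descending then position ascending.
#' @export
findHotspots <- function(profiles, minShare = 4L) {
  if (length(profiles) == 0L) stop("profile list is empty")
  if (minShare < 1L) stop("minShare must be positive")
  rows <- lapply(profiles, function(p) {
    m <- mutations(p)
    m <- m[m$effect %in% c("silent", "missense"), , drop = FALSE]
    if (!nrow(m)) return(NULL)
    data.frame(seq_id = p@seqId, pos_nt = m$pos_nt, alt_base = m$alt_base,
               effect = m$effect, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  empty <- data.frame(pos_nt = integer(), alt_base = character(),
                      effect = character(), support = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(all)) return(empty)
  all <- unique(all)  # one vote per sequence per (pos, alt)
  key <- paste(all$pos_nt, all$alt_base)
  support <- table(key)
  keep <- names(support)[support >= minShare]
  if (!length(keep)) return(empty)
  first <- all[!duplicated(key) & key %in% keep, , drop = FALSE]
  firstKey <- paste(first$pos_nt, first$alt_base)
  out <- data.frame(pos_nt = first$pos_nt, alt_base = first$alt_base,
                    effect = first$effect,
                    support = as.integer(support[firstKey]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$pos_nt, out$alt_base), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## greedy left-to-right grouping of mutated positions: extend a group while
## the next gap is <= maxGap and the resulting span stays <= maxSpan
.motifOccurrences <- function(pos, alt, maxGap, maxSpan) {
  occ <- list()
  i <- 1L
  n <- length(pos)
  while (i <= n) {
    j <- i
    while (j < n && pos[j + 1L] - pos[j] <= maxGap &&
           pos[j + 1L] - pos[i] <= maxSpan) j <- j + 1L
    if (j > i) {
      idx <- i:j
      occ[[length(occ) + 1L]] <- list(start = pos[i],
                                      offsets = pos[idx] - pos[i],
                                      alts = alt[idx])
    }
    i <- j + 1L
  }
  occ
}

#' Find recurring mismatch motifs
#'
#' Enumerates, per sequence, maximal groups of mutated positions whose
#' consecutive gaps are at most `maxGap` nt and whose span is at most
#' `maxSpan` nt, canonicalizes each group to (offsets, substituted bases)
#' and reports motifs carried by at least `minSupport` sequences anywhere.
#' Motif identity is defined by offsets and substituted bases only; single
#' isolated mutations never form a motif.
#'
#' @param profiles non-empty list of [MutationProfile-class] objects.
#' @param minSupport minimum number of distinct sequences carrying the motif
#'   at any site (default 5, i.e. "more than 4").
#' @param maxGap maximum distance between consecutive motif members
#'   (default 4 nt).
#' @param maxSpan maximum motif span (default 10 nt).
#' @return `data.frame` with columns `offsets` (comma string), `alt_bases`,
#'   `shape` (`consecutive`/`separated`), `gaps` (comma string),
#'   `support_same_site`, `support_any_site`, `first_pos`; sorted by any-site
#'   support descending then leftmost position ascending. Both support
#'   counters count distinct sequences.
#' @export
findPatterns <- function(profiles, minSupport = 5L, maxGap = 4L, maxSpan = 10L) {
  if (length(profiles) == 0L) stop("profile list is empty")
  if (maxGap < 1L) stop("maxGap must be at least 1")
  occRows <- list()
  for (p in profiles) {
    m <- mutations(p)
    m <- m[m$change_class != "ambiguous", , drop = FALSE]
    if (nrow(m) < 2L) next
    m <- m[order(m$pos_nt), , drop = FALSE]
    for (o in .motifOccurrences(m$pos_nt, m$alt_base, maxGap, maxSpan)) {
      occRows[[length(occRows) + 1L]] <- data.frame(
        seq_id = p@seqId,
        key = paste(paste(o$offsets, collapse = ","),
                    paste(o$alts, collapse = ""), sep = ":"),
        start = o$start,
        offsets = paste(o$offsets, collapse = ","),
        alt_bases = paste(o$alts, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(offsets = character(), alt_bases = character(),
                      shape = character(), gaps = character(),
                      support_same_site = integer(),
                      support_any_site = integer(), first_pos = integer(),
                      stringsAsFactors = FALSE)
  if (!length(occRows)) return(empty)
  occ <- do.call(rbind, occRows)

  out <- do.call(rbind, lapply(split(occ, occ$key), function(g) {
    anySupport <- length(unique(g$seq_id))
    bySite <- vapply(split(g$seq_id, g$start),
                     function(s) length(unique(s)), 0L)
    offs <- as.integer(strsplit(g$offsets[1], ",", fixed = TRUE)[[1]])
    gaps <- diff(offs)
    data.frame(offsets = g$offsets[1], alt_bases = g$alt_bases[1],
               shape = if (all(gaps == 1L)) "consecutive" else "separated",
               gaps = paste(gaps, collapse = ","),
               support_same_site = max(bySite),
               support_any_site = anySupport,
               first_pos = min(g$start),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$support_any_site >= minSupport, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- out[order(-out$support_any_site, out$first_pos, out$offsets), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-line mismatch count matrix
#'
#' @param profiles list of [MutationProfile-class] objects sharing one
#'   reference (may be empty when `refLength` is given: the result is then a
#'   zero-row matrix).
#' @param lineLen line length in nt (default 60).
#' @param refLength reference length; defaults to the first profile's.
#' @return Integer matrix, rows = sequence ids, columns = line indices;
#'   row sums equal each sequence's total mutation count.
#' @export
mismatchMatrix <- function(profiles, lineLen = 60L, refLength = NULL) {
  if (length(profiles) == 0L && is.null(refLength))
    stop("profile list is empty and no refLength given")
  refLen <- if (is.null(refLength)) profiles[[1]]@refLength else as.integer(refLength)
  nLines <- as.integer(ceiling(refLen / lineLen))
  m <- matrix(0L, nrow = length(profiles), ncol = nLines,
              dimnames = list(vapply(profiles, function(p) p@seqId, ""),
                              seq_len(nLines)))
  for (i in seq_along(profiles)) {
    lineOf <- (mutations(profiles[[i]])$pos_nt - 1L) %/% lineLen + 1L
    t <- table(factor(lineOf, levels = seq_len(nLines)))
    m[i, ] <- as.integer(t)
  }
  m
}
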