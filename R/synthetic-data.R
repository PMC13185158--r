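## Seeded synthetic reference CDSs and variant repositories with ground-truth
## mutation tables. The generator reproduces the statistical structure the
## mining pipeline assumes: GC-rich CDSs (~68%), variants at a controlled
## identity range, G/C-biased substituted bases, an exact silent/missense
## split where combinatorially possible, and motif templates planted at
## recorded positions. A +/-10 nt exclusion buffer around planted motifs
## keeps incidental mutations from merging into a planted group, which would
## change its canonical (offsets, alt-bases) key.

.STOPS <- c("TAA", "TAG", "TGA")

.codonAt <- function(chars, ci) chars[((ci - 1L) * 3L + 1L):((ci - 1L) * 3L + 3L)]

#' Generate a synthetic reference CDS
#'
#' Starts with ATG, ends with a single terminal stop, contains no internal
#' stop codons, and hits the GC target to within 0.1 percentage points
#' (repair by random A/T <-> G/C flips that never create a stop).
#' Deterministic under `seed`.
#'
#' @param lengthNt CDS length in nt, a multiple of 3 (default 1281,
#'   i.e. a 426-residue protein plus the terminal stop).
#' @param gcTarget target GC fraction (default 0.679).
#' @param seed integer RNG seed.
#' @param id sequence id.
#' @return A length-1 named [Biostrings::DNAStringSet].
#' @export
generateReference <- function(lengthNt = 1281L, gcTarget = 0.679, seed = NULL,
                              id = "synthetic_ref") {
  lengthNt <- as.integer(lengthNt)
  if (lengthNt %% 3L != 0L || lengthNt < 9L)
    stop("lengthNt must be a multiple of 3 and at least 9")
  g0 <- round(gcTarget * lengthNt)
  if (g0 < 2L || g0 > lengthNt - 4L)  # ATG + TGA fix 2 GC and 4 AT-capable slots
    stop("unattainable GC target for this length")
  if (!is.null(seed)) set.seed(seed)

  p <- gcTarget
  nInt <- lengthNt - 6L
  chars <- c("A", "T", "G",
             sample(c("A", "C", "G", "T"), nInt, replace = TRUE,
                    prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
             "T", "G", "A")
  nCodon <- lengthNt %/% 3L
  ## repair internal stops: all stops start with T; C keeps the frame stop-free
  for (ci in 2:(nCodon - 1L)) {
    if (paste(.codonAt(chars, ci), collapse = "") %in% .STOPS)
      chars[(ci - 1L) * 3L + 1L] <- "C"
  }
  ## GC repair toward the exact target count
  internal <- 4:(lengthNt - 3L)
  for (iter in seq_len(50L * lengthNt)) {
    delta <- g0 - sum(chars %in% c("G", "C"))
    if (delta == 0L) break
    fromSet <- if (delta > 0L) c("A", "T") else c("G", "C")
    toSet <- if (delta > 0L) c("G", "C") else c("A", "T")
    cand <- internal[chars[internal] %in% fromSet]
    if (!length(cand)) stop("unattainable GC target for this length")
    pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
    newBase <- sample(toSet, 1L)
    old <- chars[pos]
    chars[pos] <- newBase
    ci <- (pos - 1L) %/% 3L + 1L
    if (paste(.codonAt(chars, ci), collapse = "") %in% .STOPS)
      chars[pos] <- old  # rejected flip; try again
  }
  if (g0 != sum(chars %in% c("G", "C")))
    stop("unattainable GC target for this length")
  DNAStringSet(setNames(paste(chars, collapse = ""), id))
}

## enumerate single-base edits of a codon; kind = "silent" or "missense"
.codonEdits <- function(codon, kind) {
  aaRef <- unname(Biostrings::GENETIC_CODE[paste(codon, collapse = "")])
  out <- list()
  for (k in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), codon[k])) {
      alt <- codon
      alt[k] <- b
      cstr <- paste(alt, collapse = "")
      if (cstr %in% .STOPS) next
      aaAlt <- unname(Biostrings::GENETIC_CODE[cstr])
      ok <- if (kind == "silent") aaAlt == aaRef else aaAlt != aaRef
      if (ok) out[[length(out) + 1L]] <- list(offset = k, alt = b)
    }
  }
  out
}

.stopEdits <- function(codon) {
  out <- list()
  for (k in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), codon[k])) {
      alt <- codon
      alt[k] <- b
      if (paste(alt, collapse = "") %in% .STOPS)
        out[[length(out) + 1L]] <- list(offset = k, alt = b)
    }
  }
  out
}

#' Generate a synthetic variant repository with ground truth
#'
#' Each variant carries a requested number of single-base substitutions:
#' optional motif templates planted first (in the first `motifCarriers`
#' variants, at recorded positions), then synonymous codon edits for the
#' silent share and non-synonymous, non-stop edits for the rest, one edited
#' codon per mutation. Substituted bases are drawn with the `baseBias`
#' weights where the codon offers a choice. No internal stop is ever
#' created unless `stopInjection` asks for dedicated stop-carrying variants
#' (used to exercise the repository filters). Truth-table effects are
#' recomputed from the finished variant, so profiling recovers them exactly.
#'
#' @param reference the reference CDS (from [generateReference()], or any
#'   named length-1 `DNAStringSet`/character).
#' @param nVariants number of variants (default 20).
#' @param nMutations mutation count per variant (scalar or vector); when
#'   `NULL`, counts are derived from `identityRange` via
#'   `n = round((1 - identity) * length)`.
#' @param identityRange identity fractions to sample when `nMutations` is
#'   `NULL` (default `c(0.95, 0.992)`, the similarity band of the mined
#'   repository).
#' @param silentFraction fraction of (non-motif) mutations that must be
#'   silent (default 0.77).
#' @param baseBias target substituted-base fractions, summing to 1; the
#'   default (A 5%, C 35%, G 35%, T 25%) mirrors the G/C-dominated spectrum
#'   with rare A substitutions observed in the mined repository.
#' @param motifTemplates list of motif templates, each
#'   `list(offsets = c(0, ...), alt = c("G", ...))`.
#' @param motifCarriers how many of the first variants carry every template
#'   (default 0).
#' @param stopInjection how many of the last variants additionally receive a
#'   premature stop codon (default 0).
#' @param seed integer RNG seed.
#' @param idPrefix member id prefix.
#' @return A list with `repository` ([SeqRepository-class]), `truth`
#'   (`data.frame`: `variant_id`, `pos`, `ref`, `alt`, `effect`, `origin`)
#'   and `motifs` (`data.frame`: `variant_id`, `template`, `start`,
#'   `offsets`, `alt_bases`).
#' @export
generateVariants <- function(reference, nVariants = 20L, nMutations = NULL,
                             identityRange = c(0.95, 0.992),
                             silentFraction = 0.77,
                             baseBias = c(A = 0.05, C = 0.35, G = 0.35, T = 0.25),
                             motifTemplates = NULL, motifCarriers = 0L,
                             stopInjection = 0L, seed = NULL,
                             idPrefix = "var") {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(baseBias) - 1) > 1e-8) stop("baseBias must sum to 1")
  refName <- if (!is.null(names(reference))) names(reference)[1] else "reference"
  refC <- .asChars(if (is(reference, "XStringSet")) reference[[1]] else reference)
  len <- length(refC)
  if (len %% 3L != 0L) stop("reference length must be a multiple of 3")
  nCodon <- len %/% 3L

  nMutVec <- if (!is.null(nMutations)) {
    rep_len(as.integer(nMutations), nVariants)
  } else {
    ident <- runif(nVariants, identityRange[1], identityRange[2])
    as.integer(round((1 - ident) * len))
  }

  truth <- list(); motifs <- list(); seqs <- character(nVariants)
  pickAlt <- function(cands) {
    ## cands: list of list(offset, alt); weight by baseBias of the alt base
    w <- baseBias[vapply(cands, `[[`, "", "alt")]
    if (all(w == 0)) w <- rep(1, length(cands))
    cands[[sample.int(length(cands), 1L, prob = w)]]
  }

  for (v in seq_len(nVariants)) {
    vid <- sprintf("%s%03d", idPrefix, v)
    chars <- refC
    used <- logical(nCodon); used[1] <- TRUE; used[nCodon] <- TRUE
    blocked <- logical(len)
    muts <- list()
    addMut <- function(pos, alt, origin) {
      muts[[length(muts) + 1L]] <<- data.frame(
        variant_id = vid, pos = pos, ref = refC[pos], alt = alt,
        effect = NA_character_, origin = origin, stringsAsFactors = FALSE)
      chars[pos] <<- alt
    }

    ## plant motif templates
    if (v <= motifCarriers && length(motifTemplates)) {
      for (tk in seq_along(motifTemplates)) {
        tpl <- motifTemplates[[tk]]
        span <- max(tpl$offsets)
        placed <- FALSE
        for (try in seq_len(500L)) {
          s <- sample(4:(len - 3L - span), 1L)
          pos <- s + tpl$offsets
          cods <- unique((pos - 1L) %/% 3L + 1L)
          if (any(used[cods]) || any(blocked[pos])) next
          if (any(refC[pos] == tpl$alt)) next
          tmp <- chars
          tmp[pos] <- tpl$alt
          stopMade <- any(vapply(cods, function(ci)
            paste(.codonAt(tmp, ci), collapse = "") %in% .STOPS, TRUE))
          if (stopMade) next
          for (k in seq_along(pos)) addMut(pos[k], tpl$alt[k], "motif")
          used[cods] <- TRUE
          zone <- max(1L, s - 10L):min(len, s + span + 10L)
          blocked[zone] <- TRUE
          motifs[[length(motifs) + 1L]] <- data.frame(
            variant_id = vid, template = tk, start = s,
            offsets = paste(tpl$offsets, collapse = ","),
            alt_bases = paste(tpl$alt, collapse = ""),
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place motif template ", tk, " in variant ", vid)
      }
    }

    nPlanted <- length(muts)
    r <- max(0L, nMutVec[v] - nPlanted)
    nSilent <- as.integer(round(silentFraction * r))
    nMissense <- r - nSilent

    freeCodons <- which(!used)
    freeCodons <- freeCodons[!vapply(freeCodons, function(ci)
      any(blocked[((ci - 1L) * 3L + 1L):((ci - 1L) * 3L + 3L)]), TRUE)]
    freeCodons <- freeCodons[sample.int(length(freeCodons))]
    place <- function(kind, nWanted) {
      placed <- 0L
      while (placed < nWanted && length(freeCodons)) {
        ci <- freeCodons[1L]
        freeCodons <<- freeCodons[-1L]
        cands <- .codonEdits(.codonAt(refC, ci), kind)
        if (!length(cands)) next
        ch <- pickAlt(cands)
        pos <- (ci - 1L) * 3L + ch$offset
        addMut(pos, ch$alt, "random")
        used[ci] <- TRUE
        placed <- placed + 1L
      }
      if (placed < nWanted)
        stop(sprintf("variant %s: could only place %d of %d %s mutations",
                     vid, placed, nWanted, kind))
      placed
    }
    place("silent", nSilent)
    place("missense", nMissense)

    ## dedicated premature-stop injection for filter testing
    if (v > nVariants - stopInjection) {
      done <- FALSE
      while (!done && length(freeCodons)) {
        ci <- freeCodons[1L]
        freeCodons <- freeCodons[-1L]
        cands <- .stopEdits(.codonAt(refC, ci))
        if (!length(cands)) next
        ch <- cands[[sample.int(length(cands), 1L)]]
        addMut((ci - 1L) * 3L + ch$offset, ch$alt, "stop_injection")
        used[ci] <- TRUE
        done <- TRUE
      }
      if (!done) stop("variant ", vid, ": no codon available for stop injection")
    }

    seqs[v] <- paste(chars, collapse = "")
    if (length(muts)) {
      tt <- do.call(rbind, muts)
      ## recompute effects from the finished variant (consistent with the
      ## profiler even when a codon carries more than one planted change)
      varAA <- .translateChars(chars)
      refAA <- .translateChars(refC)
      ci <- (tt$pos - 1L) %/% 3L + 1L
      tt$effect <- ifelse(varAA[ci] == "*" & refAA[ci] != "*", "nonsense",
                          ifelse(varAA[ci] == refAA[ci], "silent", "missense"))
      truth[[length(truth) + 1L]] <- tt
    }
  }

  memberIds <- sprintf("%s%03d", idPrefix, seq_len(nVariants))
  repo <- SeqRepository(setNames(paste(refC, collapse = ""), refName),
                        setNames(seqs, memberIds), kind = "nucleotide",
                        source = "synthetic")
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(variant_id = character(), pos = integer(), ref = character(),
               alt = character(), effect = character(), origin = character(),
               stringsAsFactors = FALSE)
  motifDf <- if (length(motifs)) do.call(rbind, motifs) else
    data.frame(variant_id = character(), template = integer(),
               start = integer(), offsets = character(),
               alt_bases = character(), stringsAsFactors = FALSE)
  rownames(truthDf) <- NULL; rownames(motifDf) <- NULL
  list(repository = repo, truth = truthDf, motifs = motifDf)
}
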