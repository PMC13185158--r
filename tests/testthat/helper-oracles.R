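# Independent oracles used by the unit and property tests. These are
# deliberately naive implementations (exhaustive enumeration, dictionary
# counting, direct formula transcription) that share no code with the
# package internals they check.

# Exhaustive global-alignment score: full recursion over every possible
# alignment path, linear gap costs. No memoization -- this is enumeration.
enumAlignScore <- function(a, b, match = 1, mismatch = -3, gap = -2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= n) best <- max(best, gap + rec(i + 1L, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# Exhaustive 12-pair transition/transversion lookup.
TITV_ORACLE <- c(
  "A>G" = "transition", "G>A" = "transition",
  "C>T" = "transition", "T>C" = "transition",
  "A>C" = "transversion", "C>A" = "transversion",
  "A>T" = "transversion", "T>A" = "transversion",
  "C>G" = "transversion", "G>C" = "transversion",
  "G>T" = "transversion", "T>G" = "transversion")

# Brute-force hotspot counting: dictionary over (pos, alt) of silent or
# missense calls, one vote per sequence.
bruteHotspots <- function(profiles, minShare) {
  votes <- list()
  for (p in profiles) {
    m <- mutations(p)
    m <- m[m$effect %in% c("silent", "missense"), , drop = FALSE]
    for (k in seq_len(nrow(m))) {
      key <- paste(m$pos_nt[k], m$alt_base[k])
      votes[[key]] <- union(votes[[key]], p@seqId)
    }
  }
  keep <- names(votes)[vapply(votes, length, 0L) >= minShare]
  out <- data.frame(
    pos_nt = as.integer(sub(" .*", "", keep)),
    alt_base = sub(".* ", "", keep),
    support = vapply(votes[keep], length, 0L),
    stringsAsFactors = FALSE)
  out[order(-out$support, out$pos_nt, out$alt_base), , drop = FALSE]
}

# Brute-force minimum-distance proximity code for one substitution.
bruteProximityCode <- function(pos, sitePositions, window) {
  if (!length(sitePositions)) return(0L)
  d <- Inf
  for (s in sitePositions) d <- min(d, abs(pos - s))
  if (d == 0) -1L else if (d <= window) -as.integer(d + 1L) else 0L
}

# Direct transcription of the charge-patterning definition, kept separate
# from the package implementation (explicit window loops, no rolling sums).
bruteKappa <- function(seq) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch <- ifelse(aa %in% c("K", "R"), 1L, ifelse(aa %in% c("D", "E"), -1L, 0L))
  sigmaOf <- function(v) {
    fp <- mean(v > 0); fm <- mean(v < 0)
    if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
  }
  deltaOf <- function(v, g) {
    sSeq <- sigmaOf(v)
    devs <- numeric(0)
    for (i in 1:(length(v) - g + 1))
      devs <- c(devs, (sigmaOf(v[i:(i + g - 1)]) - sSeq)^2)
    mean(devs)
  }
  if (all(ch == 0)) return(0)
  nm <- sum(ch < 0); np <- sum(ch > 0); nn <- sum(ch == 0)
  h <- nn %/% 2L; t3 <- nn %/% 3L
  shapes <- function(a, b) list(
    c(a, rep(0L, nn), b),
    c(rep(0L, nn), a, b),
    c(rep(0L, h), a, b, rep(0L, nn - h)),
    c(rep(0L, t3), a, rep(0L, t3), b, rep(0L, nn - 2L * t3)),
    c(rep(0L, h), a, rep(0L, nn - h), b))
  arrangements <- c(shapes(rep(-1L, nm), rep(1L, np)),
                    shapes(rep(1L, np), rep(-1L, nm)))
  ks <- c()
  for (g in c(5L, 6L)) {
    dmax <- 0
    for (arr in arrangements) dmax <- max(dmax, deltaOf(arr, g))
    if (dmax > 0) ks <- c(ks, deltaOf(ch, g) / dmax)
  }
  if (!length(ks)) 0 else min(1, mean(ks))
}

# Random protein sequence with a guaranteed mix of charged residues.
randomProtein <- function(len) {
  paste(sample(c("A", "G", "S", "T", "L", "P", "D", "E", "K", "R", "H",
                 "Q", "N", "F", "Y", "V"), len, replace = TRUE),
        collapse = "")
}

# Random CDS of n codons (no internal stops) for toy profiling tests.
randomCds <- function(nCodon) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(codons, nCodon - 2L, replace = TRUE),
                      collapse = ""), "TGA")
}

profileOf <- function(ref, var, id = "q", ...) {
  callMutations(c(ref = ref), setNames(var, id), ...)
}
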