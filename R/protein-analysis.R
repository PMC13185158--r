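## Protein-level analysis: mapping substitutions onto structural
## annotations, physicochemical deltas, Das-Pappu charge patterning
## (FCR/NCPR/kappa) and binding-site proximity scoring used for candidate
## selection.

## Kyte-Doolittle hydropathy
.KD <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
         G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
         H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
         R = -4.5)

## integer side-chain charge at pH 7 (H treated as neutral by default)
.AA_CHARGE <- c(D = -1, E = -1, K = 1, R = 1, H = 0)

.AA_POLARITY <- c(
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  P = "nonpolar", F = "nonpolar", M = "nonpolar", W = "nonpolar",
  G = "nonpolar",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
  C = "polar",
  D = "acidic", E = "acidic",
  K = "basic", R = "basic", H = "basic")

.aaCharge <- function(aa, histidineCharge = 0) {
  ch <- unname(.AA_CHARGE[aa])
  ch[is.na(ch)] <- 0
  ch[aa == "H"] <- histidineCharge
  ch
}

#' Physicochemical delta of an amino-acid substitution
#'
#' Kyte-Doolittle hydropathy delta (`scale(alt) - scale(ref)`), integer
#' charge delta at pH 7 (D/E = -1, K/R = +1, H = 0) and the ordered polarity
#' class pair (`nonpolar`, `polar`, `acidic`, `basic`).
#'
#' @param refAA,altAA single canonical amino-acid letters.
#' @return A list with `hydropathy_delta`, `charge_delta`,
#'   `polarity_change` (character vector `c(from, to)`).
#' @examples
#' propertyDelta("P", "R")$polarity_change  # nonpolar -> basic
#' propertyDelta("I", "V")$hydropathy_delta # -0.3
#' @export
propertyDelta <- function(refAA, altAA) {
  refAA <- toupper(refAA); altAA <- toupper(altAA)
  if (!refAA %in% names(.KD) || !altAA %in% names(.KD))
    stop("non-canonical amino-acid letter: ",
         paste(setdiff(c(refAA, altAA), names(.KD)), collapse = ", "))
  list(hydropathy_delta = unname(.KD[altAA] - .KD[refAA]),
       charge_delta = .aaCharge(altAA) - .aaCharge(refAA),
       polarity_change = unname(c(.AA_POLARITY[refAA], .AA_POLARITY[altAA])))
}

#' Read a structural annotation table
#'
#' Tab-separated columns `category` (one of `domain`, `helix`, `sheet`,
#' `turn`, `loop`), `label`, `start`, `end` (1-based closed residue
#' intervals), optional `length_class`.
#'
#' @param path TSV file path.
#' @return The annotation `data.frame`.
#' @export
readAnnotationSet <- function(path) {
  ann <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", quote = "")
  need <- c("category", "label", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(ann$category), c("domain", "helix", "sheet", "turn", "loop"))
  if (length(bad)) stop("unknown annotation category: ", paste(bad, collapse = ", "))
  ann
}

#' Read a binding-site configuration table
#'
#' Tab-separated columns `pos`, `ligand` (`substrate_sugar`,
#' `substrate_lipid`, `product`, `atp`, `gtp`), `source` (`docking` or
#' `motif`), optional `note`, `ac_score`, `swissparam_score`.
#' `(pos, ligand, source)` must be unique.
#'
#' @param path TSV file path.
#' @return The binding-site `data.frame`.
#' @export
readBindingSites <- function(path) {
  sites <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "#", quote = "")
  need <- c("pos", "ligand", "source")
  if (!all(need %in% names(sites)))
    stop("binding-site table must have columns: ", paste(need, collapse = ", "))
  okLig <- c("substrate_sugar", "substrate_lipid", "product", "atp", "gtp")
  bad <- setdiff(unique(sites$ligand), okLig)
  if (length(bad)) stop("unknown ligand: ", paste(bad, collapse = ", "))
  key <- paste(sites$pos, sites$ligand, sites$source)
  if (anyDuplicated(key)) stop("duplicate (pos, ligand, source) entry")
  sites
}

#' Packaged RhlB annotation and binding-site fixtures
#'
#' Structural intervals and binding-site residue sets for the 426-residue
#' reference RhlB, transcribed from published docking and structure figures.
#' Domain A/B boundaries are only shown graphically in the source and are
#' marked approximate (user-editable) in the file.
#'
#' @return A `data.frame` (see [readAnnotationSet()] / [readBindingSites()]).
#' @export
rhlbAnnotations <- function() {
  readAnnotationSet(system.file("extdata", "rhlb_annotations.tsv",
                                package = "rhlBminer", mustWork = TRUE))
}

#' @rdname rhlbAnnotations
#' @export
rhlbBindingSites <- function() {
  readBindingSites(system.file("extdata", "rhlb_binding_sites.tsv",
                               package = "rhlBminer", mustWork = TRUE))
}

.ELEMENT_PRECEDENCE <- c("helix", "sheet", "turn", "loop")

#' Map amino-acid substitutions onto structural annotations
#'
#' One row per differing position between two equal-length proteins, with
#' the structural element assigned by interval lookup (precedence
#' helix/sheet > turn > loop > primary), the active-domain label, and the
#' physicochemical deltas of [propertyDelta()].
#'
#' @param refProtein,varProtein equal-length protein sequences (character or
#'   `AAString`); align first if lengths differ.
#' @param annotations optional annotation `data.frame`
#'   (see [readAnnotationSet()]).
#' @param seqId id recorded in the `seq_id` column (default: name of
#'   `varProtein`).
#' @return `data.frame` with columns `seq_id`, `pos_aa`, `ref_aa`, `alt_aa`,
#'   `element`, `domain`, `hydropathy_delta`, `charge_delta`,
#'   `polarity_from`, `polarity_to`.
#' @export
mapSubstitutions <- function(refProtein, varProtein, annotations = NULL,
                             seqId = NULL) {
  if (is.null(seqId))
    seqId <- if (!is.null(names(varProtein))) names(varProtein)[1] else "variant"
  a <- .asChars(refProtein); b <- .asChars(varProtein)
  if (length(a) == 0L || length(b) == 0L) stop("empty protein sequence")
  if (length(a) != length(b))
    stop("proteins differ in length; align them first")
  diffs <- which(a != b)
  lookup <- function(pos, cats) {
    if (is.null(annotations)) return(NA_character_)
    for (cat in cats) {
      sub <- annotations[annotations$category == cat, , drop = FALSE]
      hit <- which(pos >= sub$start & pos <= sub$end)
      if (length(hit)) return(sub$label[hit[1]])
    }
    NA_character_
  }
  rows <- lapply(diffs, function(p) {
    el <- NA_character_
    for (cat in .ELEMENT_PRECEDENCE) {
      lbl <- lookup(p, cat)
      if (!is.na(lbl)) { el <- lbl; break }
    }
    if (is.na(el)) el <- "primary"
    dom <- lookup(p, "domain")
    pd <- if (a[p] %in% names(.KD) && b[p] %in% names(.KD))
      propertyDelta(a[p], b[p])
    else list(hydropathy_delta = NA_real_, charge_delta = NA_real_,
              polarity_change = c(NA_character_, NA_character_))
    data.frame(seq_id = seqId, pos_aa = p, ref_aa = a[p], alt_aa = b[p],
               element = el, domain = if (is.na(dom)) NA_character_ else dom,
               hydropathy_delta = pd$hydropathy_delta,
               charge_delta = pd$charge_delta,
               polarity_from = pd$polarity_change[1],
               polarity_to = pd$polarity_change[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seq_id = character(), pos_aa = integer(),
                      ref_aa = character(), alt_aa = character(),
                      element = character(), domain = character(),
                      hydropathy_delta = numeric(), charge_delta = numeric(),
                      polarity_from = character(), polarity_to = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## candidate maximally segregated arrangements of a fixed composition:
## charge blocks with the neutral residues placed outside, between, around,
## or splitting the blocks. Evaluating delta over this family (and taking
## the max) approximates the delta of the truly most segregated permutation;
## the family is closed under reversal and global charge swap, which keeps
## kappa invariant under both.
.segregatedArrangements <- function(nNeg, nNeu, nPos) {
  blocks <- function(...) unlist(list(...))
  neg <- rep(-1, nNeg); pos <- rep(1, nPos)
  neu <- function(k) rep(0, k)
  h <- nNeu %/% 2L; t3 <- nNeu %/% 3L
  shapes <- function(a, b) list(
    blocks(a, neu(nNeu), b),                     # classic: ends apart
    blocks(neu(nNeu), a, b),                     # charges adjacent at end
    blocks(neu(h), a, b, neu(nNeu - h)),         # adjacent, centred
    blocks(neu(t3), a, neu(t3), b,
           neu(nNeu - 2L * t3)),                 # interior, separated
    blocks(neu(h), a, neu(nNeu - h), b)          # one interior block
  )
  ## both block orders keep the family closed under global charge swap
  unique(c(shapes(neg, pos), shapes(pos, neg)))
}

## mean squared deviation of blob charge asymmetry from the sequence value
.deltaG <- function(charges, blob) {
  n <- length(charges)
  fp <- mean(charges > 0); fm <- mean(charges < 0)
  fcr <- fp + fm
  sigmaSeq <- if (fcr == 0) 0 else (fp - fm)^2 / fcr
  nw <- n - blob + 1L
  ## rolling counts of positive / negative residues
  pos <- as.numeric(charges > 0); neg <- as.numeric(charges < 0)
  cp <- cumsum(pos); cn <- cumsum(neg)
  wp <- (cp[blob:n] - c(0, cp)[seq_len(nw)]) / blob
  wn <- (cn[blob:n] - c(0, cn)[seq_len(nw)]) / blob
  wf <- wp + wn
  sigma <- ifelse(wf == 0, 0, (wp - wn)^2 / wf)
  mean((sigma - sigmaSeq)^2)
}

#' Charge-patterning descriptors (FCR, NCPR, kappa)
#'
#' Fraction of charged residues `FCR = (n+ + n-)/N`, net charge per residue
#' `NCPR = (n+ - n-)/N`, and the Das-Pappu charge-segregation parameter
#' kappa: for blob sizes g in {5, 6}, `delta_g` is the mean over sliding
#' g-residue blobs of `(sigma_blob - sigma_seq)^2` with
#' `sigma = NCPR^2 / FCR` (0 where FCR is 0); each `delta_g` is normalized
#' by `delta_max`, the same quantity maximized over a family of maximally
#' segregated block arrangements of the identical composition (charge
#' blocks with the neutral residues outside, between, around or splitting
#' them), and the two ratios are averaged. The block family approximates
#' the true most-segregated permutation; for degenerate compositions (a
#' handful of charges in a short sequence) the ratio can marginally exceed
#' 1 and is truncated, with the `flag` set to `"clamped"`. kappa is 0 for a
#' fully mixed alternating pattern and 1 for a fully charge-segregated one.
#'
#' @param protein a protein sequence of length >= 6 (a terminal `*` is
#'   stripped); charges: D/E = -1, K/R = +1, H = `histidineCharge`.
#' @param histidineCharge charge assigned to histidine (default 0, pH 7).
#' @return A list of class `ChargePatternSummary` with elements `fcr`,
#'   `ncpr`, `kappa`, `flag` (`NA`, `"no_charged_residues"`, `"degenerate"`
#'   or `"clamped"`), and `n`.
#' @examples
#' chargePattern("EEEEEEKKKKKK")$kappa  # 1: already fully segregated
#' @export
chargePattern <- function(protein, histidineCharge = 0) {
  aa <- .asChars(protein)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (length(aa) < 6L) stop("protein must have at least 6 residues")
  bad <- setdiff(unique(aa), names(.KD))
  if (length(bad)) stop("non-canonical amino-acid letter: ",
                        paste(bad, collapse = ", "))
  charges <- .aaCharge(aa, histidineCharge)
  n <- length(charges)
  np <- sum(charges > 0); nm <- sum(charges < 0)
  fcr <- (np + nm) / n
  ncpr <- (np - nm) / n
  flag <- NA_character_
  if (fcr == 0) {
    kappa <- 0
    flag <- "no_charged_residues"
  } else {
    candidates <- .segregatedArrangements(nNeg = nm, nNeu = n - np - nm,
                                          nPos = np)
    ks <- vapply(c(5L, 6L), function(g) {
      dmax <- max(vapply(candidates, .deltaG, 0, blob = g))
      if (dmax == 0) return(NA_real_)
      .deltaG(charges, g) / dmax
    }, 0)
    if (all(is.na(ks))) {
      kappa <- 0
      flag <- "degenerate"
    } else {
      kappa <- mean(ks, na.rm = TRUE)
      ## the block-arrangement delta-max is an approximation; for degenerate
      ## compositions (very few charges in short sequences) the observed
      ## delta can exceed it slightly, so the ratio is truncated at 1
      if (kappa > 1) { kappa <- 1; flag <- "clamped" }
    }
  }
  structure(list(fcr = fcr, ncpr = ncpr, kappa = kappa, flag = flag, n = n),
            class = "ChargePatternSummary")
}

#' @export
print.ChargePatternSummary <- function(x, ...) {
  cat(sprintf("ChargePatternSummary (n = %d): FCR %.4f, NCPR %+.4f, kappa %.4f%s\n",
              x$n, x$fcr, x$ncpr, x$kappa,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

.LIGAND_CLASS <- c(substrate_sugar = "substrate", substrate_lipid = "substrate",
                   product = "product", atp = "nucleotide", gtp = "nucleotide")

#' Score substitutions by proximity to binding sites
#'
#' A substitution sitting exactly on a site residue scores `-1`; at distance
#' `d` with `1 <= d <= window` it scores `-(d + 1)` (so the nucleotide window
#' of 3 spans codes -2 to -4); beyond the window it scores `0`. Substrate
#' sites (sugar and lipid ligands) use `substrateWindow`, energy-nucleotide
#' sites (ATP/GTP) use `nucleotideWindow`, and product sites -- recorded for
#' context only -- use the substrate window but never trigger exclusion.
#' Sequences with a substitution coinciding with a substrate-site residue
#' are flagged excluded as potentially dysfunctional.
#'
#' @param subs substitution table (see [mapSubstitutions()]; multiple
#'   sequences may be row-bound), needing columns `seq_id`, `pos_aa`.
#' @param sites binding-site table (see [readBindingSites()]).
#' @param substrateWindow residue window for substrate sites (default 5).
#' @param nucleotideWindow residue window for energy-nucleotide sites
#'   (default 3).
#' @param proteinLength optional length check for site positions.
#' @return A list with `substitutions` (input plus `code_substrate`,
#'   `code_nucleotide`, `code_product`), `matrix` (rows = `reference` +
#'   sequence ids, columns = site residues; `+1` marks site positions in the
#'   reference row), `excluded` (character ids) and `parameters`.
#' @export
proximityScores <- function(subs, sites, substrateWindow = 5L,
                            nucleotideWindow = 3L, proteinLength = NULL) {
  if (substrateWindow < 0 || nucleotideWindow < 0)
    stop("windows must be non-negative")
  if (!all(c("seq_id", "pos_aa") %in% names(subs)))
    stop("subs needs columns seq_id and pos_aa")
  if (!is.null(proteinLength) && any(sites$pos > proteinLength | sites$pos < 1))
    stop("binding-site position outside protein length")
  sites$pos <- as.integer(sites$pos)
  subs$pos_aa <- as.integer(subs$pos_aa)
  substrateWindow <- as.integer(substrateWindow)
  nucleotideWindow <- as.integer(nucleotideWindow)
  sites$class <- unname(.LIGAND_CLASS[sites$ligand])
  winOf <- c(substrate = substrateWindow, nucleotide = nucleotideWindow,
             product = substrateWindow)

  codeFor <- function(pos, sitePos, window) {
    if (!length(sitePos)) return(0L)
    d <- min(abs(pos - sitePos))
    if (d == 0L) -1L else if (d <= window) -(d + 1L) else 0L
  }
  for (cls in c("substrate", "nucleotide", "product")) {
    sp <- sites$pos[sites$class == cls]
    subs[[paste0("code_", cls)]] <-
      vapply(subs$pos_aa, codeFor, 0L, sitePos = sp, window = winOf[[cls]])
  }
  excluded <- sort(unique(subs$seq_id[subs$code_substrate == -1L]))

  sitePos <- sort(unique(sites$pos))
  siteWin <- vapply(sitePos, function(p)
    max(winOf[sites$class[sites$pos == p]]), integer(1))
  ids <- unique(subs$seq_id)
  m <- matrix(0L, nrow = length(ids) + 1L, ncol = length(sitePos),
              dimnames = list(c("reference", ids), paste0("p", sitePos)))
  m[1L, ] <- 1L
  for (i in seq_along(ids)) {
    sp <- subs$pos_aa[subs$seq_id == ids[i]]
    for (j in seq_along(sitePos))
      m[i + 1L, j] <- codeFor(sitePos[j], sp, siteWin[j])
  }
  list(substitutions = subs, matrix = m, excluded = excluded,
       parameters = list(substrate_window = substrateWindow,
                         nucleotide_window = nucleotideWindow))
}

#' Rank candidate sequences for the next mining cycle
#'
#' Deterministic ranking: non-excluded sequences first, then by number of
#' substitutions adjacent to a binding site (descending), hotspot overlap
#' (descending), identity to the reference (ascending, favouring diversity),
#' and finally id for a stable tie-break. Each sequence is labelled by the
#' regions its mutations fall in (`active_domain`/`envelope`/`other`,
#' joined by `+`).
#'
#' @param profiles non-empty list of [MutationProfile-class] objects.
#' @param proximity optional output of [proximityScores()].
#' @param hotspots optional output of [findHotspots()].
#' @return `data.frame` ranked best-first with columns `seq_id`, `excluded`,
#'   `adjacent_sites`, `hotspot_overlap`, `identity_percent`,
#'   `region_group`, `rank`.
#' @export
selectCandidates <- function(profiles, proximity = NULL, hotspots = NULL) {
  if (length(profiles) == 0L) stop("no profiles to rank")
  hsKey <- if (!is.null(hotspots) && nrow(hotspots))
    paste(hotspots$pos_nt, hotspots$alt_base) else character()
  rows <- lapply(profiles, function(p) {
    m <- mutations(p)
    regs <- sort(unique(m$region))
    adj <- 0L
    excl <- FALSE
    if (!is.null(proximity)) {
      s <- proximity$substitutions
      s <- s[s$seq_id == p@seqId, , drop = FALSE]
      adj <- sum(s$code_substrate < -1L | s$code_nucleotide < -1L)
      excl <- p@seqId %in% proximity$excluded
    }
    data.frame(seq_id = p@seqId, excluded = excl, adjacent_sites = adj,
               hotspot_overlap = sum(paste(m$pos_nt, m$alt_base) %in% hsKey),
               identity_percent = identityPercent(p),
               region_group = if (length(regs)) paste(regs, collapse = "+") else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$excluded, -out$adjacent_sites, -out$hotspot_overlap,
                   out$identity_percent, out$seq_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
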