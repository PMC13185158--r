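## Data-cleansing rules applied to a repository before mining: strict
## similarity thresholds (> hi removed as too similar, < lo as too
## dissimilar; boundary values kept), premature-stop removal, then exact
## duplicate removal at the nucleotide and translated-protein levels.
## Rules are applied in that order; the first matching rule is recorded.
## The reference itself is never a member, so it is never removed.

#' Filter a variant repository
#'
#' @param repo a nucleotide [SeqRepository-class].
#' @param hi upper identity fraction; members with identity strictly above
#'   `100 * hi` percent are removed as `too_similar` (default 0.99).
#' @param lo lower identity fraction; members strictly below `100 * lo`
#'   are removed as `too_dissimilar` (default 0.75).
#' @param profiles optional pre-computed list of [MutationProfile-class]
#'   objects named by member id (avoids re-profiling).
#' @param ... alignment parameters forwarded to [callMutations()] for
#'   unequal-length members.
#'
#' @return A list with `repository` (the filtered [SeqRepository-class]) and
#'   `report`, a `data.frame` with columns `id` and `rule` covering every
#'   input member; `rule` is `"kept"` or one of `too_similar`,
#'   `too_dissimilar`, `premature_stop`, `duplicate_nt`, `duplicate_protein`.
#'
#' @details Protein-level duplicates are detected on the translation up to
#'   the first stop codon, since downstream analysis is protein level.
#'   Members whose length is not a multiple of 3 cannot be screened for
#'   premature stops and fall through to the duplicate rules. Filtering is
#'   idempotent: a second pass removes nothing.
#' @export
filterRepository <- function(repo, hi = 0.99, lo = 0.75, profiles = NULL, ...) {
  stopifnot(is(repo, "SeqRepository"))
  if (seqKind(repo) != "nucleotide") stop("repository must be nucleotide")
  if (hi <= lo) stop("hi must be greater than lo")
  ref <- reference(repo)
  mem <- members(repo)
  ids <- names(mem)
  rule <- setNames(rep("kept", length(mem)), ids)

  seenNt <- as.character(ref)
  refProt <- .proteinKey(as.character(ref))
  seenProt <- refProt

  for (i in seq_along(mem)) {
    s <- as.character(mem[[i]])
    idn <- ids[i]
    ident <- if (!is.null(profiles) && !is.null(profiles[[idn]])) {
      identityPercent(profiles[[idn]])
    } else if (nchar(s) == nchar(as.character(ref[[1]]))) {
      a <- .asChars(ref[[1]]); b <- .asChars(s)
      100 * sum(a == b) / length(a)
    } else {
      identityPercent(callMutations(setNames(as.character(ref), names(ref)),
                                    setNames(s, idn), ...))
    }
    if (ident > 100 * hi) { rule[i] <- "too_similar"; next }
    if (ident < 100 * lo) { rule[i] <- "too_dissimilar"; next }
    if (nchar(s) %% 3L == 0L && length(prematureStops(s)) > 0L) {
      rule[i] <- "premature_stop"; next
    }
    if (s %in% seenNt) { rule[i] <- "duplicate_nt"; next }
    pk <- if (nchar(s) %% 3L == 0L) .proteinKey(s) else NA_character_
    if (!is.na(pk) && pk %in% seenProt) { rule[i] <- "duplicate_protein"; next }
    seenNt <- c(seenNt, s)
    if (!is.na(pk)) seenProt <- c(seenProt, pk)
  }

  keep <- rule == "kept"
  kept <- new("SeqRepository",
              reference = ref, members = mem[keep], kind = repo@kind,
              meta = repo@meta[keep, , drop = FALSE])
  list(repository = kept,
       report = data.frame(id = ids, rule = unname(rule),
                           stringsAsFactors = FALSE))
}

## translation up to (excluding) the first stop
.proteinKey <- function(s) {
  aa <- .translateChars(.asChars(s))
  stop1 <- which(aa == "*")
  if (length(stop1)) aa <- aa[seq_len(stop1[1] - 1L)]
  paste(aa, collapse = "")
}
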