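## Repository construction and FASTA IO. All parsing is delegated to
## Biostrings; validation on top enforces the strict repository alphabet
## ({A,C,G,T,N} / 20 canonical aa + "*"), id uniqueness and case handling.

#' Build a variant repository
#'
#' @param reference the reference sequence: a named character of length 1 or
#'   a length-1 `XStringSet`.
#' @param members member sequences: a named character vector or `XStringSet`
#'   (may be empty).
#' @param kind `"nucleotide"` or `"protein"`.
#' @param source free-text provenance recorded per member (recycled).
#' @param cycle non-negative mining-cycle index per member (recycled).
#'
#' @return A [SeqRepository-class] object.
#' @examples
#' repo <- SeqRepository(c(ref = "ATGGCGTAA"), c(v1 = "ATGGTGTAA"),
#'                       kind = "nucleotide")
#' repo
#' @export
SeqRepository <- function(reference, members = character(), kind = c("nucleotide", "protein"),
                          source = "unknown", cycle = 0L) {
  kind <- match.arg(kind)
  as_set <- function(x) {
    if (is(x, "XStringSet")) {
      x <- setNames(toupper(as.character(x)), names(x))
    } else {
      x <- setNames(toupper(as.character(x)), names(x))
    }
    if (kind == "nucleotide") DNAStringSet(x) else AAStringSet(x)
  }
  ref <- as_set(reference)
  mem <- as_set(members)
  if (is.null(names(ref)) || !nzchar(names(ref)[1]))
    stop("reference must be named")
  meta <- data.frame(
    id = if (length(mem)) names(mem) else character(),
    source = if (length(mem)) rep_len(as.character(source), length(mem)) else character(),
    cycle = if (length(mem)) rep_len(as.integer(cycle), length(mem)) else integer(),
    stringsAsFactors = FALSE
  )
  if (any(meta$cycle < 0L)) stop("cycle indices must be non-negative")
  new("SeqRepository", reference = ref, members = mem, kind = kind, meta = meta)
}

#' Read FASTA sequences into repository members
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file, uppercases the
#' sequences, uses the header token before the first whitespace as the id and
#' validates the strict repository alphabet.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @param kind `"nucleotide"` or `"protein"`.
#' @param source,cycle provenance recorded on the returned records.
#'
#' @return A named [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] in
#'   input order, carrying `source`/`cycle` metadata columns.
#'
#' @details Errors on an empty file, on a duplicate id (naming it) and on any
#'   character outside the allowed alphabet (reporting its position).
#' @export
readFastaRepository <- function(path, kind = c("nucleotide", "protein"),
                                source = "file", cycle = 0L) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- tryCatch(readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id in FASTA: '", dup[1], "'")
  seqs <- setNames(toupper(as.character(raw)), ids)
  allowed <- if (kind == "nucleotide") .NUC_ALPHABET else .PROT_ALPHABET
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for id '", ids[i], "'")
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad))
      stop(sprintf("illegal %s character '%s' at position %d in '%s'",
                   kind, chars[bad[1]], bad[1], ids[i]))
  }
  out <- if (kind == "nucleotide") DNAStringSet(seqs) else AAStringSet(seqs)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source = rep_len(as.character(source), length(out)),
    cycle = rep_len(as.integer(cycle), length(out)))
  out
}

#' Write repository sequences as wrapped FASTA
#'
#' @param records a named `XStringSet`, a named character vector, or a
#'   [SeqRepository-class] (reference written first).
#' @param path output file path.
#' @param lineWidth positive line width; default 60, the per-line convention
#'   used throughout the mutation reports.
#'
#' @return `path`, invisibly. `readFastaRepository(writeFastaRepository(x))`
#'   recovers ids and sequences exactly.
#' @export
writeFastaRepository <- function(records, path, lineWidth = 60L) {
  if (!is.numeric(lineWidth) || lineWidth < 1)
    stop("lineWidth must be a positive integer")
  if (is(records, "SeqRepository")) {
    seqs <- c(setNames(as.character(reference(records)), names(reference(records))),
              setNames(as.character(members(records)), names(members(records))))
    records <- if (seqKind(records) == "nucleotide") DNAStringSet(seqs) else AAStringSet(seqs)
  } else if (!is(records, "XStringSet")) {
    records <- BStringSet(setNames(as.character(records), names(records)))
  }
  if (length(records) == 0L) stop("no records to write")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (missing directory): ", dir)
  writeXStringSet(records, filepath = path, width = as.integer(lineWidth))
  invisible(path)
}

#' Translate a CDS with the standard genetic code
#'
#' The first codon is translated literally (no bacterial start-codon special
#' casing: all in-scope comparisons are reference-anchored, so the same rule
#' applies to both sides). Stops are rendered as `*`, including internal ones,
#' which downstream callers flag. Codons containing `N` translate to `X`.
#'
#' @param cds a nucleotide sequence (character, `DNAString`, or
#'   `DNAStringSet`); length must be divisible by 3.
#' @return An `AAString` (or `AAStringSet` for set input).
#' @examples
#' as.character(translateCds("ATGGCGTAA"))  # "MA*"
#' @export
translateCds <- function(cds) {
  if (is(cds, "DNAStringSet")) {
    bad <- which(width(cds) %% 3L != 0L)
    if (length(bad))
      stop(sprintf("CDS length of '%s' not divisible by 3 (remainder %d)",
                   names(cds)[bad[1]], width(cds)[bad[1]] %% 3L))
    return(translate(cds, if.fuzzy.codon = "X"))
  }
  s <- if (is(cds, "DNAString")) cds else DNAString(toupper(as.character(cds)[1]))
  if (length(s) %% 3L != 0L)
    stop(sprintf("CDS length not divisible by 3 (remainder %d)", length(s) %% 3L))
  translate(s, if.fuzzy.codon = "X")
}

## codon -> aa lookup on plain characters; used in the hot paths where
## constructing XString objects per codon would dominate.
.translateChars <- function(bases) {
  ## bases: character vector of single letters, length divisible by 3
  n <- length(bases) %/% 3L
  codons <- paste0(bases[seq(1L, by = 3L, length.out = n)],
                   bases[seq(2L, by = 3L, length.out = n)],
                   bases[seq(3L, by = 3L, length.out = n)])
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # fuzzy codons (contain N)
  aa
}
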