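## Cycle-based mining orchestration: filter -> profile -> hotspot/pattern
## mining -> (protein stages when annotations/binding sites are configured)
## -> candidate selection, with every artifact written as TSV/CSV and every
## parameter logged, so that two runs with the same inputs are byte-identical.

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  path
}

#' Configuration for one mining cycle
#'
#' @param cycleIndex 1-based cycle number.
#' @param depth number of candidate entries carried into the next cycle
#'   (must be positive); the benchmark schedule uses 25 for cycles 1, 2 and
#'   4 and 40 for cycle 3.
#' @param outDir directory for this cycle's artifacts (created).
#' @param hi,lo similarity filter fractions (see [filterRepository()]).
#' @param minShare hotspot support threshold (see [findHotspots()]).
#' @param minSupport,maxGap,maxSpan motif mining parameters
#'   (see [findPatterns()]).
#' @param lineLen report line length in nt.
#' @param regions optional region table for [callMutations()].
#' @param annotations optional protein annotation table; enables the protein
#'   stage.
#' @param bindingSites optional binding-site table; enables proximity
#'   scoring.
#' @param substrateWindow,nucleotideWindow proximity windows
#'   (see [proximityScores()]).
#' @return A list of class `CycleConfig`.
#' @export
cycleConfig <- function(cycleIndex = 1L, depth = 25L, outDir = tempfile("cycle"),
                        hi = 0.99, lo = 0.75, minShare = 4L, minSupport = 5L,
                        maxGap = 4L, maxSpan = 10L, lineLen = 60L,
                        regions = NULL, annotations = NULL,
                        bindingSites = NULL, substrateWindow = 5L,
                        nucleotideWindow = 3L) {
  if (depth < 1L) stop("depth must be positive")
  structure(list(cycleIndex = as.integer(cycleIndex), depth = as.integer(depth),
                 outDir = outDir, hi = hi, lo = lo,
                 minShare = as.integer(minShare),
                 minSupport = as.integer(minSupport),
                 maxGap = as.integer(maxGap), maxSpan = as.integer(maxSpan),
                 lineLen = as.integer(lineLen), regions = regions,
                 annotations = annotations, bindingSites = bindingSites,
                 substrateWindow = as.integer(substrateWindow),
                 nucleotideWindow = as.integer(nucleotideWindow)),
            class = "CycleConfig")
}

#' Run one mining cycle
#'
#' Applies the repository filters, profiles every kept member against the
#' reference, mines hotspots and motifs, runs the protein stages when
#' annotations or binding sites are configured, ranks candidates and writes
#' all artifacts (TSV/CSV plus a JSON parameter log) into `config$outDir`.
#' The top `depth` non-excluded candidates are flagged as next-cycle
#' entries; when fewer survive, all survivors are carried and a warning is
#' logged. A stage failure aborts with the stage name; the partial manifest
#' names the artifacts already written.
#'
#' @param repo a nucleotide [SeqRepository-class].
#' @param config a [cycleConfig()] list.
#' @return A list of class `CycleReport`: `cycle`, `counts`, `filter_report`,
#'   `profiles`, `hotspots`, `patterns`, `candidates`, `carried`,
#'   `warnings`, `manifest`, `outDir`.
#' @export
runCycle <- function(repo, config = cycleConfig()) {
  stopifnot(is(repo, "SeqRepository"))
  if (length(members(repo)) == 0L) stop("repository has no members")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  warnings <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("cycle %d failed at stage '%s': %s (partial manifest: %s)",
                   config$cycleIndex, name, conditionMessage(e),
                   paste(basename(manifest), collapse = ", ")), call. = FALSE))
  }
  out <- function(name) file.path(config$outDir, name)

  flt <- stage("filter", filterRepository(repo, hi = config$hi, lo = config$lo))
  manifest <- c(manifest, .writeTsv(flt$report, out("filter_report.tsv")))
  kept <- flt$repository

  profiles <- stage("profile", {
    ref <- setNames(as.character(reference(kept)), names(reference(kept)))
    lapply(seq_along(members(kept)), function(i)
      callMutations(ref,
                    setNames(as.character(members(kept)[[i]]),
                             names(members(kept))[i]),
                    regions = config$regions, lineLen = config$lineLen))
  })
  names(profiles) <- names(members(kept))
  manifest <- c(manifest, .writeTsv(profileTable(profiles), out("profiles.tsv")))
  summaryDf <- data.frame(
    seq_id = names(profiles),
    identity_percent = vapply(profiles, identityPercent, 0),
    total_mutation_percent = vapply(profiles, function(p) p@totalMutationPercent, 0),
    n_mutations = vapply(profiles, function(p) nrow(mutations(p)), 0L),
    frameshifted = vapply(profiles, function(p) p@frameshifted, TRUE),
    stringsAsFactors = FALSE)
  manifest <- c(manifest, .writeTsv(summaryDf, out("summary.tsv")))
  comp <- stage("composition", composition(members(kept)))
  manifest <- c(manifest, .writeTsv(comp, out("composition.tsv")))

  hotspots <- patterns <- NULL
  if (length(profiles)) {
    hotspots <- stage("hotspots", findHotspots(profiles, minShare = config$minShare))
    patterns <- stage("patterns",
                      findPatterns(profiles, minSupport = config$minSupport,
                                   maxGap = config$maxGap,
                                   maxSpan = config$maxSpan))
    mm <- stage("mismatch_matrix", mismatchMatrix(profiles, lineLen = config$lineLen))
    manifest <- c(manifest, .writeTsv(hotspots, out("hotspots.tsv")))
    manifest <- c(manifest, .writeTsv(patterns, out("patterns.tsv")))
    utils::write.csv(mm, out("mismatch_matrix.csv"), quote = FALSE)
    manifest <- c(manifest, out("mismatch_matrix.csv"))
  }

  proximity <- NULL
  if (!is.null(config$bindingSites) && length(profiles)) {
    proximity <- stage("score-binding", {
      refProt <- translateCds(as.character(reference(kept)[[1]]))
      subsList <- lapply(names(profiles), function(id) {
        s <- as.character(members(kept)[[match(id, names(members(kept)))]])
        if (nchar(s) != width(reference(kept)) || nchar(s) %% 3L != 0L)
          return(NULL)
        mapSubstitutions(as.character(refProt), as.character(translateCds(s)),
                         annotations = config$annotations, seqId = id)
      })
      subs <- do.call(rbind, subsList)
      if (is.null(subs) || !nrow(subs)) NULL else
        proximityScores(subs, config$bindingSites,
                        substrateWindow = config$substrateWindow,
                        nucleotideWindow = config$nucleotideWindow)
    })
    if (!is.null(proximity)) {
      manifest <- c(manifest, .writeTsv(proximity$substitutions,
                                        out("substitutions.tsv")))
      utils::write.csv(proximity$matrix, out("penalty_matrix.csv"), quote = FALSE)
      manifest <- c(manifest, out("penalty_matrix.csv"))
      manifest <- c(manifest, .writeTsv(
        data.frame(seq_id = proximity$excluded, stringsAsFactors = FALSE),
        out("excluded.tsv")))
    }
  }

  candidates <- stage("candidates", {
    if (length(profiles))
      selectCandidates(profiles, proximity = proximity, hotspots = hotspots)
    else data.frame()
  })
  manifest <- c(manifest, .writeTsv(candidates, out("candidates.tsv")))

  eligible <- if (nrow(candidates)) candidates$seq_id[!candidates$excluded] else character()
  if (length(eligible) < config$depth) {
    warnings <- c(warnings, sprintf(
      "depth %d exceeds %d surviving candidates; carrying all survivors",
      config$depth, length(eligible)))
    warning(warnings[length(warnings)], call. = FALSE)
  }
  carried <- head(eligible, config$depth)

  params <- config[c("cycleIndex", "depth", "hi", "lo", "minShare",
                     "minSupport", "maxGap", "maxSpan", "lineLen",
                     "substrateWindow", "nucleotideWindow")]
  params$warnings <- warnings
  jsonlite::write_json(params, out("params.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest <- c(manifest, out("params.json"))

  structure(list(cycle = config$cycleIndex,
                 counts = list(n_in = nrow(flt$report),
                               n_kept = sum(flt$report$rule == "kept"),
                               n_removed = sum(flt$report$rule != "kept")),
                 filter_report = flt$report, profiles = profiles,
                 hotspots = hotspots, patterns = patterns,
                 candidates = candidates, carried = carried,
                 warnings = warnings, manifest = manifest,
                 outDir = config$outDir),
            class = "CycleReport")
}

#' A synthetic per-cycle sequence source
#'
#' Returns a function of the cycle index that emits fresh synthetic variants
#' of the given reference, standing in for the per-cycle database expansion
#' of a live mining run (same control flow, no network). The per-cycle draw
#' is deterministic in `seed`.
#'
#' @param reference reference CDS (named length-1 set or character).
#' @param perCycle variants emitted per cycle.
#' @param seed integer seed; the cycle index is folded in.
#' @param ... forwarded to [generateVariants()].
#' @return `function(cycle)` returning a named character vector.
#' @export
syntheticSequenceSource <- function(reference, perCycle = 60L, seed = 1L, ...) {
  force(reference); force(perCycle); force(seed)
  dots <- list(...)
  function(cycle) {
    args <- c(list(reference = reference, nVariants = perCycle,
                   seed = (seed * 131L + cycle) %% .Machine$integer.max,
                   idPrefix = sprintf("c%d_var", cycle)), dots)
    sim <- do.call(generateVariants, args)
    setNames(as.character(members(sim$repository)),
             names(members(sim$repository)))
  }
}

#' Run a multi-cycle mining pass
#'
#' Runs [runCycle()] for each entry of `depths`, carrying the top `depth`
#' candidates of each cycle into the next and, when a `sequenceSource` is
#' supplied, adding its per-cycle sequences to the repository before mining
#' (cycles after the first).
#'
#' @param repo the starting nucleotide [SeqRepository-class].
#' @param depths integer vector of per-cycle candidate depths
#'   (default `c(25, 25, 40, 25)`).
#' @param outDir root output directory; cycle artifacts go to
#'   `cycle<k>/` subdirectories.
#' @param sequenceSource optional `function(cycle)` returning named new
#'   member sequences (see [syntheticSequenceSource()]).
#' @param ... forwarded to [cycleConfig()] for every cycle.
#' @return A list of `CycleReport`s, invisibly classed `PipelineReport`.
#' @export
runPipeline <- function(repo, depths = c(25L, 25L, 40L, 25L),
                        outDir = tempfile("mining"), sequenceSource = NULL,
                        ...) {
  stopifnot(is(repo, "SeqRepository"))
  reports <- vector("list", length(depths))
  current <- repo
  for (k in seq_along(depths)) {
    if (k > 1L) {
      prev <- reports[[k - 1L]]
      carriedSeqs <- as.character(members(current))[match(prev$carried,
                                                          names(members(current)))]
      names(carriedSeqs) <- prev$carried
      newSeqs <- if (!is.null(sequenceSource)) sequenceSource(k) else character()
      current <- SeqRepository(
        setNames(as.character(reference(repo)), names(reference(repo))),
        c(carriedSeqs, newSeqs), kind = "nucleotide",
        source = "pipeline", cycle = k)
    }
    cfg <- cycleConfig(cycleIndex = k, depth = depths[k],
                       outDir = file.path(outDir, sprintf("cycle%d", k)), ...)
    reports[[k]] <- runCycle(current, cfg)
  }
  structure(reports, class = "PipelineReport")
}
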