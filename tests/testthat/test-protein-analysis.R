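toyAnnotations <- function() {
  data.frame(
    category = c("domain", "domain", "helix", "sheet", "turn", "loop"),
    label = c("A", "B", "h1", "b1", "t1", "l1"),
    start = c(1L, 41L, 18L, 30L, 50L, 48L),
    end = c(40L, 80L, 25L, 36L, 55L, 60L),
    stringsAsFactors = FALSE)
}

mkProt <- function(len = 80L) {
  set.seed(3)
  paste(sample(names(rhlBminer:::.KD), len, replace = TRUE), collapse = "")
}

test_that("substitutions map onto elements with the stated precedence", {
  ref <- mkProt()
  rv <- strsplit(ref, "")[[1]]
  sub_at <- function(pos, alt) {
    vv <- rv; vv[pos] <- alt
    paste(vv, collapse = "")
  }
  ann <- toyAnnotations()
  # position 21 inside helix h1
  alt21 <- setdiff(c("V", "A"), rv[21])[1]
  subs <- mapSubstitutions(ref, sub_at(21L, alt21), ann, seqId = "v")
  expect_equal(nrow(subs), 1L)
  expect_equal(subs$element, "h1")
  expect_equal(subs$domain, "A")
  # position 52 is in both turn t1 and loop l1: turn wins
  alt52 <- setdiff(c("G", "A"), rv[52])[1]
  expect_equal(mapSubstitutions(ref, sub_at(52L, alt52), ann)$element, "t1")
  # position with no interval -> primary
  alt70 <- setdiff(c("M", "L"), rv[70])[1]
  expect_equal(mapSubstitutions(ref, sub_at(70L, alt70), ann)$element, "primary")
  # identical proteins -> empty table
  expect_equal(nrow(mapSubstitutions(ref, ref, ann)), 0L)
  expect_error(mapSubstitutions(ref, substr(ref, 1, 40)), "length")
  expect_error(mapSubstitutions("", ""), "empty")
})

test_that("property deltas follow Kyte-Doolittle and pH-7 charge classes", {
  pr <- propertyDelta("P", "R")
  expect_equal(pr$polarity_change, c("nonpolar", "basic"))
  expect_equal(pr$charge_delta, 1)
  lq <- propertyDelta("L", "Q")
  expect_equal(lq$polarity_change, c("nonpolar", "polar"))
  expect_equal(lq$charge_delta, 0)
  expect_equal(propertyDelta("I", "V")$hydropathy_delta, -0.3)
  expect_equal(propertyDelta("E", "K")$charge_delta, 2)
  expect_error(propertyDelta("B", "A"), "non-canonical")
})

test_that("charge patterning matches the limiting cases", {
  seg <- chargePattern("EEEEEEKKKKKK")
  expect_equal(seg$kappa, 1)
  expect_equal(seg$fcr, 1)
  expect_equal(seg$ncpr, 0)
  mixed <- chargePattern("EKEKEKEKEKEK")
  expect_lt(mixed$kappa, 0.02)
  flat <- chargePattern("AAAAAAAA")
  expect_equal(flat$kappa, 0)
  expect_equal(flat$flag, "no_charged_residues")
  expect_error(chargePattern("EKEKE"), "at least 6")
})

test_that("kappa is in [0,1] and invariant under reversal and charge swap", {
  set.seed(41)
  for (rep in 1:200) {
    s <- randomProtein(sample(10:60, 1))
    cp <- chargePattern(s)
    expect_gte(cp$kappa, 0); expect_lte(cp$kappa, 1)
    expect_lte(abs(cp$ncpr), cp$fcr)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(chargePattern(rev_s)$kappa, cp$kappa, tolerance = 1e-12)
    swapped <- chartr("DEKR", "KRDE", s)
    expect_equal(chargePattern(swapped)$kappa, cp$kappa, tolerance = 1e-12)
  }
})

test_that("kappa agrees with an independent direct transcription", {
  set.seed(43)
  for (rep in 1:20) {
    s <- randomProtein(sample(12:50, 1))
    expect_equal(chargePattern(s)$kappa, bruteKappa(s), tolerance = 1e-6)
  }
})

test_that("proximity codes follow the -1 / -(d+1) / 0 scheme", {
  sites <- data.frame(
    pos = c(260L, 100L),
    ligand = c("substrate_sugar", "atp"),
    source = "docking", stringsAsFactors = FALSE)
  subs <- data.frame(
    seq_id = c("hit", "near", "nuc", "far"),
    pos_aa = c(260L, 263L, 103L, 270L),
    stringsAsFactors = FALSE)
  px <- proximityScores(subs, sites)
  s <- px$substitutions
  expect_equal(s$code_substrate[s$seq_id == "hit"], -1L)
  expect_equal(px$excluded, "hit")  # on-site substrate hit -> dysfunctional
  expect_equal(s$code_substrate[s$seq_id == "near"], -4L)  # distance 3
  expect_equal(s$code_nucleotide[s$seq_id == "nuc"], -4L)  # distance 3, window 3
  expect_equal(s$code_substrate[s$seq_id == "far"], 0L)    # outside window 5
  # nucleotide-site on-site hits never trigger exclusion
  px2 <- proximityScores(data.frame(seq_id = "x", pos_aa = 100L), sites)
  expect_equal(px2$excluded, character(0))
  expect_error(proximityScores(subs, sites, substrateWindow = -1), "non-negative")
})

test_that("proximity codes reproduce brute-force minimum distances", {
  set.seed(47)
  sites <- data.frame(
    pos = sample(1:400, 12),
    ligand = sample(c("substrate_sugar", "substrate_lipid", "atp", "gtp",
                      "product"), 12, replace = TRUE),
    source = "docking", stringsAsFactors = FALSE)
  subs <- data.frame(seq_id = paste0("s", rep(1:6, each = 8)),
                     pos_aa = sample(1:400, 48, replace = TRUE),
                     stringsAsFactors = FALSE)
  px <- proximityScores(subs, sites, substrateWindow = 5L, nucleotideWindow = 3L)
  s <- px$substitutions
  cls <- c(substrate_sugar = "substrate", substrate_lipid = "substrate",
           product = "product", atp = "nucleotide", gtp = "nucleotide")
  for (k in seq_len(nrow(s))) {
    expect_identical(s$code_substrate[k],
      bruteProximityCode(s$pos_aa[k], sites$pos[cls[sites$ligand] == "substrate"], 5L))
    expect_identical(s$code_nucleotide[k],
      bruteProximityCode(s$pos_aa[k], sites$pos[cls[sites$ligand] == "nucleotide"], 3L))
  }
  # excluded set is exactly the on-substrate-site sequences
  onSite <- unique(s$seq_id[s$pos_aa %in% sites$pos[cls[sites$ligand] == "substrate"]])
  expect_setequal(px$excluded, onSite)
  # matrix layout: +1 marks site positions in the reference row
  expect_true(all(px$matrix["reference", ] == 1L))
})

test_that("candidate ranking places adjacent-coded sequences first, stably", {
  set.seed(53)
  ref <- randomCds(60L)
  rv <- strsplit(ref, "")[[1]]
  mkvar <- function(pos, id) {
    qv <- rv
    for (p in pos) qv[p] <- setdiff(c("A", "C", "G", "T"), rv[p])[1]
    profileOf(ref, paste(qv, collapse = ""), id = id)
  }
  profiles <- list(mkvar(c(10L, 50L), "alpha"), mkvar(c(10L, 50L), "beta"),
                   mkvar(100L, "excl"), mkvar(130L, "adj"))
  prox <- list(
    substitutions = data.frame(
      seq_id = c("excl", "adj"), pos_aa = c(34L, 44L),
      code_substrate = c(-1L, -3L), code_nucleotide = c(0L, 0L),
      code_product = c(0L, 0L), stringsAsFactors = FALSE),
    excluded = "excl")
  ranked <- selectCandidates(profiles, proximity = prox)
  expect_equal(ranked$seq_id[1], "adj")          # adjacent-coded first
  expect_equal(ranked$seq_id[nrow(ranked)], "excl")  # excluded last
  # ties broken by id
  tied <- ranked[ranked$seq_id %in% c("alpha", "beta"), "seq_id"]
  expect_equal(tied, c("alpha", "beta"))
  expect_error(selectCandidates(list()), "no profiles")
})

test_that("packaged fixtures parse and carry the transcribed residue sets", {
  sites <- rhlbBindingSites()
  expect_true(all(c(9, 10, 13, 231, 259, 260, 306, 309, 324, 325, 346, 347) %in%
                  sites$pos[sites$ligand == "substrate_sugar"]))
  expect_true(all(c(228, 229, 231, 233) %in%
                  sites$pos[sites$ligand == "substrate_lipid"]))
  expect_true(all(c(10, 13, 260, 306, 346, 347) %in%
                  sites$pos[sites$ligand == "atp"]))
  ann <- rhlbAnnotations()
  expect_true(all(c("domain", "helix", "loop", "turn") %in% ann$category))
  expect_true(all(ann$start <= ann$end) && all(ann$end <= 426))
})
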