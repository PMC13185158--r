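# toy profile builder: plants the given (pos, alt) changes on a shared
# reference and profiles the result
plantProfile <- function(ref, changes, id) {
  qv <- strsplit(ref, "")[[1]]
  for (k in seq_len(nrow(changes))) qv[changes$pos[k]] <- changes$alt[k]
  profileOf(ref, paste(qv, collapse = ""), id = id)
}

test_that("hotspot thresholding keys on (pos, alt) and is inclusive", {
  set.seed(5)
  ref <- randomCds(60L)  # 180 nt
  rv <- strsplit(ref, "")[[1]]
  alt120 <- setdiff(c("A", "C", "G", "T"), rv[120])[1]
  alt7 <- setdiff(c("A", "C", "G", "T"), rv[7])[1]
  profiles <- c(
    lapply(1:5, function(i) plantProfile(ref, data.frame(pos = 120L, alt = alt120),
                                         paste0("s", i))),
    lapply(6:8, function(i) plantProfile(ref, data.frame(pos = 7L, alt = alt7),
                                         paste0("s", i))))
  hs <- findHotspots(profiles, minShare = 4L)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$pos_nt, 120L)
  expect_equal(hs$alt_base, alt120)
  expect_equal(hs$support, 5L)
  # >= is inclusive: a change shared by exactly 4 sequences qualifies
  hs4 <- findHotspots(profiles[1:4], minShare = 4L)
  expect_equal(hs4$support, 4L)
  # same position, different alt bases in 2+2 sequences: no hotspot
  alts <- setdiff(c("A", "C", "G", "T"), rv[60])[1:2]
  prof22 <- c(
    lapply(1:2, function(i) plantProfile(ref, data.frame(pos = 60L, alt = alts[1]),
                                         paste0("t", i))),
    lapply(3:4, function(i) plantProfile(ref, data.frame(pos = 60L, alt = alts[2]),
                                         paste0("t", i))))
  expect_equal(nrow(findHotspots(prof22, minShare = 4L)), 0L)
  expect_error(findHotspots(list()), "empty")
})

test_that("hotspots equal brute-force dictionary counting on random inputs", {
  set.seed(17)
  ref <- randomCds(80L)
  rv <- strsplit(ref, "")[[1]]
  for (rep in 1:5) {
    profiles <- lapply(1:12, function(i) {
      pos <- sample(4:237, sample(3:8, 1))
      alt <- vapply(pos, function(p)
        sample(setdiff(c("A", "C", "G", "T"), rv[p]), 1), "")
      plantProfile(ref, data.frame(pos = pos, alt = alt), paste0("r", i))
    })
    for (th in c(2L, 3L, 4L)) {
      got <- findHotspots(profiles, minShare = th)
      want <- bruteHotspots(profiles, th)
      expect_equal(got$pos_nt, want$pos_nt)
      expect_equal(got$alt_base, want$alt_base)
      expect_equal(got$support, want$support)
    }
    # monotonicity: lowering the threshold never removes a reported item
    k4 <- findHotspots(profiles, minShare = 4L)
    k3 <- findHotspots(profiles, minShare = 3L)
    expect_true(all(paste(k4$pos_nt, k4$alt_base) %in%
                    paste(k3$pos_nt, k3$alt_base)))
  }
})

test_that("motif mining reports planted motifs with correct support and shape", {
  set.seed(23)
  ref <- randomCds(60L)
  rv <- strsplit(ref, "")[[1]]
  # pick a start where offsets 0 and 2 can both become G
  st <- which(rv != "G" & c(rv[-(1:2)], "G", "G") != "G")[5]
  mk <- function(i) plantProfile(ref, data.frame(pos = c(st, st + 2L),
                                                 alt = c("G", "G")),
                                 paste0("g", i))
  pats5 <- findPatterns(lapply(1:5, mk), minSupport = 5L)
  expect_equal(nrow(pats5), 1L)
  expect_equal(pats5$offsets, "0,2")
  expect_equal(pats5$alt_bases, "GG")
  expect_equal(pats5$shape, "separated")
  expect_equal(pats5$support_any_site, 5L)
  expect_equal(pats5$support_same_site, 5L)
  # four carriers stay below the default "> 4 sequences" threshold
  expect_equal(nrow(findPatterns(lapply(1:4, mk), minSupport = 5L)), 0L)
  # a single isolated mutation is never part of a motif (length >= 2)
  lone <- plantProfile(ref, data.frame(pos = st, alt = "G"), "lone")
  patsAll <- findPatterns(c(lapply(1:5, mk), list(lone)), minSupport = 1L)
  expect_true(all(lengths(strsplit(patsAll$offsets, ",")) >= 2L))
  expect_error(findPatterns(list()), "empty")
  expect_error(findPatterns(lapply(1:5, mk), maxGap = 0L), "maxGap")
})

test_that("every reported motif occurrence can be relocated by scanning", {
  set.seed(29)
  ref <- randomCds(100L)
  rv <- strsplit(ref, "")[[1]]
  vars <- lapply(1:10, function(i) {
    pos <- sort(sample(4:297, 10))
    alt <- vapply(pos, function(p)
      sample(setdiff(c("A", "C", "G", "T"), rv[p]), 1), "")
    qv <- rv; qv[pos] <- alt
    setNames(paste(qv, collapse = ""), paste0("v", i))
  })
  profiles <- lapply(vars, function(v) profileOf(ref, v, id = names(v)))
  pats <- findPatterns(profiles, minSupport = 2L)
  for (k in seq_len(nrow(pats))) {
    offs <- as.integer(strsplit(pats$offsets[k], ",")[[1]])
    alts <- strsplit(pats$alt_bases[k], "")[[1]]
    found <- 0L
    for (v in vars) {
      vv <- strsplit(v, "")[[1]]
      for (s in seq_len(length(vv) - max(offs))) {
        if (all(vv[s + offs] == alts) && all(rv[s + offs] != alts)) {
          found <- found + 1L
          break
        }
      }
    }
    expect_gte(found, pats$support_any_site[k])
  }
})

test_that("mismatch matrix rows sum to total mutation counts", {
  set.seed(31)
  ref <- randomCds(50L)  # 150 nt -> 3 lines
  rv <- strsplit(ref, "")[[1]]
  profiles <- lapply(1:6, function(i) {
    pos <- sample(4:147, sample(0:9, 1))
    alt <- vapply(pos, function(p)
      sample(setdiff(c("A", "C", "G", "T"), rv[p]), 1), "")
    plantProfile(ref, data.frame(pos = pos, alt = alt), paste0("m", i))
  })
  mm <- mismatchMatrix(profiles)
  expect_equal(dim(mm), c(6L, 3L))
  expect_equal(unname(rowSums(mm)),
               vapply(profiles, function(p) nrow(mutations(p)), 0L))
  # single sequence, 3 mutations in line 2
  p <- plantProfile(ref, data.frame(pos = c(61L, 75L, 100L),
                                    alt = vapply(c(61L, 75L, 100L), function(i)
                                      setdiff(c("A", "C", "G", "T"), rv[i])[1], "")),
                    "one")
  expect_equal(unname(mismatchMatrix(list(p))[1, ]), c(0L, 3L, 0L))
  # empty profile list with a known reference length: all-zero matrix
  mm0 <- mismatchMatrix(list(), refLength = 150L)
  expect_equal(dim(mm0), c(0L, 3L))
})
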