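test_that("composition returns exact counts and GC percentages", {
  cs <- composition("ATGC")
  expect_equal(unlist(cs[c("a", "c", "g", "t")]), c(a = 1L, c = 1L, g = 1L, t = 1L))
  expect_equal(cs$gc_percent, 50)
  expect_equal(composition("GGCC")$gc_percent, 100)
  expect_equal(cs$gc_percent + cs$at_percent, 100)
  expect_error(composition("NNN"), "informative")
})

test_that("generated references hit the GC target (generator round-trip)", {
  ref <- generateReference(lengthNt = 1278L, gcTarget = 0.679, seed = 21)
  expect_lt(abs(composition(ref[[1]])$gc_percent - 67.9), 1.0)
})

test_that("single-substitution calls match the worked examples", {
  p <- profileOf("ATGGCGCTG", "ATGGTGCTG")
  m <- mutations(p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos_nt, 5L)
  expect_equal(m$ref_base, "C"); expect_equal(m$alt_base, "T")
  expect_equal(m$change_class, "transition")
  expect_equal(m$codon_index, 2L)
  expect_equal(m$effect, "missense")
  expect_equal(m$ref_aa, "A"); expect_equal(m$alt_aa, "V")

  m2 <- mutations(profileOf("ATGCTGTAA", "ATGCTCTAA"))
  expect_equal(m2$pos_nt, 6L)
  expect_equal(m2$change_class, "transversion")
  expect_equal(m2$effect, "silent")

  p3 <- profileOf("ATGCTGTAA", "ATGCTGTAA")
  expect_equal(nrow(mutations(p3)), 0L)
  expect_equal(identityPercent(p3), 100)
})

test_that("nonsense and N-ambiguous calls are classified correctly", {
  m <- mutations(profileOf("ATGGAGTAA", "ATGTAGTAA"))
  expect_equal(m$effect, "nonsense")
  m2 <- mutations(profileOf("ATGGAGTAA", "ATGNAGTAA"))
  expect_equal(m2$change_class, "ambiguous")
  expect_equal(m2$effect, "ambiguous")
})

test_that("equal-length calls equal a position-by-position brute force", {
  set.seed(7)
  for (rep in 1:20) {
    ref <- randomCds(30L)
    rv <- strsplit(ref, "")[[1]]
    qv <- rv
    idx <- sample(4:(length(rv) - 3L), 8)
    for (i in idx) qv[i] <- sample(setdiff(c("A", "C", "G", "T"), rv[i]), 1)
    m <- mutations(profileOf(ref, paste(qv, collapse = "")))
    brute <- which(rv != qv)
    expect_equal(m$pos_nt, brute)
    expect_equal(m$ref_base, rv[brute])
    expect_equal(m$alt_base, qv[brute])
    # transition/transversion agrees with the exhaustive 12-pair lookup
    expect_equal(m$change_class,
                 unname(TITV_ORACLE[paste0(rv[brute], ">", qv[brute])]))
  }
})

test_that("effect classes are conserved: silent+missense+nonsense+ambiguous = total", {
  set.seed(11)
  for (rep in 1:10) {
    ref <- randomCds(40L)
    rv <- strsplit(ref, "")[[1]]
    qv <- rv
    for (i in sample(seq_along(rv), 12)) {
      qv[i] <- sample(setdiff(c("A", "C", "G", "T", "N"), rv[i]), 1)
    }
    m <- mutations(profileOf(ref, paste(qv, collapse = "")))
    expect_equal(sum(m$effect %in% c("silent", "missense", "nonsense", "ambiguous")),
                 nrow(m))
  }
})

test_that("unequal lengths are aligned; frame-breaking gaps flag ambiguity", {
  ref <- "ATGGCGCTGAAA"
  # 3-nt (in-frame) deletion: downstream effects still computable
  p <- callMutations(c(ref = ref), c(q = "ATGGCGAAA"))
  expect_false(p@frameshifted)
  # 1-nt deletion breaks the frame
  p2 <- callMutations(c(ref = ref), c(q = "ATGGCGCTGAA"))
  expect_true(p2@frameshifted)
  m2 <- mutations(p2)
  if (nrow(m2)) expect_true(all(m2$effect == "ambiguous"))
  expect_error(callMutations(c(ref = ref), c(q = "")), "empty")
})

test_that("premature stop detection matches the codon-index examples", {
  expect_equal(prematureStops("ATGTAAGCGTGA"), 2L)
  expect_equal(prematureStops("ATGGCGTGA"), integer())
  expect_equal(prematureStops("ATGTAGTAATGA"), c(2L, 3L))
  expect_error(prematureStops("ATGT"), "remainder")
})

test_that("per-line rates use true line lengths", {
  ref <- randomCds(26L)  # 78 nt: one full 60-line plus an 18-nt line
  rv <- strsplit(ref, "")[[1]]
  qv <- rv
  for (i in c(5L, 20L, 41L)) qv[i] <- setdiff(c("A", "C", "G", "T"), rv[i])[1]
  p <- profileOf(ref, paste(qv, collapse = ""))
  expect_equal(perLineRates(p)[1], 5.0)
  # one mutation in the terminal 18-nt line
  qv <- rv; qv[70L] <- setdiff(c("A", "C", "G", "T"), rv[70L])[1]
  p2 <- profileOf(ref, paste(qv, collapse = ""))
  expect_equal(perLineRates(p2), c(0, 100 / 18), tolerance = 1e-12)
  expect_equal(perLineRates(profileOf(ref, ref)), c(0, 0))
  expect_error(perLineRates(p, lineLen = 0), "positive")
})

test_that("region assignment prefers active domains over envelopes", {
  regions <- regionTable(data.frame(name = "A", start = 31L, end = 45L),
                         refLength = 90L, envelopeWidth = 6L)
  expect_setequal(regions$class[regions$name == "A"], "active_domain")
  ref <- randomCds(30L)
  rv <- strsplit(ref, "")[[1]]
  qv <- rv
  for (i in c(10L, 28L, 35L)) qv[i] <- setdiff(c("A", "C", "G", "T"), rv[i])[1]
  m <- mutations(profileOf(ref, paste(qv, collapse = ""), regions = regions))
  expect_equal(m$region[m$pos_nt == 10L], "other")
  expect_equal(m$region[m$pos_nt == 28L], "envelope")
  expect_equal(m$region[m$pos_nt == 35L], "active_domain")
})
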