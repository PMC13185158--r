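test_that("reference generation is deterministic and honours the contract", {
  r1 <- generateReference(lengthNt = 1281L, gcTarget = 0.679, seed = 7)
  r2 <- generateReference(lengthNt = 1281L, gcTarget = 0.679, seed = 7)
  expect_identical(as.character(r1), as.character(r2))
  s <- as.character(r1[[1]])
  expect_equal(substr(s, 1, 3), "ATG")
  expect_true(substr(s, 1279, 1281) %in% c("TAA", "TAG", "TGA"))
  expect_equal(prematureStops(s), integer())
  expect_equal(nchar(as.character(translateCds(s))), 427L)  # 426 aa + stop
  gc <- composition(s)$gc_percent
  expect_gte(gc, 67.4); expect_lte(gc, 68.4)
  expect_error(generateReference(lengthNt = 1280L), "multiple of 3")
  expect_error(generateReference(lengthNt = 300L, gcTarget = 0.001),
               "unattainable")
})

test_that("variants carry the exact silent/missense split and round-trip", {
  ref <- generateReference(seed = 7)
  sim <- generateVariants(ref, nVariants = 6L, nMutations = 10L,
                          silentFraction = 0.8, seed = 13)
  refv <- setNames(as.character(ref), names(ref))
  for (id in names(members(sim$repository))) {
    tt <- sim$truth[sim$truth$variant_id == id, ]
    expect_equal(sum(tt$effect == "silent"), 8L)
    expect_equal(sum(tt$effect == "missense"), 2L)
    p <- callMutations(refv,
                       setNames(as.character(members(sim$repository))[[id]], id))
    m <- mutations(p)
    expect_equal(m$pos_nt, sort(tt$pos))
    o <- order(tt$pos)
    expect_equal(m$ref_base, tt$ref[o])
    expect_equal(m$alt_base, tt$alt[o])
    expect_equal(m$effect, tt$effect[o])
    expect_equal(identityPercent(p), 100 * (1 - 10 / 1281), tolerance = 1e-9)
  }
  # zero mutations -> identical to the reference
  sim0 <- generateVariants(ref, nVariants = 1L, nMutations = 0L, seed = 1)
  expect_identical(as.character(members(sim0$repository))[[1]],
                   as.character(ref[[1]]))
  # seed determinism of the whole draw
  simA <- generateVariants(ref, nVariants = 4L, seed = 99)
  simB <- generateVariants(ref, nVariants = 4L, seed = 99)
  expect_identical(as.character(members(simA$repository)),
                   as.character(members(simB$repository)))
  expect_identical(simA$truth, simB$truth)
})

test_that("planted motif templates are recovered by the miner", {
  ref <- generateReference(seed = 19)
  tpl <- list(list(offsets = c(0L, 2L), alt = c("G", "G")))
  sim <- generateVariants(ref, nVariants = 8L, nMutations = 12L,
                          motifTemplates = tpl, motifCarriers = 5L, seed = 23)
  expect_equal(nrow(sim$motifs), 5L)
  refv <- setNames(as.character(ref), names(ref))
  profiles <- lapply(names(members(sim$repository)), function(id)
    callMutations(refv, setNames(as.character(members(sim$repository))[[id]], id)))
  pats <- findPatterns(profiles, minSupport = 5L)
  expect_true(any(pats$offsets == "0,2" & pats$alt_bases == "GG" &
                  pats$support_any_site >= 5L))
})

test_that("stop injection produces filterable variants", {
  ref <- generateReference(seed = 29)
  sim <- generateVariants(ref, nVariants = 5L, nMutations = 20L,
                          stopInjection = 2L, seed = 31)
  seqs <- as.character(members(sim$repository))
  hasStop <- vapply(seqs, function(s) length(prematureStops(s)) > 0, TRUE)
  expect_equal(sum(hasStop), 2L)
  expect_true(all(hasStop[4:5]))
  flt <- filterRepository(sim$repository)
  expect_equal(sort(flt$report$id[flt$report$rule == "premature_stop"]),
               c("var004", "var005"))
})

test_that("infeasible requests fail loudly", {
  tiny <- generateReference(lengthNt = 12L, gcTarget = 0.5, seed = 1)
  expect_error(generateVariants(tiny, nVariants = 1L, nMutations = 10L,
                                silentFraction = 1, seed = 1),
               "could only place")
  expect_error(generateVariants(tiny, nVariants = 1L, nMutations = 2L,
                                baseBias = c(A = 1, C = 1, G = 0, T = 0),
                                seed = 1),
               "sum to 1")
})
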