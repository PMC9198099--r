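test_that("reference generation is seeded and honours GC content", {
  expect_identical(as.character(refSeq(makeReference(250, 0.5, seed = 7))),
                   as.character(refSeq(makeReference(250, 0.5, seed = 7))))
  gc1 <- as.character(refSeq(makeReference(500, gc = 1, seed = 8)))
  expect_true(grepl("^[GC]+$", gc1))
  # default length drawn from the amplicon-size range
  L <- length(refSeq(makeReference(seed = 9)))
  expect_true(L >= 228L && L <= 313L)
  expect_error(makeReference(100, gc = 1.5), "gc")
  expect_error(makeReference(10), ">= 23")
})

test_that("planted guides round-trip through the scanner", {
  proto <- paste0("GATT", "CC", strrep("A", 14))
  ps <- plantGuideSite(makeReference(240, seed = 3), proto, "AGG", 101L,
                       "+")
  g <- scanProtospacers(ps$ref, "NGG")
  hit <- g[start(g) == 101L & as.character(strand(g)) == "+"]
  expect_length(hit, 1L)
  expect_identical(mcols(hit)$protospacer, proto)

  # minus strand plant is found on the minus strand
  psm <- plantGuideSite(makeReference(240, seed = 4), proto, "AGG", 120L,
                        "-")
  gm <- scanProtospacers(psm$ref, "NGG")
  hitm <- gm[start(gm) == 120L & as.character(strand(gm)) == "-"]
  expect_length(hitm, 1L)
  expect_identical(mcols(hitm)$protospacer, proto)

  # the spec's target positions map back to the planted distances
  expect_identical(targetDists(ps$spec), c(15L, 16L))
  expect_identical(targetDists(psm$spec), c(15L, 16L))
  expect_error(plantGuideSite(makeReference(30, seed = 1), proto, "AGG",
                              20L, "+"), "overlaps")
})

test_that("read simulation respects its ground truth", {
  ps <- toy_spec()
  ref <- as.character(amplicon(ps$spec))
  # all-zero truth: every read is the amplicon up to orientation
  sim0 <- simulateReads(ps$spec, simTruth(errorRate = 0, nReads = 50,
                                          seed = 23))
  norm <- vapply(as.character(sim0$reads), function(r)
    if (r == ref) r else revcomp_chr(r), character(1), USE.NAMES = FALSE)
  expect_true(all(norm == ref))
  fwd <- sim0$truth$orientation == "forward"
  expect_identical(unname(as.character(sim0$reads)[fwd] == ref),
                   rep(TRUE, sum(fwd)))

  # indel_rate = 1 labels every read as indel
  sim1 <- simulateReads(ps$spec, simTruth(indelRate = 1, errorRate = 0,
                                          nReads = 40, seed = 29))
  expect_true(all(sim1$truth$indel))

  # sidecar edit labels equal the realized sequences
  sim2 <- simulateReads(ps$spec, simTruth(
    editFractions = c(`15` = 0.5, `16` = 0.3), errorRate = 0,
    nReads = 120, seed = 31))
  p15 <- 101 + 20 - 15
  oriented <- vapply(as.character(sim2$reads), function(r)
    if (substr(r, 1, 30) == substr(ref, 1, 30)) r else revcomp_chr(r),
    character(1), USE.NAMES = FALSE)
  has15 <- substr(oriented, p15, p15) == "T"
  expect_identical(has15, grepl("15", sim2$truth$edited_dists))
  expect_identical(sim2$truth$n_expected_edits,
                   as.integer(has15) +
                     (substr(oriented, 105, 105) == "T"))

  # seeded determinism
  a <- simulateReads(ps$spec, simTruth(editFractions = c(`15` = 0.4),
                                       nReads = 30, seed = 37))
  b <- simulateReads(ps$spec, simTruth(editFractions = c(`15` = 0.4),
                                       nReads = 30, seed = 37))
  expect_identical(as.character(a$reads), as.character(b$reads))
  expect_identical(a$truth, b$truth)
})

test_that("edit-fraction draws follow the binomial at depth", {
  ps <- toy_spec()
  truth <- simTruth(editFractions = c(`15` = 0.5), errorRate = 0,
                    nReads = 6800, seed = 41)
  sim <- simulateReads(ps$spec, truth)
  k <- sum(sim$truth$n_expected_edits)
  se <- sqrt(6800 * 0.5 * 0.5)
  expect_lt(abs(k - 3400), 4 * se)
})

test_that("trace simulation is deterministic and mixture-faithful", {
  ps <- toy_spec()
  wt <- as.character(amplicon(ps$spec))
  # single allele, no noise: exactly one positive channel per position
  tr <- simulateTrace(wt, 1, noise_sd = 0, seed = 1)
  expect_true(all(rowSums(peakHeights(tr) > 0) == 1))
  expect_identical(calledBases(tr), wt)
  # same seed, same trace
  t1 <- simulateTrace(wt, 1, noise_sd = 0.05, seed = 6)
  t2 <- simulateTrace(wt, 1, noise_sd = 0.05, seed = 6)
  expect_identical(peakHeights(t1), peakHeights(t2))
  # 95% edited allele reads out as 95.0 at the target
  ed <- editedAllele(ps$spec)
  tr95 <- simulateTrace(c(wt, ed), c(0.05, 0.95), noise_sd = 0, seed = 2)
  p <- targetPositions(ps$spec)[1]
  expect_equal(editProportion(tr95, p, "C", "T"), 95.0)
  expect_error(simulateTrace(c(wt, ed), c(0.5, 0.6)), "sum to 1")
})
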