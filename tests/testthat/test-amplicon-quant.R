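test_that("FASTQ reading validates records and supports gzip", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "ACGT", "+", "IIII"), f)
  reads <- readFastq(f)
  expect_length(reads, 2L)
  expect_identical(names(reads), c("r1", "r2"))

  # empty file -> empty stream
  f0 <- tempfile(fileext = ".fastq")
  file.create(f0)
  expect_length(readFastq(f0), 0L)

  # quality/sequence length mismatch names the record
  fbad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "ACGTA", "+", "III"), fbad)
  expect_error(readFastq(fbad), "r2")

  # truncated record is reported
  ftr <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), ftr)
  expect_error(readFastq(ftr), "truncated|malformed|record")

  # gzip round trip
  ps <- toy_spec()
  sim <- simulateReads(ps$spec, simTruth(nReads = 25, errorRate = 0,
                                         seed = 5))
  gz <- tempfile(fileext = ".fastq.gz")
  writeFastq(sim$reads, gz)
  back <- readFastq(gz)
  expect_identical(as.character(back), as.character(sim$reads))
})

test_that("classification follows the precedence rules", {
  ps <- toy_spec()   # + guide at 101, targets at distances 15 and 16
  spec <- ps$spec
  ref <- as.character(amplicon(spec))
  p15 <- 101 + 20 - 15  # forward position of the d=15 target C
  p16 <- 101 + 20 - 16
  classify <- function(r) classifyRead(alignRead(r, spec), spec)$category

  expect_identical(classify(ref), "WT")
  expect_identical(classify(mutate_at(ref, p15, "T")),
                   "expected_edit_only")
  both <- mutate_at(mutate_at(ref, p15, "T"), p16, "T")
  expect_identical(classify(both), "expected_edit_only")
  # a non-expected substitution inside the window
  expect_identical(classify(mutate_at(ref, p15, "G")),
                   "other_substitution")
  # expected edit plus a bystander window substitution -> other
  other_pos <- 101 + 20 - 17
  expect_identical(classify(mutate_at(both, other_pos, "G")),
                   "other_substitution")
  # substitutions outside the window are ignored by default ...
  expect_identical(classify(mutate_at(ref, 30, "N")), "WT")
  # ... unless whole-read accounting is requested
  aln <- alignRead(mutate_at(ref, 30, "G"), spec)
  expect_identical(
    classifyRead(aln, spec,
                 alignParams(wholeReadSubstitutions = TRUE))$category,
    "other_substitution")
  # 2-bp deletion inside the spacer beats an expected edit
  del <- paste0(substr(mutate_at(ref, p15, "T"), 1, 110),
                substr(ref, 113, 240))
  expect_identical(classify(del), "indel")
  # insertion strictly inside the spacer
  ins <- paste0(substr(ref, 1, 110), "GG", substr(ref, 111, 240))
  expect_identical(classify(ins), "indel")
  # garbage read -> discarded
  expect_identical(classify(random_dna(240, seed = 63)), "discarded")
})

test_that("edited target counting reports per-read edits", {
  ps <- toy_spec()
  ref <- as.character(amplicon(ps$spec))
  p15 <- 101 + 20 - 15
  cl <- classifyRead(alignRead(mutate_at(ref, p15, "T"), ps$spec), ps$spec)
  expect_identical(cl$edited_target_count, 1L)
})

test_that("quantification of constructed counts is exact", {
  ps <- toy_spec()
  ref <- as.character(amplicon(ps$spec))
  p15 <- 101 + 20 - 15
  reads <- c(rep(ref, 60), rep(mutate_at(ref, p15, "T"), 40))
  q <- quantifyAmplicon(reads, ps$spec)
  expect_identical(q@nAnalyzed, 100L)
  expect_equal(unname(targetRates(q)[as.character(p15)]), 40.0)
  expect_equal(pctIndel(q), 0)
  expect_equal(pctOther(q), 0)
  expect_equal(pctUnwanted(q), 0)
  expect_identical(unname(readCategories(q)["WT"]), 60L)
})

test_that("category partition holds and empty input errors", {
  ps <- toy_spec()
  sim <- simulateReads(ps$spec, simTruth(
    editFractions = c(`15` = 0.3, `16` = 0.5), errorRate = 0.002,
    indelRate = 0.05, nReads = 400, seed = 11))
  q <- quantifyAmplicon(sim$reads, ps$spec)
  expect_identical(sum(readCategories(q)) + q@nDiscarded, q@nInput)
  expect_identical(q@nInput, 400L)
  # per-position rows over A/C/G/T/del sum to reads covering the position
  expect_true(all(rowSums(windowCounts(q)) <= q@nAnalyzed))
  expect_error(quantifyAmplicon(character(0), ps$spec), "no reads")
  garbage <- replicate(5, random_dna(240))
  expect_error(quantifyAmplicon(garbage, ps$spec), "discarded")
})

test_that("zero-noise simulation gives 100% WT and zero rates", {
  ps <- toy_spec()
  sim <- simulateReads(ps$spec, simTruth(
    editFractions = c(`15` = 0, `16` = 0), errorRate = 0, indelRate = 0,
    nReads = 150, seed = 13))
  q <- quantifyAmplicon(sim$reads, ps$spec)
  expect_identical(unname(readCategories(q)["WT"]), 150L)
  expect_true(all(targetRates(q) == 0))
  expect_equal(pctUnwanted(q), 0)
})

test_that("reverse-complementing every read leaves the result unchanged", {
  ps <- toy_spec()
  sim <- simulateReads(ps$spec, simTruth(
    editFractions = c(`15` = 0.4, `16` = 0.6), errorRate = 0.003,
    indelRate = 0.04, nReads = 300, seed = 17))
  reads <- as.character(sim$reads)
  q1 <- quantifyAmplicon(reads, ps$spec)
  q2 <- quantifyAmplicon(vapply(reads, revcomp_chr, character(1),
                                USE.NAMES = FALSE), ps$spec)
  expect_identical(readCategories(q1), readCategories(q2))
  expect_identical(windowCounts(q1), windowCounts(q2))
  expect_equal(targetRates(q1), targetRates(q2))
})

test_that("quant reports round-trip through TSV and JSON", {
  ps <- toy_spec()
  sim <- simulateReads(ps$spec, simTruth(
    editFractions = c(`15` = 0.5, `16` = 0.2), errorRate = 0.001,
    nReads = 200, seed = 19))
  q <- quantifyAmplicon(sim$reads, ps$spec)
  tsv <- tempfile(fileext = ".tsv"); json <- tempfile(fileext = ".json")
  writeQuantReport(q, tsv, json)
  back <- readQuantReport(tsv, json)
  expect_identical(back$matrix$pos, as.integer(rownames(windowCounts(q))))
  expect_equal(as.matrix(back$matrix[, c("A", "C", "G", "T", "del")]),
               windowCounts(q), ignore_attr = TRUE)
  expect_equal(back$summary$n_input, q@nInput)
  expect_equal(back$summary$pct_indel, pctIndel(q))
  expect_equal(back$summary$pct_unwanted, pctUnwanted(q))
  expect_equal(sort(back$summary$per_target$pos),
               as.integer(names(targetRates(q))))
  expect_identical(sort(names(back$summary)),
                   sort(c("n_input", "n_discarded", "n_analyzed",
                          "categories", "per_target",
                          "pct_other_substitution", "pct_indel",
                          "pct_unwanted")))
})
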