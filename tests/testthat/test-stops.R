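test_that("single-codon examples follow the genetic code", {
  # CAG -> TAG via a sense C at position 1
  r <- stopEditsForCodon("CAG")
  expect_identical(nrow(r), 1L)
  expect_identical(r$edited_codon, "TAG")
  expect_identical(r$edited_strand, "sense")
  expect_identical(r$positions[[1]], 1L)

  # TGG (Trp): three antisense routes
  r <- stopEditsForCodon("TGG")
  expect_identical(nrow(r), 3L)
  expect_true(all(r$edited_strand == "antisense"))
  keys <- mapply(stop_set_key, r$edited_codon, r$edited_strand, r$positions)
  expect_setequal(unname(keys), c(
    stop_set_key("TAG", "antisense", 2L),
    stop_set_key("TGA", "antisense", 3L),
    stop_set_key("TAA", "antisense", c(2L, 3L))))

  # no C or G: nothing to edit
  expect_identical(nrow(stopEditsForCodon("AAA")), 0L)
  expect_error(stopEditsForCodon("AXG"), "A/C/G/T")
})

test_that("the full 64-codon table equals brute-force enumeration", {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste,
                  collapse = "")
  for (codon in codons) {
    got <- stopEditsForCodon(codon)
    want <- oracle_stop_edits(codon)
    got_keys <- if (nrow(got))
      unname(mapply(stop_set_key, got$edited_codon, got$edited_strand,
                    got$positions))
    else character(0)
    want_keys <- vapply(want, function(w)
      stop_set_key(w$edited, w$strand, w$positions), character(1))
    expect_setequal(got_keys, want_keys)
    # mixed-strand subsets never appear
    expect_true(all(got$edited_strand %in% c("sense", "antisense")))
  }
})

test_that("STOP guide design recovers a planted antisense geometry", {
  # W codon (TGG) in a CDS, with an antisense guide placed so the two
  # G-complement Cs sit at distances 15 and 16 from the PAM
  base <- makeReference(300, seed = 41)
  s <- strsplit(as.character(refSeq(base)), "")[[1]]
  cds_start <- 61L
  # residue 10 occupies forward positions 88..90
  s[88:90] <- c("T", "G", "G")
  seq0 <- paste(s, collapse = "")
  # "-" guide starting at 75 covers [75, 94]; d = pos - 75 + 1, so the
  # codon Gs at 89 and 90 sit at distances 15 and 16
  proto <- revcomp_chr(substr(seq0, 75L, 94L))
  planted <- plantGuideSite(CbeReference(seq0, id = "g"),
                            protospacer = proto, pam = "AAA",
                            position = 75L, strand = "-")
  ref <- CbeReference(as.character(refSeq(planted$ref)), id = "g",
                      cds = data.frame(start = cds_start,
                                       end = cds_start + 149L, frame = 0L))
  res <- designStopGuides(ref, 10L, pam = "NNN")
  expect_gt(length(res), 0L)
  expect_true(all(mcols(res)$protein_notation == "W10*"))
  taa <- res[mcols(res)$edited_codon == "TAA" & start(res) == 75L]
  expect_length(taa, 1L)
  expect_identical(as.integer(mcols(taa)$required_c_dists[[1]]),
                   c(15L, 16L))
  expect_identical(as.character(strand(taa)), "-")
})

test_that("inconvertible residues return empty with a reason", {
  ref <- CbeReference(paste0(strrep("G", 30), "AAA", strrep("G", 147)),
                      cds = data.frame(start = 1L, end = 180L, frame = 0L))
  res <- designStopGuides(ref, 11L, pam = "NNN")  # codon AAA
  expect_length(res, 0L)
  expect_identical(attr(res, "reason"), "codon not convertible")
})

test_that("widening the window only adds plans", {
  set.seed(71)
  for (k in 1:5) {
    ref0 <- makeReference(240, seed = 100 + k)
    s <- strsplit(as.character(refSeq(ref0)), "")[[1]]
    s[61:63] <- c("C", "A", "A")  # Q codon at residue 1
    ref <- CbeReference(paste(s, collapse = ""),
                        cds = data.frame(start = 61L, end = 180L,
                                         frame = 0L))
    narrow <- designStopGuides(ref, 1L, pam = "NNN", window = c(13L, 19L))
    wide <- designStopGuides(ref, 1L, pam = "NNN", window = c(12L, 19L))
    key <- function(g) paste(start(g), strand(g), mcols(g)$edited_codon)
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("bystander Cs are annotated with their coding consequence", {
  # guide whose window contains only the target Cs -> no bystanders
  ps <- toy_spec()
  ref <- CbeReference(as.character(refSeq(ps$ref)), id = "ref")
  g <- scanProtospacers(ref, "NGG")
  g <- g[start(g) == 101L & as.character(strand(g)) == "+"]
  expect_length(g, 1L)
  expect_identical(nrow(annotateBystanders(g, ref, c(15L, 16L))), 0L)
  # without CDS, the same window Cs are noncoding bystanders
  b <- annotateBystanders(g, ref, integer(0))
  expect_identical(b$c_dist, c(15L, 16L))
  expect_true(all(b$cds_consequence == "noncoding"))

  # constructed synonymous bystander: CTC -> CTT (both Leu), C at the
  # third codon position
  s <- rep("A", 240)
  s[101:120] <- strsplit(paste0("GAT", "CTC", strrep("A", 14)), "")[[1]]
  s[121:123] <- c("T", "G", "G")
  ref2 <- CbeReference(paste(s, collapse = ""),
                       cds = data.frame(start = 104L, end = 223L,
                                        frame = 0L))
  g2 <- scanProtospacers(ref2, "NGG")
  g2 <- g2[start(g2) == 101L & as.character(strand(g2)) == "+"]
  b2 <- annotateBystanders(g2, ref2, integer(0))
  syn <- b2[b2$c_dist == 15L, ]
  expect_identical(syn$cds_consequence, "synonymous")
  expect_identical(syn$protein_notation, "L1L")

  # missense bystander at distance 19, mirroring an R->K change 3' of the
  # intended stop: AGA (Arg) -> AAA (Lys) via an antisense G-to-A.
  # "-" guide at 101: protospacer index i maps to forward 100 + (21 - i),
  # so proto = "TCT" + T... puts the lone window C (index 2, d = 19) over
  # forward position 119 and makes forward [118,120] read AGA.
  planted3 <- plantGuideSite(makeReference(240, seed = 43),
                             protospacer = paste0("TCT", strrep("T", 17)),
                             pam = "TTT", position = 101L, strand = "-")
  fw <- as.character(refSeq(planted3$ref))
  expect_identical(substr(fw, 118L, 120L), "AGA")
  ref3 <- CbeReference(fw, cds = data.frame(start = 118L, end = 237L,
                                            frame = 0L))
  g3 <- scanProtospacers(ref3, "NNN")
  g3 <- g3[start(g3) == 101L & as.character(strand(g3)) == "-"]
  b3 <- annotateBystanders(g3, ref3, integer(0))
  expect_identical(b3$c_dist, 19L)
  expect_identical(b3$cds_consequence, "missense")
  expect_identical(b3$protein_notation, "R1K")
})
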