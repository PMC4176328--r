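# a 200-nt genome with an intron at [50, 130)
.extrGenome <- function(seed = 5) {
  set.seed(seed)
  namedGenome(chr1 = randomDNA(200))
}
.spanRead <- function(genome, a, b = 40 - a, s0 = 50, e0 = 130, qname = "r",
                      flag = 0, nm = 0) {
  seq <- paste0(substr(as.character(genome[["chr1"]]), s0 - a + 1, s0),
                substr(as.character(genome[["chr1"]]), e0 + 1, e0 + b))
  list(qname = qname, flag = flag, pos1 = s0 - a + 1,
       cigar = sprintf("%dM%dN%dM", a, e0 - s0, b), seq = seq, nm = nm)
}

test_that("support counts distinct read sequences, not alignments", {
  g <- .extrGenome()
  sam <- tempfile(fileext = ".sam")
  reads <- list(.spanRead(g, 10, qname = "r1"), .spanRead(g, 10, qname = "r2"),
                .spanRead(g, 10, qname = "r3"))
  writeSam(sam, 200, reads)
  j <- junctionsFromAlignments(sam, sourceLabel = "s1")
  expect_equal(length(j), 1L)
  expect_equal(S4Vectors::mcols(j)$support, 1L)  # identical sequences
  expect_equal(GenomicRanges::start(j) - 1L, 50L)
  expect_equal(GenomicRanges::end(j), 130L)
})

test_that("an anchor below 8 nt contributes no junction", {
  g <- .extrGenome()
  sam <- tempfile(fileext = ".sam")
  writeSam(sam, 200, list(.spanRead(g, 7, 30)))
  expect_equal(length(junctionsFromAlignments(sam)), 0L)
  writeSam(sam, 200, list(.spanRead(g, 8, 30)))
  expect_equal(length(junctionsFromAlignments(sam)), 1L)
})

test_that("EST mode requires 15-nt anchors without mismatches", {
  g <- .extrGenome()
  sam <- tempfile(fileext = ".sam")
  writeSam(sam, 200, list(.spanRead(g, 14, 20, qname = "a"),
                          .spanRead(g, 16, 20, qname = "b"),
                          .spanRead(g, 18, 20, qname = "c", nm = 1)))
  j <- junctionsFromAlignments(sam, mode = "est")
  expect_equal(S4Vectors::mcols(j)$support, 1L)  # only the 16-nt, NM=0 read
})

test_that("recovered support equals the simulator truth table", {
  set.seed(7)
  cfg <- simulationConfig(seed = 7, nCanonical = 5, nCanonicalU12 = 0,
                          nNonCanonical = 0, nTemplateSwitch = 0,
                          nHomopolymer = 0, nSnpConfounded = 0,
                          nEditedGTAA = 0, nEditedATAG = 0,
                          supportPerSource = 5)
  ref <- simulateReference(cfg)
  ev <- simulateEvidence(ref$genome, ref$truth, cfg)
  j <- junctionsFromAlignments(ev$samFiles[[1]], sourceLabel = "a")
  expect_equal(length(j), 5L)
  expect_true(all(S4Vectors::mcols(j)$support == 5L))
  m <- matchTruth(ref$genome, ref$truth, j)
  expect_false(anyNA(m))
})

test_that("source merging demands per-source presence, never pooled support", {
  mk <- function(support) junctionRanges("chr1", 50, 130, "+", support = support)
  cfg <- extractionConfig()
  kept <- mergeSources(list(A = mk(3L), B = mk(4L)), cfg)
  expect_equal(length(kept), 1L)
  expect_equal(S4Vectors::mcols(kept)$support.A, 3L)
  expect_equal(S4Vectors::mcols(kept)$support.B, 4L)
  expect_equal(length(mergeSources(list(A = mk(5L)), cfg)), 0L)
  expect_equal(length(mergeSources(list(A = mk(2L), B = mk(2L)), cfg)), 0L)
  expect_error(mergeSources(list(A = mk(3L), A = mk(3L)), cfg), "named")
})

test_that("merging a merged set with itself changes nothing", {
  mk <- function(s0, support) junctionRanges("chr1", s0, s0 + 80, "+",
                                             support = support)
  sets <- list(A = c(mk(10, 3L), mk(200, 4L)), B = c(mk(10, 5L), mk(200, 2L)))
  m1 <- mergeSources(sets)
  m2 <- mergeSources(m1)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("variant filter discards only non-canonical candidates spanning variants", {
  chars <- rep("A", 800)
  chars[51:52] <- c("G", "A"); chars[629:630] <- c("A", "G")  # GA-AG at [50,630)
  g1 <- namedGenome(chr1 = paste0(chars, collapse = ""))
  j <- junctionRanges("chr1", 50, 630, "+")
  snpAtDonor <- GenomicRanges::GRanges("chr1", IRanges::IRanges(52, 52))
  snpInside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(340, 340))
  expect_equal(length(filterVariantSpanning(j, snpAtDonor, g1)$kept), 0L)
  expect_equal(length(filterVariantSpanning(j, snpInside, g1)$kept), 1L)
  # canonical junction at the same spot passes untouched
  chars[51:52] <- c("G", "T")
  g2 <- namedGenome(chr1 = paste0(chars, collapse = ""))
  expect_equal(length(filterVariantSpanning(j, snpAtDonor, g2)$kept), 1L)
})

test_that("DUST scoring matches the brute-force triplet oracle", {
  homo <- strrep("A", 64)
  expect_gt(dustScore(homo), 2)
  expect_equal(dustScore(homo), oracleDust(homo))
  set.seed(13)
  for (i in 1:20) {
    s <- randomDNA(64)
    expect_equal(dustScore(s), oracleDust(s), tolerance = 1e-12)
  }
  rep4 <- strrep("ACGT", 16)
  expect_equal(dustScore(rep4), oracleDust(rep4))
  expect_error(dustScore("AC"), "shorter")
})

test_that("low-complexity flanks discard a junction", {
  set.seed(3)
  left <- randomDNA(80)
  g <- namedGenome(chr1 = paste0(left, strrep("A", 64), randomDNA(100),
                                 strrep("T", 80)))
  # intron [80+64, 80+64+100): left exonic anchor is the homopolymer
  j <- junctionRanges("chr1", 144, 244, "+")
  out <- filterLowComplexity(j, g)
  expect_equal(length(out$kept), 0L)
  expect_equal(S4Vectors::mcols(out$discarded)$reason, "low_complexity")
  gClean <- namedGenome(chr1 = paste0(randomDNA(144), randomDNA(100),
                                      randomDNA(80)))
  expect_equal(length(filterLowComplexity(j, gClean)$kept), 1L)
})

test_that("diploid concordance needs >= 3 coincident alignments in both haplotypes", {
  mk <- function(support) junctionRanges("chr1", 50, 130, "+", support = support)
  expect_equal(length(diploidConcordance(mk(3L), mk(5L))$kept), 1L)
  expect_equal(length(diploidConcordance(mk(3L), mk(2L))$kept), 0L)
  # maternal-only junction (paternal unmapped) is dropped
  emptyP <- junctionRanges(character(0), integer(0), integer(0), character(0),
                           support = integer(0))
  expect_equal(length(diploidConcordance(mk(4L), emptyP)$kept), 0L)
  # haplotype coordinates translated through the mapping
  map <- data.frame(chrom = "chr1", start = 60, end = 140, strand = "+",
                    target_chrom = "chr1", target_start = 50, target_end = 130,
                    target_strand = "+")
  shifted <- junctionRanges("chr1", 60, 140, "+", support = 3L)
  out <- diploidConcordance(shifted, mk(3L), maternalMap = map)
  expect_equal(length(out$kept), 1L)
  expect_equal(GenomicRanges::start(out$kept) - 1L, 50L)
})

test_that("junction library records are the excised flank concatenation", {
  g <- namedGenome(chr1 = "AAAGTATCCAGAAA")
  lib <- buildJunctionLibrary(g, junctionRanges("chr1", 3, 11, "+"), 3)
  expect_equal(as.character(lib[[1]]), "AAAAAA")
  set.seed(21)
  g2 <- namedGenome(c1 = randomDNA(2000))
  s0 <- seq(200, 1600, by = 70)
  jr <- junctionRanges(rep("c1", length(s0)), s0, s0 + 50,
                       rep(c("+", "-"), length.out = length(s0)))
  lib2 <- buildJunctionLibrary(g2, jr, 42)
  expect_true(all(Biostrings::width(lib2) == 84))
  # regeneration oracle: rebuilt from the genome, byte-identical FASTA
  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeXStringSet(lib2, f1)
  Biostrings::writeXStringSet(buildJunctionLibrary(g2, jr, 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  # flanks past the chromosome edge are skipped, not truncated
  expect_warning(libEdge <- buildJunctionLibrary(
    g2, junctionRanges("c1", 10, 60, "+"), 42), "skipped")
  expect_equal(length(libEdge), 0L)
})

test_that("filters conserve support and commute", {
  set.seed(31)
  g <- namedGenome(chr1 = randomDNA(3000))
  s0 <- seq(300, 2400, by = 300)
  jr <- junctionRanges(rep("chr1", length(s0)), s0, s0 + 120,
                       rep("+", length(s0)), support = 3:10)
  vars <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(301, 1501), width = 1))
  fv <- filterVariantSpanning(jr, vars, g)
  expect_equal(sum(S4Vectors::mcols(fv$kept)$support) +
                 sum(S4Vectors::mcols(fv$discarded)$support),
               sum(3:10))
  # variant and dust filters commute
  ab <- filterLowComplexity(filterVariantSpanning(jr, vars, g)$kept, g)$kept
  ba <- filterVariantSpanning(filterLowComplexity(jr, g)$kept, vars, g)$kept
  expect_identical(as.data.frame(ab), as.data.frame(ba))
})

test_that("repeat-interval overlap discards junction anchors", {
  set.seed(41)
  g <- namedGenome(chr1 = randomDNA(500))
  j <- junctionRanges("chr1", 100, 200, "+")
  rep1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(85, 95))
  out <- filterRepeats(j, rep1)
  expect_equal(length(out$kept), 0L)
  repFar <- GenomicRanges::GRanges("chr1", IRanges::IRanges(400, 420))
  expect_equal(length(filterRepeats(j, repFar)$kept), 1L)
})
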