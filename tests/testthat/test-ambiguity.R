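test_that("a junction without flanking matches has a single placement", {
  # intron [5,13): genome[5]='T' vs genome[13]='C'; genome[4]='G' vs genome[12]='A'
  g <- namedGenome(chr1 = "AAACGTTTTTTTACAA")
  grp <- enumeratePlacements(g, junctionRanges("chr1", 5, 13, "+"))
  expect_equal(length(placements(grp)), 1L)
  expect_equal(directRepeatLength(grp), 0L)
})

test_that("an implanted 3-nt direct repeat yields 4 placements", {
  # repeat 'TCA' at intron start and immediately after the intron end
  g <- namedGenome(chr1 = paste0("AACT", "TCA", "GGGGGG", "TCA", "CCTT"))
  # intron [4, 13): genome[4..6]="TCA" == genome[13..15]="TCA"
  grp <- enumeratePlacements(g, junctionRanges("chr1", 4, 13, "+"))
  expect_equal(directRepeatLength(grp), 3L)
  expect_equal(length(placements(grp)), 4L)
  expect_equal(S4Vectors::mcols(placements(grp))$shift, 0:3)
})

test_that("placement enumeration equals the spliced-product identity oracle", {
  set.seed(61)
  for (i in 1:1000) {
    len <- sample(60:120, 1)
    # low-alphabet genomes provoke repeats
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1))
    g <- namedGenome(c1 = paste0(chars, collapse = ""))
    s0 <- sample(32:40, 1)
    e0 <- s0 + sample(5:15, 1)
    grp <- enumeratePlacements(g, junctionRanges("c1", s0, e0, "+"))
    want <- oraclePlacements(g, "c1", s0, e0)
    expect_equal(S4Vectors::mcols(placements(grp))$shift, want)
  }
})

test_that("every placement in a group excises the same spliced product", {
  set.seed(67)
  g <- namedGenome(c1 = paste0(sample(c("A", "T"), 300, replace = TRUE),
                               collapse = ""))
  grp <- enumeratePlacements(g, junctionRanges("c1", 100, 160, "+"))
  chr <- as.character(g[["c1"]])
  spliced <- vapply(seq_along(placements(grp)), function(i) {
    p <- placements(grp)[i]
    paste0(substr(chr, 1, GenomicRanges::start(p) - 1),
           substr(chr, GenomicRanges::end(p) + 1, nchar(chr)))
  }, character(1))
  expect_equal(length(unique(spliced)), 1L)
  expect_equal(length(placements(grp)),
               grp@leftShift + grp@rightShift + 1L)
})

test_that("a canonical placement is always rescued over a non-canonical one", {
  # shift 0 gives GA-AG, shift +1 gives a GT-AG canonical placement:
  # need genome[s]==genome[e] and placement (s+1,e+1) reading GT..AG
  pwm <- toyPWM()
  chars <- rep("C", 120)
  # 0-based: pos50..52 = GGT, pos89..91 = CAG; junction [50,91) reads GG-CA,
  # the right-shifted placement [51,92) reads GT-AG (canonical), and the
  # shift exists because pos50 == pos91 ('G')
  chars[51:53] <- c("G", "G", "T")
  chars[90:92] <- c("C", "A", "G")
  g <- namedGenome(chr1 = paste0(chars, collapse = ""))
  j <- junctionRanges("chr1", 50, 91, "+")
  grp <- enumeratePlacements(g, j)
  expect_gte(directRepeatLength(grp), 1L)
  cats <- categorizeDinucleotides2(g, placements(grp))
  expect_true(any(cats$category == "CANONICAL"))
  res <- resolvePlacement(grp, g, pwm)
  expect_true(res$rescuedCanonical)
  chosen <- categorizeDinucleotides2(g, res$chosen)
  expect_equal(chosen$category, "CANONICAL")
})

test_that("a singleton group resolves to itself without rescue", {
  chars <- rep("C", 200)
  chars[c(60, 120)] <- "G"; chars[c(61, 121)] <- "T"  # pos59/60 vs pos119/120
  chars[120] <- "A"  # break the left-shift match: pos119='A' vs pos59='G'
  chars[121] <- "A"  # break the right-shift match: pos120='A' vs pos60='T'
  g <- namedGenome(chr1 = paste0(chars, collapse = ""))
  grp <- enumeratePlacements(g, junctionRanges("chr1", 60, 120, "+"))
  expect_equal(length(placements(grp)), 1L)
  res <- resolvePlacement(grp, g, toyPWM())
  expect_false(res$rescuedCanonical)
  expect_equal(S4Vectors::mcols(res$chosen)$shift, 0L)
})

test_that("resolution matches an exhaustive argmax oracle and ignores input order", {
  set.seed(71)
  pwm <- toyPWM()
  nRescued <- 0
  for (i in 1:200) {
    chars <- sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                    prob = c(0.35, 0.35, 0.15, 0.15))
    g <- namedGenome(c1 = paste0(chars, collapse = ""))
    grp <- enumeratePlacements(g, junctionRanges("c1", 60, 120, "+"))
    res <- resolvePlacement(grp, g, pwm)
    sc <- scoreJunctions(pwm, g, placements(grp))$final_score
    cats <- categorizeDinucleotides2(g, placements(grp))
    canonical <- cats$category == "CANONICAL"
    pool <- if (any(canonical)) which(canonical) else seq_along(sc)
    expect_equal(S4Vectors::mcols(res$chosen)$final_score, max(sc[pool]))
    expect_equal(res$rescuedCanonical, any(canonical))
    nRescued <- nRescued + res$rescuedCanonical
    # resolver never emits a non-canonical placement when a canonical exists
    if (any(canonical))
      expect_equal(categorizeDinucleotides2(g, res$chosen)$category,
                   "CANONICAL")
    # order invariance: reverse the placements inside the group
    grpRev <- methods::new("AmbiguityGroup",
                           placements = rev(placements(grp)),
                           leftShift = grp@rightShift,
                           rightShift = grp@leftShift,
                           directRepeatLength = grp@directRepeatLength)
    resRev <- resolvePlacement(grpRev, g, pwm)
    expect_identical(as.data.frame(GenomicRanges::granges(resRev$chosen)),
                     as.data.frame(GenomicRanges::granges(res$chosen)))
  }
})

test_that("score ties break toward the smallest shift, then leftmost", {
  # uniform matrix: every placement scores identically
  unif <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  mats <- list(u2_5 = unif, u2_3 = matrix(0.25, 4, 17, dimnames = dimnames(unif)[c(1, 2)]),
               u12_5 = matrix(0.25, 4, 12), u12_3 = matrix(0.25, 4, 17))
  for (s in names(mats)) rownames(mats[[s]]) <- c("A", "C", "G", "T")
  pwm <- methods::new("PWMModel", matrices = mats, windows = defaultWindows(),
                      pseudocount = 0)
  g <- namedGenome(c1 = strrep("A", 300))   # maximal ambiguity, all AA-AA
  grp <- enumeratePlacements(g, junctionRanges("c1", 100, 200, "+"))
  res <- resolvePlacement(grp, g, pwm)
  expect_equal(S4Vectors::mcols(res$chosen)$shift, 0L)
})
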