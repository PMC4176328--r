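test_that("PWM training frequencies follow the pseudocount formula", {
  seqs <- rep("CAGGTAAGT", 10)
  train <- list(u2_5 = seqs, u2_3 = rep(strrep("T", 14), 10) |> paste0("CAG"),
                u12_5 = rep("CAGATATCCTTT", 10),
                u12_3 = rep(paste0(strrep("T", 14), "CAG"), 10))
  m0 <- buildPWM(train, pseudocount = 0)
  expect_equal(unname(pwmMatrix(m0, "u2_5")["C", 1]), 1)
  expect_equal(unname(pwmMatrix(m0, "u2_5")["A", 1]), 0)
  m1 <- buildPWM(train, pseudocount = 1)
  expect_equal(unname(pwmMatrix(m1, "u2_5")["G", 3]), 11 / 14)
  expect_equal(unname(pwmMatrix(m1, "u2_5")["A", 3]), 1 / 14)
  expect_error(buildPWM(lapply(train, head, 5)), "too few")
})

test_that("trained frequencies recover a known generating distribution", {
  set.seed(17)
  gen <- matrix(c(0.5, 0.2, 0.2, 0.1), 4, 9,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  n <- 200
  seqs <- vapply(seq_len(n), function(i) {
    paste0(apply(gen, 2, function(p) sample(rownames(gen), 1, prob = p)),
           collapse = "")
  }, character(1))
  train <- list(u2_5 = seqs,
                u2_3 = rep(paste0(strrep("T", 14), "CAG"), 10),
                u12_5 = rep("CAGATATCCTTT", 10),
                u12_3 = rep(paste0(strrep("T", 14), "CAG"), 10))
  m <- buildPWM(train, pseudocount = 0)
  est <- pwmMatrix(m, "u2_5")
  se <- sqrt(gen * (1 - gen) / n)
  expect_true(all(abs(est - gen) <= 3 * se + 1e-12))
})

test_that("site scores are min-max normalised: consensus 100, anti-consensus 0", {
  pwm <- toyPWM()
  for (s in c("u2_5", "u2_3", "u12_5", "u12_3")) {
    m <- pwmMatrix(pwm, s)
    cons <- paste0(rownames(m)[apply(m, 2, which.max)], collapse = "")
    anti <- paste0(rownames(m)[apply(m, 2, which.min)], collapse = "")
    expect_equal(scoreSite(m, cons), 100)
    expect_equal(scoreSite(m, anti), 0)
  }
  expect_error(scoreSite(pwmMatrix(pwm, "u2_5"), "ACGT"), "width")
})

test_that("site scoring equals the brute-force formula on random windows", {
  set.seed(23)
  m <- pwmMatrix(buildPWM(list(
    u2_5 = replicate(50, randomDNA(9)),
    u2_3 = replicate(50, randomDNA(17)),
    u12_5 = replicate(50, randomDNA(12)),
    u12_3 = replicate(50, randomDNA(17))), pseudocount = 0.5), "u2_5")
  wins <- replicate(1000, randomDNA(9))
  got <- scoreSite(m, wins)
  want <- vapply(wins, oracleScoreSite, numeric(1), freq = m)
  expect_equal(got, unname(want), tolerance = 1e-9)
})

test_that("improving a window base toward the column argmax never lowers the score", {
  set.seed(29)
  pwm <- toyPWM()
  m <- pwmMatrix(pwm, "u2_5")
  for (i in 1:50) {
    w <- randomDNA(9)
    p <- sample(9, 1)
    better <- w
    substr(better, p, p) <- rownames(m)[which.max(m[, p])]
    expect_gte(scoreSite(m, better), scoreSite(m, w))
  }
})

test_that("junction scores combine sites by mean and models by max", {
  pwm <- toyPWM()
  # genome whose + junction windows are exactly the U2 consensus
  ex5 <- "CAG"; in5 <- "GTAAGT"; in3 <- "TTTTTTTTTTTCAG"; ex3 <- "GTG"
  intronMid <- strrep("C", 40)
  g <- namedGenome(chr1 = paste0(strrep("A", 20), ex5, in5, intronMid, in3,
                                 ex3, strrep("A", 20)))
  s0 <- 23; e0 <- 23 + 6 + 40 + 14
  sc <- scoreJunctions(pwm, g, junctionRanges("chr1", s0, e0, "+"))
  expect_equal(sc$u2_score, 100)
  expect_equal(sc$final_score, 100)
  expect_equal(sc$best_model, "U2")
  # anti-consensus acceptor halves the U2 score
  anti3 <- paste0(rownames(pwmMatrix(pwm, "u2_3"))[
    apply(pwmMatrix(pwm, "u2_3"), 2, which.min)], collapse = "")
  g2 <- namedGenome(chr1 = paste0(strrep("A", 20), ex5, in5, intronMid,
                                  substr(anti3, 1, 14),
                                  substr(anti3, 15, 17), strrep("A", 20)))
  sc2 <- scoreJunctions(pwm, g2, junctionRanges("chr1", s0, e0, "+"))
  expect_equal(sc2$u2_score, 50)
})

test_that("junction scoring equals a brute-force max-of-means oracle", {
  set.seed(37)
  pwm <- toyPWM()
  g <- namedGenome(c1 = randomDNA(5000))
  s0 <- seq(100, 4500, by = 22)[1:200]
  jr <- junctionRanges(rep("c1", 200), s0, s0 + 90,
                       rep(c("+", "-"), 100))
  got <- scoreJunctions(pwm, g, jr)
  win <- junctionWindows(g, jr)
  for (i in seq_len(200)) {
    u2 <- mean(c(oracleScoreSite(pwmMatrix(pwm, "u2_5"), win$u2_5[i]),
                 oracleScoreSite(pwmMatrix(pwm, "u2_3"), win$u2_3[i])))
    u12 <- mean(c(oracleScoreSite(pwmMatrix(pwm, "u12_5"), win$u12_5[i]),
                  oracleScoreSite(pwmMatrix(pwm, "u12_3"), win$u12_3[i])))
    expect_equal(got$final_score[i], max(u2, u12), tolerance = 1e-9)
  }
})

test_that("null calibration is the nearest-rank percentile of the scrambled pool", {
  expect_equal(nearestRankPercentile(1:100, 95), 95)
  expect_equal(nearestRankPercentile(c(5, 1, 9), 50), 5)
  # constant windows: every scramble scores identically
  pwm <- toyPWM()
  g <- namedGenome(chr1 = paste0(strrep("G", 30), strrep("A", 100),
                                 strrep("G", 30)))
  j <- junctionRanges("chr1", 40, 120, "+")
  thr <- calibrateNullThreshold(pwm, g, j,
                                classifierConfig(nullScrambles = 50, seed = 1))
  pool <- attr(thr, "pool")
  expect_equal(length(unique(round(pool, 9))), 1L)
  expect_equal(as.numeric(thr), pool[1])
})

test_that("calibration is deterministic and matches the sort-and-index oracle", {
  set.seed(43)
  pwm <- toyPWM()
  g <- namedGenome(c1 = randomDNA(4000))
  s0 <- seq(150, 3500, by = 170)
  jr <- junctionRanges(rep("c1", length(s0)), s0, s0 + 95,
                       rep("+", length(s0)))
  cfgA <- classifierConfig(nullScrambles = 100, seed = 99)
  t1 <- calibrateNullThreshold(pwm, g, jr, cfgA)
  t2 <- calibrateNullThreshold(pwm, g, jr, cfgA)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_equal(as.numeric(t1), oraclePercentile(attr(t1, "pool"), 95))
  expect_error(calibrateNullThreshold(pwm, g, jr[0],
                                      classifierConfig()), "at least one")
})

test_that("the classification rule follows the published order", {
  cfg <- classifierConfig()
  expect_equal(classifyJunctions(85, 55, FALSE, 500, cfg), "U2U12_LIKE")
  expect_equal(classifyJunctions(60, 55, TRUE, 500, cfg), "U2U12_LIKE")
  expect_equal(classifyJunctions(60, 55, FALSE, 500, cfg), "NON_U2U12")
  expect_equal(classifyJunctions(95, 55, FALSE, 79, cfg), "NON_U2U12")
  expect_equal(classifyJunctions(95, 55, FALSE, 80, cfg), "U2U12_LIKE")
  expect_equal(classifyJunctions(50, 55, TRUE, 500, cfg), "NON_U2U12")
  # exact boundaries: the rescue band is inclusive on both ends
  expect_equal(classifyJunctions(55, 55, TRUE, 500, cfg), "U2U12_LIKE")
  expect_equal(classifyJunctions(70, 55, TRUE, 500, cfg), "U2U12_LIKE")
  expect_equal(classifyJunctions(70, 55, FALSE, 500, cfg), "NON_U2U12")
  expect_warning(classifyJunctions(80, 75, FALSE, 500, cfg), "rescue band")
  # total and deterministic over a grid
  grid <- expand.grid(score = seq(0, 100, by = 5), shares = c(TRUE, FALSE),
                      len = c(10, 79, 80, 1000))
  c1 <- classifyJunctions(grid$score, 55, grid$shares, grid$len, cfg)
  c2 <- classifyJunctions(grid$score, 55, grid$shares, grid$len, cfg)
  expect_identical(c1, c2)
  expect_true(all(c1 %in% c("U2U12_LIKE", "NON_U2U12")))
})

test_that("shared-site detection keys donor and acceptor per strand", {
  can <- junctionRanges(c("c1", "c1"), c(100, 500), c(200, 700), c("+", "-"))
  cand <- junctionRanges(
    c("c1", "c1", "c1", "c1"),
    c(100, 150, 520, 320),
    c(260, 200, 800, 420),
    c("+", "+", "-", "+"))
  expect_equal(sharesCanonicalSite(cand, can), c(TRUE, TRUE, FALSE, FALSE))
  # minus-strand donor is the genomic end coordinate
  candM <- junctionRanges("c1", 420, 700, "-")
  expect_true(sharesCanonicalSite(candM, can))
})

test_that("PWM TSV persistence round-trips", {
  set.seed(51)
  m <- buildPWM(list(u2_5 = replicate(20, randomDNA(9)),
                     u2_3 = replicate(20, randomDNA(17)),
                     u12_5 = replicate(20, randomDNA(12)),
                     u12_3 = replicate(20, randomDNA(17))),
                pseudocount = 0.5)
  f <- tempfile(fileext = ".tsv")
  writePWM(m, f)
  m2 <- readPWM(f)
  for (s in c("u2_5", "u2_3", "u12_5", "u12_3"))
    expect_equal(pwmMatrix(m2, s), pwmMatrix(m, s), tolerance = 1e-12)
  expect_equal(pwmWindows(m2), pwmWindows(m))
})

test_that("PWMModel validity rejects malformed matrices", {
  pwm <- toyPWM()
  bad <- pwm@matrices
  bad$u2_5[1, 1] <- 0.9
  expect_error(methods::new("PWMModel", matrices = bad,
                            windows = defaultWindows(), pseudocount = 0),
               "sum to 1")
})
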