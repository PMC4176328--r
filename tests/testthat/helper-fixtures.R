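# Shared fixtures and independent brute-force oracles.

.fx <- new.env(parent = emptyenv())

# Default-condition simulation + pipeline run, computed once per test run.
defaultSimRun <- function() {
  if (!exists("simRun", envir = .fx)) {
    cfg <- simulationConfig()
    ref <- simulateReference(cfg)
    ev <- simulateEvidence(ref$genome, ref$truth, cfg)
    srcs <- list()
    for (s in names(ev$samFiles))
      srcs[[s]] <- junctionsFromAlignments(ev$samFiles[[s]], sourceLabel = s)
    res <- discoverSpliceSites(ref$genome, srcs,
                               variants = readVariants(ev$vcfFile),
                               pileup = ev$pileup, coverage = ev$coverage)
    assign("simRun", list(cfg = cfg, ref = ref, ev = ev, sources = srcs,
                          res = res), envir = .fx)
  }
  get("simRun", envir = .fx)
}

randomDNA <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

namedGenome <- function(...) {
  g <- Biostrings::DNAStringSet(c(...))
  g
}

# --- independent oracles ---------------------------------------------------

# strand-flip oracle: extract on the reverse-complemented chromosome with
# mirrored coordinates, never using the implementation's minus-strand path
oracleDinucsMinus <- function(genome, chrom, start0, end0) {
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  rc <- Biostrings::reverseComplement(genome[[chrom]])
  rcGenome <- Biostrings::DNAStringSet(rc)
  names(rcGenome) <- chrom
  s2 <- len - end0; e2 <- len - start0
  j <- junctionRanges(chrom, s2, e2, "+")
  extractDinucleotides(rcGenome, j)
}

# brute-force min-max normalised PWM score
oracleScoreSite <- function(freq, window) {
  ch <- strsplit(window, "")[[1]]
  raw <- 0
  for (p in seq_along(ch)) {
    f <- if (ch[p] %in% rownames(freq)) freq[ch[p], p] else min(freq[, p])
    raw <- raw + f
  }
  lo <- sum(apply(freq, 2, min)); hi <- sum(apply(freq, 2, max))
  100 * (raw - lo) / (hi - lo)
}

# sort-and-index nearest-rank percentile
oraclePercentile <- function(x, p) {
  xs <- sort(x)
  xs[max(1, ceiling(length(xs) * p / 100))]
}

# spliced-product identity scan over all shifts in +/- maxShift
oraclePlacements <- function(genome, chrom, s0, e0, maxShift = 30L) {
  chr <- as.character(genome[[chrom]])
  len <- nchar(chr)
  splice <- function(s, e) paste0(substr(chr, 1, s), substr(chr, e + 1, len))
  ref <- splice(s0, e0)
  keep <- integer(0)
  for (sh in seq.int(-maxShift, maxShift)) {
    s <- s0 + sh; e <- e0 + sh
    if (s < 0 || e > len) next
    if (splice(s, e) == ref) keep <- c(keep, sh)
  }
  sort(keep)
}

# brute-force triplet DUST score over all windows
oracleDust <- function(seq, window = 64L) {
  n <- nchar(seq)
  trip <- substring(seq, 1:(n - 2), 3:n)
  best <- 0
  for (ws in 1:max(1, length(trip) - (window - 3))) {
    we <- min(length(trip), ws + window - 3)
    cc <- table(trip[ws:we])
    L <- we - ws + 3
    best <- max(best, sum(cc * (cc - 1) / 2) / max(1, L - 3))
  }
  best
}

# all-pairs near-canonical scan
oracleNearCanonical <- function(candDonor, candAcc, canDonor, canAcc,
                                maxDist = 10L) {
  any(abs(canDonor - candDonor) <= maxDist & abs(canAcc - candAcc) <= maxDist)
}

# simple consensus PWM model for small tests: peaked columns around given
# consensus strings, exact widths of defaultWindows()
toyPWM <- function(peak = 0.7) {
  cons <- list(u2_5 = "CAGGTAAGT", u2_3 = "TTTTTTTTTTTCAGGTG",
               u12_5 = "CAGATATCCTTT", u12_3 = "TTCCTTAACTTTACATG")
  mats <- lapply(cons, function(s) {
    ch <- strsplit(s, "")[[1]]
    m <- matrix((1 - peak) / 3, 4, length(ch),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(ch, rownames(m)), seq_along(ch))] <- peak
    m
  })
  methods::new("PWMModel", matrices = mats, windows = defaultWindows(),
               pseudocount = 0)
}

# SAM writing helper: records = list(list(qname, flag, chrom, pos1, cigar,
# seq, nm))
writeSam <- function(path, chromLen, records, chrom = "chr1") {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chromLen))
  for (r in records) {
    lines <- c(lines, paste(r$qname, r$flag, chrom, r$pos1, 50L, r$cigar,
                            "*", 0L, 0L, r$seq, "*",
                            paste0("NM:i:", r$nm %||% 0L), sep = "\t"))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
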