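# Internal helpers shared across modules.

# 0-based half-open <-> GRanges (1-based closed) conversion for intron intervals.
.start0 <- function(gr) GenomicRanges::start(gr) - 1L
.end0 <- function(gr) GenomicRanges::end(gr)

.assertGenome <- function(genome) {
  if (!methods::is(genome, "DNAStringSet") || is.null(names(genome)))
    stop("genome must be a named DNAStringSet (see readGenome())")
  invisible(genome)
}

# Bounds-checked 0-based half-open subsequence retrieval; never clips silently.
.getSeq0 <- function(genome, chrom, start0, end0) {
  idx <- match(chrom, names(genome))
  if (anyNA(idx))
    stop("unknown chromosome: ", paste(unique(chrom[is.na(idx)]), collapse = ", "))
  len <- Biostrings::width(genome)[idx]
  bad <- start0 < 0L | end0 > len | end0 < start0
  if (any(bad))
    stop(sprintf("interval out of bounds: %s:[%d,%d) on sequence of length %d",
                 chrom[bad][1L], start0[bad][1L], end0[bad][1L], len[bad][1L]))
  out <- character(length(chrom))
  keep <- end0 > start0
  if (any(keep)) {
    ss <- Biostrings::subseq(genome[idx[keep]], start = start0[keep] + 1L,
                             end = end0[keep])
    out[keep] <- as.character(ss)
  }
  out
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Nearest-rank percentile: smallest value with at least p% of the data at or below it.
nearestRankPercentile <- function(x, p) {
  stopifnot(length(x) > 0L, p > 0, p <= 100)
  sort(x)[max(1L, ceiling(p / 100 * length(x)))]
}

.checkStrand <- function(strand) {
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  strand
}
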