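#' Near-canonical test for non-canonical candidates
#'
#' A candidate is near-canonical when some canonical junction on the same
#' chromosome and strand has both its donor within \code{maxDist} nt of the
#' candidate's donor and its acceptor within \code{maxDist} nt of the
#' candidate's acceptor (distances measured between like ends).
#'
#' @param candidates \code{GRanges} of non-canonical candidates.
#' @param canonical \code{GRanges} of canonical junctions.
#' @param maxDist maximal per-end distance (nt).
#' @return \code{DataFrame} with logical \code{near_canonical} and, for the
#'   closest canonical junction, \code{donor_dist} and \code{acceptor_dist}
#'   (NA when no canonical junction shares chromosome and strand).
#' @export
nearCanonical <- function(candidates, canonical, maxDist = 10L) {
  cc <- paste0(GenomicRanges::seqnames(candidates), GenomicRanges::strand(candidates))
  kk <- paste0(GenomicRanges::seqnames(canonical), GenomicRanges::strand(canonical))
  minus <- as.character(GenomicRanges::strand(candidates)) == "-"
  candDonor <- ifelse(minus, .end0(candidates), .start0(candidates))
  candAcc <- ifelse(minus, .start0(candidates), .end0(candidates))
  kminus <- as.character(GenomicRanges::strand(canonical)) == "-"
  canDonor <- ifelse(kminus, .end0(canonical), .start0(canonical))
  canAcc <- ifelse(kminus, .start0(canonical), .end0(canonical))
  n <- length(candidates)
  near <- logical(n); dd <- rep(NA_integer_, n); da <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- which(kk == cc[i])
    if (length(j) == 0L) next
    d1 <- abs(canDonor[j] - candDonor[i])
    d2 <- abs(canAcc[j] - candAcc[i])
    best <- which.min(pmax(d1, d2))
    dd[i] <- d1[best]; da[i] <- d2[best]
    near[i] <- any(d1 <= maxDist & d2 <= maxDist)
  }
  S4Vectors::DataFrame(near_canonical = near, donor_dist = dd,
                       acceptor_dist = da)
}

#' Longest exonic homopolymer run adjacent to the splice sites
#'
#' Measures the single-base run starting at the exonic base immediately
#' adjacent to each splice site and extending away from the intron; the
#' reported value is the larger of the two ends.
#'
#' @param genome named \code{DNAStringSet}.
#' @param junctions \code{GRanges} of junctions.
#' @param minRun run length (nt) at or above which the junction is flagged.
#' @param maxScan how far into the exon the run is followed (nt).
#' @return \code{DataFrame} with integer \code{homopolymer_run} and logical
#'   \code{homopolymer_flag}.
#' @export
homopolymerRun <- function(genome, junctions, minRun = 5L, maxScan = 50L) {
  .assertGenome(genome)
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  runLen <- function(seq) {
    if (nchar(seq) == 0L) return(0L)
    ch <- strsplit(seq, "")[[1L]]
    run <- cumsum(ch != ch[1L]) == 0L
    sum(run)
  }
  out <- vapply(seq_along(junctions), function(i) {
    # exonic flank left of the intron, read away from the site
    lo <- max(0L, s0[i] - maxScan)
    leftFlank <- .getSeq0(genome, chrom[i], lo, s0[i])
    left <- runLen(paste(rev(strsplit(leftFlank, "")[[1L]]), collapse = ""))
    # exonic flank right of the intron
    hi <- min(len[i], e0[i] + maxScan)
    right <- runLen(.getSeq0(genome, chrom[i], e0[i], hi))
    max(left, right)
  }, integer(1))
  S4Vectors::DataFrame(homopolymer_run = out,
                       homopolymer_flag = out >= minRun)
}

#' GC fraction of a junction region
#'
#' (G + C) / (A + C + G + T) over the intron (default) or the intron plus
#' flanks; N bases are excluded from the denominator.
#'
#' @param genome named \code{DNAStringSet}.
#' @param junctions \code{GRanges} of junctions.
#' @param flank additional exonic flank (nt) on each side (0 = intron only).
#' @return numeric vector of GC fractions (error on an all-N region).
#' @export
gcFraction <- function(genome, junctions, flank = 0L) {
  .assertGenome(genome)
  s0 <- pmax(0L, .start0(junctions) - flank)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  e0 <- pmin(len, .end0(junctions) + flank)
  seqs <- Biostrings::DNAStringSet(.getSeq0(genome, chrom, s0, e0))
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  denom <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(denom == 0))
    stop("GC fraction undefined: region contains no unambiguous bases")
  rowSums(freq[, c("C", "G"), drop = FALSE]) / denom
}

#' Partition non-U2/U12 candidates into artifact signatures
#'
#' Candidates near (both ends within \code{maxDist} nt of) a canonical
#' junction are split by the presence of an adjacent exonic homopolymer run
#' (\code{NEAR_CANONICAL_HOMOPOLYMER} vs \code{NEAR_CANONICAL_OTHER});
#' isolated candidates with a long direct repeat or high intronic GC are
#' \code{TEMPLATE_SWITCH_LIKE} (template-switching signature); the remainder
#' is \code{UNEXPLAINED}. All measurements are reported raw so users can
#' re-threshold.
#'
#' @param candidates non-U2/U12 candidates (\code{GRanges}).
#' @param canonical canonical junction set (\code{GRanges}).
#' @param genome named \code{DNAStringSet}.
#' @param maxDist near-canonical per-end distance (nt).
#' @param minRun homopolymer run threshold (nt).
#' @param repeatMin direct-repeat length (nt) for the template-switch call.
#' @param gcMin intronic GC fraction for the template-switch call.
#' @param maxShift search range for the direct repeat (nt).
#' @return \code{DataFrame}: \code{partition}, \code{near_canonical},
#'   \code{donor_dist}, \code{acceptor_dist}, \code{homopolymer_run},
#'   \code{direct_repeat_length}, \code{gc_fraction}.
#' @export
partitionArtifacts <- function(candidates, canonical, genome, maxDist = 10L,
                               minRun = 5L, repeatMin = 6L, gcMin = 0.6,
                               maxShift = 30L) {
  near <- nearCanonical(candidates, canonical, maxDist)
  hp <- homopolymerRun(genome, candidates, minRun)
  gc <- gcFraction(genome, candidates)
  rep_len <- vapply(seq_along(candidates), function(i) {
    enumeratePlacements(genome, candidates[i], maxShift)@directRepeatLength
  }, integer(1))
  partition <- ifelse(near$near_canonical,
                      ifelse(hp$homopolymer_flag, "NEAR_CANONICAL_HOMOPOLYMER",
                             "NEAR_CANONICAL_OTHER"),
                      ifelse(rep_len >= repeatMin | gc >= gcMin,
                             "TEMPLATE_SWITCH_LIKE", "UNEXPLAINED"))
  S4Vectors::DataFrame(partition = partition,
                       near_canonical = near$near_canonical,
                       donor_dist = near$donor_dist,
                       acceptor_dist = near$acceptor_dist,
                       homopolymer_run = hp$homopolymer_run,
                       direct_repeat_length = rep_len,
                       gc_fraction = gc)
}
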