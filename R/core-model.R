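#' Read a reference genome from FASTA
#'
#' Loads a multi-record FASTA file into a named \code{DNAStringSet}. Bases are
#' uppercased on load; the fraction of soft-masked (lowercase) bases per
#' sequence is retained in the \code{masked_fraction} metadata column so that
#' masking state can be reported, but it is never used by any filter.
#' Chromosome names are taken verbatim from the FASTA headers (first word);
#' no "chr" normalisation is applied.
#'
#' @param path path to a FASTA file (may be line-wrapped).
#' @return a named \code{DNAStringSet}, one element per sequence.
#' @export
readGenome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  chr <- as.character(raw)
  nlow <- vapply(gregexpr("[acgtn]", chr), function(m) {
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1))
  genome <- Biostrings::DNAStringSet(toupper(chr))
  names(genome) <- names(raw)
  S4Vectors::mcols(genome)$masked_fraction <- nlow / Biostrings::width(genome)
  genome
}

#' Construct a set of splice junctions
#'
#' Builds a \code{GRanges} of intron intervals from 0-based half-open
#' coordinates, the convention used by all of the package's file interfaces
#' (BED tracks and junction TSV tables). \code{start} is the first intronic
#' base and \code{end} is one past the last intronic base, so the intron
#' length is \code{end - start}. Intron lengths down to 1 nt are accepted.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open intron interval.
#' @param strand "+" or "-" per junction.
#' @param ... further per-junction metadata columns (e.g. per-source support
#'   or per-sample coverage), recycled as by \code{DataFrame}.
#' @return a \code{GRanges} of introns with any supplied metadata columns.
#' @export
junctionRanges <- function(chrom, start, end, strand, ...) {
  if (any(end <= start))
    stop("junctions must satisfy end > start (intron length >= 1)")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = .checkStrand(strand))
  extra <- S4Vectors::DataFrame(...)
  if (ncol(extra) > 0L) S4Vectors::mcols(gr) <- extra
  gr
}

#' Terminal dinucleotides of introns
#'
#' Extracts the donor (intron 5' end) and acceptor (intron 3' end)
#' dinucleotides in transcript orientation. On the minus strand the genomic
#' end of the intron is the donor and both 2-mers are reverse-complemented.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param junctions a \code{GRanges} of introns (see \code{junctionRanges}).
#' @return a \code{DataFrame} with character columns \code{donor} and
#'   \code{acceptor}.
#' @export
extractDinucleotides <- function(genome, junctions) {
  .assertGenome(genome)
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  if (any(e0 - s0 < 2L))
    stop("degenerate intron: dinucleotide extraction needs intron length >= 2")
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  left <- .getSeq0(genome, chrom, s0, s0 + 2L)
  right <- .getSeq0(genome, chrom, e0 - 2L, e0)
  minus <- as.character(GenomicRanges::strand(junctions)) == "-"
  donor <- ifelse(minus, .revcomp(right), left)
  acceptor <- ifelse(minus, .revcomp(left), right)
  S4Vectors::DataFrame(donor = donor, acceptor = acceptor)
}

CANONICAL_PAIRS <- c("GT-AG", "GC-AG", "AT-AC")

#' Canonical / non-canonical dinucleotide taxonomy
#'
#' A junction is canonical iff its donor-acceptor pair is GT-AG, GC-AG or
#' AT-AC; every other pair is a non-canonical candidate. Pairs containing N
#' are never called canonical and are flagged ambiguous.
#'
#' @param donor,acceptor character vectors of 2-mers (transcript orientation).
#' @return a \code{DataFrame} with columns \code{category}
#'   ("CANONICAL"/"NONCANONICAL_CANDIDATE"), \code{subtype} (the canonical
#'   pair, or NA), and logical \code{ambiguous_base}.
#' @export
categorizeDinucleotides <- function(donor, acceptor) {
  pair <- paste0(donor, "-", acceptor)
  amb <- grepl("N", pair, fixed = TRUE)
  canonical <- pair %in% CANONICAL_PAIRS & !amb
  S4Vectors::DataFrame(
    category = ifelse(canonical, "CANONICAL", "NONCANONICAL_CANDIDATE"),
    subtype = ifelse(canonical, pair, NA_character_),
    ambiguous_base = amb)
}
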