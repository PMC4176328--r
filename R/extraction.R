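#' Extraction and filtering parameters
#'
#' Bundles the thresholds of the ab initio junction filters. Defaults follow
#' the pipeline's published settings: gapped RNA-seq alignments contribute
#' only with anchors of at least 8 nt, cDNA/EST alignments need anchors of at
#' least 15 nt without mismatches, a junction is present in a source when at
#' least 3 distinct supporting sequences are seen, and it must be present in
#' at least 2 independent data sources.
#'
#' @param minAnchorRnaseq minimum anchor (nt) for RNA-seq gapped alignments.
#' @param minAnchorEst minimum anchor (nt) for cDNA/EST alignments.
#' @param maxMismatchesEst maximum mismatches allowed for an EST alignment.
#' @param minSupport distinct supporting sequences needed for presence in one
#'   source.
#' @param minSources number of sources a junction must be present in.
#' @param dustThreshold DUST low-complexity score above which a flank is
#'   flagged.
#' @param dustWindow DUST window length (nt).
#' @param anchorSpan exonic window (nt) each side of the intron treated as the
#'   read footprint by the SNP/indel filter.
#' @return a list of class \code{extractionConfig}.
#' @export
extractionConfig <- function(minAnchorRnaseq = 8L, minAnchorEst = 15L,
                             maxMismatchesEst = 0L, minSupport = 3L,
                             minSources = 2L, dustThreshold = 2.0,
                             dustWindow = 64L, anchorSpan = 25L) {
  cfg <- list(minAnchorRnaseq = as.integer(minAnchorRnaseq),
              minAnchorEst = as.integer(minAnchorEst),
              maxMismatchesEst = as.integer(maxMismatchesEst),
              minSupport = as.integer(minSupport),
              minSources = as.integer(minSources),
              dustThreshold = dustThreshold,
              dustWindow = as.integer(dustWindow),
              anchorSpan = as.integer(anchorSpan))
  if (any(unlist(cfg) < 0)) stop("all extraction thresholds must be >= 0")
  structure(cfg, class = "extractionConfig")
}

.junctionKey <- function(gr) {
  if (length(gr) == 0L) return(character(0))
  paste0(GenomicRanges::seqnames(gr), ":", .start0(gr), "-", .end0(gr),
         "(", GenomicRanges::strand(gr), ")")
}

#' Derive supported junctions from gapped alignments
#'
#' Reads gapped alignments (SAM or BAM; skipped-region N operations mark
#' candidate introns) and emits one junction per distinct gap. An alignment
#' contributes support to a gap only when both flanking aligned blocks reach
#' the mode's minimum anchor length; support counts distinct read sequences,
#' not alignments, so PCR duplicates collapse. In \code{mode = "est"} the
#' alignment must additionally carry \code{NM == 0} (no mismatches).
#' Secondary and supplementary alignments are excluded.
#'
#' @param file path to a SAM or BAM file of gapped alignments.
#' @param config an \code{\link{extractionConfig}}.
#' @param sourceLabel label identifying the data source.
#' @param mode "rnaseq" (anchor >= \code{minAnchorRnaseq}) or "est"
#'   (anchor >= \code{minAnchorEst}, no mismatches).
#' @return a \code{GRanges} of junctions with metadata columns \code{support}
#'   (distinct supporting sequences) and \code{source}.
#' @export
junctionsFromAlignments <- function(file, config = extractionConfig(),
                                    sourceLabel = "sample",
                                    mode = c("rnaseq", "est")) {
  mode <- match.arg(mode)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param, use.names = TRUE)
  minAnchor <- if (mode == "est") config$minAnchorEst else config$minAnchorRnaseq
  if (mode == "est") {
    nm <- S4Vectors::mcols(gal)$NM
    if (anyNA(nm)) stop("EST mode requires the NM tag on every alignment")
    gal <- gal[nm <= config$maxMismatchesEst]
  }
  emptySet <- function() {
    junctionRanges(character(0), integer(0), integer(0), character(0),
                   support = integer(0), source = character(0))
  }
  if (length(gal) == 0L) return(emptySet())

  blocks <- GenomicAlignments::grglist(gal)  # aligned blocks, N gaps split
  nb <- S4Vectors::elementNROWS(blocks)
  gapped <- which(nb >= 2L)
  rows <- list()
  for (i in gapped) {
    b <- blocks[[i]]
    w <- GenomicRanges::width(b)
    st <- GenomicRanges::end(b)[-length(b)]       # last exonic base (1-based)
    en <- GenomicRanges::start(b)[-1L] - 1L       # base before next block
    ok <- w[-length(w)] >= minAnchor & w[-1L] >= minAnchor & en > st
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gal)[i]),
      start0 = st[ok], end0 = en[ok],
      strand = as.character(GenomicRanges::strand(gal)[i]),
      seq = as.character(S4Vectors::mcols(gal)$seq[i]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(emptySet())
  tab <- do.call(rbind, rows)
  key <- paste0(tab$chrom, ":", tab$start0, "-", tab$end0, "(", tab$strand, ")")
  support <- vapply(split(tab$seq, key), function(s) length(unique(s)), integer(1))
  first <- tab[match(unique(key), key), , drop = FALSE]
  jr <- junctionRanges(first$chrom, first$start0, first$end0, first$strand,
                       support = as.integer(support[unique(key)]),
                       source = sourceLabel)
  sort(jr)
}

#' Merge junction sets across data sources
#'
#' A junction is retained iff it reaches \code{minSupport} distinct
#' supporting sequences in at least \code{minSources} sources; per-source
#' support is never pooled for the presence test. Sources coming from the
#' same individual must be collapsed by the caller beforehand.
#'
#' @param junctionSets named list of \code{GRanges}, one per source, each with
#'   a \code{support} metadata column; names are the source labels. A single
#'   already-merged \code{GRanges} (with \code{support.<label>} columns) is
#'   also accepted and is split back into per-source sets first.
#' @param config an \code{\link{extractionConfig}}.
#' @return a \code{GRanges} with one \code{support.<label>} column per source
#'   (0 where absent) and \code{n_sources_present}.
#' @export
mergeSources <- function(junctionSets, config = extractionConfig()) {
  if (methods::is(junctionSets, "GRanges")) {
    mc <- S4Vectors::mcols(junctionSets)
    scols <- grep("^support\\.", colnames(mc), value = TRUE)
    junctionSets <- lapply(scols, function(cn) {
      gr <- junctionSets
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(support = mc[[cn]])
      gr[mc[[cn]] > 0L]
    })
    names(junctionSets) <- sub("^support\\.", "", scols)
  }
  labels <- names(junctionSets)
  if (is.null(labels) || anyDuplicated(labels))
    stop("junctionSets must be a uniquely named list (one entry per source)")
  keys <- lapply(junctionSets, .junctionKey)
  allKeys <- unique(unlist(keys, use.names = FALSE))
  supp <- sapply(seq_along(junctionSets), function(i) {
    s <- integer(length(allKeys))
    s[match(keys[[i]], allKeys)] <- S4Vectors::mcols(junctionSets[[i]])$support
    s
  })
  supp <- matrix(supp, nrow = length(allKeys),
                 dimnames = list(NULL, paste0("support.", labels)))
  present <- rowSums(supp >= config$minSupport)
  keep <- present >= config$minSources
  # rebuild coordinates from the keys
  m <- regmatches(allKeys, regexec("^(.*):(\\d+)-(\\d+)\\(([+-])\\)$", allKeys))
  coords <- do.call(rbind, m)
  gr <- junctionRanges(coords[, 2L], as.integer(coords[, 3L]),
                       as.integer(coords[, 4L]), coords[, 5L])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(supp,
    n_sources_present = as.integer(present), check.names = FALSE)
  sort(gr[keep])
}

#' Read variants from a VCF file
#'
#' @param path VCF file path.
#' @return a \code{GRanges} of variant loci (indels span their REF allele).
#' @export
readVariants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  GenomicRanges::granges(gr)
}

.junctionFootprint <- function(junctions, anchorSpan, genome = NULL) {
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  lo <- pmax(0L, s0 - anchorSpan)
  # donor dinuc + acceptor dinuc + both exonic anchor windows, per junction
  GenomicRanges::GRangesList(lapply(seq_along(junctions), function(i) {
    GenomicRanges::GRanges(chrom[i], IRanges::IRanges(
      start = c(s0[i] + 1L, e0[i] - 1L, lo[i] + 1L, e0[i] + 1L),
      end = c(s0[i] + 2L, e0[i], s0[i], e0[i] + anchorSpan)))
  }))
}

#' Discard non-canonical candidates spanning known variants
#'
#' Alignments over SNPs or indels can fake non-canonical junctions. A
#' non-canonical candidate is discarded when any variant overlaps its
#' terminal dinucleotides or its exonic anchor windows; canonical junctions
#' pass untouched.
#'
#' @param junctions \code{GRanges} of junctions.
#' @param variants \code{GRanges} of variants (see \code{\link{readVariants}}).
#' @param genome genome for dinucleotide categorisation.
#' @param config an \code{\link{extractionConfig}} (supplies
#'   \code{anchorSpan}).
#' @return list with \code{kept} and \code{discarded} (\code{GRanges}; the
#'   latter carries a \code{reason} column).
#' @export
filterVariantSpanning <- function(junctions, variants, genome,
                                  config = extractionConfig()) {
  cat <- categorizeDinucleotides2(genome, junctions)
  fp <- .junctionFootprint(junctions, config$anchorSpan)
  hits <- IRanges::overlapsAny(fp, variants)
  drop <- cat$category == "NONCANONICAL_CANDIDATE" & hits
  discarded <- junctions[drop]
  if (length(discarded))
    S4Vectors::mcols(discarded)$reason <- "variant_spanning"
  list(kept = junctions[!drop], discarded = discarded)
}

# categorize directly from genome + junctions
#' @rdname categorizeDinucleotides
#' @param genome a named \code{DNAStringSet}.
#' @param junctions a \code{GRanges} of introns.
#' @export
categorizeDinucleotides2 <- function(genome, junctions) {
  dn <- extractDinucleotides(genome, junctions)
  cbind(dn, categorizeDinucleotides(dn$donor, dn$acceptor))
}

#' DUST low-complexity score
#'
#' Classic triplet-based low-complexity score: within each sliding window the
#' overlapping 3-mers are counted and the score is
#' \eqn{\sum_t c_t (c_t - 1) / 2} divided by (window length - 3). The
#' reported score is the maximum over all windows. A 64-nt homopolymer scores
#' ~31; random sequence scores well below 1.
#'
#' @param sequence a character string of nucleotides (length >= 3).
#' @param window sliding window length (nt).
#' @param word word size (fixed at 3 for the classic score).
#' @return numeric score.
#' @export
dustScore <- function(sequence, window = 64L, word = 3L) {
  n <- nchar(sequence)
  if (n < word) stop("sequence shorter than DUST word size: score undefined")
  starts <- seq_len(max(1L, n - word + 1L))
  trip <- substring(sequence, starts, starts + word - 1L)
  winStarts <- seq_len(max(1L, length(trip) - (window - word)))
  best <- 0
  for (ws in winStarts) {
    we <- min(length(trip), ws + window - word)
    cc <- table(trip[ws:we])
    L <- (we - ws + 1L) + word - 1L  # window length in nt
    sc <- sum(cc * (cc - 1) / 2) / max(1L, L - word)
    if (sc > best) best <- sc
  }
  best
}

#' Discard junctions flanked by low-complexity sequence
#'
#' Applies \code{\link{dustScore}} to the two exonic anchor windows and the
#' two intronic terminus windows of each junction (each of length
#' \code{dustWindow}, truncated at chromosome bounds and at the intron
#' midpoint); the junction is discarded when any window exceeds
#' \code{dustThreshold}.
#'
#' @inheritParams filterVariantSpanning
#' @return list with \code{kept} and \code{discarded}.
#' @export
filterLowComplexity <- function(junctions, genome,
                                config = extractionConfig()) {
  .assertGenome(genome)
  w <- config$dustWindow
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  flagged <- vapply(seq_along(junctions), function(i) {
    regions <- rbind(
      c(max(0L, s0[i] - w), s0[i]),                      # 5' exonic anchor
      c(e0[i], min(len[i], e0[i] + w)),                  # 3' exonic anchor
      c(s0[i], min(s0[i] + w, e0[i])),                   # intron 5' terminus
      c(max(e0[i] - w, s0[i]), e0[i]))                   # intron 3' terminus
    for (r in seq_len(nrow(regions))) {
      if (regions[r, 2L] - regions[r, 1L] < 3L) next
      seq <- .getSeq0(genome, chrom[i], regions[r, 1L], regions[r, 2L])
      if (dustScore(seq, window = w) > config$dustThreshold) return(TRUE)
    }
    FALSE
  }, logical(1))
  discarded <- junctions[flagged]
  if (length(discarded)) S4Vectors::mcols(discarded)$reason <- "low_complexity"
  list(kept = junctions[!flagged], discarded = discarded)
}

#' Discard junctions whose anchors overlap repeat intervals
#'
#' Replaces a licensed repeat-library screen with a user-supplied BED of
#' repeat intervals: a junction whose exonic anchor windows or terminal
#' dinucleotides overlap any interval is discarded.
#'
#' @param junctions \code{GRanges} of junctions.
#' @param repeats \code{GRanges} of repeat intervals (e.g.
#'   \code{rtracklayer::import} of a BED file).
#' @param config an \code{\link{extractionConfig}}.
#' @return list with \code{kept} and \code{discarded}.
#' @export
filterRepeats <- function(junctions, repeats, config = extractionConfig()) {
  fp <- .junctionFootprint(junctions, config$anchorSpan)
  drop <- IRanges::overlapsAny(fp, repeats)
  discarded <- junctions[drop]
  if (length(discarded)) S4Vectors::mcols(discarded)$reason <- "repeat_overlap"
  list(kept = junctions[!drop], discarded = discarded)
}

.applyMapping <- function(junctions, mapping) {
  if (is.null(mapping)) {
    return(list(mapped = junctions, unmapped = junctions[integer(0)],
                idx = seq_along(junctions)))
  }
  srcKey <- paste0(mapping$chrom, ":", mapping$start, "-", mapping$end,
                   "(", mapping$strand, ")")
  idx <- match(.junctionKey(junctions), srcKey)
  ok <- !is.na(idx)
  mapped <- junctionRanges(mapping$target_chrom[idx[ok]],
                           mapping$target_start[idx[ok]],
                           mapping$target_end[idx[ok]],
                           mapping$target_strand[idx[ok]])
  S4Vectors::mcols(mapped) <- S4Vectors::mcols(junctions[ok])
  list(mapped = mapped, unmapped = junctions[!ok], idx = which(ok))
}

#' Diploid-concordance filter
#'
#' For a sample aligned separately to its maternal and paternal haplotype
#' genomes, a junction is kept iff, after translating both haplotype
#' coordinate systems into a common one, the identical interval is present
#' with at least \code{minSupport} supporting alignments in \emph{both}
#' haplotypes. Junctions without a mapping are excluded with reason
#' "unmapped".
#'
#' @param maternal,paternal per-haplotype \code{GRanges} with \code{support}.
#' @param maternalMap,paternalMap coordinate mappings (see
#'   \code{\link{readCoordinateMapping}}); \code{NULL} means coordinates are
#'   already common.
#' @param config an \code{\link{extractionConfig}}.
#' @return list with \code{kept} (common coordinates, columns
#'   \code{support.maternal}/\code{support.paternal}) and \code{excluded}.
#' @export
diploidConcordance <- function(maternal, paternal, maternalMap = NULL,
                               paternalMap = NULL,
                               config = extractionConfig()) {
  mm <- .applyMapping(maternal, maternalMap)
  pp <- .applyMapping(paternal, paternalMap)
  mKey <- .junctionKey(mm$mapped); pKey <- .junctionKey(pp$mapped)
  common <- intersect(mKey, pKey)
  mi <- match(common, mKey); pi <- match(common, pKey)
  ms <- S4Vectors::mcols(mm$mapped)$support[mi]
  ps <- S4Vectors::mcols(pp$mapped)$support[pi]
  ok <- ms >= config$minSupport & ps >= config$minSupport
  kept <- mm$mapped[mi][ok]
  S4Vectors::mcols(kept) <- S4Vectors::DataFrame(
    support.maternal = ms[ok], support.paternal = ps[ok])
  excluded <- c(GenomicRanges::granges(mm$unmapped),
                GenomicRanges::granges(pp$unmapped),
                GenomicRanges::granges(mm$mapped[mi][!ok]))
  list(kept = sort(kept), excluded = excluded)
}

#' Build a junction-library FASTA
#'
#' Writes one record per junction: \code{flankLen} exonic nt upstream of the
#' intron concatenated with \code{flankLen} exonic nt downstream, intron
#' excised — the spliced sequence a junction-spanning read would produce.
#' Records are named \code{<chrom>:<start>-<end>(<strand>)} with 0-based
#' half-open coordinates. Junctions whose flanks would run past a chromosome
#' end are skipped with a warning (never truncated).
#'
#' @param genome named \code{DNAStringSet}.
#' @param junctions \code{GRanges} of junctions.
#' @param flankLen exonic flank length (nt); the conventional choice is
#'   read length minus the minimum anchor.
#' @param file optional path; when given the library is written as FASTA.
#' @return a \code{DNAStringSet} (invisibly when \code{file} is given).
#' @export
buildJunctionLibrary <- function(genome, junctions, flankLen, file = NULL) {
  .assertGenome(genome)
  stopifnot(flankLen >= 1L)
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  ok <- s0 - flankLen >= 0L & e0 + flankLen <= len
  if (any(!ok))
    warning(sum(!ok), " junction(s) too close to a chromosome edge; skipped")
  idx <- which(ok)
  seqs <- paste0(.getSeq0(genome, chrom[idx], s0[idx] - flankLen, s0[idx]),
                 .getSeq0(genome, chrom[idx], e0[idx], e0[idx] + flankLen))
  lib <- Biostrings::DNAStringSet(seqs)
  names(lib) <- .junctionKey(junctions[idx])
  if (!is.null(file)) {
    Biostrings::writeXStringSet(lib, file)
    return(invisible(lib))
  }
  lib
}
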