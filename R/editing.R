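#' Read a base-level pileup table
#'
#' Expected columns: \code{chrom}, \code{pos} (0-based genomic position),
#' \code{strand}, \code{countA}, \code{countC}, \code{countG}, \code{countT}
#' — counts on the genomic plus strand.
#'
#' @param path TSV file path.
#' @return a data.frame.
#' @export
readPileup <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "countA", "countC", "countG", "countT")
  if (!all(need %in% colnames(tab)))
    stop("pileup table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' A-to-I editing evidence at an adenosine
#'
#' On the transcript strand, an adenosine with at least \code{minReads}
#' reads supporting G and a G fraction (G / (A + G)) of at least
#' \code{minFraction} passes as edited. A queried position whose reference
#' base is not A is not editable and never passes.
#'
#' @param countA,countG transcript-strand read counts supporting A and G.
#' @param refBase transcript-strand reference base at the position.
#' @param minReads minimum G-supporting reads.
#' @param minFraction minimum editing fraction G / (A + G).
#' @return \code{DataFrame} with \code{fraction} and logical \code{passes}.
#' @export
detectEditing <- function(countA, countG, refBase = "A", minReads = 3L,
                          minFraction = 0.2) {
  stopifnot(all(countA >= 0), all(countG >= 0))
  tot <- countA + countG
  fraction <- ifelse(tot > 0, countG / tot, 0)
  passes <- refBase == "A" & countG >= minReads & fraction >= minFraction
  S4Vectors::DataFrame(fraction = fraction, passes = passes)
}

#' Recode edited splice dinucleotides
#'
#' Each adenosine of the donor/acceptor pair with passing A>G evidence is
#' replaced by G (inosine is read as guanosine by both the spliceosome and
#' the sequencer). Evidence at a non-A position is a contract error.
#'
#' @param donor,acceptor character vectors of 2-mers.
#' @param passes logical matrix with one row per junction and columns
#'   \code{donor1, donor2, acceptor1, acceptor2} (or a length-4 vector for a
#'   single pair): which positions carry passing evidence.
#' @return \code{DataFrame} with \code{donor}, \code{acceptor} (recoded) and
#'   logical \code{became_canonical} (the recoded pair is GT-AG, GC-AG or
#'   AT-AC).
#' @export
recodeEdited <- function(donor, acceptor, passes) {
  if (is.vector(passes)) passes <- matrix(passes, nrow = 1L)
  stopifnot(ncol(passes) == 4L, nrow(passes) == length(donor))
  quad <- matrix(unlist(strsplit(paste0(donor, acceptor), ""),
                        use.names = FALSE), ncol = 4L, byrow = TRUE)
  if (any(passes & quad != "A"))
    stop("editing evidence at a non-adenosine position")
  quad[passes] <- "G"
  newDonor <- paste0(quad[, 1L], quad[, 2L])
  newAcceptor <- paste0(quad[, 3L], quad[, 4L])
  S4Vectors::DataFrame(
    donor = newDonor, acceptor = newAcceptor,
    became_canonical = paste0(newDonor, "-", newAcceptor) %in% CANONICAL_PAIRS)
}

#' Editing evidence and recoding for junction dinucleotides
#'
#' For each junction, the four terminal-dinucleotide positions are looked up
#' in the pileup. For minus-strand junctions the genomic T>C counts are
#' translated to transcript-strand A>G. Positions whose transcript base is
#' not adenosine are skipped; an adenosine without a pileup row is reported
#' as \code{no_data} (distinct from negative evidence).
#'
#' @param genome named \code{DNAStringSet}.
#' @param junctions \code{GRanges} of junctions.
#' @param pileup pileup data.frame (see \code{\link{readPileup}}).
#' @param minReads,minFraction evidence thresholds
#'   (see \code{\link{detectEditing}}).
#' @return \code{DataFrame} with original and recoded dinucleotides,
#'   \code{became_canonical}, \code{n_passing} and logical \code{no_data}
#'   (some adenosine lacked a pileup row).
#' @export
annotateEditing <- function(genome, junctions, pileup, minReads = 3L,
                            minFraction = 0.2) {
  dn <- extractDinucleotides(genome, junctions)
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  minus <- as.character(GenomicRanges::strand(junctions)) == "-"
  pileKey <- paste0(pileup$chrom, ":", pileup$pos)
  n <- length(junctions)
  passes <- matrix(FALSE, n, 4L)
  noData <- logical(n)
  for (i in seq_len(n)) {
    # genomic 0-based positions of donor1, donor2, acceptor1, acceptor2
    gpos <- if (minus[i]) c(e0[i] - 1L, e0[i] - 2L, s0[i] + 1L, s0[i])
            else c(s0[i], s0[i] + 1L, e0[i] - 2L, e0[i] - 1L)
    bases <- strsplit(paste0(dn$donor[i], dn$acceptor[i]), "")[[1L]]
    for (p in which(bases == "A")) {
      row <- match(paste0(chrom[i], ":", gpos[p]), pileKey)
      if (is.na(row)) { noData[i] <- TRUE; next }
      a <- if (minus[i]) pileup$countT[row] else pileup$countA[row]
      g <- if (minus[i]) pileup$countC[row] else pileup$countG[row]
      passes[i, p] <- detectEditing(a, g, "A", minReads, minFraction)$passes
    }
  }
  rec <- recodeEdited(dn$donor, dn$acceptor, passes)
  S4Vectors::DataFrame(
    donor = dn$donor, acceptor = dn$acceptor,
    edited_donor = rec$donor, edited_acceptor = rec$acceptor,
    became_canonical = rec$became_canonical,
    n_passing = rowSums(passes), no_data = noData)
}
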