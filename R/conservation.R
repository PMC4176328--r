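#' Read a precomputed coordinate mapping
#'
#' A TSV produced by an external lift-over (or by the simulator) with
#' columns \code{chrom, start, end, strand, target_chrom, target_start,
#' target_end, target_strand}, all intervals 0-based half-open. Mappings are
#' single-valued per source interval; unmapped intervals are simply absent.
#'
#' @param path TSV file path.
#' @return a data.frame.
#' @export
readCoordinateMapping <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "target_chrom", "target_start",
            "target_end", "target_strand")
  if (!all(need %in% colnames(tab)))
    stop("mapping table must have columns: ", paste(need, collapse = ", "))
  srcKey <- paste0(tab$chrom, ":", tab$start, "-", tab$end, "(", tab$strand, ")")
  if (anyDuplicated(srcKey))
    stop("mapping must be single-valued per source interval")
  if (any(tab$target_end <= tab$target_start))
    stop("inconsistent mapping: target interval inverted without strand flip")
  tab
}

#' Cross-species conservation status of junctions
#'
#' A junction is CONSERVED when its mapped coordinates are present in the
#' other species' junction set (extracted with the same pipeline rules) and
#' the splice-site dinucleotides read from the other genome are identical;
#' COORD_MATCH_DINUC_DIFF when the interval matches but the dinucleotides
#' differ; NOT_FOUND when the mapped interval is absent from the other set;
#' UNMAPPED when the mapping table has no record for the junction. "Same
#' coordinates" is exact interval equality after mapping, with no slack.
#'
#' @param junctions \code{GRanges} of junctions in the source genome.
#' @param genome source-species genome (named \code{DNAStringSet}).
#' @param mapping mapping data.frame (see
#'   \code{\link{readCoordinateMapping}}).
#' @param otherJunctions \code{GRanges} of the other species' junctions.
#' @param otherGenome the other species' genome.
#' @return \code{DataFrame} with \code{status}, the source dinucleotides and
#'   the other-species dinucleotides (NA where not applicable).
#' @export
conservationStatus <- function(junctions, genome, mapping, otherJunctions,
                               otherGenome) {
  dn <- extractDinucleotides(genome, junctions)
  mapped <- .applyMapping(junctions, mapping)
  n <- length(junctions)
  status <- rep("UNMAPPED", n)
  otherDonor <- otherAcceptor <- rep(NA_character_, n)
  if (length(mapped$idx)) {
    otherKey <- .junctionKey(otherJunctions)
    mKey <- .junctionKey(mapped$mapped)
    found <- mKey %in% otherKey
    status[mapped$idx] <- "NOT_FOUND"
    if (any(found)) {
      odn <- extractDinucleotides(otherGenome, mapped$mapped[found])
      ii <- mapped$idx[found]
      otherDonor[ii] <- odn$donor
      otherAcceptor[ii] <- odn$acceptor
      same <- odn$donor == dn$donor[ii] & odn$acceptor == dn$acceptor[ii]
      status[ii] <- ifelse(same, "CONSERVED", "COORD_MATCH_DINUC_DIFF")
    }
  }
  S4Vectors::DataFrame(status = status, donor = dn$donor,
                       acceptor = dn$acceptor, other_donor = otherDonor,
                       other_acceptor = otherAcceptor)
}
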