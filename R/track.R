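#' Junction identifier grammar
#'
#' A junction ID encodes the splice-site dinucleotides and the read
#' coverage: \code{"<donor>-<acceptor>[<coverage>]"}, e.g. \code{GA-AG[37]}.
#' An ASCII hyphen is emitted; \code{parseTrackId} also accepts the en-dash
#' used in print.
#'
#' @param donor,acceptor 2-mers.
#' @param coverage non-negative integer read coverage.
#' @return character vector of IDs.
#' @export
junctionId <- function(donor, acceptor, coverage) {
  stopifnot(all(coverage >= 0))
  paste0(donor, "-", acceptor, "[", as.integer(coverage), "]")
}

#' @rdname junctionId
#' @param id ID string to parse.
#' @return \code{parseTrackId}: a data.frame with \code{donor},
#'   \code{acceptor}, \code{coverage}.
#' @export
parseTrackId <- function(id) {
  re <- "^([ACGTN]{2})[-–]([ACGTN]{2})\\[([0-9]+)\\]$"
  m <- regmatches(id, regexec(re, id))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed junction ID: ", id[bad][1L])
  tab <- do.call(rbind, m)
  data.frame(donor = tab[, 2L], acceptor = tab[, 3L],
             coverage = as.integer(tab[, 4L]), stringsAsFactors = FALSE)
}

# 5-bin colour ramps; U2/U12-like greens get lighter with HIGHER score,
# non-U2/U12 reds get lighter with LOWER score; canonical is fixed grey.
.GREEN_RAMP <- c("0,90,0", "0,140,0", "60,180,60", "120,220,120", "180,255,180")
.RED_RAMP <- c("90,0,0", "150,0,0", "200,60,60", "230,120,120", "255,180,180")
.CANONICAL_RGB <- "80,80,80"

#' @rdname writeJunctionTrack
#' @export
trackColor <- function(class, score) {
  bin <- pmin(5L, pmax(1L, ceiling(score / 20)))
  bin[score == 0] <- 1L
  ifelse(class == "CANONICAL", .CANONICAL_RGB,
         ifelse(class == "U2U12_LIKE", .GREEN_RAMP[bin], .RED_RAMP[6L - bin]))
}

#' Write a genome-browser junction track (BED12)
#'
#' Junctions are drawn as an intron flanked by two 8-nt exon blocks; the
#' record name is the junction ID (\code{\link{junctionId}}); colours encode
#' the class and PWM score (greens for U2/U12-like, lighter with higher
#' similitude; reds for non-U2/U12, lighter with lower similitude; canonical
#' junctions in a fixed neutral grey). Coordinates are 0-based BED.
#'
#' @param junctions \code{GRanges} of junctions.
#' @param genome named \code{DNAStringSet} (for the ID dinucleotides).
#' @param class per-junction class: "CANONICAL", "U2U12_LIKE" or
#'   "NON_U2U12".
#' @param score per-junction PWM score (0-100).
#' @param coverage per-junction total read coverage.
#' @param file output path.
#' @param trackName name in the track header line.
#' @return the path, invisibly.
#' @export
writeJunctionTrack <- function(junctions, genome, class, score, coverage,
                               file, trackName = "spliceSieve") {
  if (length(class) != length(junctions) || anyNA(class))
    stop("every junction must carry a class")
  dn <- extractDinucleotides(genome, junctions)
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  ord <- order(as.character(GenomicRanges::seqnames(junctions)), s0)
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(junctions)),
    chromStart = s0 - 8L,
    chromEnd = e0 + 8L,
    name = junctionId(dn$donor, dn$acceptor, coverage),
    score = pmin(1000L, as.integer(round(score * 10))),
    strand = as.character(GenomicRanges::strand(junctions)),
    thickStart = s0 - 8L,
    thickEnd = e0 + 8L,
    itemRgb = trackColor(class, score),
    blockCount = 2L,
    blockSizes = "8,8",
    blockStarts = paste0("0,", e0 - s0 + 8L),
    stringsAsFactors = FALSE)[ord, ]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s" itemRgb="On"', trackName), con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' Re-ingest a junction track
#'
#' @param file a BED12 track written by \code{\link{writeJunctionTrack}}.
#' @return \code{GRanges} of junctions with \code{donor}, \code{acceptor},
#'   \code{coverage} and \code{itemRgb} metadata.
#' @export
readJunctionTrack <- function(file) {
  bed <- rtracklayer::import(file, format = "bed")
  s0 <- GenomicRanges::start(bed) - 1L + 8L
  e0 <- GenomicRanges::end(bed) - 8L
  ids <- parseTrackId(S4Vectors::mcols(bed)$name)
  junctionRanges(as.character(GenomicRanges::seqnames(bed)), s0, e0,
                 as.character(GenomicRanges::strand(bed)),
                 donor = ids$donor, acceptor = ids$acceptor,
                 coverage = ids$coverage,
                 itemRgb = S4Vectors::mcols(bed)$itemRgb)
}

#' Junction table TSV I/O
#'
#' Writes junctions as a TSV with 0-based half-open coordinates
#' (\code{chrom, start, end, strand}) followed by all metadata columns
#' (per-source support, per-sample coverage, scores, flags).
#'
#' @param junctions \code{GRanges} of junctions.
#' @param file file path.
#' @return \code{readJunctionTable} returns a \code{GRanges}.
#' @export
writeJunctionTable <- function(junctions, file) {
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(junctions)),
                    start = .start0(junctions), end = .end0(junctions),
                    strand = as.character(GenomicRanges::strand(junctions)),
                    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(junctions)
  if (ncol(mc) > 0L) tab <- cbind(tab, as.data.frame(mc, optional = TRUE))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeJunctionTable
#' @export
readJunctionTable <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  gr <- junctionRanges(tab$chrom, tab$start, tab$end, tab$strand)
  extra <- tab[, setdiff(colnames(tab), c("chrom", "start", "end", "strand")),
               drop = FALSE]
  if (ncol(extra) > 0L)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(extra, check.names = FALSE)
  gr
}
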