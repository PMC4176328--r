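SRE_CLASSES <- c("ESE", "ESS", "ISE", "ISS")

#' Construct a splicing-regulatory-element hexamer set
#'
#' SRE classes group into identity classes: exon-identity elements
#' (EIE = ESE + ISS) and intron-identity elements (IIE = ISE + ESS).
#'
#' @param hexamers character vector of 6-mers.
#' @param sreClass one of ESE, ESS, ISE, ISS.
#' @return a list of class \code{hexamerSet} with fields \code{hexamers},
#'   \code{sreClass}, \code{identityGroup}.
#' @export
hexamerSet <- function(hexamers, sreClass) {
  sreClass <- match.arg(sreClass, SRE_CLASSES)
  hexamers <- toupper(hexamers)
  if (any(nchar(hexamers) != 6L) || any(grepl("[^ACGT]", hexamers)))
    stop("hexamers must be 6-mers over A, C, G, T")
  structure(list(hexamers = unique(hexamers), sreClass = sreClass,
                 identityGroup = if (sreClass %in% c("ESE", "ISS")) "EIE"
                                 else "IIE"),
            class = "hexamerSet")
}

#' Read a hexamer list file
#'
#' Plain text: a header line naming the SRE class (optionally prefixed with
#' \code{#} or \code{>}), then one 6-mer per line.
#'
#' @param path file path.
#' @return a \code{\link{hexamerSet}}.
#' @export
readHexamerSet <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  cls <- toupper(sub("^[#>]+\\s*", "", lines[1L]))
  if (!cls %in% SRE_CLASSES)
    stop("header must name the SRE class (ESE/ESS/ISE/ISS), got: ", lines[1L])
  hexamerSet(lines[-1L], cls)
}

#' Pool hexamer sets into an identity group
#'
#' @param ... \code{hexamerSet} objects of the same identity group
#'   (EIE = ESE + ISS, IIE = ISE + ESS).
#' @return a list with \code{hexamers} and \code{identityGroup}.
#' @export
identityGroupSet <- function(...) {
  sets <- list(...)
  grp <- unique(vapply(sets, `[[`, character(1), "identityGroup"))
  if (length(grp) != 1L)
    stop("all sets must belong to one identity group (EIE or IIE)")
  structure(list(hexamers = unique(unlist(lapply(sets, `[[`, "hexamers"))),
                 sreClass = NA_character_, identityGroup = grp),
            class = "hexamerSet")
}

SRE_REGIONS <- c("five_exonic", "five_intronic", "three_intronic",
                 "three_exonic")

# transcript-oriented context around each splice site, window exonic +
# window intronic + `extra` nt beyond the 3' edge so hexamers starting at
# the last offsets are evaluable. Junctions whose context would cross a
# chromosome end are dropped (reported via attribute).
.siteContexts <- function(genome, junctions, window, extra = 5L) {
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  minus <- as.character(GenomicRanges::strand(junctions)) == "-"
  # genomic extents needed at each genomic end of the intron
  okLeft <- s0 - window - extra >= 0L & s0 + window + extra <= len
  okRight <- e0 - window - extra >= 0L & e0 + window + extra <= len
  ok <- okLeft & okRight
  idx <- which(ok)
  five <- three <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (!minus[i]) {
      five[k] <- .getSeq0(genome, chrom[i], s0[i] - window, s0[i] + window + extra)
      three[k] <- .getSeq0(genome, chrom[i], e0[i] - window, e0[i] + window + extra)
    } else {
      five[k] <- .revcomp(.getSeq0(genome, chrom[i], e0[i] - window - extra,
                                   e0[i] + window))
      three[k] <- .revcomp(.getSeq0(genome, chrom[i], s0[i] - window - extra,
                                    s0[i] + window))
    }
  }
  list(five = five, three = three, used = idx)
}

# start offsets (1-based within the context string) of set hexamers
.hexamerStarts <- function(contexts, hexamers) {
  if (length(contexts) == 0L) return(list())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(hexamers))
  lapply(contexts, function(sq) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(sq))
    sort(unique(unlist(Biostrings::startIndex(m), use.names = FALSE)))
  })
}

# per-junction logical occurrence matrices for the four 100-nt regions
.regionOccurrence <- function(genome, junctions, hexamers, window) {
  ctx <- .siteContexts(genome, junctions, window)
  nUsed <- length(ctx$used)
  occ <- lapply(SRE_REGIONS, function(r) matrix(FALSE, nUsed, window))
  names(occ) <- SRE_REGIONS
  fiveStarts <- .hexamerStarts(ctx$five, hexamers$hexamers)
  threeStarts <- .hexamerStarts(ctx$three, hexamers$hexamers)
  for (k in seq_len(nUsed)) {
    # five context: offsets 1..window exonic, window+1..2*window intronic
    st <- fiveStarts[[k]]
    ex <- st[st <= window]
    int <- st[st > window & st <= 2L * window] - window
    occ$five_exonic[k, ex] <- TRUE
    occ$five_intronic[k, int] <- TRUE
    # three context: offsets 1..window intronic, window+1..2*window exonic
    st <- threeStarts[[k]]
    int <- st[st <= window]
    ex <- st[st > window & st <= 2L * window] - window
    occ$three_intronic[k, int] <- TRUE
    occ$three_exonic[k, ex] <- TRUE
  }
  list(occ = occ, used = ctx$used)
}

#' Positional SRE hexamer density around splice sites
#'
#' For each of four 100-nt windows (5' exonic, 5' intronic, 3' intronic, 3'
#' exonic, transcript orientation) the raw density at an offset is the
#' fraction of junctions with a set-member hexamer starting at that offset.
#' The smoothed profile is a centered moving average of width \code{smooth}
#' (NA at the edges the average cannot cover). Junctions whose windows would
#' cross a chromosome end are skipped and the junction count adjusted.
#'
#' @param junctions \code{GRanges} of junctions.
#' @param genome named \code{DNAStringSet}.
#' @param hexamers a \code{\link{hexamerSet}} (or identity-group pool).
#' @param window window length (nt).
#' @param smooth smoothing width (nt).
#' @return a list of class \code{densityProfile}: per region a data.frame
#'   with \code{offset} (5'-exonic offsets are negative, counting toward the
#'   site), \code{raw}, \code{smoothed}; plus \code{junction_count}.
#' @export
positionalDensity <- function(junctions, genome, hexamers, window = 100L,
                              smooth = 10L) {
  if (length(junctions) == 0L) stop("positional density of an empty junction set")
  ro <- .regionOccurrence(genome, junctions, hexamers, window)
  nUsed <- length(ro$used)
  if (nUsed == 0L) stop("no junction had complete windows")
  smoother <- function(x) as.numeric(stats::filter(x, rep(1 / smooth, smooth),
                                                   sides = 2L))
  offsets <- list(five_exonic = seq.int(-window, -1L),
                  five_intronic = seq_len(window),
                  three_intronic = seq.int(-window, -1L),
                  three_exonic = seq_len(window))
  profiles <- lapply(SRE_REGIONS, function(r) {
    raw <- colMeans(ro$occ[[r]])
    data.frame(offset = offsets[[r]], raw = raw, smoothed = smoother(raw))
  })
  names(profiles) <- SRE_REGIONS
  structure(c(profiles, list(junction_count = nUsed, smooth = smooth)),
            class = "densityProfile")
}

#' Pearson chi-squared on a 2 x 2 start/non-start table
#'
#' Shared statistical core of \code{\link{compareDensity}}: rows are the two
#' groups, columns are hexamer-start and non-start position counts. 1 df, no
#' continuity correction.
#'
#' @param hitsA,totalA hexamer-start count and total positions in group A.
#' @param hitsB,totalB same for group B.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{table}.
#' @export
densityChiSquared <- function(hitsA, totalA, hitsB, totalB) {
  tab <- rbind(A = c(hits = hitsA, nonhits = totalA - hitsA),
               B = c(hits = hitsB, nonhits = totalB - hitsB))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared undefined: zero marginal in the contingency table")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 5))
    warning("expected count below 5; chi-squared approximation may be poor")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab)
}

#' Compare SRE density between two junction groups
#'
#' Builds the 2 x 2 table (group x hexamer-start vs non-start positions,
#' summed over the region) and applies Pearson's chi-squared test with 1
#' degree of freedom and no continuity correction. An expected count below 5
#' triggers a small-sample warning.
#'
#' @param junctionsA,junctionsB the two junction groups (\code{GRanges}).
#' @param genome named \code{DNAStringSet}.
#' @param hexamers a \code{\link{hexamerSet}}.
#' @param region one of \code{"five_exonic", "five_intronic",
#'   "three_intronic", "three_exonic"}.
#' @param window window length (nt).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{table}.
#' @export
compareDensity <- function(junctionsA, junctionsB, genome, hexamers,
                           region = "five_intronic", window = 100L) {
  region <- match.arg(region, SRE_REGIONS)
  count <- function(j) {
    ro <- .regionOccurrence(genome, j, hexamers, window)
    hits <- sum(ro$occ[[region]])
    total <- length(ro$used) * window
    c(hits = hits, nonhits = total - hits)
  }
  a <- count(junctionsA); b <- count(junctionsB)
  densityChiSquared(a["hits"], sum(a), b["hits"], sum(b))
}
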