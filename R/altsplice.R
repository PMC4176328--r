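# transcript-orientation splice-site keys
.donorKey <- function(gr) {
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  pos <- ifelse(minus, .end0(gr), .start0(gr))
  paste0(GenomicRanges::seqnames(gr), ":", pos, GenomicRanges::strand(gr))
}
.acceptorKey <- function(gr) {
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  pos <- ifelse(minus, .start0(gr), .end0(gr))
  paste0(GenomicRanges::seqnames(gr), ":", pos, GenomicRanges::strand(gr))
}

#' Group junctions into splice-variant groups
#'
#' Two junctions belong to the same group when they share a donor site or an
#' acceptor site; groups are the transitive closure of that relation. The
#' group is the denominator of psi.
#'
#' @param junctions \code{GRanges} of placement-resolved junctions.
#' @return integer vector of group ids along \code{junctions}.
#' @export
spliceVariantGroups <- function(junctions) {
  n <- length(junctions)
  if (n == 0L) return(integer(0))
  keys <- c(.donorKey(junctions), .acceptorKey(junctions))
  sites <- factor(keys)
  g <- igraph::make_empty_graph(n = n + nlevels(sites), directed = FALSE)
  g <- igraph::add_edges(g, rbind(rep(seq_len(n), 2L),
                                  n + as.integer(sites)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  as.integer(factor(comp, levels = unique(comp)))
}

#' Type alternative-splicing events
#'
#' Junctions sharing a donor with differing acceptors are alternative 3'
#' splice-site events; shared acceptor with differing donors, alternative 5'.
#' A junction spanning the union of two junctions that flank an internal
#' exon is an exon-skipping event and the flanking pair is the
#' exon-inclusion path. Junctions sharing no site and not in a skipping
#' triple are constitutive. When an unspliced depth track is supplied, a
#' junction whose intron carries unspliced depth of at least
#' \code{retentionFraction} of its flanking exonic depth is additionally
#' flagged as intron retention.
#'
#' @param junctions \code{GRanges} of junctions.
#' @param depth optional \code{GRanges} with a \code{score} column of
#'   unspliced read depth (e.g. a bedGraph imported with
#'   \code{rtracklayer::import}).
#' @param retentionFraction intron/exon depth ratio that calls retention.
#' @param flankWidth exonic flank (nt) used for the retention comparison.
#' @return \code{DataFrame} with \code{event_type} and logical
#'   \code{intron_retention}.
#' @export
classifyEvents <- function(junctions, depth = NULL, retentionFraction = 0.5,
                           flankWidth = 25L) {
  n <- length(junctions)
  dk <- .donorKey(junctions); ak <- .acceptorKey(junctions)
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  str <- as.character(GenomicRanges::strand(junctions))

  altD <- ave(seq_len(n), dk, FUN = length) > 1L  # shared donor
  altA <- ave(seq_len(n), ak, FUN = length) > 1L  # shared acceptor

  skipping <- logical(n); inclusion <- logical(n)
  for (i in seq_len(n)) {
    j1 <- which(chrom == chrom[i] & str == str[i] & s0 == s0[i] & e0 < e0[i])
    j2 <- which(chrom == chrom[i] & str == str[i] & e0 == e0[i] & s0 > s0[i])
    if (length(j1) == 0L || length(j2) == 0L) next
    for (a in j1) {
      hit <- j2[s0[j2] > e0[a]]
      if (length(hit)) {
        skipping[i] <- TRUE
        inclusion[a] <- TRUE
        inclusion[hit] <- TRUE
      }
    }
  }
  eventType <- rep("CONSTITUTIVE", n)
  eventType[altA] <- "ALT_5PRIME"
  eventType[altD] <- "ALT_3PRIME"
  eventType[inclusion & !skipping] <- "EXON_INCLUSION"
  eventType[skipping] <- "EXON_SKIPPING"

  retention <- rep(NA, n)
  if (is.null(depth)) {
    warning("no unspliced depth track supplied; intron-retention typing skipped")
  } else {
    meanDepth <- function(gr) {
      ov <- GenomicRanges::findOverlaps(gr, depth)
      if (length(ov) == 0L) return(numeric(length(gr)) * 0)
      inter <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                         depth[S4Vectors::subjectHits(ov)],
                                         ignore.strand = TRUE)
      contrib <- GenomicRanges::width(inter) *
        S4Vectors::mcols(depth)$score[S4Vectors::subjectHits(ov)]
      tot <- tapply(contrib, S4Vectors::queryHits(ov), sum)
      out <- numeric(length(gr))
      out[as.integer(names(tot))] <- tot
      out / GenomicRanges::width(gr)
    }
    intr <- GenomicRanges::granges(junctions)
    fl <- junctionRanges(rep(chrom, 2L),
                         c(pmax(0L, s0 - flankWidth), e0),
                         c(pmax(1L, s0), e0 + flankWidth), rep(str, 2L))
    di <- meanDepth(intr)
    de <- meanDepth(fl)
    exMean <- (de[seq_len(n)] + de[n + seq_len(n)]) / 2
    retention <- exMean > 0 & di >= retentionFraction * exMean
  }
  S4Vectors::DataFrame(event_type = eventType, intron_retention = retention)
}

#' Wilson score confidence interval
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level.
#' @return matrix with columns \code{lo}, \code{hi}.
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(lo = pmax(0, center - half), hi = pmin(1, center + half))
}

#' Intron usage (psi) with confidence interval
#'
#' psi is the junction's coverage divided by the summed coverage of its
#' splice-variant group in that sample, with a 95\% Wilson score interval
#' treating the junction's reads as successes among the group's reads.
#'
#' @param coverage read count of the junction in one sample.
#' @param groupTotal summed read count of the group in that sample.
#' @param conf confidence level.
#' @return list with \code{psi}, \code{lo}, \code{hi}.
#' @export
computePsi <- function(coverage, groupTotal, conf = 0.95) {
  if (any(groupTotal <= 0))
    stop("psi undefined: splice-variant group has zero coverage")
  ci <- wilsonInterval(coverage, groupTotal, conf)
  list(psi = coverage / groupTotal, lo = ci[, "lo"], hi = ci[, "hi"])
}

.coverageMatrix <- function(junctions, samples = NULL) {
  mc <- S4Vectors::mcols(junctions)
  covCols <- grep("^cov\\.", colnames(mc), value = TRUE)
  if (!is.null(samples)) covCols <- paste0("cov.", samples)
  if (length(covCols) == 0L) stop("junctions carry no cov.<sample> columns")
  m <- as.matrix(as.data.frame(mc[covCols]))
  colnames(m) <- sub("^cov\\.", "", covCols)
  m
}

#' Per-sample psi table for a junction set
#'
#' @param junctions \code{GRanges} with per-sample coverage columns
#'   (\code{cov.<sample>}).
#' @param groups group ids (see \code{\link{spliceVariantGroups}}); computed
#'   when omitted.
#' @param conf confidence level for the Wilson interval.
#' @return data.frame with junction key, sample, coverage, group total, psi
#'   and CI bounds (psi is NA where the group has no coverage in a sample).
#' @export
psiTable <- function(junctions, groups = spliceVariantGroups(junctions),
                     conf = 0.95) {
  covm <- .coverageMatrix(junctions)
  key <- .junctionKey(junctions)
  out <- list()
  for (smp in colnames(covm)) {
    tot <- ave(covm[, smp], groups, FUN = sum)
    ok <- tot > 0
    psi <- lo <- hi <- rep(NA_real_, length(tot))
    if (any(ok)) {
      p <- computePsi(covm[ok, smp], tot[ok], conf)
      psi[ok] <- p$psi; lo[ok] <- p$lo; hi[ok] <- p$hi
    }
    out[[smp]] <- data.frame(junction = key, group = groups, sample = smp,
                             coverage = covm[, smp], group_total = tot,
                             psi = psi, ci_lo = lo, ci_hi = hi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minor-isoform coverage filter (1:20 rule)
#'
#' A junction is kept iff its total coverage (summed over samples) is at
#' least \code{ratio} times the total coverage of its splice-variant group's
#' most abundant member, inclusive; the predominant member itself is always
#' kept.
#'
#' @param junctions \code{GRanges} with \code{cov.<sample>} columns.
#' @param groups group ids; computed when omitted.
#' @param ratio minimum coverage ratio to the predominant variant.
#' @return logical vector along \code{junctions}: kept.
#' @export
filterMinorIsoform <- function(junctions,
                               groups = spliceVariantGroups(junctions),
                               ratio = 1 / 20) {
  tot <- rowSums(.coverageMatrix(junctions))
  predominant <- ave(tot, groups, FUN = max)
  tot >= ratio * predominant
}

#' Cross-sample psi comparison for one junction
#'
#' Lists per-sample psi with its Wilson interval and flags sample pairs
#' whose intervals do not overlap as differential.
#'
#' @param psiRows rows of \code{\link{psiTable}} for a single junction
#'   (at least two samples with defined psi).
#' @return the input rows, with attribute \code{"differential"}: a
#'   data.frame of sample pairs with non-overlapping intervals.
#' @export
tissueTable <- function(psiRows) {
  ok <- psiRows[!is.na(psiRows$psi), , drop = FALSE]
  if (nrow(ok) < 2L) stop("need psi in at least two samples")
  if (length(unique(ok$junction)) != 1L)
    stop("tissueTable expects rows of a single junction")
  pairs <- utils::combn(seq_len(nrow(ok)), 2L)
  nonOverlap <- apply(pairs, 2L, function(p) {
    a <- ok[p[1L], ]; b <- ok[p[2L], ]
    a$ci_lo > b$ci_hi || b$ci_lo > a$ci_hi
  })
  diffs <- data.frame(sample1 = ok$sample[pairs[1L, ]],
                      sample2 = ok$sample[pairs[2L, ]])[nonOverlap, ,
                                                        drop = FALSE]
  attr(ok, "differential") <- diffs
  ok
}
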