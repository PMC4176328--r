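#' Attach per-sample coverage to junctions
#'
#' Joins a junction coverage table (columns \code{chrom, start, end, strand}
#' plus \code{cov.<sample>} columns, 0-based half-open) onto a junction set
#' by exact interval identity. Junctions absent from the table get zero
#' coverage.
#'
#' @param junctions \code{GRanges} of junctions.
#' @param coverage coverage data.frame or TSV path.
#' @return the junctions with \code{cov.<sample>} metadata columns added.
#' @export
attachCoverage <- function(junctions, coverage) {
  if (is.character(coverage))
    coverage <- utils::read.delim(coverage, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  key <- paste0(coverage$chrom, ":", coverage$start, "-", coverage$end,
                "(", coverage$strand, ")")
  idx <- match(.junctionKey(junctions), key)
  for (cn in grep("^cov\\.", colnames(coverage), value = TRUE)) {
    v <- coverage[[cn]][idx]
    v[is.na(v)] <- 0L
    S4Vectors::mcols(junctions)[[cn]] <- v
  }
  junctions
}

#' Run the non-canonical splice-site discovery pipeline
#'
#' End-to-end driver: merges per-source junction sets (distinct-sequence
#' support in >= minSupport sequences and >= minSources sources), splits
#' canonical from non-canonical candidates, applies the SNP/indel and
#' low-complexity filters to the candidates, trains U2/U12 PWMs on the
#' canonical junctions found (U12 on the AT-AC subset), resolves
#' direct-repeat placement ambiguity (rescuing candidates with an ambiguous
#' canonical placement), calibrates the scrambled-sequence null threshold,
#' applies the classification rule, partitions the non-U2/U12 candidates
#' into artifact signatures, and (when a pileup is supplied) annotates
#' A-to-I editing at the candidate dinucleotides.
#'
#' @param genome named \code{DNAStringSet}.
#' @param sources named list of per-source junction \code{GRanges} (each
#'   with a \code{support} column), e.g. from
#'   \code{\link{junctionsFromAlignments}}.
#' @param variants optional \code{GRanges} of SNPs/indels.
#' @param pileup optional pileup data.frame (see \code{\link{readPileup}}).
#' @param coverage optional coverage table (see
#'   \code{\link{attachCoverage}}).
#' @param extraction an \code{\link{extractionConfig}}.
#' @param classifier a \code{\link{classifierConfig}}.
#' @param trainU12Min minimum AT-AC junctions needed to train the U12
#'   matrices.
#' @return list with \code{canonical} (GRanges), \code{candidates} (GRanges
#'   with dinucleotides, scores, classification, artifact partition, editing
#'   columns), \code{discarded} (GRanges with reasons), \code{pwm},
#'   \code{threshold}.
#' @export
discoverSpliceSites <- function(genome, sources, variants = NULL,
                                pileup = NULL, coverage = NULL,
                                extraction = extractionConfig(),
                                classifier = classifierConfig(),
                                trainU12Min = 10L) {
  merged <- mergeSources(sources, extraction)
  if (!is.null(coverage)) merged <- attachCoverage(merged, coverage)
  cat <- categorizeDinucleotides2(genome, merged)
  S4Vectors::mcols(merged) <- cbind(S4Vectors::mcols(merged), cat)
  canonical <- merged[cat$category == "CANONICAL"]
  candidates <- merged[cat$category == "NONCANONICAL_CANDIDATE"]
  discarded <- list()

  if (!is.null(variants)) {
    fv <- filterVariantSpanning(candidates, variants, genome, extraction)
    candidates <- fv$kept
    discarded$variant <- fv$discarded
  }
  fl <- filterLowComplexity(candidates, genome, extraction)
  candidates <- fl$kept
  discarded$dust <- fl$discarded

  u12 <- !is.na(S4Vectors::mcols(canonical)$subtype) &
    S4Vectors::mcols(canonical)$subtype == "AT-AC"
  if (sum(u12) < trainU12Min)
    stop("too few AT-AC junctions to train the U12 matrices (", sum(u12), ")")
  pwm <- trainPWM(genome, canonical, u12)

  # placement ambiguity: rescue candidates with a canonical placement
  if (length(candidates)) {
    resolved <- resolveJunctions(genome, candidates, pwm)
    rescued <- S4Vectors::mcols(resolved)$rescued_canonical
    if (any(rescued)) {
      resc <- resolved[rescued]
      cat2 <- categorizeDinucleotides2(genome, resc)
      keepCols <- intersect(colnames(S4Vectors::mcols(canonical)),
                            colnames(S4Vectors::mcols(resc)))
      mc <- S4Vectors::mcols(resc)[keepCols]
      mc$category <- cat2$category; mc$subtype <- cat2$subtype
      mc$donor <- cat2$donor; mc$acceptor <- cat2$acceptor
      resc2 <- GenomicRanges::granges(resc)
      S4Vectors::mcols(resc2) <- mc
      canonical <- c(canonical, resc2[, colnames(S4Vectors::mcols(canonical))])
    }
    candidates <- resolved[!rescued]
    # placements may have shifted: refresh dinucleotides
    cat3 <- categorizeDinucleotides2(genome, candidates)
    S4Vectors::mcols(candidates)$donor <- cat3$donor
    S4Vectors::mcols(candidates)$acceptor <- cat3$acceptor
  }

  threshold <- NA_real_
  if (length(candidates)) {
    threshold <- calibrateNullThreshold(pwm, genome, candidates, classifier)
    sc <- scoreJunctions(pwm, genome, candidates)
    shares <- sharesCanonicalSite(candidates, canonical)
    cls <- classifyJunctions(sc$final_score, as.numeric(threshold), shares,
                             GenomicRanges::width(candidates), classifier)
    mc <- S4Vectors::mcols(candidates)
    mc$u2_score <- sc$u2_score; mc$u12_score <- sc$u12_score
    mc$best_model <- sc$best_model; mc$final_score <- sc$final_score
    mc$shares_canonical_site <- shares
    mc$classification <- cls
    S4Vectors::mcols(candidates) <- mc

    nonU2U12 <- which(cls == "NON_U2U12")
    part <- rep(NA_character_, length(candidates))
    if (length(nonU2U12)) {
      rep_len <- S4Vectors::mcols(candidates)$direct_repeat_length[nonU2U12]
      ar <- partitionArtifacts(candidates[nonU2U12], canonical, genome)
      part[nonU2U12] <- ar$partition
      S4Vectors::mcols(candidates)$homopolymer_run <- NA_integer_
      S4Vectors::mcols(candidates)$homopolymer_run[nonU2U12] <- ar$homopolymer_run
      S4Vectors::mcols(candidates)$gc_fraction <- NA_real_
      S4Vectors::mcols(candidates)$gc_fraction[nonU2U12] <- ar$gc_fraction
    }
    S4Vectors::mcols(candidates)$partition <- part

    if (!is.null(pileup)) {
      ed <- annotateEditing(genome, candidates, pileup)
      S4Vectors::mcols(candidates)$edited_donor <- ed$edited_donor
      S4Vectors::mcols(candidates)$edited_acceptor <- ed$edited_acceptor
      S4Vectors::mcols(candidates)$became_canonical <- ed$became_canonical
    }
  }
  list(canonical = canonical, candidates = candidates,
       discarded = discarded, pwm = pwm,
       threshold = as.numeric(threshold))
}

#' Match reported junctions to simulator truth records
#'
#' A reported junction matches a truth record when it coincides with any
#' direct-repeat-equivalent placement of the truth junction (pipeline
#' placement resolution may legitimately shift a junction within its
#' ambiguity group).
#'
#' @param genome named \code{DNAStringSet}.
#' @param truth truth table from \code{\link{simulateReference}}.
#' @param reported \code{GRanges} of reported junctions.
#' @param maxShift placement search range (nt).
#' @return integer vector along \code{truth} rows: index of the matching
#'   reported junction, or NA.
#' @export
matchTruth <- function(genome, truth, reported, maxShift = 30L) {
  repKey <- .junctionKey(reported)
  vapply(seq_len(nrow(truth)), function(i) {
    tj <- junctionRanges(truth$chrom[i], truth$start[i], truth$end[i],
                         truth$strand[i])
    pl <- placements(enumeratePlacements(genome, tj, maxShift))
    hit <- match(.junctionKey(pl), repKey)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
}
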