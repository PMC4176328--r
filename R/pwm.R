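#' @import methods
NULL

SITE_TYPES <- c("u2_5", "u2_3", "u12_5", "u12_3")

#' PWMModel: splice-site position weight matrices
#'
#' Holds per-position base-frequency matrices for the four splice-site types
#' (U2 donor/acceptor, U12 donor/acceptor) together with the window each
#' matrix covers. A window is specified as (exonic nt, intronic nt) around
#' the splice site, in transcript orientation. Scores derived from a model
#' are min-max normalised to a 0-100 scale (Shapiro-Senapathy style), so the
#' consensus sequence of a matrix scores exactly 100 and the anti-consensus
#' exactly 0.
#'
#' @slot matrices named list of 4 x width numeric matrices (rows A,C,G,T;
#'   columns sum to 1) for sites \code{u2_5, u2_3, u12_5, u12_3}.
#' @slot windows named list of integer pairs \code{c(exon, intron)} per site.
#' @slot pseudocount the pseudocount used at training time.
#' @export
setClass("PWMModel", representation(
  matrices = "list", windows = "list", pseudocount = "numeric"))

setValidity("PWMModel", function(object) {
  if (!setequal(names(object@matrices), SITE_TYPES))
    return("matrices must be named u2_5, u2_3, u12_5, u12_3")
  for (s in SITE_TYPES) {
    m <- object@matrices[[s]]
    if (!identical(rownames(m), c("A", "C", "G", "T")))
      return("matrix rows must be A, C, G, T")
    if (any(abs(colSums(m) - 1) > 1e-9))
      return(sprintf("columns of %s must sum to 1", s))
    if (sum(object@windows[[s]]) != ncol(m))
      return(sprintf("window of %s does not match matrix width", s))
  }
  TRUE
})

setMethod("show", "PWMModel", function(object) {
  cat("PWMModel with 4 site matrices (pseudocount ",
      object@pseudocount, ")\n", sep = "")
  for (s in SITE_TYPES) {
    w <- object@windows[[s]]
    cat(sprintf("  %-6s %2d exonic + %2d intronic nt, consensus %s\n", s,
                w[1L], w[2L], pwmConsensus(object, s)))
  }
})

#' Default splice-site window specification
#'
#' U2 donor: 3 exonic + 6 intronic nt; U2 acceptor: 14 intronic + 3 exonic;
#' U12 donor: 3 exonic + 9 intronic (the U12 donor consensus extends deeper
#' into the intron); U12 acceptor: 14 intronic + 3 exonic.
#'
#' @return named list of \code{c(exon, intron)} integer pairs.
#' @export
defaultWindows <- function() {
  list(u2_5 = c(3L, 6L), u2_3 = c(3L, 14L),
       u12_5 = c(3L, 9L), u12_3 = c(3L, 14L))
}

#' @rdname pwmAccessors
#' @param object a \code{PWMModel}.
#' @param site one of \code{"u2_5", "u2_3", "u12_5", "u12_3"}.
#' @export
pwmMatrix <- function(object, site) object@matrices[[match.arg(site, SITE_TYPES)]]

#' Accessors for PWMModel
#' @rdname pwmAccessors
#' @export
pwmWindows <- function(object) object@windows

#' @rdname pwmAccessors
#' @export
pwmConsensus <- function(object, site) {
  m <- pwmMatrix(object, site)
  paste0(rownames(m)[apply(m, 2L, which.max)], collapse = "")
}

#' Build a PWM from aligned site sequences
#'
#' Column frequencies are \code{(count + pseudocount) / (n + 4 pseudocount)}.
#'
#' @param sequences named list with character vectors of aligned window
#'   sequences for each of the four site types.
#' @param windows window specification (see \code{\link{defaultWindows}}).
#' @param pseudocount per-base pseudocount added to every column.
#' @param minTraining minimum training sequences per site type.
#' @return a \code{\link{PWMModel}}.
#' @export
buildPWM <- function(sequences, windows = defaultWindows(), pseudocount = 1,
                     minTraining = 10L) {
  mats <- lapply(SITE_TYPES, function(s) {
    seqs <- sequences[[s]]
    if (length(seqs) < minTraining)
      stop("too few training sequences for site ", s, " (need >= ",
           minTraining, ")")
    w <- sum(windows[[s]])
    if (any(nchar(seqs) != w))
      stop("training sequences for ", s, " must all have width ", w)
    counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    m <- matrix(0, 4L, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    hit <- intersect(rownames(counts), rownames(m))
    m[hit, ] <- counts[hit, , drop = FALSE]
    (m + pseudocount) / (length(seqs) + 4 * pseudocount)
  })
  names(mats) <- SITE_TYPES
  methods::new("PWMModel", matrices = mats, windows = windows[SITE_TYPES],
               pseudocount = pseudocount)
}

# Window sequence around one splice site, transcript orientation.
# end = "five" (donor) or "three" (acceptor); ex/int = exonic/intronic widths.
.siteWindows <- function(genome, junctions, end, ex, int) {
  s0 <- .start0(junctions); e0 <- .end0(junctions)
  chrom <- as.character(GenomicRanges::seqnames(junctions))
  minus <- as.character(GenomicRanges::strand(junctions)) == "-"
  out <- character(length(junctions))
  fivePlus <- (!minus & end == "five") | (minus & end == "three")
  # genomic window at the intron 5' (left) genomic end
  if (any(fivePlus)) {
    seq <- .getSeq0(genome, chrom[fivePlus], s0[fivePlus] - ex,
                    s0[fivePlus] + int)
    out[fivePlus] <- seq
  }
  if (any(!fivePlus)) {
    seq <- .getSeq0(genome, chrom[!fivePlus], e0[!fivePlus] - int,
                    e0[!fivePlus] + ex)
    out[!fivePlus] <- seq
  }
  out[minus] <- .revcomp(out[minus])
  out
}

#' Extract the four site windows of junctions
#'
#' @param genome named \code{DNAStringSet}.
#' @param junctions \code{GRanges} of introns.
#' @param windows window specification.
#' @return named list of character vectors (one window per junction) for
#'   sites \code{u2_5, u2_3, u12_5, u12_3}.
#' @export
junctionWindows <- function(genome, junctions, windows = defaultWindows()) {
  .assertGenome(genome)
  out <- lapply(SITE_TYPES, function(s) {
    end <- if (grepl("_5$", s)) "five" else "three"
    w <- windows[[s]]
    .siteWindows(genome, junctions, end, w[1L], w[2L])
  })
  names(out) <- SITE_TYPES
  out
}

# windows (character) -> integer index matrix rows=sequences, cols=positions;
# N (or any non-ACGT base) becomes NA and scores as the column minimum.
.windowIndexMatrix <- function(windowSeqs, width) {
  if (any(nchar(windowSeqs) != width))
    stop("window sequence width does not match matrix width")
  chars <- matrix(unlist(strsplit(windowSeqs, ""), use.names = FALSE),
                  nrow = length(windowSeqs), ncol = width, byrow = TRUE)
  matrix(match(chars, c("A", "C", "G", "T")), nrow = nrow(chars))
}

.scoreIndexMatrix <- function(freq, idx) {
  w <- ncol(freq)
  colMin <- apply(freq, 2L, min)
  colMax <- apply(freq, 2L, max)
  lookup <- freq[cbind(as.vector(idx), rep(seq_len(w), each = nrow(idx)))]
  lookup[is.na(lookup)] <- colMin[rep(seq_len(w), each = nrow(idx))][is.na(lookup)]
  raw <- rowSums(matrix(lookup, nrow = nrow(idx)))
  rng <- sum(colMax) - sum(colMin)
  if (rng == 0) return(rep(100, nrow(idx)))
  100 * (raw - sum(colMin)) / rng
}

#' Score site windows against one PWM
#'
#' The raw score of a window is the sum over positions of the frequency of
#' the observed base; it is min-max normalised to 0-100 using the columnwise
#' minimal and maximal attainable sums, so the consensus scores 100 and the
#' anti-consensus 0. N scores as the column minimum.
#'
#' @param matrix a 4 x width frequency matrix (rows A,C,G,T).
#' @param windowSeqs character vector of window sequences (width must match).
#' @return numeric vector of scores in [0, 100].
#' @export
scoreSite <- function(matrix, windowSeqs) {
  idx <- .windowIndexMatrix(windowSeqs, ncol(matrix))
  .scoreIndexMatrix(matrix, idx)
}

#' Score junctions under the U2 and U12 models
#'
#' Each model's score is the mean of its donor-site and acceptor-site scores;
#' the junction's final score is the better of the two models (ties go to
#' U2).
#'
#' @param model a \code{\link{PWMModel}}.
#' @param genome named \code{DNAStringSet}.
#' @param junctions \code{GRanges} of introns.
#' @return \code{DataFrame} with \code{u2_score}, \code{u12_score},
#'   \code{best_model}, \code{final_score}.
#' @export
scoreJunctions <- function(model, genome, junctions) {
  win <- junctionWindows(genome, junctions, model@windows)
  sc <- lapply(SITE_TYPES, function(s) scoreSite(model@matrices[[s]], win[[s]]))
  names(sc) <- SITE_TYPES
  u2 <- (sc$u2_5 + sc$u2_3) / 2
  u12 <- (sc$u12_5 + sc$u12_3) / 2
  S4Vectors::DataFrame(
    u2_score = u2, u12_score = u12,
    best_model = ifelse(u2 >= u12, "U2", "U12"),
    final_score = pmax(u2, u12))
}

#' Classifier configuration
#'
#' @param directThreshold score above which a junction is U2/U12-like
#'   outright (fixed at 70.00 in the published rule).
#' @param nullScrambles scramble iterations for the null calibration.
#' @param nullPercentile percentile of the scrambled-score pool used as
#'   threshold (fixed at 95).
#' @param minIntron introns shorter than this (nt) are non-U2/U12 outright
#'   (fixed at 80).
#' @param seed integer seed for the scrambling RNG.
#' @return a list of class \code{classifierConfig}.
#' @export
classifierConfig <- function(directThreshold = 70.00, nullScrambles = 10000L,
                             nullPercentile = 95, minIntron = 80L,
                             seed = 1L) {
  stopifnot(directThreshold >= 0, directThreshold <= 100,
            nullPercentile > 0, nullPercentile <= 100)
  structure(list(directThreshold = directThreshold,
                 nullScrambles = as.integer(nullScrambles),
                 nullPercentile = nullPercentile,
                 minIntron = as.integer(minIntron),
                 seed = as.integer(seed)),
            class = "classifierConfig")
}

#' Calibrate the scrambled-sequence null threshold
#'
#' For every scramble iteration the letters of each site window are permuted
#' uniformly at random (composition preserved), the junction is rescored, and
#' all scrambled final scores are pooled. The threshold is the nearest-rank
#' 95th percentile (or \code{nullPercentile}) of the pool. Deterministic
#' given \code{config$seed}.
#'
#' @param model a \code{\link{PWMModel}}.
#' @param genome named \code{DNAStringSet}.
#' @param junctions junctions whose windows are scrambled (typically the
#'   non-canonical candidates under test).
#' @param config a \code{\link{classifierConfig}}.
#' @return the threshold score; the pooled scrambled scores are attached as
#'   attribute \code{"pool"}.
#' @export
calibrateNullThreshold <- function(model, genome, junctions,
                                   config = classifierConfig()) {
  if (length(junctions) == 0L)
    stop("null calibration needs at least one junction window")
  if (!is.null(config$seed)) set.seed(config$seed)
  win <- junctionWindows(genome, junctions, model@windows)
  nS <- config$nullScrambles
  n <- length(junctions)
  siteScores <- lapply(SITE_TYPES, function(s) {
    freq <- model@matrices[[s]]
    idx <- .windowIndexMatrix(win[[s]], ncol(freq))
    big <- idx[rep(seq_len(n), times = nS), , drop = FALSE]
    big <- t(apply(big, 1L, sample))
    .scoreIndexMatrix(freq, big)
  })
  names(siteScores) <- SITE_TYPES
  pool <- pmax((siteScores$u2_5 + siteScores$u2_3) / 2,
               (siteScores$u12_5 + siteScores$u12_3) / 2)
  thr <- nearestRankPercentile(pool, config$nullPercentile)
  attr(thr, "pool") <- pool
  thr
}

#' Which junctions share a splice site with a canonical junction?
#'
#' A site is shared when a canonical junction on the same chromosome and
#' strand has the identical donor coordinate or the identical acceptor
#' coordinate.
#'
#' @param junctions candidate junctions (\code{GRanges}).
#' @param canonical canonical junction set (\code{GRanges}).
#' @return logical vector along \code{junctions}.
#' @export
sharesCanonicalSite <- function(junctions, canonical) {
  donorKey <- function(gr) {
    minus <- as.character(GenomicRanges::strand(gr)) == "-"
    pos <- ifelse(minus, .end0(gr), .start0(gr))
    paste0(GenomicRanges::seqnames(gr), ":", pos, GenomicRanges::strand(gr))
  }
  acceptorKey <- function(gr) {
    minus <- as.character(GenomicRanges::strand(gr)) == "-"
    pos <- ifelse(minus, .start0(gr), .end0(gr))
    paste0(GenomicRanges::seqnames(gr), ":", pos, GenomicRanges::strand(gr))
  }
  donorKey(junctions) %in% donorKey(canonical) |
    acceptorKey(junctions) %in% acceptorKey(canonical)
}

#' Classify non-canonical junctions as U2/U12-like or non-U2/U12
#'
#' Decision rule, in order: (1) intron shorter than \code{minIntron} nt is
#' non-U2/U12; (2) final score above \code{directThreshold} (70.00) is
#' U2/U12-like outright; (3) a score between the calibrated null threshold
#' and 70.00 is U2/U12-like only when the junction shares a splice site with
#' a canonical junction; (4) everything else is non-U2/U12. If the calibrated
#' threshold exceeds 70.00 the rescue band (3) is empty and a warning is
#' issued.
#'
#' @param finalScore numeric vector of junction scores (0-100).
#' @param threshold calibrated null threshold
#'   (\code{\link{calibrateNullThreshold}}).
#' @param sharesSite logical vector: shares a canonical splice site.
#' @param intronLength integer vector of intron lengths (nt).
#' @param config a \code{\link{classifierConfig}}.
#' @return character vector, "U2U12_LIKE" or "NON_U2U12".
#' @export
classifyJunctions <- function(finalScore, threshold, sharesSite, intronLength,
                              config = classifierConfig()) {
  stopifnot(all(is.finite(finalScore)), all(is.finite(intronLength)))
  if (threshold > config$directThreshold)
    warning("calibrated null threshold (", round(threshold, 2),
            ") exceeds the direct threshold (", config$directThreshold,
            "); the shared-site rescue band is empty")
  out <- rep("NON_U2U12", length(finalScore))
  rule2 <- finalScore > config$directThreshold
  rule3 <- !rule2 & finalScore >= threshold &
    finalScore <= config$directThreshold & sharesSite
  out[rule2 | rule3] <- "U2U12_LIKE"
  out[intronLength < config$minIntron] <- "NON_U2U12"
  out
}

#' Persist / restore a PWMModel as TSV
#'
#' One row per matrix position (columns \code{site, pos, A, C, G, T});
#' window specs and pseudocount are stored in comment header lines.
#'
#' @param model a \code{\link{PWMModel}}.
#' @param path file path.
#' @return \code{readPWM} returns a \code{\link{PWMModel}}.
#' @export
writePWM <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#pseudocount\t%g", model@pseudocount), con)
  for (s in SITE_TYPES)
    writeLines(sprintf("#window\t%s\t%d\t%d", s, model@windows[[s]][1L],
                       model@windows[[s]][2L]), con)
  writeLines("site\tpos\tA\tC\tG\tT", con)
  for (s in SITE_TYPES) {
    m <- model@matrices[[s]]
    for (p in seq_len(ncol(m)))
      writeLines(paste(c(s, p, format(m[, p], digits = 17)), collapse = "\t"),
                 con)
  }
  invisible(path)
}

#' @rdname writePWM
#' @export
readPWM <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  pc <- as.numeric(strsplit(grep("^#pseudocount", hdr, value = TRUE),
                            "\t")[[1L]][2L])
  windows <- list()
  for (h in grep("^#window", hdr, value = TRUE)) {
    f <- strsplit(h, "\t")[[1L]]
    windows[[f[2L]]] <- as.integer(f[3:4])
  }
  tab <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]))
  mats <- lapply(split(tab, tab$site), function(d) {
    d <- d[order(d$pos), ]
    m <- t(as.matrix(d[, c("A", "C", "G", "T")]))
    dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
    m
  })
  methods::new("PWMModel", matrices = mats[SITE_TYPES],
               windows = windows[SITE_TYPES], pseudocount = pc)
}

#' Train splice-site PWMs from classified junctions
#'
#' U2 matrices are trained on the GT-AG (and optionally GC-AG) junctions;
#' U12 matrices on the junctions flagged U12-type by the caller (typically
#' the AT-AC subset).
#'
#' @param genome named \code{DNAStringSet}.
#' @param junctions canonical training junctions (\code{GRanges}).
#' @param u12 logical vector along \code{junctions}: TRUE for U12-type.
#' @param windows window specification.
#' @param pseudocount pseudocount (see \code{\link{buildPWM}}).
#' @param minTraining minimum training junctions per site type.
#' @return a \code{\link{PWMModel}}.
#' @export
trainPWM <- function(genome, junctions, u12, windows = defaultWindows(),
                     pseudocount = 1, minTraining = 10L) {
  w2 <- junctionWindows(genome, junctions[!u12], windows)
  w12 <- junctionWindows(genome, junctions[u12], windows)
  buildPWM(list(u2_5 = w2$u2_5, u2_3 = w2$u2_3,
                u12_5 = w12$u12_5, u12_3 = w12$u12_3),
           windows = windows, pseudocount = pseudocount,
           minTraining = minTraining)
}
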