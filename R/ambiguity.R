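#' AmbiguityGroup: equivalent placements of one junction
#'
#' Direct repeats at a junction's flanks make several intron placements
#' excise to the identical mature transcript. An \code{AmbiguityGroup} holds
#' all such placements of one junction, obtained by sliding the intron left
#' and right while the flanking bases match.
#'
#' @slot placements \code{GRanges} of the equivalent intron placements, with
#'   a \code{shift} metadata column (0 = the input placement).
#' @slot leftShift,rightShift maximal shifts (nt) in each direction.
#' @slot directRepeatLength \code{leftShift + rightShift} (nt).
#' @export
setClass("AmbiguityGroup", representation(
  placements = "GRanges", leftShift = "integer", rightShift = "integer",
  directRepeatLength = "integer"))

setValidity("AmbiguityGroup", function(object) {
  n <- object@leftShift + object@rightShift + 1L
  if (length(object@placements) != n)
    return("placements must contain leftShift + rightShift + 1 entries")
  if (length(unique(GenomicRanges::width(object@placements))) != 1L)
    return("all placements must have equal intron length")
  TRUE
})

setMethod("show", "AmbiguityGroup", function(object) {
  cat("AmbiguityGroup:", length(object@placements), "placement(s),",
      "direct repeat", object@directRepeatLength, "nt\n")
})

#' @rdname AmbiguityGroup-class
#' @param object an \code{AmbiguityGroup}.
#' @export
placements <- function(object) object@placements

#' @rdname AmbiguityGroup-class
#' @export
directRepeatLength <- function(object) object@directRepeatLength

#' Enumerate direct-repeat-equivalent placements of a junction
#'
#' The intron \code{[start, end)} can shift right by \code{k} when
#' \code{genome[start + i] == genome[end + i]} for all \code{i < k}, and
#' left symmetrically; every such shift excises the identical spliced
#' sequence. Shifts are capped at \code{maxShift} and truncated at
#' chromosome boundaries. Spliced-product identity is asserted for every
#' enumerated placement.
#'
#' @param genome named \code{DNAStringSet}.
#' @param junction a length-1 \code{GRanges} intron.
#' @param maxShift maximal shift searched in each direction (nt).
#' @return an \code{\link{AmbiguityGroup}}.
#' @export
enumeratePlacements <- function(genome, junction, maxShift = 30L) {
  stopifnot(length(junction) == 1L)
  .assertGenome(genome)
  chrom <- as.character(GenomicRanges::seqnames(junction))
  s0 <- .start0(junction); e0 <- .end0(junction)
  chr <- genome[[chrom]]
  len <- length(chr)
  base <- function(p) as.character(Biostrings::subseq(chr, p + 1L, p + 1L))
  right <- 0L
  while (right < maxShift && e0 + right < len &&
         base(s0 + right) == base(e0 + right)) right <- right + 1L
  left <- 0L
  while (left < maxShift && s0 - left > 0L &&
         base(s0 - left - 1L) == base(e0 - left - 1L)) left <- left + 1L
  shifts <- seq.int(-left, right)
  pl <- junctionRanges(rep(chrom, length(shifts)), s0 + shifts, e0 + shifts,
                       rep(as.character(GenomicRanges::strand(junction)),
                           length(shifts)),
                       shift = shifts)
  # spliced-product invariance check (flanks capped at the chromosome)
  lo <- max(0L, s0 - left - 5L); hi <- min(len, e0 + right + 5L)
  spliced <- vapply(seq_along(shifts), function(i) {
    paste0(.getSeq0(genome, chrom, lo, s0 + shifts[i]),
           .getSeq0(genome, chrom, e0 + shifts[i], hi))
  }, character(1))
  stopifnot(length(unique(spliced)) == 1L)
  methods::new("AmbiguityGroup", placements = pl, leftShift = left,
               rightShift = right,
               directRepeatLength = left + right)
}

#' Resolve an ambiguity group to a single placement
#'
#' If any placement carries canonical dinucleotides the junction is rescued:
#' the canonical placement with the highest PWM score is chosen and the
#' junction is not reported as non-canonical. Otherwise the placement with
#' the highest final PWM score wins; score ties break toward the smallest
#' absolute shift, then leftmost.
#'
#' @param group an \code{\link{AmbiguityGroup}}.
#' @param genome named \code{DNAStringSet}.
#' @param model a \code{\link{PWMModel}}.
#' @return list with \code{chosen} (length-1 \code{GRanges}, with
#'   \code{shift} and \code{final_score}), \code{rescuedCanonical} (logical)
#'   and \code{scores} (per placement).
#' @export
resolvePlacement <- function(group, genome, model) {
  pl <- group@placements
  sc <- scoreJunctions(model, genome, pl)$final_score
  cat <- categorizeDinucleotides2(genome, pl)
  canonical <- cat$category == "CANONICAL"
  pool <- if (any(canonical)) which(canonical) else seq_along(pl)
  shift <- S4Vectors::mcols(pl)$shift
  ord <- pool[order(-sc[pool], abs(shift[pool]), shift[pool])]
  chosen <- pl[ord[1L]]
  S4Vectors::mcols(chosen)$final_score <- sc[ord[1L]]
  list(chosen = chosen, rescuedCanonical = any(canonical), scores = sc)
}

#' Resolve placement ambiguity for a set of junctions
#'
#' Convenience wrapper running \code{\link{enumeratePlacements}} and
#' \code{\link{resolvePlacement}} over a junction set.
#'
#' @param genome named \code{DNAStringSet}.
#' @param junctions \code{GRanges} of junctions.
#' @param model a \code{\link{PWMModel}}.
#' @param maxShift maximal shift searched (nt).
#' @return \code{GRanges} of chosen placements with metadata columns
#'   \code{shift}, \code{final_score}, \code{rescued_canonical},
#'   \code{direct_repeat_length}, plus the input metadata.
#' @export
resolveJunctions <- function(genome, junctions, model, maxShift = 30L) {
  res <- lapply(seq_along(junctions), function(i) {
    grp <- enumeratePlacements(genome, junctions[i], maxShift)
    r <- resolvePlacement(grp, genome, model)
    ch <- r$chosen
    S4Vectors::mcols(ch)$rescued_canonical <- r$rescuedCanonical
    S4Vectors::mcols(ch)$direct_repeat_length <- grp@directRepeatLength
    ch
  })
  out <- do.call(c, res)
  inMc <- S4Vectors::mcols(junctions)
  if (ncol(inMc) > 0L)
    S4Vectors::mcols(out) <- cbind(S4Vectors::mcols(out), inMc)
  out
}
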