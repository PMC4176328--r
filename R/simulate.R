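#' Simulation configuration
#'
#' Defines the synthetic study conditions: a genome of independent gene
#' cassettes, each carrying one implanted junction (or junction group), with
#' matching alignment, variant and pileup evidence. Defaults implant ~100
#' canonical junctions (15 of them U12-type AT-AC for minor-spliceosome
#' training), 20 U2/U12-like non-canonical junctions (exactly one deviant
#' terminal dinucleotide in an otherwise consensus context, intron >= 80
#' nt), 10 template-switch artifacts (short intron, planted 8-nt direct
#' repeat, GC-rich), 10 homopolymer artifacts (false junction within 10 nt
#' of a canonical one, 5-nt exonic T-run adjacent), 5 SNP-confounded
#' candidates and 4 editable junctions (2 GT-AA + 2 AT-AG with planted A>G
#' pileups).
#'
#' @param seed RNG seed; identical config + seed gives identical output.
#' @param nCanonical canonical U2 (GT-AG) implants.
#' @param nCanonicalU12 canonical U12 (AT-AC) implants (counted within the
#'   canonical class).
#' @param nNonCanonical U2/U12-like non-canonical implants.
#' @param nTemplateSwitch template-switch artifact implants.
#' @param nHomopolymer homopolymer artifact implants.
#' @param nSnpConfounded SNP-confounded implants.
#' @param nEditedGTAA,nEditedATAG edited-junction implants.
#' @param nAlt3Pairs,nAlt5Pairs,nSkipTriples alternative-splicing implants
#'   (canonical junction groups for event typing and psi).
#' @param intronRange canonical intron length range (nt).
#' @param tsIntronRange template-switch intron length range (nt; below 80 by
#'   construction).
#' @param exonLen exon length (nt).
#' @param spacer background nt between gene cassettes.
#' @param backgroundGC background GC fraction.
#' @param tsGC template-switch intron GC fraction.
#' @param readLength simulated read length (nt).
#' @param supportPerSource distinct spanning reads per junction per source.
#' @param coverageRange per-sample junction-group read depth range.
#' @param altPsi planted minor-isoform psi in alternative groups.
#' @param samples sample (tissue) labels for coverage.
#' @param sources data-source labels for alignment evidence.
#' @return a list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(seed = 42L, nCanonical = 85L, nCanonicalU12 = 15L,
                             nNonCanonical = 20L, nTemplateSwitch = 10L,
                             nHomopolymer = 10L, nSnpConfounded = 5L,
                             nEditedGTAA = 2L, nEditedATAG = 2L,
                             nAlt3Pairs = 0L, nAlt5Pairs = 0L,
                             nSkipTriples = 0L,
                             intronRange = c(84L, 400L),
                             tsIntronRange = c(40L, 70L),
                             exonLen = 150L, spacer = 60L,
                             backgroundGC = 0.45, tsGC = 0.72,
                             readLength = 76L, supportPerSource = 4L,
                             coverageRange = c(20L, 60L), altPsi = 0.3,
                             samples = c("adrenal", "brain"),
                             sources = c("rnaseq_a", "rnaseq_b")) {
  cfg <- as.list(environment())
  counts <- unlist(cfg[grep("^n[A-Z]", names(cfg))])
  if (any(counts < 0)) stop("implant counts must be >= 0")
  if (intronRange[1L] < 84L)
    stop("canonical introns must be >= 84 nt (acceptor window + rule margin)")
  structure(cfg, class = "simulationConfig")
}

# Generating consensus models: sharply peaked per-position base frequencies
# around fixed consensus strings. The same consensus world is later learned
# back by trainPWM, which makes implant classification provable rather than
# probabilistic.
.generatorPWMs <- function(peak = 0.85) {
  cons <- list(u2_5 = "CAGGTAAGT",
               u2_3 = "TCCTTCTTTCTCAGGTG",
               u12_5 = "CAGATATCCTTT",
               u12_3 = "TTCCTTAACTTTACATG")
  lapply(cons, function(s) {
    ch <- strsplit(s, "")[[1L]]
    m <- matrix((1 - peak) / 3, 4L, length(ch),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(ch, rownames(m)), seq_along(ch))] <- peak
    m
  })
}

.sampleFromPWM <- function(freq, n) {
  bases <- rownames(freq)
  vapply(seq_len(n), function(i) {
    paste0(vapply(seq_len(ncol(freq)), function(p) {
      sample(bases, 1L, prob = freq[, p])
    }, character(1)), collapse = "")
  }, character(1))
}

.pwmConsensusString <- function(freq) {
  paste0(rownames(freq)[apply(freq, 2L, which.max)], collapse = "")
}

# sample one element from a range vector (safe for length-1 vectors)
.sampleOne <- function(x) x[sample.int(length(x), 1L)]

.randomSeq <- function(n, gc) {
  if (n == 0L) return("")
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

.overlay <- function(chars, at0, insert) {
  ins <- strsplit(insert, "")[[1L]]
  chars[at0 + seq_along(ins)] <- ins
  chars
}

# windows for one intron [s,e) in transcript coords; canonical = sampled
# from the generating model, otherwise exact consensus.
.plantSiteWindows <- function(chars, s, e, pwms, type = c("u2", "u12"),
                              sampled = TRUE, donor = NULL, acceptor = NULL) {
  type <- match.arg(type)
  d5 <- pwms[[paste0(type, "_5")]]; d3 <- pwms[[paste0(type, "_3")]]
  w5 <- if (sampled) .sampleFromPWM(d5, 1L) else .pwmConsensusString(d5)
  w3 <- if (sampled) .sampleFromPWM(d3, 1L) else .pwmConsensusString(d3)
  if (is.null(donor)) donor <- if (type == "u2") "GT" else "AT"
  if (is.null(acceptor)) acceptor <- if (type == "u2") "AG" else "AC"
  substr(w5, 4L, 5L) <- donor        # window = 3 exonic + intron start
  substr(w3, 13L, 14L) <- acceptor   # window = 14 intronic + 3 exonic
  chars <- .overlay(chars, s - 3L, w5)
  .overlay(chars, e - 14L, w3)
}

.NC_DEVIATIONS <- data.frame(
  donor = c("GA", "GT", "GT", "TT", "GT", "CT", "GT", "GG"),
  acceptor = c("AG", "TG", "GG", "AG", "CG", "AG", "AT", "AG"),
  stringsAsFactors = FALSE)

# one gene cassette in transcript orientation; returns sequence + junctions
.buildCassette <- function(class, cfg, pwms, deviationIdx = 1L) {
  E <- cfg$exonLen
  L <- switch(class,
    template_switch = .sampleOne(seq(cfg$tsIntronRange[1L], cfg$tsIntronRange[2L])),
    homopolymer = 84L,
    .sampleOne(seq(cfg$intronRange[1L], cfg$intronRange[2L])))
  nIntrons <- if (class == "skip_triple") 2L else 1L
  midExon <- 60L
  segs <- if (nIntrons == 2L) c(E, L, midExon, L, E) else c(E, L, E)
  gc <- cfg$backgroundGC
  chars <- strsplit(paste0(vapply(segs, function(w) .randomSeq(w, gc),
                                  character(1)), collapse = ""), "")[[1L]]
  jx <- list()
  addJ <- function(s, e, class, pair, u12 = FALSE, ...) {
    c(list(s = s, e = e, class = class, donor = substr(pair, 1L, 2L),
           acceptor = substr(pair, 4L, 5L), u12 = u12), list(...))
  }
  s <- E; e <- E + L
  if (class == "canonical_u2") {
    chars <- .plantSiteWindows(chars, s, e, pwms, "u2")
    jx[[1L]] <- addJ(s, e, "canonical", "GT-AG")
  } else if (class == "canonical_u12") {
    chars <- .plantSiteWindows(chars, s, e, pwms, "u12")
    jx[[1L]] <- addJ(s, e, "canonical", "AT-AC", u12 = TRUE)
  } else if (class == "u2u12_like" || class == "snp_confounded") {
    dev <- if (class == "snp_confounded") c("GA", "AG")
           else unlist(.NC_DEVIATIONS[(deviationIdx - 1L) %% nrow(.NC_DEVIATIONS) + 1L, ])
    chars <- .plantSiteWindows(chars, s, e, pwms, "u2", sampled = FALSE,
                               donor = dev[1L], acceptor = dev[2L])
    extras <- if (class == "snp_confounded") {
      # SNP at the deviant donor base (transcript offset s+1); ALT restores GT
      list(snp_offset = s + 1L, snp_alt = "T")
    } else list()
    jx[[1L]] <- do.call(addJ, c(list(s, e, class,
                                     paste0(dev[1L], "-", dev[2L])), extras))
  } else if (class == "edited_GT_AA") {
    chars <- .plantSiteWindows(chars, s, e, pwms, "u2", sampled = FALSE,
                               acceptor = "AA")
    jx[[1L]] <- addJ(s, e, "edited_GT_AA", "GT-AA", edited_offset = e - 1L)
  } else if (class == "edited_AT_AG") {
    chars <- .plantSiteWindows(chars, s, e, pwms, "u2", sampled = FALSE,
                               donor = "AT")
    jx[[1L]] <- addJ(s, e, "edited_AT_AG", "AT-AG", edited_offset = s)
  } else if (class == "template_switch") {
    # GC-rich intron, non-canonical GC-flavoured termini, 8-nt direct repeat
    for (i in (s + 1L):e) chars[i] <- strsplit(.randomSeq(1L, cfg$tsGC), "")[[1L]]
    chars <- .overlay(chars, s, "AG")
    chars <- .overlay(chars, e - 2L, "CC")
    chars[e + seq_len(8L)] <- chars[s + seq_len(8L)]  # copy -> right shift 8
    jx[[1L]] <- addJ(s, e, "template_switch", "AG-CC", repeat_len = 8L)
  } else if (class == "homopolymer") {
    chars <- .plantSiteWindows(chars, s, e, pwms, "u2")
    chars[(s - 8L):(s - 2L) + 1L] <- "T"  # 7-nt exonic T run ending 2 nt before the donor
    fs <- s - 3L; fe <- e - 9L            # false junction, 78-nt apparent intron
    # pin the false acceptor context so the false junction has no
    # direct-repeat shift (placement resolution must not move it)
    chars <- .overlay(chars, e - 11L, "CAC")
    jx[[1L]] <- addJ(s, e, "canonical", "GT-AG", subtype = "homopolymer_host")
    jx[[2L]] <- addJ(fs, fe, "homopolymer_artifact",
                     paste0(chars[fs + 1L], chars[fs + 2L], "-",
                            chars[fe - 1L], chars[fe]), homopolymer_run = 5L)
  } else if (class == "alt3_pair") {
    e2 <- e + 12L
    chars <- .plantSiteWindows(chars, s, e2, pwms, "u2")  # minor acceptor
    chars <- .plantSiteWindows(chars, s, e, pwms, "u2")   # major acceptor
    jx[[1L]] <- addJ(s, e, "canonical", "GT-AG", event = "ALT_3PRIME", psi = 1 - cfg$altPsi)
    jx[[2L]] <- addJ(s, e2, "canonical", "GT-AG", event = "ALT_3PRIME", psi = cfg$altPsi)
  } else if (class == "alt5_pair") {
    s2 <- s - 12L
    chars <- .plantSiteWindows(chars, s2, e, pwms, "u2")
    chars <- .plantSiteWindows(chars, s, e, pwms, "u2")
    jx[[1L]] <- addJ(s, e, "canonical", "GT-AG", event = "ALT_5PRIME", psi = 1 - cfg$altPsi)
    jx[[2L]] <- addJ(s2, e, "canonical", "GT-AG", event = "ALT_5PRIME", psi = cfg$altPsi)
  } else if (class == "skip_triple") {
    s1 <- E; e1 <- E + L; s2 <- E + L + midExon; e2 <- s2 + L
    chars <- .plantSiteWindows(chars, s1, e1, pwms, "u2")
    chars <- .plantSiteWindows(chars, s2, e2, pwms, "u2")
    half <- (1 - cfg$altPsi)
    jx[[1L]] <- addJ(s1, e1, "canonical", "GT-AG", event = "EXON_INCLUSION", psi = half)
    jx[[2L]] <- addJ(s2, e2, "canonical", "GT-AG", event = "EXON_INCLUSION", psi = half)
    jx[[3L]] <- addJ(s1, e2, "canonical", "GT-AG", event = "EXON_SKIPPING", psi = cfg$altPsi)
  } else stop("unknown cassette class: ", class)
  # re-read actual dinucleotides (overlays may interact)
  for (i in seq_along(jx)) {
    jx[[i]]$donor <- paste0(chars[jx[[i]]$s + 1L], chars[jx[[i]]$s + 2L])
    jx[[i]]$acceptor <- paste0(chars[jx[[i]]$e - 1L], chars[jx[[i]]$e])
  }
  list(seq = paste0(chars, collapse = ""), junctions = jx)
}

# non-canonical implants must not acquire an ambiguous canonical placement
.cassetteClean <- function(cassette) {
  ncClasses <- c("u2u12_like", "snp_confounded", "template_switch",
                 "homopolymer_artifact", "edited_GT_AA", "edited_AT_AG")
  g <- Biostrings::DNAStringSet(cassette$seq)
  names(g) <- "cassette"
  clen <- nchar(cassette$seq)
  for (j in cassette$junctions) {
    if (!(j$class %in% ncClasses)) next
    pl <- enumeratePlacements(g, junctionRanges("cassette", j$s, j$e, "+"))
    cat <- categorizeDinucleotides2(g, placements(pl))
    if (any(cat$category == "CANONICAL")) return(FALSE)
    if (j$class == "template_switch" && directRepeatLength(pl) < 6L)
      return(FALSE)
    # implants that must survive the low-complexity filter are certified
    # against it here (anchor and terminus windows below the DUST threshold)
    w <- 64L
    regions <- rbind(c(max(0L, j$s - w), j$s), c(j$e, min(clen, j$e + w)),
                     c(j$s, min(j$s + w, j$e)), c(max(j$e - w, j$s), j$e))
    for (r in seq_len(nrow(regions))) {
      if (regions[r, 2L] - regions[r, 1L] < 3L) next
      sq <- substr(cassette$seq, regions[r, 1L] + 1L, regions[r, 2L])
      if (dustScore(sq, window = w) > 2.0) return(FALSE)
    }
  }
  TRUE
}

#' Simulate a reference genome with implanted junction classes
#'
#' Builds one gene cassette per implant on a single chromosome
#' (\code{sim1}), alternating strands, and returns the genome together with
#' the ground-truth table. Cassettes whose random background would give a
#' non-canonical implant an ambiguous canonical placement (or erode a
#' planted direct repeat) are resampled.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir optional output directory; when given, \code{genome.fa} and
#'   \code{truth.tsv} are written there.
#' @return list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame: gene, class, subtype, chrom, start, end,
#'   strand, donor, acceptor, intron_len, u12, event, psi, repeat_len,
#'   homopolymer_run, edited_offset0/snp_offset0 in genome coordinates).
#' @export
simulateReference <- function(config = simulationConfig(), dir = NULL) {
  set.seed(config$seed)
  pwms <- .generatorPWMs()
  plan <- c(rep("canonical_u2", config$nCanonical),
            rep("canonical_u12", config$nCanonicalU12),
            rep("u2u12_like", config$nNonCanonical),
            rep("template_switch", config$nTemplateSwitch),
            rep("homopolymer", config$nHomopolymer),
            rep("snp_confounded", config$nSnpConfounded),
            rep("edited_GT_AA", config$nEditedGTAA),
            rep("edited_AT_AG", config$nEditedATAG),
            rep("alt3_pair", config$nAlt3Pairs),
            rep("alt5_pair", config$nAlt5Pairs),
            rep("skip_triple", config$nSkipTriples))
  pieces <- character(0)
  rows <- list()
  offset <- 0L
  for (gi in seq_along(plan)) {
    for (try in seq_len(50L)) {
      cassette <- .buildCassette(plan[gi], config, pwms, deviationIdx = gi)
      if (.cassetteClean(cassette)) break
      if (try == 50L) stop("could not build a clean cassette for ", plan[gi])
    }
    strand <- if (gi %% 2L == 0L) "-" else "+"
    clen <- nchar(cassette$seq)
    seqOut <- if (strand == "-") .revcomp(cassette$seq) else cassette$seq
    pad <- .randomSeq(config$spacer, config$backgroundGC)
    pieces <- c(pieces, pad, seqOut)
    offset <- offset + config$spacer
    for (j in cassette$junctions) {
      if (strand == "+") {
        gs <- offset + j$s; ge <- offset + j$e
        ePos <- if (!is.null(j$edited_offset)) offset + j$edited_offset else NA
        sPos <- if (!is.null(j$snp_offset)) offset + j$snp_offset else NA
      } else {
        gs <- offset + clen - j$e; ge <- offset + clen - j$s
        ePos <- if (!is.null(j$edited_offset)) offset + clen - 1L - j$edited_offset else NA
        sPos <- if (!is.null(j$snp_offset)) offset + clen - 1L - j$snp_offset else NA
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sprintf("gene%03d", gi), class = j$class,
        subtype = if (!is.null(j$subtype)) j$subtype else NA_character_,
        chrom = "sim1", start = gs, end = ge, strand = strand,
        donor = j$donor, acceptor = j$acceptor,
        intron_len = j$e - j$s, u12 = isTRUE(j$u12),
        event = if (!is.null(j$event)) j$event else "CONSTITUTIVE",
        psi = if (!is.null(j$psi)) j$psi else 1,
        repeat_len = if (!is.null(j$repeat_len)) j$repeat_len else NA_integer_,
        homopolymer_run = if (!is.null(j$homopolymer_run)) j$homopolymer_run
                          else NA_integer_,
        edited_pos0 = ePos, snp_pos0 = sPos,
        stringsAsFactors = FALSE)
    }
    offset <- offset + clen
  }
  pieces <- c(pieces, .randomSeq(config$spacer, config$backgroundGC))
  genome <- Biostrings::DNAStringSet(paste0(pieces, collapse = ""))
  names(genome) <- "sim1"
  truth <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(genome = genome, truth = truth)
}

#' @rdname simulateReference
#' @param truth truth table from \code{simulateReference}.
#' @return \code{truthJunctions}: the truth records as a \code{GRanges}.
#' @export
truthJunctions <- function(truth) {
  junctionRanges(truth$chrom, truth$start, truth$end, truth$strand,
                 class = truth$class, gene = truth$gene)
}

.samSpanningReads <- function(genome, truth, config, source) {
  chrLen <- Biostrings::width(genome)[1L]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome)[1L], chrLen))
  rl <- config$readLength
  anchors <- seq(10L, by = 4L, length.out = config$supportPerSource)
  recs <- character(0)
  for (i in seq_len(nrow(truth))) {
    s0 <- truth$start[i]; e0 <- truth$end[i]
    flag <- if (truth$strand[i] == "-") 16L else 0L
    for (a in anchors) {
      b <- rl - a
      seq <- paste0(.getSeq0(genome, truth$chrom[i], s0 - a, s0),
                    .getSeq0(genome, truth$chrom[i], e0, e0 + b))
      recs <- c(recs, paste(
        sprintf("%s_j%d_a%d_%s", truth$gene[i], i, a, source), flag,
        truth$chrom[i], s0 - a + 1L, 50L,
        sprintf("%dM%dN%dM", a, e0 - s0, b), "*", 0L, 0L,
        seq, "*", "NM:i:0", sep = "\t"))
    }
  }
  c(hdr, recs)
}

#' Simulate alignment, coverage, variant and pileup evidence
#'
#' Emits junction-spanning gapped alignments (SAM, one file per source,
#' \code{supportPerSource} distinct read sequences per junction), a
#' per-sample junction coverage table, a VCF with the SNPs that confound the
#' snp_confounded implants, and a pileup table planting A>G evidence at the
#' edited implants' adenosines. In \code{mode = "exact"} coverages equal the
#' planted values; in \code{mode = "noisy"} member coverages are binomial
#' draws of the group depth at the planted psi.
#'
#' @param genome,truth output of \code{\link{simulateReference}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @param dir output directory for the SAM/VCF/TSV files.
#' @param mode "exact" or "noisy".
#' @return list with \code{samFiles}, \code{coverage} (data.frame),
#'   \code{coverageFile}, \code{vcfFile}, \code{pileup} (data.frame),
#'   \code{pileupFile}.
#' @export
simulateEvidence <- function(genome, truth, config = simulationConfig(),
                             dir = tempfile("simev"),
                             mode = c("exact", "noisy")) {
  mode <- match.arg(mode)
  set.seed(config$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samFiles <- character(0)
  for (src in config$sources) {
    f <- file.path(dir, paste0(src, ".sam"))
    writeLines(.samSpanningReads(genome, truth, config, src), f)
    samFiles[src] <- f
  }
  # per-sample coverage: group depth per gene cassette, split by planted psi
  cov <- matrix(0L, nrow(truth), length(config$samples),
                dimnames = list(NULL, config$samples))
  for (g in unique(truth$gene)) {
    idx <- which(truth$gene == g)
    for (smp in config$samples) {
      depth <- .sampleOne(seq(config$coverageRange[1L], config$coverageRange[2L]))
      cov[idx, smp] <- if (mode == "exact")
        as.integer(round(depth * truth$psi[idx]))
      else stats::rbinom(length(idx), depth, truth$psi[idx])
    }
  }
  coverage <- data.frame(chrom = truth$chrom, start = truth$start,
                         end = truth$end, strand = truth$strand,
                         stringsAsFactors = FALSE)
  for (smp in config$samples) coverage[[paste0("cov.", smp)]] <- cov[, smp]
  covFile <- file.path(dir, "coverage.tsv")
  utils::write.table(coverage, covFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # VCF for the SNP-confounded implants
  vcfFile <- file.path(dir, "variants.vcf")
  snp <- truth[!is.na(truth$snp_pos0), , drop = FALSE]
  vcfLines <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s,length=%d>", names(genome)[1L],
                        Biostrings::width(genome)[1L]),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(snp)) {
    ref <- .getSeq0(genome, snp$chrom, snp$snp_pos0, snp$snp_pos0 + 1L)
    alt <- ifelse(ref == "A", "T", "A")
    vcfLines <- c(vcfLines, sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t.",
                                    snp$chrom, snp$snp_pos0 + 1L, ref, alt))
  }
  writeLines(vcfLines, vcfFile)
  # pileup rows for every terminal adenosine of the edited implants
  pile <- list()
  ed <- truth[grepl("^edited_", truth$class), , drop = FALSE]
  for (i in seq_len(nrow(ed))) {
    s0 <- ed$start[i]; e0 <- ed$end[i]; minus <- ed$strand[i] == "-"
    gpos <- if (minus) c(e0 - 1L, e0 - 2L, s0 + 1L, s0)
            else c(s0, s0 + 1L, e0 - 2L, e0 - 1L)
    bases <- strsplit(paste0(ed$donor[i], ed$acceptor[i]), "")[[1L]]
    for (p in which(bases == "A")) {
      edited <- gpos[p] == ed$edited_pos0[i]
      aN <- if (edited) 10L else 20L
      gN <- if (edited) 10L else 0L
      row <- data.frame(chrom = ed$chrom[i], pos = gpos[p],
                        strand = ed$strand[i], countA = 0L, countC = 0L,
                        countG = 0L, countT = 0L, stringsAsFactors = FALSE)
      if (minus) { row$countT <- aN; row$countC <- gN }
      else { row$countA <- aN; row$countG <- gN }
      pile[[length(pile) + 1L]] <- row
    }
  }
  pileup <- if (length(pile)) do.call(rbind, pile)
            else data.frame(chrom = character(0), pos = integer(0),
                            strand = character(0), countA = integer(0),
                            countC = integer(0), countG = integer(0),
                            countT = integer(0))
  pileupFile <- file.path(dir, "pileup.tsv")
  utils::write.table(pileup, pileupFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(samFiles = samFiles, coverage = coverage, coverageFile = covFile,
       vcfFile = vcfFile, pileup = pileup, pileupFile = pileupFile)
}
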