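---
title: "SpliceSieve: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpliceSieve: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Nearly all spliceosomal introns carry GT–AG, GC–AG or AT–AC terminal
dinucleotides. Junctions with any other termini ("non-canonical") do occur in
RNA-seq data, but the observed set is dominated by false positives: alignment
errors around polymorphisms, indel-prone homopolymers next to genuine
canonical junctions, and reverse-transcriptase template switching across
direct repeats. SpliceSieve implements a discovery pipeline that extracts
junctions from gapped alignments, filters them stringently, and separates the
residue into (i) junctions whose flanking sequence still fits the U2 or U12
spliceosomal consensus ("U2/U12-like") and (ii) everything else
("non-U2/U12"), which it further partitions into artifact signatures. It also
quantifies alternative splice-site usage (psi), detects A-to-I editing that
converts GT–AA / AT–AG termini into functional canonical sites, profiles
splicing-regulatory-element (SRE) hexamer density, and tests cross-species
conservation.

# Coordinates and containers

Junctions are intron intervals. Every file interface (junction TSV, BED
track, mapping TSV, pileup TSV) and the `junctionRanges()` constructor speak
0-based half-open coordinates: `start` is the first intronic base, `end` one
past the last. Internally junctions live in `GRanges` (1-based closed, the
Bioconductor convention); the conversion happens exactly once, in the
constructor and the writers. Genomes are named `DNAStringSet`s, uppercased on
load; soft-masking is recorded per sequence but never used by a filter, which
instead rely on an explicit repeat-interval BED and the DUST score.

# Extraction and the stringent filters

A gapped alignment contributes a junction only when both flanking aligned
blocks reach the minimum anchor (8 nt for RNA-seq, 15 nt and zero mismatches
for cDNA/EST evidence). Support counts *distinct read sequences*, not
alignments, so PCR duplicates collapse; a junction is "present" in a source
at 3 distinct sequences and must be present in at least 2 independent sources
(per-source presence, never pooled counts). Non-canonical candidates are
additionally discarded when

* a SNP or indel overlaps their terminal dinucleotides or exonic anchor
  windows (25 nt, matching the aligner's mismatch window; the exact read
  footprint is not defined more precisely by the published protocol, so the
  anchor window is our operationalisation);
* any anchor or intron-terminus window exceeds the classic DUST triplet
  score threshold (window 64, word 3, threshold 2.0 — DUST's conventional
  defaults, since the protocol names the tool without parameters);
* (for diploid designs) the junction is not seen with support of at least 3
  in *both* haplotype alignments after translation to common coordinates.
  The published wording ("coincident alignments") is ambiguous about whether
  3 is per haplotype or overall; we use the stricter per-haplotype reading.

SAM ingestion goes through Rsamtools/GenomicAlignments; VCFs through
VariantAnnotation; BED through rtracklayer. Since the per-read SAM NM tag is
the only mismatch information available, EST mode requires NM = 0 for the
whole read rather than only in the anchor blocks — slightly stricter than
the stated rule.

# PWM scoring and classification

Four position frequency matrices are trained from user-supplied canonical
junctions: U2 donor (3 exonic + 6 intronic nt), U2 acceptor (14 intronic + 3
exonic), U12 donor (3 + 9) and U12 acceptor (14 + 3). These widths are
defaults, chosen to cover the informative positions of the respective
consensus; published reference matrices vary and the windows are fully
configurable. Column frequencies are `(count + pseudocount)/(n + 4p)`.

A window's raw score is the sum of the observed-base frequencies; it is
min–max normalised so that the per-column best sum maps to 100 and the worst
to 0 (the Shapiro–Senapathy convention — a fixed cutoff of 70.00 only makes
sense on such a percent-like scale). A junction's model score is the *mean*
of its donor and acceptor site scores and its final score the *max* over the
U2 and U12 models; the original protocol assigns a single score per junction
without stating the combiner, so the mean/max combination is our design
choice, flagged for sensitivity analysis.

The null model scrambles each candidate's site windows by within-window
letter permutation — composition-preserving, which is the most defensible
reading of "scrambled sequences" (column-shuffling would retain positional
information). All scrambled final scores are pooled and the threshold is the
nearest-rank 95th percentile (no interpolation, hence exactly reproducible).

Classification applies, in order: intron shorter than 80 nt → non-U2/U12;
final score above 70.00 → U2/U12-like; score in `[threshold, 70.00]` *and*
sharing a donor or acceptor coordinate with a canonical junction →
U2/U12-like; otherwise non-U2/U12. The stated rule places the calibrated
threshold below 70.00; if a calibration ever exceeds it the rescue band is
empty and the classifier warns rather than guessing.

# Placement ambiguity

A direct repeat of length `r` at the junction flanks creates `r + 1` intron
placements with identical spliced product. `enumeratePlacements()` slides the
intron while the flanking bases match (capped at ±30 nt — longer repeats are
template-switch territory) and asserts spliced-product identity for every
placement. If any placement reads canonical dinucleotides the junction is
*rescued*: reported canonical, never as a non-canonical discovery. Otherwise
the placement with the best PWM fit is chosen; ties break toward the
smallest absolute shift, then leftmost (the tie-break is ours; score ties are
not discussed in the original protocol).

# Alternative splicing

Junctions sharing a donor or acceptor site form splice-variant groups
(transitive closure). psi for a junction in a sample is its coverage divided
by the group's summed coverage — the group is our denominator choice, since
"total RNA-seq coverage of each splice junction" leaves it open. The 95%
interval is the Wilson score interval (better extreme-psi behaviour than
normal approximation, still a standard "binomial confidence interval").
The minor-isoform rule keeps junctions whose total coverage is at least 1/20
of the group's most abundant member, inclusive at the boundary and pooled
over samples. Intron retention requires an optional unspliced-depth track
(bedGraph); a junction is flagged when mean intronic depth reaches half the
flanking exonic depth (the 0.5 fraction is configurable — the original
category list does not state a detection rule).

# Artifact signatures and editing

Non-U2/U12 candidates partition exhaustively and exclusively into:
near-canonical (both ends within 10 nt of a canonical junction) with an
adjacent exonic homopolymer run of ≥ 5 nt; near-canonical without such a
run; isolated with a template-switch signature (direct repeat ≥ 6 nt *or*
intronic GC ≥ 0.6); and unexplained. The repeat/GC cutoffs are deliberate,
configurable defaults: the source evidence is distributional (artifact
classes show longer repeats and higher GC), so all raw measurements are
reported alongside the partition for re-thresholding. GC is computed over
the intron by default; the region is configurable because the original
figure does not state it.

Editing evidence at a terminal adenosine passes at ≥ 3 G-supporting reads
and a G fraction ≥ 0.2 (invented, configurable thresholds — the published
criterion is only "consistent A>G mismatches"). Passing adenosines are
recoded to G and the pair re-categorised; GT–AA and AT–AG junctions thereby
become canonical GT–AG, the biological signature of A-to-I editing at splice
sites. Genomic T>C evidence on minus-strand junctions is translated to
transcript-strand A>G by the junction-level wrapper.

# SRE density

Hexamer sets (ESE/ESS/ISE/ISS; EIE = ESE+ISS, IIE = ISE+ESS) are inputs —
the published screens are licensed data and ship with their own terms, so
SpliceSieve reads plain hexamer lists instead of embedding them. Density at
an offset is the fraction of junctions with a set hexamer *starting* there
(all overlapping occurrences count; collapsing runs would discard
information and the original counting rule is unstated), over four 100-nt
windows around the splice sites, smoothed by a centred width-10 moving
average (NA at edges the average cannot cover). Group comparison uses a 2×2
Pearson chi-squared (1 df, no continuity correction) on start vs non-start
position totals.

# The simulator

`simulateReference()` builds one gene cassette per implant on a single
chromosome, alternating strands, and emits matching evidence
(`simulateEvidence()`): spanning gapped alignments in SAM (4 distinct
anchors per junction per source, 2 sources), a per-sample coverage table, a
VCF for the SNP-confounded implants, and pileups planting A>G evidence at
the edited implants. Site contexts are drawn from sharply peaked generating
consensus models; the classifier later re-learns essentially the same
matrices from the simulated canonical junctions, which is what makes
recovery provable rather than probabilistic. Non-canonical implant contexts
are the exact consensus with exactly one deviant terminal dinucleotide
(intron ≥ 84 nt), so their PWM scores clear the 70.00 rule with a wide
margin; template-switch implants use 40–70-nt introns (below the 80-nt rule)
with a planted 8-nt repeat and GC ≈ 0.7; homopolymer implants pair a
canonical junction with a false junction 3/9 nt away whose apparent intron
is 78 nt, flanked by a 5-nt exonic T run pinned so that it admits no
placement shift. A rejection step certifies every non-canonical implant
against accidental canonical placements, eroded repeats, and the DUST
filter, resampling the cassette when the random background violates the
construction (this keeps the end-to-end guarantees seed-independent).

Default study conditions: 100 canonical implants (15 of them AT–AC U12-type,
enough to train the U12 matrices), 20 U2/U12-like, 10 template-switch, 10
homopolymer, 5 SNP-confounded and 4 edited implants; exons of 150 nt;
introns 84–400 nt; per-sample group depths 20–60 reads; background GC 0.45.
These sizes keep a full simulate–extract–classify cycle around a minute on
one core while leaving every class populated enough for rate estimates.

What the simulator does *not* emulate: sequencing errors beyond the planted
artifact classes, expression-level realism, multi-exon gene structure beyond
the implanted events, intron-retention reads, or repeat families. Passing
recovery tests therefore demonstrates the pipeline's decision logic under
its stated assumptions, not its behaviour on real libraries.

# Numerical choices and degenerate inputs

Nearest-rank percentiles throughout (no interpolation). Score ties in
placement resolution break deterministically (smallest |shift|, then
leftmost). N bases never classify as canonical, score as the column minimum,
and are excluded from GC denominators; an all-N region is an error rather
than a silent 0/0. Out-of-bounds genome access is always an error, never a
clip; junction-library flanks that would cross a chromosome end skip the
record with a warning. Empty inputs (no junctions to calibrate on, zero
group coverage for psi, zero chi-squared marginals) raise errors distinct
from negative results.

# Interfaces

All analysis steps are exported R functions; `discoverSpliceSites()` chains
them. A thin command-line front-end
(`inst/scripts/splicesieve.R`) exposes simulate / extract / classify /
events / artifacts / editing / sre / conserve / track subcommands over the
same functions for shell pipelines. The genome-browser track writer encodes
each junction as an intron flanked by two 8-nt exon blocks, names it
`<donor>-<acceptor>[<coverage>]`, and colours it by class and score (greens
for U2/U12-like, lighter with higher similitude; reds for non-U2/U12,
lighter with lower; canonical in fixed grey; five discrete bins per ramp).

# Known limitations

Read alignment itself is out of scope: the package consumes gapped SAM/BAM
(or BED12 junction evidence) produced by an external aligner, and the
junction-library FASTA it writes is meant to be fed back through such an
aligner. Lift-over chains are consumed as precomputed mapping tables.
Branch-point and polypyrimidine-tract models, RNA secondary structure, and
annotation-wide overlap analyses are deliberately absent.
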