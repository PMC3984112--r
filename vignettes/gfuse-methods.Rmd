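---
title: "Fusion transcript detection in degraded FFPE RNA-Seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion transcript detection in degraded FFPE RNA-Seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfuse)
```

## The problem

RNA extracted from formalin-fixed paraffin-embedded (FFPE) tumor blocks is
heavily fragmented (median fragment around 100 bp) and intron-rich: roughly
60% of uniquely mapped read bases fall in introns because substantial amounts
of unspliced pre-mRNA survive fixation while cytoplasmic mRNA degrades.
Libraries are therefore short-insert, low-complexity, single-end (50 bp here)
and strand-specific. Under these conditions, paired-end "bridging read"
evidence for fusion transcripts does not exist, and split reads spanning a
fusion junction are rare — often one read, sometimes none, per true event in
a sample. gfuse compensates by pooling evidence across a cohort: candidate
junctions nominated in any sample are re-examined in every sample, using both
read alignment and an expression-discontinuity statistic.

A fusion junction is written `+chr17:5250220->+chr17:11532734`: the donor
position is the last base of the preserved donor side, the acceptor position
the first base of the preserved acceptor side, and the sign gives the
transcription direction on the chromosome. All internal coordinates are
1-based inclusive; the UCSC refGene annotation's 0-based half-open
coordinates are converted once, at parse time.

## Pipeline

1. **Filter and map.** Reads must have at least 15 bases with base quality
   Q20 or higher, and must not match an abundant-sequence blacklist (rRNA-,
   mitochondria-, PhiX-like) with 45 or more of 50 bases. Surviving reads are
   mapped by a seed-and-extend aligner (15-mer seeds, both strands) that
   reports contiguous placements, local splices (two co-directional segments
   on one chromosome with a gap under 1 Mb) and *distant* splices (any other
   two-segment placement). Uniquely mapped local reads feed per-feature base
   counts over every exon and intron ("gene tables").
2. **Retest.** Each distant-spliced read is realigned with settings that
   favor a single-locus placement, allowing one indel of at most 1 bp. If
   44 or more bases match at one locus, the read is a local alignment in
   disguise and is discarded.
3. **Extract candidates.** Reads with a mismatch within 5 bp of the junction
   on either segment, or with a segment antisense to its overlapping gene
   (the protocol is directional), are removed. Remaining reads are grouped by
   exact junction, annotated against the collapsed per-symbol gene models,
   and screened: junctions touching pseudogenes, unannotated regions or
   ambiguously overlapping genes are dropped, as are within-gene
   rearrangements and read-throughs. A candidate must satisfy at least one
   of: different chromosomes, different genes, opposite strands, or at least
   1 Mb separation on one chromosome.
4. **Templates.** Per candidate, five 100 bp templates are built (fusion,
   donor mRNA, acceptor mRNA, donor pre-mRNA, acceptor pre-mRNA; exonic
   flanks are spliced sequence, pre-mRNA flanks raw genomic sequence; no
   fusion pre-mRNA exists because the DNA breakpoint is unknown). Candidates
   whose templates are byte-identical to another set's, or whose 300 bp
   donor/acceptor templates share an exact substring longer than 14 bp, or
   which lack a full exonic flank, are removed. Survivors are pooled across
   cohorts into one template index.
5. **Remap.** For each library, reads near any template locus plus all
   unmapped reads are remapped to the template index (contiguous placements
   only). Junction support requires a uniquely best placement on the fusion
   template spanning the midpoint by at least 6 bases with no mismatch
   inside the overhang.
6. **Profile expression.** Gene tables are normalized by median-of-ratios
   library size factors. For each candidate and sample, feature counts are
   floored at 5 reads' worth of bases, converted to per-length coverages, and
   summarized as Interrupt Ratios (IR): mean preserved-side coverage divided
   by mean discarded-side coverage, separately for donor and acceptor. The
   intron immediately downstream of the donor splice site and the one
   immediately upstream of the acceptor splice site are excluded — the DNA
   breakpoint lies somewhere inside them. Profiling is per cohort; samples
   are ranked by max(IR~donor~, IR~acceptor~).
7. **Classify.** Tier-1: at least two non-redundant junction reads
   (distinct offset/sequence pairs), regardless of expression. Tier-2:
   exactly one non-redundant read plus an interrupted expression pattern.
   Tier-3: no read, an interrupted pattern, and the same junction called
   Tier-1/2 in another sample (or supplied on an externally confirmed list).
   Junctions shared by samples none of which has evidence are removed.
   Reading frame is predicted from CDS phases at the junction; multiple
   junctions between one gene pair in a sample are all reported with the
   best-supported one flagged dominant.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `qualMinBases` / `qualMinScore` | 15 / 20 | quality filter threshold |
| `blacklistMinMatches` | 45 | abundance filter (matches out of 50) |
| `k` | 15 | aligner seed length |
| `minSeg` | 16 | minimum split-segment length |
| `retestMatched` | 44 | retest discard threshold (matched bases) |
| `junctionMismatchWindow` | 5 | junction-proximal mismatch window (bp) |
| `homologyMinShared` | 15 | homology removal (= "more than 14 bp") |
| `minCandidateDistance` | 1e6 | same-chromosome candidacy distance (bp) |
| `overhangMin` | 6 | junction overhang for support reads |
| `padFloorReads` | 5 | count floor, in reads (x read length bases) |
| `irFoldMedian` / `irFloor` | 3 / 2 | interrupted-expression call |

Scoring in the internal aligner is match +1, mismatch −1, with a penalty of 2
for introducing a splice; uniqueness demands a strictly best placement. The
mapper's guarantee is deliberately modest: a split read is recovered exactly
when each segment retains an intact seed (at least `k`+5 exact bases per
side, at most one mismatch per segment). That envelope matches what a 15-mer
seed index can see, and the property-based aligner tests stay inside it.

## Design decisions worth knowing

* **Junction slide and exon-boundary snapping.** When the first acceptor
  bases happen to equal the genomic continuation of the donor (or vice
  versa), the split placement is score-equivalent over a small breakpoint
  range. The mapper reports that slide range and the junction module prefers
  the shift whose donor/acceptor coordinates coincide with annotated exon
  3'/5' boundaries (production aligners consume known splice sites the same
  way); ties resolve to the maximal donor segment. This is what makes
  junction coordinates base-pair exact on fusions planted at exon
  boundaries.
* **IR formula.** The ratio is computed on per-length coverages
  (counts / size factor, floored, divided by feature length), averaged per
  side over features. Averaging unweighted across features, rather than
  pooling bases, keeps a long intron from dominating a side — consistent
  with per-feature, length-normalized expression displays. The count floor
  is specified in reads; since the gene table stores base counts, it is
  applied as 5 × read length bases.
* **Interrupted threshold.** No numeric cutoff exists in the source method
  (samples were reviewed against the cohort heatmap); the package flags a
  sample when its IR reaches both 3× the cohort median and an absolute 2.0.
  The fold-of-median term adapts to baseline noise; the absolute floor keeps
  single-sample cohorts and flat cohorts conservative.
* **Overhang ≥ 6 with a clean overhang.** The source method keeps a
  documented 10 bp-overhang read and sets no explicit minimum. Six bases
  balances that precedent against the chance of a random 50-mer matching a
  template across the midpoint; "clean" means no mismatch within the
  overhang distance of the midpoint on either side.
* **Homology by exact longest common substring.** The original BLAST check
  is replaced by an exact common-substring test at the same threshold
  ("more than 14 bp"). At 300 bp scale this is deterministic,
  dependency-free, and stricter than gapped BLAST hits.
* **Read-through definition.** Named but not defined in the source: here,
  co-directional, different genes, acceptor downstream of the donor in
  transcription direction, under 1 Mb (mirroring the candidacy distance).
* **Manual review replaced by rules.** The published tier rules are applied
  deterministically; Tier-3's "similar expression to a confirmed fusion"
  anchor becomes interrupted-flag + cross-sample Tier-1/2 support (or a
  user-supplied confirmed-junction list), since no wet lab exists here.
* **Criterion-4 distance** is measured junction-to-junction (whether the
  source used junction or gene distance is unstated).
* **Template remapping is sense-strand only**, matching the directional
  protocol; templates are written 5'→3' in the transcription direction of
  their source gene, fusion templates donor-then-acceptor.

## The simulator

`buildToyCohort()` generates the study conditions end to end: a toy genome
(default two 2.4 Mb chromosomes, 20 genes of 4–8 exons with 150–300 bp exons
and 0.4–2 kb introns), UCSC-style annotation, an rRNA-like/PhiX-like
blacklist, and per-sample 50 bp directional FASTQ. Fragment lengths are
log-normal with median 100 bp (σ~log~ = 0.45, a free parameter — only the
median is reported for FFPE RNA) and a 20 bp floor; fragments shorter than
the read length are dropped, as vendor pipelines drop adapter-dominated
reads. Reads are the 5' 50 bp of each fragment, sense strand. A pre-mRNA
read fraction of 0.72 reproduces the ~60% intronic base fraction of FFPE
libraries given the default gene architecture (introns are ~80% of the gene
span). Contaminants default to 5% of reads. Each gene's CDS is written into
the genome as a clean ORF (ATG, stop-free codons, terminal stop), which is
what makes translation-based frame oracles exact.

Fusions are planted at exon boundaries; carrier samples receive exactly
`junctionReads` junction-spanning reads (distinct offsets, ≥ 20 bp on each
side) plus background fusion reads that avoid the junction, so Tier-1
(≥ 2 reads), Tier-2 (exactly 1) and Tier-3 (0 reads, expression only)
scenarios are constructed precisely rather than approximately. Fusion
abundance is `expressionFold` times the acceptor's baseline, which drives
the acceptor-side IR discontinuity.

What the simulator does *not* emulate: formalin adduct miscalls and other
position-dependent error profiles, PCR duplication, adapter read-through,
repetitive and paralogous genome structure, and realistic transcriptome
complexity (tens of genes, not tens of thousands). Passing tests on this
cohort demonstrate the pipeline's logic — filters, template discrimination,
normalization, tiering — under the stated fragment/intron/strand regime, not
performance on real FFPE libraries.

## Problem sizes and numerical notes

The validation cohort used by the tests and by `scripts/acceptance.R` is 12
samples × 4,000 reads over a 4.8 Mb genome with six fusions
(`exampleCohortConfig()`); the specificity cohort is 12 × 17,000 fusion-free
reads; the aligner equivalence check uses 200 reads against a 10 kb genome
with an all-positions oracle; frame prediction is checked against ribosome
simulation on 50 random fusions. These sizes exercise every code path while
keeping a full run in minutes on one core.

Degenerate inputs are handled explicitly: an empty candidate list
short-circuits to an empty (but well-formed) report; a cohort of one sample
has no cohort statistics and uses the absolute IR floor only; features with
a zero geometric mean are excluded from size-factor medians, and an all-zero
library is an error; an IR side left empty after the breakpoint-intron
exclusion yields an undefined-IR marker (NA) rather than a number.

## Limitations

Cohort evidence is only as good as the cohort: a private fusion with one
read and no expression discontinuity is rejected by design. The toy aligner
is not a production spliced aligner — real data should enter through the SAM
ingestion path using alignments from a dedicated tool. The IR statistic
assumes the gene table captures baseline expression on both sides of the
junction; genes silent in every sample give uninformative (floored) ratios.
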