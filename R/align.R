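#' Pipeline tuning parameters
#'
#' Defaults encode the published filter thresholds (quality: >= 15 bases at
#' Q20+; abundance: >= 45/50 matches to a blacklist sequence; retest: discard
#' a distant read whose best single-locus local alignment has >= 44 matched
#' bases with a gap tolerance of 1 bp; junction mismatch window: 5 bp;
#' homology: shared exact substring of more than 14 bp; candidacy distance:
#' 1 Mb) together with internal aligner settings for toy-scale genomes.
#'
#' @param readLen read length in bases
#' @param k k-mer seed length of the genome index
#' @param minSeg minimum split-segment length in the query
#' @param maxIntron maximum gap treated as a local (within-gene) splice
#' @param splicePenalty score penalty of a two-segment placement
#' @param maxFrames cap on candidate placements examined per read
#' @param qualMinBases,qualMinScore quality filter: keep a read with at least
#'   `qualMinBases` bases at quality >= `qualMinScore`
#' @param blacklistMinMatches abundance filter: drop at this many matches
#' @param blacklistK seed length for blacklist matching
#' @param retestMatched discard a distant read whose retest local alignment
#'   reaches this many matched bases
#' @param junctionMismatchWindow drop junction reads with a mismatch within
#'   this many terminal bases of either segment
#' @param homologyMinShared remove a template set sharing an exact substring
#'   of at least this length between donor and acceptor templates
#' @param minCandidateDistance same-chromosome candidacy distance (criterion 4)
#' @param overhangMin minimum junction overhang of a fusion support read
#' @param padFloorReads count floor in reads (applied as reads x readLen bases)
#' @param irFoldMedian,irFloor interrupted-expression call: IR at least
#'   `irFoldMedian` times the cohort median and at least `irFloor`
#' @return a named list of parameters
#' @export
gfuseParams <- function(readLen = 50, k = 15, minSeg = 16, maxIntron = 1e6,
                        splicePenalty = 2, maxFrames = 96,
                        qualMinBases = 15, qualMinScore = 20,
                        blacklistMinMatches = 45, blacklistK = 8,
                        retestMatched = 44, junctionMismatchWindow = 5,
                        homologyMinShared = 15, minCandidateDistance = 1e6,
                        overhangMin = 6, padFloorReads = 5,
                        irFoldMedian = 3, irFloor = 2) {
  list(readLen = readLen, k = k, minSeg = minSeg, maxIntron = maxIntron,
       splicePenalty = splicePenalty, maxFrames = maxFrames,
       qualMinBases = qualMinBases, qualMinScore = qualMinScore,
       blacklistMinMatches = blacklistMinMatches, blacklistK = blacklistK,
       retestMatched = retestMatched,
       junctionMismatchWindow = junctionMismatchWindow,
       homologyMinShared = homologyMinShared,
       minCandidateDistance = minCandidateDistance,
       overhangMin = overhangMin, padFloorReads = padFloorReads,
       irFoldMedian = irFoldMedian, irFloor = irFloor)
}

#' k-mer index over a genome
#'
#' @slot ptr external pointer to the C++ index
#' @slot chromNames chromosome names, in index order
#' @slot k seed length
#' @name GenomeIndex-class
#' @aliases GenomeIndex
#' @exportClass GenomeIndex
setClass("GenomeIndex",
  representation(ptr = "externalptr", chromNames = "character", k = "integer"))

#' Build a k-mer seed index for the internal aligner
#' @param genome a named [Biostrings::DNAStringSet]
#' @param k seed length (default 15)
#' @return a [GenomeIndex-class]
#' @export
genomeIndex <- function(genome, k = 15) {
  seqs <- as.character(genome)
  new("GenomeIndex", ptr = .cppIndexBuild(seqs, as.integer(k)),
      chromNames = names(genome), k = as.integer(k))
}

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex over", length(object@chromNames), "sequence(s), k =",
      object@k, "\n")
})

#' Base-quality read filter
#'
#' A read is kept when it has at least `minBases` bases (at any position)
#' with a base quality of `minScore` or above.
#'
#' @param quals a [Biostrings::BStringSet] or character vector of
#'   Sanger-scaled (offset 33) quality strings
#' @param minBases,minScore filter thresholds
#' @return logical vector, TRUE = keep
#' @export
passesQualityFilter <- function(quals, minBases = 15, minScore = 20) {
  q <- as.character(quals)
  .cppQualCount(q, 33L, as.integer(minScore)) >= minBases
}

#' Abundant-sequence (blacklist) read filter
#'
#' Drops reads that align to any blacklist sequence (rRNA-like, PhiX-like,
#' mitochondrial, ...) with at least `minMatches` matching bases out of the
#' read length (>= 45/50 by default); either strand, no gaps.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector
#' @param blacklist [Biostrings::DNAStringSet] of abundant sequences
#' @param minMatches matched-base threshold at which a read is dropped
#' @param k seed length used to locate candidate placements
#' @return logical vector, TRUE = keep
#' @export
passesAbundanceFilter <- function(reads, blacklist, minMatches = 45, k = 8) {
  if (is.null(blacklist) || length(blacklist) == 0)
    return(rep(TRUE, length(reads)))
  m <- .cppBlacklistMatches(as.character(blacklist), as.character(reads),
                            as.integer(k))
  m < minMatches
}

.KINDS <- c("unmapped", "local", "local_spliced", "distant")

#' Map reads with the internal seed-and-extend aligner
#'
#' Returns the best-scoring placement per read: contiguous (`local`), locally
#' spliced (two segments on one chromosome/strand in transcription-consistent
#' order with a gap below `maxIntron`), or distant-spliced (`distant`: two
#' segments on any chromosomes/strands). `unique` is TRUE only when the best
#' score is achieved by exactly one placement. For split placements the
#' breakpoint is slid to the maximal donor segment and the slide-equivalent
#' breakpoint range is reported (`slide_lo`/`slide_hi`), so downstream
#' annotation can snap junctions to exon boundaries.
#'
#' @param index a [GenomeIndex-class]
#' @param reads [Biostrings::DNAStringSet] or character vector (named ids)
#' @param params [gfuseParams()]
#' @return a `data.frame` with one row per read: `read_id`, `kind`, `score`,
#'   `unique`, per-segment coordinates (`chrom1`, `strand1`, `gstart1`, ...),
#'   mismatch query positions, `breakpoint`, slide range and the donor /
#'   acceptor genomic positions of split placements
#' @export
mapReads <- function(index, reads, params = gfuseParams()) {
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  res <- .cppMapReads(index@ptr, as.character(reads),
                      as.integer(params$minSeg), params$maxIntron,
                      as.integer(params$splicePenalty),
                      as.integer(params$maxFrames))
  df <- data.frame(read_id = ids, kind = .KINDS[res$kind + 1L],
                   score = res$score, unique = res$unique,
                   stringsAsFactors = FALSE)
  df$chrom1 <- index@chromNames[res$chrom1]
  df$strand1 <- c("-", NA, "+")[res$strand1 + 2L]
  df$gstart1 <- res$gstart1; df$gend1 <- res$gend1
  df$qstart1 <- res$qstart1; df$qend1 <- res$qend1
  df$nmis1 <- res$nmis1; df$mis1 <- as.character(res$mis1)
  df$chrom2 <- index@chromNames[res$chrom2]
  df$strand2 <- c("-", NA, "+")[res$strand2 + 2L]
  df$gstart2 <- res$gstart2; df$gend2 <- res$gend2
  df$qstart2 <- res$qstart2; df$qend2 <- res$qend2
  df$nmis2 <- res$nmis2; df$mis2 <- as.character(res$mis2)
  df$breakpoint <- res$breakpoint
  df$slide_lo <- res$slide_lo; df$slide_hi <- res$slide_hi
  df$donor_pos <- res$donor_g; df$acceptor_pos <- res$acceptor_g
  df
}

#' Local-realignment retest of distant-spliced reads
#'
#' Recomputes the best single-locus local alignment of each read with
#' parameters favoring local placement (at most one indel of 1 bp). A read
#' whose local alignment reaches `retestMatched` (default 44) matched bases is
#' a false-positive distant splice and is discarded.
#'
#' @param index a [GenomeIndex-class]
#' @param reads reads previously reported distant-spliced
#' @param params [gfuseParams()]
#' @return a `data.frame` with `read_id`, `local_matches` and `keep`
#' @export
retestDistantReads <- function(index, reads, params = gfuseParams()) {
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  m <- .cppRetestLocal(index@ptr, as.character(reads),
                       as.integer(params$maxFrames))
  data.frame(read_id = ids, local_matches = m,
             keep = m < params$retestMatched, stringsAsFactors = FALSE)
}

# GRanges of the aligned segments of an alignment table (optionally restricted
# to uniquely mapped local/local_spliced rows, the gene-table contributors)
.segment_ranges <- function(aln, uniqueOnly = TRUE) {
  use <- if (uniqueOnly)
    aln$kind %in% c("local", "local_spliced") & aln$unique
  else !aln$kind %in% "unmapped"
  a <- aln[use, , drop = FALSE]
  seg1 <- GRanges(a$chrom1, IRanges(a$gstart1, a$gend1), strand = a$strand1)
  mcols(seg1)$read_id <- a$read_id
  two <- !is.na(a$chrom2)
  seg2 <- GRanges(a$chrom2[two], IRanges(a$gstart2[two], a$gend2[two]),
                  strand = a$strand2[two])
  mcols(seg2)$read_id <- a$read_id[two]
  .bind_granges(list(seg1, seg2))
}

#' Count aligned bases per gene feature
#'
#' The feature count is the number of aligned bases from uniquely mapped,
#' filter-passing reads falling inside the feature interval; non-unique reads
#' contribute nothing anywhere.
#'
#' @param aln alignment table from [mapReads()] (already filtered for quality
#'   and abundance)
#' @param features `GRanges` of exon/intron features (see [allFeatures()])
#' @return integer vector of base counts parallel to `features`
#' @export
countFeatures <- function(aln, features) {
  segs <- .segment_ranges(aln, uniqueOnly = TRUE)
  counts <- integer(length(features))
  if (length(segs) == 0) return(counts)
  ov <- findOverlaps(segs, features, ignore.strand = TRUE)
  if (length(ov) == 0) return(counts)
  w <- width(pintersect(segs[queryHits(ov)], features[subjectHits(ov)],
                        ignore.strand = TRUE))
  tab <- tapply(w, subjectHits(ov), sum)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Assemble the per-sample gene table
#'
#' The "gene table" is the base-count matrix over every exon and intron
#' feature of the annotated genes, one column per sample, stored as a
#' [SummarizedExperiment::SummarizedExperiment] whose rowRanges carry the
#' feature annotation (`gene`, `kind`, `ordinal`).
#'
#' @param alnList named list of alignment tables, one per sample
#' @param models a collapsed [GeneModelSet-class]
#' @return a `SummarizedExperiment` with assay `basecount`
#' @export
buildGeneTable <- function(alnList, models) {
  feats <- allFeatures(models)
  mat <- vapply(alnList, countFeatures, integer(length(feats)),
                features = feats)
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(alnList))
  colnames(mat) <- names(alnList)
  rownames(mat) <- paste0(mcols(feats)$gene, ".", mcols(feats)$kind,
                          mcols(feats)$ordinal)
  SummarizedExperiment(assays = list(basecount = mat), rowRanges = feats,
                       colData = DataFrame(
                         sample = names(alnList),
                         total_bases = colSums(mat),
                         row.names = names(alnList)))
}
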