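# Step 3: turn surviving distant-spliced reads into annotated candidate
# fusion junctions (mismatch/antisense read filter, exon-boundary snapping,
# grouping, gene annotation, candidacy criteria).

# exon boundary lookup tables (transcription-direction 3' ends and 5' starts)
.boundary_sets <- function(models) {
  tx <- models@transcripts
  don <- character(0); acc <- character(0)
  for (i in seq_len(nrow(tx))) {
    ex <- models@exons[[i]]
    if (tx$strand[i] == "+") {
      don <- c(don, paste(tx$chrom[i], "+", end(ex)))
      acc <- c(acc, paste(tx$chrom[i], "+", start(ex)))
    } else {
      don <- c(don, paste(tx$chrom[i], "-", start(ex)))
      acc <- c(acc, paste(tx$chrom[i], "-", end(ex)))
    }
  }
  list(donor3 = unique(don), acceptor5 = unique(acc))
}

# Snap slide-equivalent split placements to annotated exon boundaries.
# The mapper reports breakpoints at the maximal donor extension together with
# the slide range over which placements score identically; among those the
# shift whose donor/acceptor positions coincide with annotated exon 3'/5'
# boundaries is preferred (most boundaries won, ties to maximal donor).
.snap_junctions <- function(aln, models) {
  bs <- .boundary_sets(models)
  dist <- which(aln$kind == "distant")
  for (i in dist) {
    b <- aln$breakpoint[i]
    lo <- aln$slide_lo[i]
    if (is.na(b) || is.na(lo) || lo >= b) next
    shifts <- seq(lo - b, 0)  # non-positive: b was slid to the maximum
    d1 <- ifelse(aln$strand1[i] == "+", 1, -1)
    d2 <- ifelse(aln$strand2[i] == "+", 1, -1)
    dp <- aln$donor_pos[i] + shifts * d1
    ap <- aln$acceptor_pos[i] + shifts * d2
    sc <- (paste(aln$chrom1[i], aln$strand1[i], dp) %in% bs$donor3) +
      (paste(aln$chrom2[i], aln$strand2[i], ap) %in% bs$acceptor5)
    best <- which(sc == max(sc))
    pick <- best[length(best)]  # largest shift (i.e. maximal donor) on ties
    s <- shifts[pick]
    if (s == 0) next
    aln$donor_pos[i] <- dp[pick]
    aln$acceptor_pos[i] <- ap[pick]
    aln$breakpoint[i] <- b + s
    # segment bounds follow the breakpoint shift
    if (aln$strand1[i] == "+") aln$gend1[i] <- aln$gend1[i] + s
    else aln$gstart1[i] <- aln$gstart1[i] - s
    if (aln$strand2[i] == "+") aln$gstart2[i] <- aln$gstart2[i] + s
    else aln$gend2[i] <- aln$gend2[i] - s
    aln$qend1[i] <- aln$breakpoint[i]
    aln$qstart2[i] <- aln$breakpoint[i] + 1
  }
  aln
}

.parse_mis <- function(s) {
  if (is.na(s) || !nzchar(s)) integer(0)
  else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Junction-read filter (mismatch window and antisense test)
#'
#' A surviving distant-spliced read is dropped when it has any mismatch
#' within `junctionMismatchWindow` (default 5) terminal aligned bases of
#' either segment adjacent to the junction, or when either segment lies
#' antisense to its overlapping annotated gene (directional protocol). A
#' segment overlapping no gene is not antisense (the unannotated rejection
#' handles it later).
#'
#' @param aln alignment table rows of kind `distant` that passed the retest
#' @param models collapsed [GeneModelSet-class]
#' @param params [gfuseParams()]
#' @return logical vector, TRUE = keep
#' @export
junctionReadFilter <- function(aln, models, params = gfuseParams()) {
  w <- params$junctionMismatchWindow
  n <- nrow(aln)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    b <- aln$breakpoint[i]
    m1 <- .parse_mis(aln$mis1[i])
    m2 <- .parse_mis(aln$mis2[i])
    # distance 1 = the aligned base adjacent to the junction
    if (any(b - m1 + 1 <= w) || any(m2 - b <= w)) { keep[i] <- FALSE; next }
    g1 <- .genes_at(models, aln$chrom1[i], aln$donor_pos[i])
    g2 <- .genes_at(models, aln$chrom2[i], aln$acceptor_pos[i])
    tx <- models@transcripts
    s1 <- tx$strand[match(g1, tx$symbol)]
    s2 <- tx$strand[match(g2, tx$symbol)]
    if ((length(g1) && !any(s1 == aln$strand1[i])) ||
        (length(g2) && !any(s2 == aln$strand2[i])))
      keep[i] <- FALSE
  }
  keep
}

#' Group junction reads and annotate the junctions
#'
#' Reads are grouped by their exact (donor position, acceptor position) pair;
#' each junction end is annotated to the collapsed gene model overlapping it
#' on the read strand. A junction is tagged `pseudogene`, `unannotated` or
#' `ambiguous` when either side maps to a flagged pseudogene, to no gene, or
#' to more than one gene symbol.
#'
#' @param aln filtered distant alignment rows (after [junctionReadFilter()]);
#'   must carry a `sample` column
#' @param models collapsed [GeneModelSet-class]
#' @return `data.frame` with one row per distinct junction: coordinates,
#'   junction string, genes, supporting read ids/samples and
#'   `rejection_reason` (NA when annotatable)
#' @export
groupAndAnnotate <- function(aln, models) {
  if (nrow(aln) == 0)
    return(data.frame(junction = character(), donor_chrom = character(),
                      donor_pos = numeric(), donor_strand = character(),
                      acceptor_chrom = character(), acceptor_pos = numeric(),
                      acceptor_strand = character(), donor_gene = character(),
                      acceptor_gene = character(), n_reads = integer(),
                      read_ids = character(), samples = character(),
                      rejection_reason = character(), stringsAsFactors = FALSE))
  key <- .junction_string(aln$chrom1, aln$donor_pos, aln$strand1,
                          aln$chrom2, aln$acceptor_pos, aln$strand2)
  tx <- models@transcripts
  rows <- lapply(split(seq_len(nrow(aln)), key), function(ii) {
    a <- aln[ii[1], ]
    annotate_end <- function(chrom, pos, strand) {
      g <- .genes_at(models, chrom, pos, strand)
      if (length(g) == 0) return(list(gene = NA_character_, reason = "unannotated"))
      if (length(g) > 1) return(list(gene = NA_character_, reason = "ambiguous"))
      if (tx$isPseudogene[match(g, tx$symbol)])
        return(list(gene = g, reason = "pseudogene"))
      list(gene = g, reason = NA_character_)
    }
    d <- annotate_end(a$chrom1, a$donor_pos, a$strand1)
    ac <- annotate_end(a$chrom2, a$acceptor_pos, a$strand2)
    reason <- if (!is.na(d$reason)) d$reason else ac$reason
    data.frame(junction = key[ii[1]],
               donor_chrom = a$chrom1, donor_pos = a$donor_pos,
               donor_strand = a$strand1,
               acceptor_chrom = a$chrom2, acceptor_pos = a$acceptor_pos,
               acceptor_strand = a$strand2,
               donor_gene = d$gene, acceptor_gene = ac$gene,
               n_reads = length(ii),
               read_ids = paste(aln$read_id[ii], collapse = ","),
               samples = paste(unique(aln$sample[ii]), collapse = ","),
               rejection_reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fusion candidacy test
#'
#' An annotated junction is a candidate fusion when it is not within a single
#' gene, not a transcript read-through, and satisfies at least one of:
#' different chromosomes; different gene symbols; opposite strands on the
#' same chromosome; at least `minCandidateDistance` (1 Mb) apart on the same
#' chromosome. A read-through is an ordinary co-directional splice between
#' adjacent genes: same chromosome, same strand, different genes, acceptor
#' downstream of the donor in transcription direction, closer than 1 Mb.
#'
#' @param aj one row of the [groupAndAnnotate()] table (not
#'   annotation-rejected)
#' @param params [gfuseParams()]
#' @return list with `candidate` (logical) and `reason` (`"same_gene"`,
#'   `"read_through"`, a satisfied criterion tag, or `"no_criterion"`)
#' @export
isCandidateFusion <- function(aj, params = gfuseParams()) {
  if (!is.na(aj$donor_gene) && !is.na(aj$acceptor_gene) &&
      aj$donor_gene == aj$acceptor_gene)
    return(list(candidate = FALSE, reason = "same_gene"))
  sameChrom <- aj$donor_chrom == aj$acceptor_chrom
  sameStrand <- aj$donor_strand == aj$acceptor_strand
  dist <- abs(aj$donor_pos - aj$acceptor_pos)
  diffGene <- !is.na(aj$donor_gene) && !is.na(aj$acceptor_gene) &&
    aj$donor_gene != aj$acceptor_gene
  if (sameChrom && sameStrand && diffGene &&
      dist < params$minCandidateDistance) {
    downstream <- if (aj$donor_strand == "+")
      aj$acceptor_pos > aj$donor_pos else aj$acceptor_pos < aj$donor_pos
    if (downstream)
      return(list(candidate = FALSE, reason = "read_through"))
  }
  if (!sameChrom) return(list(candidate = TRUE, reason = "different_chromosomes"))
  if (diffGene && !sameStrand)
    return(list(candidate = TRUE, reason = "opposite_strands"))
  if (diffGene) return(list(candidate = TRUE, reason = "different_genes"))
  if (!sameStrand) return(list(candidate = TRUE, reason = "opposite_strands"))
  if (dist >= params$minCandidateDistance)
    return(list(candidate = TRUE, reason = "distance"))
  list(candidate = FALSE, reason = "no_criterion")
}

#' Extract candidate fusion junctions from mapped reads
#'
#' Applies the junction-read filter, exon-boundary snapping, grouping,
#' annotation and the candidacy criteria in one step.
#'
#' @param aln alignment table (all samples pooled; needs a `sample` column)
#'   containing the retest-surviving distant rows
#' @param models collapsed [GeneModelSet-class]
#' @param params [gfuseParams()]
#' @return the annotated junction table with columns `candidate` and
#'   `reason` added; rejected junctions are retained with their reason
#' @export
extractCandidateJunctions <- function(aln, models, params = gfuseParams()) {
  dist <- aln[aln$kind == "distant" & aln$unique, , drop = FALSE]
  dist <- .snap_junctions(dist, models)
  keep <- junctionReadFilter(dist, models, params)
  aj <- groupAndAnnotate(dist[keep, , drop = FALSE], models)
  if (nrow(aj) == 0) {
    aj$candidate <- logical(0); aj$reason <- character(0)
    return(aj)
  }
  verdicts <- lapply(seq_len(nrow(aj)), function(i) {
    if (!is.na(aj$rejection_reason[i]))
      return(list(candidate = FALSE, reason = aj$rejection_reason[i]))
    isCandidateFusion(aj[i, ], params)
  })
  aj$candidate <- vapply(verdicts, `[[`, NA, "candidate")
  aj$reason <- vapply(verdicts, `[[`, "", "reason")
  aj
}
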