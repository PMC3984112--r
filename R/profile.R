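# Step 6: library-size normalization, Interrupt Ratios and per-cohort
# expression-discontinuity nomination.

#' Median-of-ratios library size factors
#'
#' For each sample j the factor is the median over features f of
#' count(f, j) / geometric mean over samples of count(f, .); features whose
#' geometric mean is zero (any zero count) are excluded from the median.
#'
#' @param counts feature x sample count matrix (>= 2 samples)
#' @return named positive numeric vector of size factors
#' @export
computeSizeFactors <- function(counts) {
  stopifnot(ncol(counts) >= 2)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  sf <- apply(counts, 2, function(cnt) {
    r <- log(cnt[use]) - logGeo[use]
    r <- r[is.finite(r)]
    if (length(r) == 0) stop("degenerate library: no usable features")
    exp(median(r))
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate library size factor")
  sf
}

# transcription-ordered feature rows of one gene in the gene table
.gene_feature_rows <- function(geneTable, gene) {
  rd <- rowData(geneTable)
  ii <- which(rd$gene == gene)
  ii[order(rd$order[ii])]
}

# preserved / excluded / discarded partition of a gene's features around a
# junction base; `side` donor keeps the upstream (5') features, acceptor the
# downstream (3') features. The breakpoint-adjacent intron on the discarded
# side is excluded (DNA breakpoint position unknown within it).
.split_features <- function(geneTable, gene, chrom, pos, side) {
  rows <- .gene_feature_rows(geneTable, gene)
  gr <- rowRanges(geneTable)[rows]
  rd <- rowData(geneTable)[rows, ]
  hit <- which(as.character(seqnames(gr)) == chrom & start(gr) <= pos &
                 end(gr) >= pos)
  if (length(hit) == 0) return(NULL)
  f <- hit[1]
  n <- length(rows)
  isIntron <- rd$kind == "intron"
  if (side == "donor") {
    if (isIntron[f]) { pres <- seq_len(f - 1); excl <- f }
    else {
      pres <- seq_len(f)
      excl <- if (f < n && isIntron[f + 1]) f + 1 else integer(0)
    }
    disc <- setdiff(seq_len(n), c(pres, excl))
  } else {
    if (isIntron[f]) {
      pres <- if (f < n) seq(f + 1, n) else integer(0)
      excl <- f
    } else {
      pres <- seq(f, n)
      excl <- if (f > 1 && isIntron[f - 1]) f - 1 else integer(0)
    }
    disc <- setdiff(seq_len(n), c(pres, excl))
  }
  list(preserved = rows[pres], discarded = rows[disc], excluded = rows[excl])
}

#' Interrupt Ratio of a junction in one sample
#'
#' Feature counts are normalized by the sample's library size factor and
#' floored at `padFloorReads` reads' worth of bases, then divided by feature
#' length to give coverages. The IR of a fusion partner is the mean coverage
#' over the preserved-side features divided by the mean coverage over the
#' discarded-side features, excluding the intron immediately after the donor
#' splice site (donor gene) and the intron immediately before the acceptor
#' splice site (acceptor gene), whose interior harbors the unknown DNA
#' breakpoint.
#'
#' @param geneTable the gene-table [SummarizedExperiment::SummarizedExperiment]
#' @param aj one candidate junction row (coordinates + genes)
#' @param sample sample name (column of the gene table)
#' @param factors size factors from [computeSizeFactors()]
#' @param padFloorReads count floor in reads (default 5)
#' @param readLen read length used to convert the floor to base counts
#' @return named list `ir_donor`, `ir_acceptor` (NA when a side is empty)
#' @export
interruptRatio <- function(geneTable, aj, sample, factors,
                           padFloorReads = 5, readLen = 50) {
  cnt <- assay(geneTable, "basecount")[, sample]
  f <- factors[[sample]]
  floorBases <- padFloorReads * readLen
  lens <- width(rowRanges(geneTable))
  covOf <- function(rows) {
    if (length(rows) == 0) return(NA_real_)
    mean(pmax(cnt[rows] / f, floorBases) / lens[rows])
  }
  irFor <- function(gene, chrom, pos, side) {
    sp <- .split_features(geneTable, gene, chrom, pos, side)
    if (is.null(sp)) return(NA_real_)
    p <- covOf(sp$preserved); d <- covOf(sp$discarded)
    if (is.na(p) || is.na(d)) return(NA_real_)
    p / d
  }
  list(ir_donor = irFor(aj$donor_gene, aj$donor_chrom, aj$donor_pos, "donor"),
       ir_acceptor = irFor(aj$acceptor_gene, aj$acceptor_chrom,
                           aj$acceptor_pos, "acceptor"))
}

#' Interrupt Ratios of all candidate junctions across a cohort
#'
#' @param geneTable gene table restricted (by column selection) to one cohort
#' @param candidates candidate junction table
#' @param samples cohort sample names
#' @param factors size factors for those samples
#' @param padFloorReads,readLen see [interruptRatio()]
#' @return `data.frame` with one row per junction x sample: `ir_donor`,
#'   `ir_acceptor`
#' @export
profileCohort <- function(geneTable, candidates, samples, factors,
                          padFloorReads = 5, readLen = 50) {
  grid <- expand.grid(j = seq_len(nrow(candidates)), sample = samples,
                      stringsAsFactors = FALSE)
  irs <- lapply(seq_len(nrow(grid)), function(i) {
    interruptRatio(geneTable, candidates[grid$j[i], ], grid$sample[i],
                   factors, padFloorReads, readLen)
  })
  data.frame(junction = candidates$junction[grid$j], sample = grid$sample,
             ir_donor = vapply(irs, `[[`, 0, "ir_donor"),
             ir_acceptor = vapply(irs, `[[`, 0, "ir_acceptor"),
             stringsAsFactors = FALSE)
}

#' Flag interrupted expression and rank samples by IR within a cohort
#'
#' Samples are ranked per junction by max(ir_donor, ir_acceptor); a sample is
#' flagged interrupted when that statistic reaches at least `foldMedian`
#' times the cohort median and at least `floor`. A cohort of one sample has
#' no cohort statistics and is flagged by the absolute threshold alone.
#'
#' @param ir output of [profileCohort()] (one cohort)
#' @param foldMedian,floor thresholds (defaults 3 and 2)
#' @return `ir` with `ir_max`, `cohort_rank` (1 = highest IR) and
#'   `interrupted` columns added
#' @export
nominateInterrupted <- function(ir, foldMedian = 3, floor = 2) {
  ir$ir_max <- pmax(ir$ir_donor, ir$ir_acceptor, na.rm = TRUE)
  ir$ir_max[is.na(ir$ir_donor) & is.na(ir$ir_acceptor)] <- NA_real_
  ir$cohort_rank <- NA_integer_
  ir$interrupted <- FALSE
  for (j in unique(ir$junction)) {
    ii <- which(ir$junction == j)
    stat <- ir$ir_max[ii]
    ir$cohort_rank[ii] <- rank(-stat, ties.method = "first", na.last = "keep")
    thr <- if (length(ii) > 1)
      max(foldMedian * median(stat, na.rm = TRUE), floor) else floor
    ir$interrupted[ii] <- !is.na(stat) & stat >= thr
  }
  ir
}

#' Center-scaled expression matrix of one gene across a cohort
#'
#' Size-factor-normalized feature counts, centered per feature across the
#' cohort (rows sum to ~0), as used for expression heatmaps with samples
#' ordered by IR.
#'
#' @param geneTable gene table
#' @param gene gene symbol
#' @param factors size factors
#' @return matrix (features x samples), transcription order
#' @export
centerScaledMatrix <- function(geneTable, gene, factors) {
  rows <- .gene_feature_rows(geneTable, gene)
  m <- assay(geneTable, "basecount")[rows, , drop = FALSE]
  m <- sweep(m, 2, unlist(factors[colnames(m)]), "/")
  sweep(m, 1, rowMeans(m), "-")
}
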