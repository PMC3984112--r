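# Step 7: integrate read and expression evidence into Tier-1/2/3 calls,
# predict reading-frame status, and write the final reports.

#' Count non-redundant junction support reads
#'
#' Reads are redundant when they share both template offset and sequence
#' (exact duplicates of low-complexity libraries); each distinct
#' (offset, sequence) pair counts once.
#'
#' @param support supporting hits of one junction + sample
#'   (see [fusionSupportReads()])
#' @return integer count
#' @export
countNonredundant <- function(support) {
  if (nrow(support) == 0) return(0L)
  length(unique(paste(support$offset, support$seq)))
}

#' Classify fusion evidence into tiers
#'
#' Per (junction, sample): Tier-1 requires at least two non-redundant
#' junction-spanning reads, regardless of expression; Tier-2 exactly one
#' non-redundant read plus an interrupted expression pattern; Tier-3 no read
#' but an interrupted pattern shared with the same junction called Tier-1/2
#' in another sample (or confirmed externally). Everything else is rejected —
#' in particular, junctions shared by several samples none of which has read
#' or expression evidence.
#'
#' @param evidence `data.frame` with columns `junction`, `sample`,
#'   `n_nonredundant`, `interrupted`
#' @param confirmedJunctions optional junction strings with external (assay)
#'   confirmation, granting cross-sample support
#' @return `evidence` with `cross_sample_support` and `tier` (`"Tier-1"`,
#'   `"Tier-2"`, `"Tier-3"`, `"rejected"`) columns added
#' @export
classifyTiers <- function(evidence, confirmedJunctions = character()) {
  n <- evidence$n_nonredundant
  tier <- rep("rejected", nrow(evidence))
  tier[n >= 2] <- "Tier-1"
  tier[n == 1 & evidence$interrupted] <- "Tier-2"
  strongBy <- tapply(tier %in% c("Tier-1", "Tier-2"), evidence$junction, sum)
  nStrong <- as.vector(strongBy[evidence$junction])
  evidence$cross_sample_support <-
    (nStrong - (tier %in% c("Tier-1", "Tier-2"))) > 0 |
    evidence$junction %in% confirmedJunctions
  tier[n == 0 & evidence$interrupted & evidence$cross_sample_support] <- "Tier-3"
  evidence$tier <- tier
  evidence
}

#' Reading-frame prediction for a fusion junction
#'
#' Computes the donor CDS phase at the junction (coding bases from the CDS
#' start up to and including the junction base, mod 3) and the acceptor phase
#' (coding bases strictly 5' of the acceptor position within its CDS, mod 3)
#' on the per-transcript models. `"in"` when the phases agree and both
#' positions lie inside a CDS; `"noncoding"` when either side falls outside
#' any CDS (UTR or non-coding transcript); `"unknown"` when a junction
#' position is not exonic in any transcript of its gene. When the genome is
#' supplied, a phase-matched junction whose chimeric junction-spanning codon
#' is a stop codon is reported `"out"` (the fusion truncates at the
#' junction instead of producing a chimeric protein).
#'
#' @param aj one candidate junction row
#' @param models the per-transcript [GeneModelSet-class] (not collapsed)
#' @param genome optional named [Biostrings::DNAStringSet] for the
#'   junction-codon check
#' @return `"in"`, `"out"`, `"noncoding"` or `"unknown"`
#' @export
predictFrame <- function(aj, models, genome = NULL) {
  tx <- models@transcripts
  di <- .tx_containing(models, aj$donor_chrom, aj$donor_pos, aj$donor_strand)
  ai <- .tx_containing(models, aj$acceptor_chrom, aj$acceptor_pos,
                       aj$acceptor_strand)
  if (is.na(di) || is.na(ai)) return("unknown")
  phase_of <- function(i, pos, inclusive) {
    if (is.na(tx$cdsStart[i])) return(NULL)  # non-coding transcript
    cds5 <- if (tx$strand[i] == "+") tx$cdsStart[i] else tx$cdsEnd[i]
    cds3 <- if (tx$strand[i] == "+") tx$cdsEnd[i] else tx$cdsStart[i]
    sPos <- .spliced_offset(models, i, pos)
    s5 <- .spliced_offset(models, i, cds5)
    s3 <- .spliced_offset(models, i, cds3)
    if (is.na(sPos)) return(NA)
    if (sPos < s5 || sPos > s3) return(NULL)  # UTR
    nc <- if (inclusive) sPos - s5 + 1 else sPos - s5
    nc %% 3
  }
  pd <- phase_of(di, aj$donor_pos, inclusive = TRUE)
  pa <- phase_of(ai, aj$acceptor_pos, inclusive = FALSE)
  if (is.null(pd) || is.null(pa)) return("noncoding")
  if (is.na(pd) || is.na(pa)) return("unknown")
  if (pd != pa) return("out")
  if (!is.null(genome) && pd != 0) {
    # chimeric codon spanning the junction: last `pd` donor coding bases plus
    # the first 3 - `pd` acceptor bases; a stop here truncates the protein
    dSeq <- .spliced_sequence(models, di, genome)
    aSeq <- .spliced_sequence(models, ai, genome)
    dOff <- .spliced_offset(models, di, aj$donor_pos)
    aOff <- .spliced_offset(models, ai, aj$acceptor_pos)
    codon <- paste0(substr(dSeq, dOff - pd + 1, dOff),
                    substr(aSeq, aOff, aOff + (3 - pd) - 1))
    if (codon %in% c("TAA", "TAG", "TGA")) return("out")
  }
  "in"
}

#' Write the final fusion report
#'
#' Emits `fusions.tsv` (one row per called junction x sample: junction
#' string, partner genes, tier, non-redundant read count, donor/acceptor IR,
#' frame, dominant-junction flag), `assay_templates.fa` (the 300 bp template
#' sets of reported junctions, for qRT-PCR probe design) and `summary.tsv`
#' (per-step retention counts of the run).
#'
#' @param calls classified evidence table (rows with tier != "rejected" are
#'   reported)
#' @param outDir output directory (created if needed)
#' @param sets300 named list of width-300 [TemplateSet-class] by junction
#' @param retention named numeric vector of per-step retention counts
#' @return invisible list of written paths
#' @export
writeReport <- function(calls, outDir, sets300 = NULL, retention = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  called <- calls[calls$tier != "rejected", , drop = FALSE]
  cols <- intersect(c("junction", "sample", "donor_gene", "acceptor_gene",
                      "tier", "n_nonredundant", "ir_donor", "ir_acceptor",
                      "in_frame", "dominant"), names(called))
  fusionsPath <- file.path(outDir, "fusions.tsv")
  write.table(called[, cols, drop = FALSE], fusionsPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- list(fusions = fusionsPath)
  if (!is.null(sets300) && nrow(called)) {
    keep <- sets300[intersect(unique(called$junction), names(sets300))]
    if (length(keep)) {
      paths$templates <- writeTemplateFasta(keep,
                                            file.path(outDir, "assay_templates.fa"))
    }
  }
  if (!is.null(retention)) {
    sumPath <- file.path(outDir, "summary.tsv")
    write.table(data.frame(step = names(retention),
                           count = as.numeric(retention)),
                sumPath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$summary <- sumPath
  }
  invisible(paths)
}
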