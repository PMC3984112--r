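# End-to-end orchestration of the detection pipeline over one or more
# cohorts of single-end FFPE RNA-Seq libraries.

.load_sample <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    reads <- readDNAStringSet(x, format = "fastq", with.qualities = TRUE)
    quals <- mcols(reads)$qualities
    names(quals) <- names(reads)
    mcols(reads) <- NULL
    list(reads = reads, quals = BStringSet(quals))
  } else {
    list(reads = x$reads, quals = x$quals)
  }
}

#' Run the full fusion-detection pipeline
#'
#' Executes, in order: read quality and abundance filtering; genome mapping
#' with split-read discovery and gene-table counting; local-realignment
#' retest of distant reads; junction-read filtering, grouping, annotation
#' and candidacy screening (candidates pooled across cohorts); five-template
#' set construction with duplicate and homology filters; per-library read
#' retrieval and template remapping for junction support; per-cohort
#' library-size normalization and Interrupt Ratio profiling; and tier
#' classification with frame prediction.
#'
#' @param samples named list; each element is a FASTQ path or a list with
#'   `reads` ([Biostrings::DNAStringSet]) and `quals`
#'   ([Biostrings::BStringSet])
#' @param genome named [Biostrings::DNAStringSet] or FASTA path
#' @param models a [GeneModelSet-class] or refGene path
#' @param blacklist [Biostrings::DNAStringSet], FASTA path, or NULL
#' @param cohorts named list of sample-name vectors; expression profiling is
#'   carried out separately within each cohort while candidate templates are
#'   pooled across them (default: all samples form one cohort)
#' @param params [gfuseParams()]
#' @param confirmedJunctions junction strings with external confirmation
#'   (grants Tier-3 cross-sample support)
#' @param outDir optional report directory (see [writeReport()])
#' @return a list with the alignment tables, gene table, size factors,
#'   junction/candidate tables, template sets and index, remap hits, support
#'   reads, IR table, the classified `calls` table and per-step `retention`
#'   counts
#' @export
runGfuse <- function(samples, genome, models, blacklist = NULL,
                     cohorts = NULL, params = gfuseParams(),
                     confirmedJunctions = character(), outDir = NULL) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(models)) models <- readRefGene(models)
  if (is.character(blacklist)) blacklist <- readDNAStringSet(blacklist)
  if (is.null(cohorts)) cohorts <- list(cohort1 = names(samples))
  collapsed <- collapseBySymbol(models)
  idx <- genomeIndex(genome, params$k)

  loaded <- lapply(samples, .load_sample)
  retention <- c(reads_total = sum(vapply(loaded, function(s)
    length(s$reads), 0)))

  # Step 1: quality + abundance filters, mapping, gene tables
  alnList <- list()
  keptReads <- list(); keptQuals <- list()
  for (sn in names(loaded)) {
    rq <- loaded[[sn]]
    okQ <- passesQualityFilter(rq$quals, params$qualMinBases,
                               params$qualMinScore)
    okB <- passesAbundanceFilter(rq$reads, blacklist,
                                 params$blacklistMinMatches, params$blacklistK)
    keep <- okQ & okB
    keptReads[[sn]] <- rq$reads[keep]
    keptQuals[[sn]] <- rq$quals[keep]
    aln <- mapReads(idx, keptReads[[sn]], params)
    aln$sample <- sn
    alnList[[sn]] <- aln
  }
  retention["reads_after_filters"] <- sum(vapply(keptReads, length, 0))
  geneTable <- buildGeneTable(alnList, collapsed)

  # Step 2: retest distant-spliced reads with local-favoring realignment
  distAll <- do.call(rbind, lapply(alnList, function(a)
    a[a$kind == "distant" & a$unique, , drop = FALSE]))
  retention["distant_reads"] <- if (is.null(distAll)) 0 else nrow(distAll)
  if (!is.null(distAll) && nrow(distAll)) {
    seqsByRow <- setNames(
      unlist(lapply(names(alnList), function(sn) {
        ids <- distAll$read_id[distAll$sample == sn]
        as.character(keptReads[[sn]][ids])
      })),
      unlist(lapply(names(alnList), function(sn)
        distAll$read_id[distAll$sample == sn])))
    rt <- retestDistantReads(idx, DNAStringSet(seqsByRow), params)
    distAll <- distAll[rt$keep[match(distAll$read_id, rt$read_id)], ,
                       drop = FALSE]
  }
  retention["distant_after_retest"] <- if (is.null(distAll)) 0 else nrow(distAll)

  # Step 3: junction extraction over the pooled reads
  aj <- if (!is.null(distAll) && nrow(distAll))
    extractCandidateJunctions(distAll, collapsed, params)
  else extractCandidateJunctions(
    data.frame(read_id = character(), kind = character(), unique = logical())[0, ],
    collapsed, params)
  retention["junctions_grouped"] <- nrow(aj)
  candidates <- aj[aj$candidate %in% TRUE, , drop = FALSE]
  retention["candidate_junctions"] <- nrow(candidates)

  cohortOf <- setNames(rep(names(cohorts), lengths(cohorts)),
                       unlist(cohorts))
  emptyCalls <- data.frame(junction = character(), sample = character(),
                           n_nonredundant = integer(), interrupted = logical(),
                           cross_sample_support = logical(), tier = character(),
                           stringsAsFactors = FALSE)
  result <- list(alignments = alnList, geneTable = geneTable,
                 junctions = aj, candidates = candidates, params = params,
                 retention = retention, calls = emptyCalls)

  if (nrow(candidates) == 0) {
    retention["template_sets"] <- 0
    retention["called_junctions"] <- 0
    result$retention <- retention
    if (!is.null(outDir)) writeReport(emptyCalls, outDir, retention = retention)
    return(result)
  }

  # Step 4: five-template sets (pooled), duplicate + homology filters
  sets100 <- lapply(seq_len(nrow(candidates)), function(i)
    buildTemplateSet(candidates[i, ], genome, collapsed, 100))
  sets300 <- lapply(seq_len(nrow(candidates)), function(i)
    buildTemplateSet(candidates[i, ], genome, collapsed, 300))
  names(sets100) <- candidates$junction
  names(sets300) <- candidates$junction
  dd <- dedupeTemplateSets(sets100)
  surviving <- names(dd$kept)
  hf <- lapply(surviving, function(j)
    homologyFilter(sets300[[j]], sets100[[j]], params$homologyMinShared))
  surviving <- surviving[vapply(hf, `[[`, NA, "keep")]
  retention["template_sets"] <- length(surviving)
  result$templateSets100 <- sets100
  result$templateSets300 <- sets300
  if (length(surviving) == 0) {
    retention["called_junctions"] <- 0
    result$retention <- retention
    if (!is.null(outDir)) writeReport(emptyCalls, outDir, retention = retention)
    return(result)
  }
  tIndex <- buildTemplateIndex(sets100[surviving])
  result$templateIndex <- tIndex
  candidates <- candidates[candidates$junction %in% surviving, , drop = FALSE]

  # Step 5: retrieve + remap reads, collect junction support
  hitsAll <- list()
  for (sn in names(alnList)) {
    ids <- selectReadsForRemap(alnList[[sn]], tIndex, params$readLen)
    if (length(ids) == 0) next
    h <- remapToTemplates(keptReads[[sn]][ids], tIndex, params$k)
    if (nrow(h)) { h$sample <- sn; hitsAll[[sn]] <- h }
  }
  hits <- if (length(hitsAll)) do.call(rbind, hitsAll) else NULL
  support <- if (!is.null(hits))
    fusionSupportReads(hits, params$overhangMin) else NULL
  result$hits <- hits
  result$support <- support
  retention["support_reads"] <- if (is.null(support)) 0 else nrow(support)

  # Step 6: per-cohort normalization + Interrupt Ratio profiling
  sfs <- list(); irAll <- list()
  for (cn in names(cohorts)) {
    cs <- cohorts[[cn]]
    counts <- assay(geneTable, "basecount")[, cs, drop = FALSE]
    sf <- if (length(cs) >= 2) computeSizeFactors(counts)
          else setNames(1, cs)
    sfs[[cn]] <- sf
    ir <- profileCohort(geneTable, candidates, cs, as.list(sf),
                        params$padFloorReads, params$readLen)
    irAll[[cn]] <- nominateInterrupted(ir, params$irFoldMedian, params$irFloor)
  }
  ir <- do.call(rbind, irAll)
  rownames(ir) <- NULL
  result$sizeFactors <- sfs
  result$ir <- ir

  # Step 7: evidence integration, tiers, frame, report
  evidence <- ir[, c("junction", "sample", "ir_donor", "ir_acceptor",
                     "ir_max", "cohort_rank", "interrupted")]
  evidence$n_nonredundant <- vapply(seq_len(nrow(evidence)), function(i) {
    if (is.null(support)) return(0L)
    countNonredundant(support[support$junction == evidence$junction[i] &
                                support$sample == evidence$sample[i], ,
                              drop = FALSE])
  }, 0L)
  calls <- classifyTiers(evidence, confirmedJunctions)
  ci <- match(calls$junction, candidates$junction)
  calls$donor_gene <- candidates$donor_gene[ci]
  calls$acceptor_gene <- candidates$acceptor_gene[ci]
  frames <- vapply(seq_len(nrow(candidates)), function(i)
    predictFrame(candidates[i, ], models, genome), "")
  calls$in_frame <- frames[ci]
  # dominant junction per gene pair within a sample (most support reads)
  calls$dominant <- TRUE
  key <- paste(calls$sample, calls$donor_gene, calls$acceptor_gene)
  for (kk in unique(key[duplicated(key)])) {
    ii <- which(key == kk)
    calls$dominant[ii] <- seq_along(ii) ==
      which.max(calls$n_nonredundant[ii])
  }
  result$calls <- calls
  retention["called_junctions"] <- length(unique(
    calls$junction[calls$tier != "rejected"]))
  result$retention <- retention
  if (!is.null(outDir))
    writeReport(calls, outDir, sets300 = result$templateSets300,
                retention = retention)
  result
}
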