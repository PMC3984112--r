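# Step 4: five-template sets per candidate junction, duplicate and homology
# filters, and the pooled template index used for remapping.

#' Five-template set of one candidate fusion junction
#'
#' The set holds, at a given width `w` (100 bp for remapping, 300 bp for
#' assay design), five sequences each made of two w/2 flanks joined at a
#' junction: the fusion template (donor preserved exonic flank + acceptor
#' preserved exonic flank), donor and acceptor mRNA templates (preserved +
#' discarded exonic flanks of one gene, i.e. the wild-type spliced sequence
#' across the splice site) and donor/acceptor pre-mRNA templates (contiguous
#' genomic sequence around each splice site, strand-oriented). Because the
#' DNA breakpoint is unknown, no fusion pre-mRNA template exists; the set has
#' exactly five roles.
#'
#' @slot junction junction string
#' @slot width template width (bp)
#' @slot sequences named character of length 5 (`fusion`, `donor`,
#'   `acceptor`, `donor_pre`, `acceptor_pre`)
#' @slot flankOk FALSE when fewer than width/2 exonic bases exist on any
#'   required side
#' @slot loci [GenomicRanges::GRanges] of the genomic intervals contributing
#'   to the flanks (used to retrieve reads near the junction)
#' @name TemplateSet-class
#' @aliases TemplateSet
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(junction = "character", width = "integer",
                 sequences = "character", flankOk = "logical",
                 loci = "GRanges"))

setValidity("TemplateSet", function(object) {
  roles <- c("fusion", "donor", "acceptor", "donor_pre", "acceptor_pre")
  if (!identical(names(object@sequences), roles))
    return("sequences must be named fusion, donor, acceptor, donor_pre, acceptor_pre")
  TRUE
})

#' @export
setMethod("templateSequences", "TemplateSet", function(x, ...) x@sequences)

setMethod("show", "TemplateSet", function(object) {
  cat("TemplateSet (", object@width, " bp) for ", object@junction,
      if (!object@flankOk) "  [insufficient exonic flank]", "\n", sep = "")
})

# spliced exonic sequence and per-base genomic positions of one collapsed
# gene, in transcription order
.gene_spliced <- function(models, i, genome) {
  tx <- models@transcripts
  ex <- models@exons[[i]]
  if (tx$strand[i] == "+") {
    pos <- unlist(lapply(seq_along(ex), function(j) start(ex)[j]:end(ex)[j]))
  } else {
    pos <- unlist(lapply(rev(seq_along(ex)), function(j) end(ex)[j]:start(ex)[j]))
  }
  list(seq = .spliced_sequence(models, i, genome), pos = pos,
       chrom = tx$chrom[i], strand = tx$strand[i])
}

# exonic flank around a junction base: `side` upstream keeps bases up to and
# including the junction base (donor-preserved style); downstream starts at /
# after it depending on `includePos`
.exonic_flank <- function(sp, pos, len, side = c("upstream", "downstream"),
                          includePos = TRUE) {
  side <- match.arg(side)
  sOff <- match(pos, sp$pos)
  if (is.na(sOff)) return(list(seq = "", ranges = IRanges(), ok = FALSE))
  idx <- if (side == "upstream") {
    hi <- if (includePos) sOff else sOff - 1L
    seq(hi - len + 1L, hi)
  } else {
    lo <- if (includePos) sOff else sOff + 1L
    seq(lo, lo + len - 1L)
  }
  ok <- all(idx >= 1L & idx <= length(sp$pos))
  idx <- idx[idx >= 1L & idx <= length(sp$pos)]
  if (length(idx) == 0L) return(list(seq = "", ranges = IRanges(), ok = FALSE))
  list(seq = substr(sp$seq, min(idx), max(idx)),
       ranges = IRanges::reduce(IRanges(sort(sp$pos[idx]), sort(sp$pos[idx]))),
       ok = ok)
}

# contiguous genomic (pre-mRNA) flanks around a splice site, strand oriented
.pre_template <- function(genome, chrom, pos, strand, half) {
  n <- length(genome[[chrom]])
  if (strand == "+") {
    up <- fetchSequence(genome, chrom, max(1, pos - half + 1), pos, "+")
    dn <- fetchSequence(genome, chrom, pos + 1, min(n, pos + half), "+")
    rng <- IRanges(max(1, pos - half + 1), min(n, pos + half))
  } else {
    up <- fetchSequence(genome, chrom, pos, min(n, pos + half - 1), "-")
    dn <- fetchSequence(genome, chrom, max(1, pos - half), pos - 1, "-")
    rng <- IRanges(max(1, pos - half), min(n, pos + half - 1))
  }
  list(seq = paste0(up, dn), ranges = rng)
}

#' Build the five-template set of a candidate junction
#'
#' Exonic flanks are spliced transcript sequence (introns skipped) written
#' 5'->3' in the transcription direction of the source gene; pre-mRNA flanks
#' are raw genomic sequence around each splice site. `flankOk` is FALSE when
#' fewer than `width/2` exonic bases exist on any required side (including a
#' junction falling outside the annotated exons of its gene).
#'
#' @param aj one row of the candidate junction table (needs coordinates and
#'   `donor_gene`/`acceptor_gene`)
#' @param genome named [Biostrings::DNAStringSet]
#' @param models collapsed [GeneModelSet-class]
#' @param width 100 or 300
#' @return a [TemplateSet-class]
#' @export
buildTemplateSet <- function(aj, genome, models, width = 100) {
  stopifnot(width %% 2 == 0)
  half <- as.integer(width / 2)
  tx <- models@transcripts
  di <- match(aj$donor_gene, tx$symbol)
  ai <- match(aj$acceptor_gene, tx$symbol)
  if (is.na(di) || is.na(ai)) stop("junction genes not found in models")
  spd <- .gene_spliced(models, di, genome)
  spa <- .gene_spliced(models, ai, genome)

  dPres <- .exonic_flank(spd, aj$donor_pos, half, "upstream", includePos = TRUE)
  dDisc <- .exonic_flank(spd, aj$donor_pos, half, "downstream", includePos = FALSE)
  aPres <- .exonic_flank(spa, aj$acceptor_pos, half, "downstream", includePos = TRUE)
  aDisc <- .exonic_flank(spa, aj$acceptor_pos, half, "upstream", includePos = FALSE)
  dPre <- .pre_template(genome, aj$donor_chrom, aj$donor_pos,
                        aj$donor_strand, half)
  aPre <- .pre_template(genome, aj$acceptor_chrom, aj$acceptor_pos,
                        aj$acceptor_strand, half)

  seqs <- c(fusion = paste0(dPres$seq, aPres$seq),
            donor = paste0(dPres$seq, dDisc$seq),
            acceptor = paste0(aDisc$seq, aPres$seq),
            donor_pre = dPre$seq, acceptor_pre = aPre$seq)
  loci <- .bind_granges(list(
    GRanges(spd$chrom, c(dPres$ranges, dDisc$ranges, dPre$ranges)),
    GRanges(spa$chrom, c(aPres$ranges, aDisc$ranges, aPre$ranges))))
  loci <- GenomicRanges::reduce(loci)
  new("TemplateSet", junction = aj$junction, width = as.integer(width),
      sequences = seqs,
      flankOk = dPres$ok && dDisc$ok && aPres$ok && aDisc$ok,
      loci = loci)
}

#' Remove template sets sharing an identical template
#'
#' A candidate is removed when any of its five width-100 templates is
#' byte-identical to any template of a different set (both sets go);
#' identical templates within one set (e.g. donor mRNA = donor pre-mRNA for a
#' single-exon gene) are not grounds for removal.
#'
#' @param sets list of width-100 [TemplateSet-class] objects (cohort-pooled)
#' @return list with `kept` (surviving sets) and `removed` (data.frame of
#'   junction + reason)
#' @export
dedupeTemplateSets <- function(sets) {
  if (length(sets) <= 1)
    return(list(kept = sets,
                removed = data.frame(junction = character(),
                                     reason = character())))
  seqTab <- data.frame(
    set = rep(seq_along(sets), each = 5L),
    seq = unlist(lapply(sets, function(s) unname(s@sequences))),
    stringsAsFactors = FALSE)
  bad <- logical(length(sets))
  for (sq in unique(seqTab$seq[duplicated(seqTab$seq)])) {
    owners <- unique(seqTab$set[seqTab$seq == sq])
    if (length(owners) > 1) bad[owners] <- TRUE
  }
  list(kept = sets[!bad],
       removed = data.frame(
         junction = vapply(sets[bad], function(s) s@junction, ""),
         reason = rep("duplicate_template", sum(bad)),
         stringsAsFactors = FALSE))
}

#' Homology filter on the 300 bp template set
#'
#' A candidate is removed when (1) its donor and acceptor mRNA templates
#' share an exact common substring of at least `minShared` bases (default 15,
#' i.e. identity of more than 14 bp), (2) its donor and acceptor pre-mRNA
#' templates do, or (3) the width-100 set lacks a full exonic flank on any
#' required side. The longest-common-substring test is symmetric in donor and
#' acceptor.
#'
#' @param set300 the width-300 [TemplateSet-class]
#' @param set100 the width-100 [TemplateSet-class] of the same junction
#' @param minShared removal threshold on the shared substring length
#' @return list with `keep` (logical) and `reason`
#' @export
homologyFilter <- function(set300, set100, minShared = 15) {
  s <- set300@sequences
  if (!set100@flankOk)
    return(list(keep = FALSE, reason = "insufficient_exonic_flank"))
  if (.cppLcsLength(s[["donor"]], s[["acceptor"]]) >= minShared)
    return(list(keep = FALSE, reason = "mrna_homology"))
  if (.cppLcsLength(s[["donor_pre"]], s[["acceptor_pre"]]) >= minShared)
    return(list(keep = FALSE, reason = "premrna_homology"))
  list(keep = TRUE, reason = NA_character_)
}

#' Pooled template index
#'
#' All five templates of every surviving candidate set, searchable for
#' best-placement remapping of 50 bp reads; each template is tagged with its
#' junction and role.
#'
#' @slot sequences template sequences
#' @slot junction,role parallel tags
#' @slot width template width
#' @slot loci `GRanges` of flank loci with a `junction` metadata column
#' @name TemplateIndex-class
#' @aliases TemplateIndex
#' @exportClass TemplateIndex
setClass("TemplateIndex",
  representation(sequences = "character", junction = "character",
                 role = "character", width = "integer", loci = "GRanges"))

setMethod("show", "TemplateIndex", function(object) {
  cat("TemplateIndex:", length(object@sequences), "templates (",
      length(unique(object@junction)), "junction sets ), width",
      object@width, "bp\n")
})

#' Build the pooled template index from surviving sets
#' @param sets list of width-100 [TemplateSet-class] objects after the
#'   duplicate and homology filters
#' @return a [TemplateIndex-class]
#' @export
buildTemplateIndex <- function(sets) {
  stopifnot(length(sets) >= 1)
  roles <- c("fusion", "donor", "acceptor", "donor_pre", "acceptor_pre")
  loci <- .bind_granges(lapply(sets, function(s) {
    g <- s@loci
    mcols(g)$junction <- s@junction
    g
  }))
  new("TemplateIndex",
      sequences = unlist(lapply(sets, function(s) unname(s@sequences))),
      junction = rep(vapply(sets, function(s) s@junction, ""), each = 5L),
      role = rep(roles, length(sets)),
      width = sets[[1]]@width,
      loci = loci)
}

#' Export templates as FASTA
#' @param sets list of [TemplateSet-class] (any width)
#' @param path output FASTA path
#' @return the path, invisibly
#' @export
writeTemplateFasta <- function(sets, path) {
  seqs <- unlist(lapply(sets, function(s)
    setNames(s@sequences, paste0(s@junction, "|", names(s@sequences)))))
  writeXStringSet(DNAStringSet(seqs), path)
  invisible(path)
}
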