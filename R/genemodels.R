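#' Gene models parsed from UCSC refGene annotation
#'
#' Holds a set of stranded transcript models (ordered exons plus CDS bounds).
#' File coordinates in the refGene dialect are 0-based half-open; they are
#' converted to 1-based inclusive at parse time and kept that way everywhere
#' in the package, matching the single-base UCSC-style positions used in
#' junction strings.
#'
#' @slot transcripts a `data.frame` with columns `name`, `symbol`, `chrom`,
#'   `strand`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd` (NA for non-coding)
#'   and `isPseudogene`
#' @slot exons a [IRanges::IRangesList] of 1-based inclusive exon intervals,
#'   parallel to `transcripts`, sorted by genomic coordinate
#' @name GeneModelSet-class
#' @aliases GeneModelSet
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(transcripts = "data.frame", exons = "list"))

setValidity("GeneModelSet", function(object) {
  tx <- object@transcripts
  need <- c("name", "symbol", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "isPseudogene")
  if (!all(need %in% names(tx)))
    return(paste("transcripts must have columns:", paste(need, collapse = ", ")))
  if (length(object@exons) != nrow(tx))
    return("exons list must be parallel to transcripts")
  for (i in seq_along(object@exons)) {
    ex <- object@exons[[i]]
    if (!is(ex, "IRanges")) return("each exons element must be an IRanges")
    if (length(ex) == 0L) return("each transcript needs at least one exon")
    st <- start(ex); en <- end(ex)
    if (is.unsorted(st, strictly = TRUE) && length(ex) > 1L)
      return("exons must be sorted by genomic coordinate")
    if (length(ex) > 1L && any(st[-1] <= en[-length(ex)]))
      return("exons must be non-overlapping")
    if (st[1] < tx$txStart[i] || en[length(ex)] > tx$txEnd[i])
      return("tx span must cover all exons")
  }
  TRUE
})

#' @export
GeneModelSet <- function(transcripts, exons) {
  names(exons) <- transcripts$name
  new("GeneModelSet", transcripts = transcripts, exons = exons)
}

setMethod("show", "GeneModelSet", function(object) {
  tx <- object@transcripts
  cat("GeneModelSet with", nrow(tx), "transcript(s),",
      length(unique(tx$symbol)), "gene symbol(s)\n")
  if (nrow(tx)) {
    cat("  chromosomes:", paste(unique(tx$chrom), collapse = ", "), "\n")
    cat("  pseudogenes flagged:", sum(tx$isPseudogene), "\n")
  }
})

#' @export
setMethod("length", "GeneModelSet", function(x) nrow(x@transcripts))

#' Accessors for GeneModelSet
#' @param x a [GeneModelSet-class]
#' @return `transcripts()` the transcript table; `exonRanges()` the exon
#'   interval list
#' @export
transcripts <- function(x) x@transcripts

#' @rdname transcripts
#' @export
exonRanges <- function(x) x@exons

#' Read UCSC refGene annotation
#'
#' Parses the tab-separated refGene dialect (`bin, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, score,
#' name2, ...`). File coordinates are 0-based half-open and are converted to
#' 1-based inclusive. Transcripts whose `name` or `name2` appears in
#' `pseudogeneIds` are flagged (refGene itself carries no pseudogene column;
#' the id list is the configurable stand-in for that annotation source).
#'
#' @param path path to a refGene-format file
#' @param pseudogeneIds character vector of gene/transcript ids to flag
#' @return a [GeneModelSet-class]
#' @export
readRefGene <- function(path, pseudogeneIds = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  if (n == 0L) stop("empty refGene file: ", path)
  nf <- lengths(fields)
  if (any(nf < 13L)) {
    bad <- which(nf < 13L)[1]
    stop("refGene format error at line ", bad, ": expected >= 13 columns, got ",
         nf[bad])
  }
  tx <- data.frame(
    name = vapply(fields, `[`, "", 2L),
    symbol = vapply(fields, `[`, "", 13L),
    chrom = vapply(fields, `[`, "", 3L),
    strand = vapply(fields, `[`, "", 4L),
    txStart = as.numeric(vapply(fields, `[`, "", 5L)) + 1,
    txEnd = as.numeric(vapply(fields, `[`, "", 6L)),
    cdsStart = as.numeric(vapply(fields, `[`, "", 7L)) + 1,
    cdsEnd = as.numeric(vapply(fields, `[`, "", 8L)),
    stringsAsFactors = FALSE
  )
  noCds <- tx$cdsStart > tx$cdsEnd  # file cdsStart == cdsEnd marks non-coding
  tx$cdsStart[noCds] <- NA_real_
  tx$cdsEnd[noCds] <- NA_real_
  tx$isPseudogene <- tx$name %in% pseudogeneIds | tx$symbol %in% pseudogeneIds
  exCount <- as.integer(vapply(fields, `[`, "", 9L))
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    st <- as.numeric(strsplit(fields[[i]][10L], ",", fixed = TRUE)[[1]])
    en <- as.numeric(strsplit(fields[[i]][11L], ",", fixed = TRUE)[[1]])
    if (length(st) != exCount[i] || length(en) != exCount[i])
      stop("refGene format error at line ", i, ": exonCount=", exCount[i],
           " but ", length(st), "/", length(en), " exon bounds listed")
    exons[[i]] <- IRanges(start = st + 1, end = en)
  }
  GeneModelSet(tx, exons)
}

#' @describeIn readRefGene write a GeneModelSet back to refGene format
#'   (inverse of the reader; used by the simulator)
#' @param x a [GeneModelSet-class]
#' @export
setMethod("writeRefGene", "GeneModelSet", function(x, path, ...) {
  tx <- x@transcripts
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    ex <- x@exons[[i]]
    cdsS <- if (is.na(tx$cdsStart[i])) tx$txEnd[i] else tx$cdsStart[i] - 1
    cdsE <- if (is.na(tx$cdsEnd[i])) tx$txEnd[i] else tx$cdsEnd[i]
    paste(
      0L, tx$name[i], tx$chrom[i], tx$strand[i],
      format(tx$txStart[i] - 1, scientific = FALSE),
      format(tx$txEnd[i], scientific = FALSE),
      format(cdsS, scientific = FALSE), format(cdsE, scientific = FALSE),
      length(ex),
      paste0(paste(format(start(ex) - 1, scientific = FALSE, trim = TRUE),
                   collapse = ","), ","),
      paste0(paste(format(end(ex), scientific = FALSE, trim = TRUE),
                   collapse = ","), ","),
      0L, tx$symbol[i], "unk", "unk",
      paste0(paste(rep("-1", length(ex)), collapse = ","), ","),
      sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
})

#' Collapse transcripts to one union-of-exons model per gene symbol
#'
#' Overlapping transcripts of a gene symbol are merged into a single model
#' with the union of their exons; CDS bounds are dropped (annotation and
#' counting work per symbol, while frame prediction keeps the per-transcript
#' models).
#'
#' @param x a [GeneModelSet-class]
#' @return a [GeneModelSet-class] with one entry per symbol
#' @export
setMethod("collapseBySymbol", "GeneModelSet", function(x, ...) {
  tx <- x@transcripts
  keys <- split(seq_len(nrow(tx)), tx$symbol)
  rows <- list(); exs <- list()
  for (sym in names(keys)) {
    ii <- keys[[sym]]
    if (length(unique(tx$chrom[ii])) > 1L || length(unique(tx$strand[ii])) > 1L)
      stop("cannot collapse symbol ", sym, ": transcripts on multiple loci")
    un <- IRanges::reduce(do.call(c, unname(x@exons[ii])))
    rows[[sym]] <- data.frame(
      name = sym, symbol = sym, chrom = tx$chrom[ii][1], strand = tx$strand[ii][1],
      txStart = min(start(un)), txEnd = max(end(un)),
      cdsStart = NA_real_, cdsEnd = NA_real_,
      isPseudogene = any(tx$isPseudogene[ii]), stringsAsFactors = FALSE)
    exs[[sym]] <- un
  }
  GeneModelSet(do.call(rbind, unname(rows)), unname(exs))
})

#' Exon/intron features of one gene in transcription order
#'
#' Ordinals follow the transcription direction: ordinal 1 is the 5'-most
#' feature, so for a minus-strand gene exon 1 is the genomically rightmost
#' exon. Introns are the gaps between consecutive exons (exon count = intron
#' count + 1).
#'
#' @param x a [GeneModelSet-class]
#' @param gene transcript name or symbol present in `x`
#' @return a [GenomicRanges::GRanges] with metadata columns `gene`, `kind`
#'   (`"exon"`/`"intron"`), `ordinal` and `order` (1-based transcription-order
#'   rank across both kinds)
#' @export
setMethod("featuresOf", "GeneModelSet", function(x, gene, ...) {
  i <- match(gene, x@transcripts$name)
  if (is.na(i)) i <- match(gene, x@transcripts$symbol)
  if (is.na(i)) stop("unknown gene: ", gene)
  ex <- x@exons[[i]]
  chrom <- x@transcripts$chrom[i]
  strand <- x@transcripts$strand[i]
  ne <- length(ex)
  if (ne > 1L) {
    ints <- IRanges(start = end(ex)[-ne] + 1, end = start(ex)[-1] - 1)
  } else {
    ints <- IRanges()
  }
  # genomic order: e1 i1 e2 i2 ... ; ordinals assigned in transcription order
  starts <- c(start(ex), start(ints))
  ends <- c(end(ex), end(ints))
  kind <- c(rep("exon", ne), rep("intron", length(ints)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; kind <- kind[o]
  nfeat <- length(starts)
  txorder <- if (strand == "+") seq_len(nfeat) else rev(seq_len(nfeat))
  ordinal <- integer(nfeat)
  ordinal[kind == "exon"] <- rank(txorder[kind == "exon"])
  ordinal[kind == "intron"] <- rank(txorder[kind == "intron"])
  gr <- GRanges(chrom, IRanges(starts, ends), strand = strand)
  mcols(gr) <- DataFrame(gene = x@transcripts$symbol[i], kind = kind,
                         ordinal = as.integer(ordinal),
                         order = as.integer(txorder))
  gr[order(mcols(gr)$order)]
})

# concatenate GRanges after harmonizing their seqlevels
.bind_granges <- function(grs) {
  grs <- grs[vapply(grs, length, 0L) > 0 | seq_along(grs) == 1]
  lv <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  grs <- lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  do.call(c, unname(grs))
}

#' All exon/intron features of every gene in a model set
#' @param x a [GeneModelSet-class] (typically collapsed per symbol)
#' @return a `GRanges` concatenating [featuresOf()] over all genes
#' @export
allFeatures <- function(x) {
  grs <- lapply(x@transcripts$name, function(g) featuresOf(x, g))
  .bind_granges(grs)
}

#' Fetch genomic sequence
#'
#' @param genome a named [Biostrings::DNAStringSet] (one entry per chromosome)
#' @param chrom chromosome name
#' @param start,end 1-based inclusive interval
#' @param strand `"+"` returns the top strand, `"-"` the reverse complement
#' @return an uppercase character scalar
#' @export
fetchSequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- length(genome[[chrom]])
  if (start < 1 || end > n || start > end)
    stop("coordinates out of range for ", chrom, ": ", start, "-", end)
  s <- subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- reverseComplement(s)
  toupper(as.character(s))
}

# --- spliced-transcript helpers -------------------------------------------

# exons of transcript i in transcription order (list of c(start, end))
.tx_exons_txorder <- function(x, i) {
  ex <- x@exons[[i]]
  if (x@transcripts$strand[i] == "-") ex <- rev(ex)
  ex
}

# spliced (mRNA) sequence of transcript i, 5'->3'
.spliced_sequence <- function(x, i, genome) {
  tx <- x@transcripts
  ex <- .tx_exons_txorder(x, i)
  paste(vapply(seq_along(ex), function(j)
    fetchSequence(genome, tx$chrom[i], start(ex)[j], end(ex)[j], tx$strand[i]),
    ""), collapse = "")
}

# 1-based spliced offset of a genomic position within transcript i
# (number of exonic bases from the transcript 5' end up to pos, inclusive);
# NA if pos is not exonic
.spliced_offset <- function(x, i, pos) {
  tx <- x@transcripts
  ex <- .tx_exons_txorder(x, i)
  cum <- 0L
  for (j in seq_along(ex)) {
    s <- start(ex)[j]; e <- end(ex)[j]
    if (pos >= s && pos <= e) {
      within <- if (tx$strand[i] == "+") pos - s + 1 else e - pos + 1
      return(cum + within)
    }
    cum <- cum + (e - s + 1)
  }
  NA_integer_
}

# index of the transcript (rows of x@transcripts) whose exons contain pos on
# the given chrom/strand; first match wins
.tx_containing <- function(x, chrom, pos, strand = NULL) {
  tx <- x@transcripts
  hit <- which(tx$chrom == chrom & tx$txStart <= pos & tx$txEnd >= pos &
                 (if (is.null(strand)) TRUE else tx$strand == strand))
  for (i in hit) {
    ex <- x@exons[[i]]
    if (any(pos >= start(ex) & pos <= end(ex))) return(i)
  }
  NA_integer_
}

# symbols of collapsed genes overlapping a position (any part, exon or intron)
.genes_at <- function(x, chrom, pos, strand = NULL) {
  tx <- x@transcripts
  hit <- tx$chrom == chrom & tx$txStart <= pos & tx$txEnd >= pos
  if (!is.null(strand)) hit <- hit & tx$strand == strand
  unique(tx$symbol[hit])
}
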