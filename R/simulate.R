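#' Configuration for the synthetic FFPE cohort simulator
#'
#' The simulator emulates the salient properties of directional single-end
#' RNA-Seq libraries from archival FFPE tissue: ~100 bp median RNA fragments
#' (log-normal lengths with a hard 20 bp floor), 50 bp reads taken from the 5'
#' end of each fragment, a large unspliced (pre-mRNA) component that makes the
#' intronic base fraction of emitted reads land around 60%, strand-specific
#' reads, abundant contaminant sequences (rRNA-like/PhiX-like), and implanted
#' fusion transcripts with a machine-readable truth set.
#'
#' @slot seed RNG seed; identical config + seed gives byte-identical output
#' @slot nSamples number of libraries in the cohort
#' @slot nGenes,nChroms,chromLen toy genome layout
#' @slot fusions list of [fusionSpec()] entries
#' @slot fragmentMedianBp,fragmentSdlog fragment length model (log-normal)
#' @slot readLen read length in bases
#' @slot premrnaFraction proportion of reads drawn from unspliced pre-mRNA
#' @slot contaminantFraction proportion of reads from blacklist sequences
#' @slot depth reads per sample
#' @slot directional if TRUE all reads are sense-strand
#' @name SimConfig-class
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
  representation(seed = "numeric", nSamples = "integer", nGenes = "integer",
                 nChroms = "integer", chromLen = "numeric", fusions = "list",
                 fragmentMedianBp = "numeric", fragmentSdlog = "numeric",
                 readLen = "integer", premrnaFraction = "numeric",
                 contaminantFraction = "numeric", depth = "integer",
                 directional = "logical", qualityChar = "character"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  fr <- c(object@premrnaFraction, object@contaminantFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@readLen < 20L) msg <- c(msg, "readLen must be >= 20")
  if (object@nGenes < 1L || object@nSamples < 1L)
    msg <- c(msg, "need at least one gene and one sample")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimConfig-class
#' @param seed,nSamples,nGenes,nChroms,chromLen,fusions,fragmentMedianBp,fragmentSdlog,readLen,premrnaFraction,contaminantFraction,depth,directional,qualityChar
#'   see slot documentation
#' @export
simConfig <- function(seed = 1, nSamples = 12, nGenes = 20, nChroms = 2,
                      chromLen = 2.4e6, fusions = list(),
                      fragmentMedianBp = 100, fragmentSdlog = 0.45,
                      readLen = 50, premrnaFraction = 0.72,
                      contaminantFraction = 0.05, depth = 5000,
                      directional = TRUE, qualityChar = "D") {
  new("SimConfig", seed = seed, nSamples = as.integer(nSamples),
      nGenes = as.integer(nGenes), nChroms = as.integer(nChroms),
      chromLen = chromLen, fusions = fusions,
      fragmentMedianBp = fragmentMedianBp, fragmentSdlog = fragmentSdlog,
      readLen = as.integer(readLen), premrnaFraction = premrnaFraction,
      contaminantFraction = contaminantFraction, depth = as.integer(depth),
      directional = directional, qualityChar = qualityChar)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSamples, "samples,", object@nGenes, "genes on",
      object@nChroms, "chromosome(s) of", format(object@chromLen, big.mark = ","),
      "bp\n  depth", object@depth, "reads/sample, fragment median",
      object@fragmentMedianBp, "bp, pre-mRNA fraction", object@premrnaFraction,
      "\n ", length(object@fusions), "fusion spec(s)\n")
})

#' Specify one implanted fusion
#'
#' Junctions are planted at exon boundaries: the donor side keeps exons
#' 1..`donorExon` (transcription order) and the acceptor side keeps exons
#' `acceptorExon`..end. Exactly `junctionReads` junction-spanning reads are
#' planted per carrier sample (distinct offsets, >= 20 bp on each side of the
#' junction); background reads from the fusion transcript avoid the junction
#' so the split-read count is controlled precisely, which is what the
#' Tier-1/2/3 scenarios need.
#'
#' @param donorGene,acceptorGene gene symbols (must be distinct unless the
#'   same-gene rejection path is being exercised)
#' @param donorExon,acceptorExon 1-based exon ordinals in transcription order
#' @param samples character vector of carrier sample names
#' @param expressionFold fusion transcript abundance relative to the acceptor
#'   gene's baseline expression
#' @param junctionReads number of junction-spanning reads planted per carrier
#' @return a list usable in the `fusions` slot of [simConfig()]
#' @export
fusionSpec <- function(donorGene, donorExon, acceptorGene, acceptorExon,
                       samples, expressionFold = 10, junctionReads = 5) {
  list(donorGene = donorGene, donorExon = as.integer(donorExon),
       acceptorGene = acceptorGene, acceptorExon = as.integer(acceptorExon),
       samples = as.character(samples), expressionFold = expressionFold,
       junctionReads = as.integer(junctionReads))
}

#' Log-normal RNA fragment lengths
#'
#' Draws are parameterized so the distribution median equals `median`
#' (log-normal median = exp(meanlog)); a hard floor of `floor` bases reflects
#' that very short fragments are not recoverable from the library.
#'
#' @param n number of fragments
#' @param median target median length in bp
#' @param sdlog log-scale standard deviation (0 gives all-equal lengths)
#' @param floor minimum length
#' @return integer vector of lengths
#' @export
fragmentLengths <- function(n, median = 100, sdlog = 0.45, floor = 20) {
  stopifnot(n >= 1)
  pmax(as.integer(round(rlnorm(n, meanlog = log(median), sdlog = sdlog))),
       as.integer(floor))
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.revcomp <- function(s) as.character(reverseComplement(DNAString(s)))

# random codons excluding stop codons
.rand_codons <- function(ncodon) {
  all3 <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  ok <- setdiff(all3, .STOPS)
  paste(sample(ok, ncodon, replace = TRUE), collapse = "")
}

# Lay out gene structures on the toy genome. Genes are spaced evenly along
# each chromosome (with jitter) so that intra-chromosomal pairs both under
# and over 1 Mb apart exist for candidacy-rule scenarios.
.make_gene_defs <- function(config) {
  nG <- config@nGenes; nC <- config@nChroms
  perChrom <- ceiling(nG / nC)
  defs <- list()
  g <- 0L
  for (ci in seq_len(nC)) {
    nHere <- min(perChrom, nG - g)
    if (nHere <= 0) break
    margin <- 2e4
    spacing <- (config@chromLen - 2 * margin) / nHere
    for (j in seq_len(nHere)) {
      g <- g + 1L
      nE <- sample(4:8, 1)
      exLens <- sample(150:300, nE, replace = TRUE)
      inLens <- if (nE > 1) sample(400:2000, nE - 1, replace = TRUE) else integer()
      span <- sum(exLens) + sum(inLens)
      gStart <- round(margin + (j - 1) * spacing + runif(1, 0, spacing * 0.2))
      strand <- sample(c("+", "-"), 1)
      txLen <- sum(exLens)
      cds5 <- sample(20:60, 1)
      cds3 <- sample(20:60, 1)
      cdsLen <- txLen - cds5 - cds3 + 1
      cdsLen <- cdsLen - (cdsLen %% 3)
      defs[[g]] <- list(symbol = sprintf("GENE%02d", g),
                        name = sprintf("NM_%04d", g),
                        chrom = sprintf("chr%d", ci), strand = strand,
                        start = gStart, exLens = exLens, inLens = inLens,
                        span = span, cds5 = cds5, cdsLen = cdsLen)
    }
  }
  defs
}

# genomic exon intervals (sorted by coordinate) for a gene def
.def_exons <- function(def) {
  lens <- def$exLens
  n <- length(lens)
  starts <- integer(n); ends <- integer(n)
  pos <- def$start
  for (j in seq_len(n)) {
    starts[j] <- pos
    ends[j] <- pos + lens[j] - 1
    pos <- ends[j] + 1 + if (j < n) def$inLens[j] else 0
  }
  IRanges(starts, ends)
}

# map a spliced (transcription-order) offset to a genomic position
.def_spliced_to_genomic <- function(def, off) {
  ex <- .def_exons(def)
  lensTx <- if (def$strand == "+") def$exLens else rev(def$exLens)
  cum <- cumsum(lensTx)
  j <- which(off <= cum)[1]
  within <- off - c(0, cum)[j]
  if (def$strand == "+") start(ex)[j] + within - 1
  else end(ex)[length(ex) - j + 1] - within + 1
}

# Build the toy genome and GeneModelSet. Each gene's mRNA is constructed with
# a clean ORF (ATG, stop-free codons, terminal stop) and written back into the
# exonic genome positions, so translation-based frame checks are meaningful.
.make_genome <- function(config, defs) {
  chromNames <- sprintf("chr%d", seq_len(config@nChroms))
  chroms <- setNames(vapply(chromNames, function(x) .rand_dna(config@chromLen), ""),
                     chromNames)
  txRows <- list(); exList <- list(); mrnas <- character(length(defs))
  for (i in seq_along(defs)) {
    def <- defs[[i]]
    txLen <- sum(def$exLens)
    utr5 <- .rand_dna(def$cds5 - 1)
    cds <- paste0("ATG", .rand_codons(def$cdsLen / 3 - 2), sample(.STOPS, 1))
    utr3 <- .rand_dna(txLen - nchar(utr5) - nchar(cds))
    mrna <- paste0(utr5, cds, utr3)
    mrnas[i] <- mrna
    ex <- .def_exons(def)
    lensTx <- if (def$strand == "+") def$exLens else rev(def$exLens)
    offs <- c(0, cumsum(lensTx))
    for (j in seq_along(lensTx)) {
      piece <- substr(mrna, offs[j] + 1, offs[j + 1])
      gj <- if (def$strand == "+") j else length(lensTx) - j + 1
      if (def$strand == "-") piece <- .revcomp(piece)
      substr(chroms[[def$chrom]], start(ex)[gj], end(ex)[gj]) <- piece
    }
    cdsG <- sort(c(.def_spliced_to_genomic(def, def$cds5),
                   .def_spliced_to_genomic(def, def$cds5 + def$cdsLen - 1)))
    txRows[[i]] <- data.frame(
      name = def$name, symbol = def$symbol, chrom = def$chrom,
      strand = def$strand, txStart = min(start(ex)), txEnd = max(end(ex)),
      cdsStart = cdsG[1], cdsEnd = cdsG[2], isPseudogene = FALSE,
      stringsAsFactors = FALSE)
    exList[[i]] <- ex
  }
  genome <- DNAStringSet(chroms)
  models <- GeneModelSet(do.call(rbind, txRows), exList)
  list(genome = genome, models = models, mrnas = mrnas)
}

# fusion transcript, junction coordinates and translation-based frame status
.make_fusion <- function(spec, defs, mrnas) {
  di <- which(vapply(defs, `[[`, "", "symbol") == spec$donorGene)
  ai <- which(vapply(defs, `[[`, "", "symbol") == spec$acceptorGene)
  if (!length(di) || !length(ai))
    stop("fusion spec references unknown gene: ",
         if (!length(di)) spec$donorGene else spec$acceptorGene)
  dd <- defs[[di]]; ad <- defs[[ai]]
  dLensTx <- if (dd$strand == "+") dd$exLens else rev(dd$exLens)
  aLensTx <- if (ad$strand == "+") ad$exLens else rev(ad$exLens)
  if (spec$donorExon > length(dLensTx) || spec$acceptorExon > length(aLensTx))
    stop("fusion spec references a missing exon ordinal")
  J <- sum(dLensTx[seq_len(spec$donorExon)])
  aOff <- sum(aLensTx[seq_len(spec$acceptorExon - 1)]) + 1
  donorSeq <- substr(mrnas[di], 1, J)
  acceptorSeq <- substr(mrnas[ai], aOff, nchar(mrnas[ai]))
  fusion <- paste0(donorSeq, acceptorSeq)
  donorPos <- .def_spliced_to_genomic(dd, J)
  acceptorPos <- .def_spliced_to_genomic(ad, aOff)
  junction <- .junction_string(dd$chrom, donorPos, dd$strand,
                               ad$chrom, acceptorPos, ad$strand)
  # frame status by translation: in-frame iff ribosome scanning from the donor
  # ATG terminates exactly at the acceptor's native stop codon
  dCds5 <- dd$cds5
  aCds5 <- ad$cds5
  aStop <- aCds5 + ad$cdsLen - 3  # spliced start of acceptor's stop codon
  frame <- "noncoding"
  if (J >= dCds5 + 2 && aOff > aCds5 && aOff <= aStop) {
    fusCds <- paste0(substr(mrnas[di], dCds5, J),
                     substr(mrnas[ai], aOff, aStop + 2))
    expectStop <- (J - dCds5 + 1) + (aStop - aOff) + 1
    ncod <- nchar(fusCds) %/% 3
    aa <- as.character(translate(DNAString(substr(fusCds, 1, ncod * 3))))
    stars <- which(strsplit(aa, "")[[1]] == "*")
    firstStop <- if (length(stars)) (stars[1] - 1) * 3 + 1 else NA_integer_
    frame <- if (!is.na(firstStop) && firstStop == expectStop) "in" else "out"
  }
  list(junction = junction, seq = fusion, J = J,
       donorGene = spec$donorGene, acceptorGene = spec$acceptorGene,
       frame = frame, inFrame = identical(frame, "in"))
}

# Draw `n` reads from one source sequence (5' ends of log-normal fragments).
# `avoid` is an optional 1-based junction offset: fragments whose read would
# span the boundary between position `avoid` and `avoid`+1 are resampled.
.reads_from_source <- function(seqchar, n, config, avoid = NA) {
  L <- nchar(seqchar)
  rl <- config@readLen
  out <- character(0)
  starts <- integer(0)
  guard <- 0L
  while (length(out) < n && guard < 60L) {
    guard <- guard + 1L
    ndraw <- max(16L, ceiling((n - length(out)) * 1.4))
    fl <- fragmentLengths(ndraw, config@fragmentMedianBp, config@fragmentSdlog)
    st <- sapply(fl, function(f) sample.int(max(1L, L - f + 1L), 1L))
    eff <- pmin(fl, L - st + 1L)
    keep <- eff >= rl
    if (!is.na(avoid)) keep <- keep & !(st <= avoid & st + rl - 1 >= avoid + 1)
    st <- st[keep]
    if (length(st)) {
      out <- c(out, substring(seqchar, st, st + rl - 1))
      starts <- c(starts, st)
    }
  }
  n2 <- min(n, length(out))
  list(reads = out[seq_len(n2)], starts = starts[seq_len(n2)])
}

#' Emit FFPE-like reads from a weighted transcript pool
#'
#' Each read is the first `readLen` bases of a fragment drawn from a pool
#' entry (fragments shorter than the read length are dropped and resampled).
#'
#' @param pool `data.frame` with columns `id`, `seq`, `weight` and optionally
#'   `gene`, `form`
#' @param n number of reads to emit
#' @param config a [SimConfig-class]
#' @return list with `reads` (character), `meta` (`data.frame` of source id,
#'   gene, form and source offset per read)
#' @export
emitReads <- function(pool, n, config) {
  stopifnot(nrow(pool) >= 1)
  counts <- as.vector(stats::rmultinom(1, n, pool$weight / sum(pool$weight)))
  reads <- character(0)
  meta <- list()
  for (i in seq_len(nrow(pool))) {
    if (counts[i] == 0) next
    rs <- .reads_from_source(pool$seq[i], counts[i], config)
    reads <- c(reads, rs$reads)
    meta[[length(meta) + 1L]] <- data.frame(
      id = pool$id[i],
      gene = if ("gene" %in% names(pool)) pool$gene[i] else NA_character_,
      form = if ("form" %in% names(pool)) pool$form[i] else NA_character_,
      offset = rs$starts, stringsAsFactors = FALSE)
  }
  list(reads = reads, meta = do.call(rbind, meta))
}

#' Simulate a toy FFPE cohort
#'
#' Generates a toy genome with annotated genes (clean ORFs written into the
#' exonic sequence), a contaminant blacklist, per-sample directional 50 bp
#' FASTQ read sets with the configured fusions implanted, and a truth table
#' listing every planted junction with exact coordinates. Deterministic for a
#' given config (the seed lives in the config).
#'
#' @param config a [SimConfig-class]
#' @param outDir optional directory; when given, writes `genome.fa`,
#'   `refgene.txt`, `blacklist.fa`, one `<sample>.fastq` per sample and
#'   `truth.tsv`
#' @return a list with elements `genome` (DNAStringSet), `models`
#'   ([GeneModelSet-class]), `blacklist` (DNAStringSet), `mrnas`, `fusions`
#'   (per-spec junction/sequence/frame info), `samples` (named list with
#'   `reads`, `quals`, `meta` per sample) and `truth` (`data.frame`)
#' @export
buildToyCohort <- function(config, outDir = NULL) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()), add = TRUE)
  set.seed(config@seed)

  defs <- .make_gene_defs(config)
  gm <- .make_genome(config, defs)
  blacklist <- DNAStringSet(setNames(
    c(.rand_dna(2000), .rand_dna(1800), .rand_dna(1500)),
    c("rRNA_like_1", "rRNA_like_2", "PhiX_like")))

  fusions <- lapply(config@fusions, .make_fusion, defs = defs, mrnas = gm$mrnas)

  sampleNames <- sprintf("S%02d", seq_len(config@nSamples))
  baseline <- rlnorm(config@nGenes, 0, 0.5)
  symbols <- vapply(defs, `[[`, "", "symbol")
  spans <- vapply(defs, function(d) {
    fetchSequence(gm$genome, d$chrom, d$start, d$start + d$span - 1,
                  d$strand)
  }, "")

  rl <- config@readLen
  qual1 <- paste(rep(config@qualityChar, rl), collapse = "")
  truth <- list()
  samples <- list()
  for (s in seq_along(sampleNames)) {
    sn <- sampleNames[s]
    jitter <- rlnorm(config@nGenes, 0, 0.2)
    w <- baseline * jitter
    pool <- rbind(
      data.frame(id = paste0(symbols, ".m"), seq = gm$mrnas, gene = symbols,
                 form = "mrna", weight = w * (1 - config@premrnaFraction),
                 stringsAsFactors = FALSE),
      data.frame(id = paste0(symbols, ".p"), seq = spans, gene = symbols,
                 form = "premrna", weight = w * config@premrnaFraction,
                 stringsAsFactors = FALSE))
    if (config@contaminantFraction > 0) {
      bw <- sum(w) * config@contaminantFraction / (1 - config@contaminantFraction)
      pool <- rbind(pool, data.frame(
        id = names(blacklist), seq = as.character(blacklist),
        gene = NA_character_, form = "contaminant",
        weight = rep(bw / length(blacklist), length(blacklist)),
        stringsAsFactors = FALSE))
    }
    # background fusion expression (junction-avoiding reads)
    fusHere <- which(vapply(seq_along(fusions), function(i)
      sn %in% config@fusions[[i]]$samples, NA))
    allReads <- character(0); allMeta <- list()
    em <- emitReads(pool, config@depth, config)
    allReads <- em$reads; allMeta[[1]] <- em$meta
    for (fi in fusHere) {
      spec <- config@fusions[[fi]]
      fus <- fusions[[fi]]
      aW <- w[match(spec$acceptorGene, symbols)]
      fW <- spec$expressionFold * aW
      nBg <- round(config@depth * fW / (sum(pool$weight) + fW))
      if (nBg > 0) {
        rs <- .reads_from_source(fus$seq, nBg, config, avoid = fus$J)
        allReads <- c(allReads, rs$reads)
        allMeta[[length(allMeta) + 1L]] <- data.frame(
          id = paste0("fusion.", fi), gene = NA_character_, form = "fusion",
          offset = rs$starts, stringsAsFactors = FALSE)
      }
      nJ <- spec$junctionReads
      if (nJ > 0) {
        s1 <- sample(20:30, min(nJ, 11L))
        if (nJ > 11L) s1 <- c(s1, sample(20:30, nJ - 11L, replace = TRUE))
        st <- fus$J - s1 + 1
        allReads <- c(allReads, substring(fus$seq, st, st + rl - 1))
        allMeta[[length(allMeta) + 1L]] <- data.frame(
          id = paste0("fusion.", fi), gene = NA_character_,
          form = "fusion_junction", offset = st, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        junction = fus$junction, sample = sn, n_planted_junction_reads = nJ,
        in_frame = fus$inFrame, stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, allMeta)
    if (!config@directional && length(allReads)) {
      flip <- runif(length(allReads)) < 0.5
      allReads[flip] <- as.character(
        reverseComplement(DNAStringSet(allReads[flip])))
      meta$antisense <- flip
    } else {
      meta$antisense <- FALSE
    }
    ids <- sprintf("%s.r%06d", sn, seq_along(allReads))
    reads <- DNAStringSet(setNames(allReads, ids))
    meta$read_id <- ids
    quals <- BStringSet(setNames(rep(qual1, length(allReads)), ids))
    samples[[sn]] <- list(reads = reads, quals = quals, meta = meta)
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(junction = character(), sample = character(),
               n_planted_junction_reads = integer(), in_frame = logical(),
               stringsAsFactors = FALSE)

  res <- list(genome = gm$genome, models = gm$models, blacklist = blacklist,
              mrnas = gm$mrnas, fusions = fusions, samples = samples,
              truth = truth, config = config)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(gm$genome, file.path(outDir, "genome.fa"))
    writeXStringSet(blacklist, file.path(outDir, "blacklist.fa"))
    writeRefGene(gm$models, file.path(outDir, "refgene.txt"))
    for (sn in names(samples)) {
      writeXStringSet(samples[[sn]]$reads, file.path(outDir, paste0(sn, ".fastq")),
                      format = "fastq", qualities = samples[[sn]]$quals)
    }
    write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$outDir <- outDir
  }
  res
}

#' Reference validation cohort configuration
#'
#' A 12-sample cohort on a two-chromosome toy genome (~20 genes) with six
#' implanted fusions spanning the candidacy geometries the pipeline must
#' distinguish: two inter-chromosomal events, two intra-chromosomal
#' co-directional events at least 1 Mb apart, one opposite-strand event, and
#' one recurrent event carried by two samples. Gene pairs are chosen from the
#' seed-determined layout so every planted junction satisfies a candidacy
#' criterion and leaves full exonic template flanks.
#'
#' @param seed RNG seed (drives genome layout and read sampling)
#' @param depth reads per sample
#' @param junctionReads junction-spanning reads planted per carrier sample
#' @return a [SimConfig-class]
#' @export
exampleCohortConfig <- function(seed = 1, depth = 4000, junctionReads = 4) {
  base <- simConfig(seed = seed, nSamples = 12, nGenes = 20, nChroms = 2,
                    chromLen = 2.4e6, depth = depth)
  # probe the seed-determined gene layout to select suitable partners
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  defs <- .make_gene_defs(base)
  info <- data.frame(
    symbol = vapply(defs, `[[`, "", "symbol"),
    chrom = vapply(defs, `[[`, "", "chrom"),
    strand = vapply(defs, `[[`, "", "strand"),
    start = vapply(defs, function(d) d$start, 0),
    nExons = vapply(defs, function(d) length(d$exLens), 0L),
    stringsAsFactors = FALSE)
  avail <- rep(TRUE, nrow(info))
  pickPair <- function(relation) {
    for (d in which(avail)) {
      cand <- which(avail & relation(d) & seq_len(nrow(info)) != d)
      if (length(cand)) {
        a <- cand[1]
        avail[c(d, a)] <<- FALSE
        return(c(d, a))
      }
    }
    stop("layout does not admit the requested geometry")
  }
  midEx <- function(i) max(2L, min(3L, info$nExons[i] - 1L))
  addFusion <- function(pair, samples) {
    d <- pair[1]; a <- pair[2]
    fusionSpec(info$symbol[d], midEx(d), info$symbol[a], midEx(a),
               samples = samples, junctionReads = junctionReads)
  }
  fusions <- list()
  # the distance-constrained pairs are chosen first, while the layout is free:
  # two intra-chromosomal co-directional fusions >= 1 Mb apart
  for (k in 1:2) {
    p <- pickPair(function(d) info$chrom == info$chrom[d] &
                    info$strand == info$strand[d] &
                    abs(info$start - info$start[d]) >= 1.05e6)
    fusions[[length(fusions) + 1L]] <- addFusion(p, sprintf("S%02d", 4 + k))
  }
  # one opposite-strand fusion on a single chromosome
  p <- pickPair(function(d) info$chrom[d] == info$chrom &
                  info$strand != info$strand[d])
  fusions[[length(fusions) + 1L]] <- addFusion(p, "S07")
  # two inter-chromosomal fusions + one recurrent inter-chromosomal fusion
  carriers <- list("S01", "S02", c("S03", "S04"))
  for (k in 1:3) {
    p <- pickPair(function(d) info$chrom[d] == "chr1" & info$chrom == "chr2")
    fusions[[length(fusions) + 1L]] <- addFusion(p, carriers[[k]])
  }
  base@fusions <- fusions
  base
}

#' Intronic base fraction of a simulated sample
#'
#' Computed from the simulator's per-read source metadata: pre-mRNA reads
#' contribute the bases of their genomic footprint that fall outside exons;
#' spliced mRNA and fusion reads are fully exonic; contaminant reads are
#' excluded from the denominator (they do not map to the genome).
#'
#' @param cohort result of [buildToyCohort()]
#' @param sample sample name(s); default all
#' @return fraction of intronic bases among gene-derived read bases
#' @export
intronicBaseFraction <- function(cohort, sample = names(cohort$samples)) {
  tx <- transcripts(cohort$models)
  rl <- cohort$config@readLen
  intronic <- 0; total <- 0
  for (sn in sample) {
    meta <- cohort$samples[[sn]]$meta
    meta <- meta[meta$form %in% c("mrna", "premrna", "fusion",
                                  "fusion_junction"), , drop = FALSE]
    total <- total + nrow(meta) * rl
    pre <- meta[meta$form == "premrna", , drop = FALSE]
    if (!nrow(pre)) next
    pre$gene <- sub("\\.p$", "", pre$id)
    for (g in unique(pre$gene)) {
      i <- match(g, tx$symbol)
      ex <- cohort$models@exons[[i]]
      offs <- pre$offset[pre$gene == g]
      # genomic footprint of a pre-mRNA read starting at sense offset `o`
      if (tx$strand[i] == "+") {
        st <- tx$txStart[i] + offs - 1; en <- st + rl - 1
      } else {
        en <- tx$txEnd[i] - offs + 1; st <- en - rl + 1
      }
      rr <- IRanges(st, en)
      ov <- findOverlaps(rr, ex)
      exonic <- tapply(width(IRanges::pintersect(rr[queryHits(ov)],
                                                 ex[subjectHits(ov)])),
                       queryHits(ov), sum)
      exTotal <- sum(exonic)
      intronic <- intronic + sum(width(rr)) - exTotal
    }
  }
  intronic / total
}
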