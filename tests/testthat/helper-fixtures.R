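# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no binary fixtures.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

mutate_bases <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# A small deterministic genome for alignment unit tests.
tiny_genome <- function(seed = 42, len = c(chrA = 8000, chrB = 6000)) {
  set.seed(seed)
  Biostrings::DNAStringSet(vapply(len, rand_dna, ""))
}

# Hand-built two-gene annotation on a given genome (plus strand gene on chrA,
# minus strand gene on chrB), exon structure chosen so every flank used in
# template tests is well defined.
two_gene_models <- function() {
  tx <- data.frame(
    name = c("NM_A", "NM_B"), symbol = c("GENEA", "GENEB"),
    chrom = c("chrA", "chrB"), strand = c("+", "-"),
    txStart = c(1001, 1501), txEnd = c(2800, 3700),
    cdsStart = c(1051, 1601), cdsEnd = c(2750, 3650),
    isPseudogene = c(FALSE, FALSE), stringsAsFactors = FALSE)
  exons <- list(
    IRanges::IRanges(start = c(1001, 1501, 2101, 2601),
                     end = c(1200, 1800, 2300, 2800)),
    IRanges::IRanges(start = c(1501, 2101, 2901, 3401),
                     end = c(1700, 2400, 3100, 3700)))
  GeneModelSet(tx, exons)
}

# Brute-force all-positions contiguous alignment oracle: best matched-base
# count and every location attaining it, both strands. Independent of the
# package's seed-and-extend path.
oracle_best_local <- function(genome, read) {
  r <- strsplit(read, "")[[1]]
  rc <- strsplit(revcomp_chr(read), "")[[1]]
  L <- length(r)
  best <- -1L
  locs <- list()
  for (cn in names(genome)) {
    g <- strsplit(as.character(genome[[cn]]), "")[[1]]
    nOff <- length(g) - L + 1
    for (strand in c("+", "-")) {
      q <- if (strand == "+") r else rc
      sc <- integer(nOff)
      for (j in seq_len(L)) sc <- sc + (g[j:(j + nOff - 1)] == q[j])
      mx <- max(sc)
      if (mx > best) { best <- mx; locs <- list() }
      if (mx == best)
        locs[[length(locs) + 1]] <- data.frame(
          chrom = cn, strand = strand, start = which(sc == mx),
          stringsAsFactors = FALSE)
    }
  }
  list(matches = best, locs = do.call(rbind, locs))
}

# Independently splice a fusion mRNA from genome + annotation (exons 1..dEx of
# the donor joined to exons aEx..end of the acceptor, transcription order).
oracle_fusion_mrna <- function(genome, models, donor, dEx, acceptor, aEx) {
  splice <- function(gene, keep) {
    tx <- transcripts(models)
    i <- match(gene, tx$symbol)
    ex <- exonRanges(models)[[i]]
    ord <- if (tx$strand[i] == "+") seq_along(ex) else rev(seq_along(ex))
    paste(vapply(ord[keep], function(j)
      fetchSequence(genome, tx$chrom[i], IRanges::start(ex)[j],
                    IRanges::end(ex)[j], tx$strand[i]), ""), collapse = "")
  }
  tx <- transcripts(models)
  nA <- length(exonRanges(models)[[match(acceptor, tx$symbol)]])
  paste0(splice(donor, seq_len(dEx)), splice(acceptor, seq(aEx, nA)))
}

# Minimal candidate-junction row as produced by the junctions module.
aj_row <- function(junction = NULL, dchrom, dpos, dstrand, achrom, apos,
                   astrand, dgene = NA, agene = NA) {
  if (is.null(junction))
    junction <- paste0(dstrand, dchrom, ":", dpos, "->", astrand, achrom,
                       ":", apos)
  data.frame(junction = junction, donor_chrom = dchrom, donor_pos = dpos,
             donor_strand = dstrand, acceptor_chrom = achrom,
             acceptor_pos = apos, acceptor_strand = astrand,
             donor_gene = dgene, acceptor_gene = agene,
             stringsAsFactors = FALSE)
}

# Gene table SummarizedExperiment with prescribed counts over the features of
# `models` (collapsed), for expression-profiling oracles.
make_gene_table <- function(models, counts) {
  feats <- allFeatures(models)
  stopifnot(nrow(counts) == length(feats))
  rownames(counts) <- paste0(S4Vectors::mcols(feats)$gene, ".",
                             S4Vectors::mcols(feats)$kind,
                             S4Vectors::mcols(feats)$ordinal)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(basecount = counts), rowRanges = feats,
    colData = S4Vectors::DataFrame(sample = colnames(counts),
                                   row.names = colnames(counts)))
}

qual_string <- function(qs) {
  # qs: integer vector of Phred scores
  intToUtf8(qs + 33L)
}

# Translation-based frame oracle over a simulated cohort: splice the fusion
# coding sequence from genome + annotation, translate from the donor ATG and
# report "in" iff the ribosome terminates exactly at the acceptor's native
# stop codon. Returns NA for junctions outside both CDSs. Walks exons itself,
# independently of the package's phase arithmetic.
frame_oracle <- function(co, di, ai, dEx, aEx) {
  tx <- transcripts(co$models)
  spliced_pos <- function(i, pos) {
    ex <- exonRanges(co$models)[[i]]
    ord <- if (tx$strand[i] == "+") seq_along(ex) else rev(seq_along(ex))
    cum <- 0L
    for (jj in ord) {
      s <- IRanges::start(ex)[jj]; e <- IRanges::end(ex)[jj]
      if (pos >= s && pos <= e)
        return(cum + if (tx$strand[i] == "+") pos - s + 1 else e - pos + 1)
      cum <- cum + e - s + 1
    }
    NA_integer_
  }
  splice_all <- function(i) {
    ex <- exonRanges(co$models)[[i]]
    ord <- if (tx$strand[i] == "+") seq_along(ex) else rev(seq_along(ex))
    paste(vapply(ord, function(jj)
      fetchSequence(co$genome, tx$chrom[i], IRanges::start(ex)[jj],
                    IRanges::end(ex)[jj], tx$strand[i]), ""), collapse = "")
  }
  exd <- exonRanges(co$models)[[di]]; exa <- exonRanges(co$models)[[ai]]
  dOrd <- if (tx$strand[di] == "+") seq_along(exd) else rev(seq_along(exd))
  aOrd <- if (tx$strand[ai] == "+") seq_along(exa) else rev(seq_along(exa))
  dpos <- if (tx$strand[di] == "+") IRanges::end(exd)[dOrd[dEx]] else
    IRanges::start(exd)[dOrd[dEx]]
  apos <- if (tx$strand[ai] == "+") IRanges::start(exa)[aOrd[aEx]] else
    IRanges::end(exa)[aOrd[aEx]]
  dCds5 <- spliced_pos(di, if (tx$strand[di] == "+") tx$cdsStart[di] else
    tx$cdsEnd[di])
  aCds5 <- spliced_pos(ai, if (tx$strand[ai] == "+") tx$cdsStart[ai] else
    tx$cdsEnd[ai])
  aCds3 <- spliced_pos(ai, if (tx$strand[ai] == "+") tx$cdsEnd[ai] else
    tx$cdsStart[ai])
  J <- spliced_pos(di, dpos)
  aOff <- spliced_pos(ai, apos)
  if (J < dCds5 + 2 || aOff <= aCds5 || aOff > aCds3 - 2)
    return(list(frame = NA, dpos = dpos, apos = apos))
  fusCds <- paste0(substr(splice_all(di), dCds5, J),
                   substr(splice_all(ai), aOff, aCds3))
  ncod <- nchar(fusCds) %/% 3
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(fusCds, 1, ncod * 3)))), "")[[1]]
  stars <- which(aa == "*")
  firstStop <- if (length(stars)) (stars[1] - 1) * 3 + 1 else NA
  expectStop <- (J - dCds5 + 1) + (aCds3 - 2 - aOff) + 1
  list(frame = if (!is.na(firstStop) && firstStop == expectStop) "in" else
    "out", dpos = dpos, apos = apos)
}
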