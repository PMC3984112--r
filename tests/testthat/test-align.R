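# Read filters, split-read mapping, retest filter, gene-table counting, SAM
# round trip.

test_that("quality filter keeps reads with >= 15 bases at Q20 or above", {
  q30 <- qual_string(rep(30, 50))
  q15 <- qual_string(c(rep(20, 15), rep(10, 35)))
  q14 <- qual_string(c(rep(20, 14), rep(10, 36)))
  expect_equal(passesQualityFilter(c(q30, q15, q14)), c(TRUE, TRUE, FALSE))
})

test_that("abundance filter drops at 45/50 matches and keeps below", {
  set.seed(31)
  bl <- Biostrings::DNAStringSet(c(rRNA = rand_dna(2000)))
  blc <- as.character(bl[[1]])
  exact <- substr(blc, 501, 550)
  m5 <- mutate_bases(substr(blc, 101, 150), c(4, 14, 24, 34, 44))   # 45 matches
  m6 <- mutate_bases(substr(blc, 301, 350), c(4, 14, 24, 34, 44, 49)) # 44
  unrelated <- rand_dna(50)
  expect_equal(passesAbundanceFilter(c(exact, m5, m6, unrelated), bl),
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("exact reads map locally and uniquely at their locus", {
  genome <- tiny_genome(41)
  idx <- genomeIndex(genome)
  g <- as.character(genome$chrA)
  aln <- mapReads(idx, Biostrings::DNAStringSet(c(x = substr(g, 1234, 1283))))
  expect_equal(aln$kind, "local")
  expect_true(aln$unique)
  expect_equal(aln$chrom1, "chrA")
  expect_equal(aln$gstart1, 1234)
  expect_equal(aln$gend1, 1283)
  expect_equal(aln$strand1, "+")
})

test_that("a read planted across two chromosomes is distant-spliced at the
           exact junction", {
  genome <- tiny_genome(42)
  idx <- genomeIndex(genome)
  gA <- as.character(genome$chrA); gB <- as.character(genome$chrB)
  rd <- paste0(substr(gA, 2001, 2025), substr(gB, 4001, 4025))
  aln <- mapReads(idx, Biostrings::DNAStringSet(c(f = rd)))
  expect_equal(aln$kind, "distant")
  expect_true(aln$unique)
  expect_equal(aln$chrom1, "chrA")
  expect_equal(aln$donor_pos, 2025)  # last base of segment 1
  expect_equal(aln$chrom2, "chrB")
  expect_equal(aln$acceptor_pos, 4001)  # first base of segment 2
})

test_that("a read occurring at two identical loci is not unique", {
  set.seed(43)
  core <- rand_dna(50)
  chr <- paste0(rand_dna(500), core, rand_dna(500), core, rand_dna(500))
  idx <- genomeIndex(Biostrings::DNAStringSet(c(c1 = chr)))
  aln <- mapReads(idx, Biostrings::DNAStringSet(c(x = core)))
  expect_equal(aln$kind, "local")
  expect_false(aln$unique)
})

test_that("minus-strand placements agree with the reverse complement", {
  genome <- tiny_genome(44)
  idx <- genomeIndex(genome)
  g <- as.character(genome$chrB)
  rd <- revcomp_chr(substr(g, 3001, 3050))
  aln <- mapReads(idx, Biostrings::DNAStringSet(c(x = rd)))
  expect_equal(aln$kind, "local")
  expect_equal(aln$strand1, "-")
  expect_equal(aln$gstart1, 3001)
  expect_equal(aln$gend1, 3050)
})

test_that("seed-and-extend placements match a brute-force oracle", {
  # best score and location over all contiguous placements, both strands,
  # on a <= 10 kb genome; reads carry up to 2 mutations
  genome <- Biostrings::DNAStringSet(c(chrA = {set.seed(71); rand_dna(7000)},
                                       chrB = {set.seed(72); rand_dna(3000)}))
  idx <- genomeIndex(genome)
  set.seed(73)
  n <- 200
  reads <- character(n); truth <- vector("list", n)
  for (i in seq_len(n)) {
    cn <- sample(names(genome), 1)
    g <- as.character(genome[[cn]])
    st <- sample.int(nchar(g) - 49, 1)
    rd <- substr(g, st, st + 49)
    nmut <- sample(0:2, 1)
    if (nmut > 0) rd <- mutate_bases(rd, sample(50, nmut))
    if (runif(1) < 0.5) rd <- revcomp_chr(rd)
    reads[i] <- rd
  }
  aln <- mapReads(idx, setNames(reads, paste0("r", seq_len(n))))
  for (i in seq_len(n)) {
    orc <- oracle_best_local(genome, reads[i])
    expect_equal(aln$kind[i], "local")
    expect_equal((aln$score[i] + 50) / 2, orc$matches, info = i)
    hit <- any(orc$locs$chrom == aln$chrom1[i] &
                 orc$locs$strand == aln$strand1[i] &
                 orc$locs$start == aln$gstart1[i])
    expect_true(hit, info = i)
  }
})

test_that("retest discards at 44 matched bases and keeps below", {
  genome <- tiny_genome(100)
  idx <- genomeIndex(genome)
  g <- as.character(genome$chrA)
  set.seed(100)
  # 46 matches through a 1 bp deletion: chimera-looking but local
  r46 <- mutate_bases(paste0(substr(g, 3001, 3025), substr(g, 3027, 3051)),
                      c(3, 10, 40, 48))
  # clustered mutations leave 43 matches at the only matching locus
  r43 <- mutate_bases(substr(g, 4001, 4050), c(2, 4, 6, 8, 10, 12, 14))
  # exactly 44 matches: the boundary case is discarded
  r44 <- mutate_bases(substr(g, 5001, 5050), c(2, 4, 6, 8, 10, 12))
  rt <- retestDistantReads(idx, Biostrings::DNAStringSet(
    c(a = r46, b = r43, c = r44)))
  expect_equal(rt$local_matches, c(46, 43, 44))
  expect_equal(rt$keep, c(FALSE, TRUE, FALSE))
})

test_that("retest removes pseudo-chimeras but keeps genuine fusion reads", {
  genome <- tiny_genome(101)
  idx <- genomeIndex(genome)
  gA <- as.character(genome$chrA); gB <- as.character(genome$chrB)
  set.seed(101)
  # pseudo-chimeras: contiguous 50-mers treated as if they had been split
  starts <- sample.int(7000, 200)
  pc <- substr(rep(gA, 200), starts, starts + 49)
  rt <- retestDistantReads(idx, setNames(pc, paste0("p", 1:200)))
  expect_gte(mean(!rt$keep), 0.99)
  # genuine chimeras have no strong single-locus placement
  fus <- vapply(1:20, function(i) {
    a <- sample.int(6000, 1); b <- sample.int(5000, 1)
    paste0(substr(gA, a, a + 24), substr(gB, b, b + 24))
  }, "")
  rtf <- retestDistantReads(idx, setNames(fus, paste0("f", 1:20)))
  expect_true(all(rtf$keep))
  expect_true(all(rtf$local_matches <= 30 + 15))  # < 44 by a margin
})

test_that("feature counting sums aligned bases by interval intersection", {
  gm <- two_gene_models()
  feats <- allFeatures(collapseBySymbol(gm))
  # GENEA features (genomic order within gene): e(1001-1200) i(1201-1500)
  # e(1501-1800) i(1801-2100) e(2101-2300) i(2301-2600) e(2601-2800)
  aln <- data.frame(
    read_id = c("in_exon", "split", "nonuniq"),
    kind = c("local", "local", "local"),
    unique = c(TRUE, TRUE, FALSE),
    chrom1 = "chrA", strand1 = "+",
    gstart1 = c(1051, 1171, 1051), gend1 = c(1100, 1220, 1100),
    stringsAsFactors = FALSE)
  aln$chrom2 <- NA_character_; aln$strand2 <- NA_character_
  aln$gstart2 <- NA_integer_; aln$gend2 <- NA_integer_
  cnt <- countFeatures(aln, feats)
  ga <- which(S4Vectors::mcols(feats)$gene == "GENEA")
  exon1 <- ga[S4Vectors::mcols(feats)$kind[ga] == "exon" &
                S4Vectors::mcols(feats)$ordinal[ga] == 1]
  intron1 <- ga[S4Vectors::mcols(feats)$kind[ga] == "intron" &
                  S4Vectors::mcols(feats)$ordinal[ga] == 1]
  expect_equal(cnt[exon1], 50 + 30)   # full read + exon part of the split
  expect_equal(cnt[intron1], 20)      # intron part of the boundary read
  # conservation: counted bases equal aligned bases (features tile the gene)
  expect_equal(sum(cnt), 100)
})

test_that("the SAM round trip reproduces the gene table", {
  cfg <- simConfig(seed = 55, nSamples = 1, nGenes = 4, nChroms = 2,
                   chromLen = 1.5e5, depth = 1500,
                   fusions = list(fusionSpec("GENE01", 2, "GENE03", 2,
                                             samples = "S01",
                                             junctionReads = 3)))
  co <- buildToyCohort(cfg)
  idx <- genomeIndex(co$genome)
  aln <- mapReads(idx, co$samples$S01$reads)
  collapsed <- collapseBySymbol(co$models)
  gt1 <- buildGeneTable(list(S01 = aln), collapsed)
  sam <- tempfile(fileext = ".sam")
  writeAlignmentsSam(aln, co$samples$S01$reads, co$samples$S01$quals, sam,
                     co$genome)
  back <- readAlignmentsSam(sam)
  gt2 <- buildGeneTable(list(S01 = back$aln), collapsed)
  expect_equal(SummarizedExperiment::assay(gt1, "basecount"),
               SummarizedExperiment::assay(gt2, "basecount"))
})
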