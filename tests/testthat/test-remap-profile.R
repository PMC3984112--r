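# Read retrieval, template remapping, size factors, Interrupt Ratios and
# cohort nomination.

acceptor_models <- function() {
  tx <- data.frame(name = "ACC", symbol = "ACC", chrom = "chr1", strand = "+",
                   txStart = 1001, txEnd = 1450, cdsStart = NA, cdsEnd = NA,
                   isPseudogene = FALSE, stringsAsFactors = FALSE)
  # 5 exons / 4 introns, every feature exactly 50 bp
  GeneModelSet(tx, list(IRanges::IRanges(seq(1001, 1401, by = 100),
                                         seq(1050, 1450, by = 100))))
}

acc_junction <- function() {
  aj_row(dchrom = "chr9", dpos = 7000, dstrand = "+",
         achrom = "chr1", apos = 1201, astrand = "+",
         dgene = "DON", agene = "ACC")
}

test_that("remap places junction reads on the fusion template with the
           expected overhang", {
  cfg <- simConfig(seed = 81, nSamples = 1, nGenes = 4, nChroms = 1,
                   chromLen = 1.5e5, depth = 50,
                   fusions = list(fusionSpec("GENE01", 2, "GENE03", 2, "S01")))
  co <- buildToyCohort(cfg)
  gm <- collapseBySymbol(co$models)
  fus <- co$fusions[[1]]
  j <- parseJunction(fus$junction)
  aj <- aj_row(junction = fus$junction, dchrom = j@donorChrom,
               dpos = j@donorPos, dstrand = j@donorStrand,
               achrom = j@acceptorChrom, apos = j@acceptorPos,
               astrand = j@acceptorStrand, dgene = fus$donorGene,
               agene = fus$acceptorGene)
  idx <- buildTemplateIndex(list(buildTemplateSet(aj, co$genome, gm, 100)))
  # 20/30 split around the junction
  rd <- substring(fus$seq, fus$J - 19, fus$J + 30)
  h <- remapToTemplates(Biostrings::DNAStringSet(c(r = rd)), idx)
  expect_equal(h$role, "fusion")
  expect_true(h$unique_best)
  expect_equal(h$junction_overhang, 20L)
  expect_true(h$clean_overhang)
  # read from the unfused acceptor pre-mRNA spanning the splice site: the
  # genomic template wins over the spliced ones
  pre <- fetchSequence(co$genome, j@acceptorChrom, j@acceptorPos - 25,
                       j@acceptorPos + 24, j@acceptorStrand)
  h2 <- remapToTemplates(Biostrings::DNAStringSet(c(p = pre)), idx)
  expect_equal(h2$role, "acceptor_pre")
})

test_that("fusion support requires role, uniqueness and a clean overhang of
           at least 6", {
  hits <- data.frame(
    read_id = c("a", "b", "c", "d"),
    role = c("fusion", "fusion", "donor", "fusion"),
    junction = "j", offset = c(30, 46, 30, 20),
    matches = 50, unique_best = c(TRUE, TRUE, TRUE, FALSE),
    junction_overhang = c(10L, 3L, 20L, 25L),
    clean_overhang = TRUE, seq = "x", stringsAsFactors = FALSE)
  kept <- fusionSupportReads(hits)
  expect_equal(kept$read_id, "a")  # overhang 10 kept; 3 dropped; controls and
                                   # non-unique hits are never support
})

test_that("read retrieval takes flank-adjacent and unmapped reads only", {
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100))
  S4Vectors::mcols(loci)$junction <- "j"
  idx <- new("TemplateIndex", sequences = "A", junction = "j",
             role = "fusion", width = 100L, loci = loci)
  aln <- data.frame(
    read_id = c("far", "near", "edge", "um"),
    kind = c("local", "local", "local", "unmapped"),
    unique = TRUE,
    chrom1 = "chr1", strand1 = "+",
    gstart1 = c(15000, 5120, 4901, NA), gend1 = c(15049, 5169, 4950, NA),
    chrom2 = NA_character_, strand2 = NA_character_,
    gstart2 = NA_integer_, gend2 = NA_integer_, stringsAsFactors = FALSE)
  ids <- selectReadsForRemap(aln, idx, readLen = 50)
  expect_setequal(ids, c("near", "edge", "um"))
})

test_that("size factors follow the closed-form median-of-ratios", {
  m <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  sf <- computeSizeFactors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)
  # identical libraries: unit factors
  m2 <- cbind(A = c(5, 9, 14), B = c(5, 9, 14))
  expect_equal(unname(computeSizeFactors(m2)), c(1, 1))
  # scale equivariance: multiplying one library by c scales its factor by
  # c * c^(-1/m) and the others by c^(-1/m) through the geomean reference
  set.seed(82)
  m3 <- matrix(rpois(60, 80) + 1, ncol = 3,
               dimnames = list(NULL, c("A", "B", "C")))
  sf3 <- computeSizeFactors(m3)
  m3b <- m3; m3b[, "B"] <- m3b[, "B"] * 4
  sf3b <- computeSizeFactors(m3b)
  adj <- 4^(-1 / 3)
  expect_equal(unname(sf3b), unname(sf3 * c(adj, 4 * adj, adj)),
               tolerance = 1e-9)
  # all-zero library is degenerate
  expect_error(computeSizeFactors(cbind(A = c(0, 0), B = c(1, 2))),
               "degenerate")
})

test_that("size factors agree with DESeq2's median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(83)
  m <- matrix(rnbinom(200, mu = 150, size = 5), ncol = 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  m[m == 0] <- 1
  ours <- computeSizeFactors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("Interrupt Ratio reproduces direct arithmetic", {
  gm <- acceptor_models()
  # uniform coverage: IR = 1
  cntU <- matrix(5000, nrow = 9, ncol = 2, dimnames = list(NULL, c("A", "B")))
  gtU <- make_gene_table(gm, cntU)
  irU <- interruptRatio(gtU, acc_junction(), "A", list(A = 1, B = 1))
  expect_equal(irU$ir_acceptor, 1, tolerance = 1e-9)
  # preserved coverage 50 vs floored discarded coverage 5: IR = 10
  feats <- allFeatures(gm)
  ord <- S4Vectors::mcols(feats)$order
  cnt <- matrix(0, nrow = 9, ncol = 2, dimnames = list(NULL, c("A", "B")))
  cnt[ord >= 5, "A"] <- 2500     # e3, i3, e4, i4, e5 -> coverage 50
  cnt[, "B"] <- 600
  gt <- make_gene_table(gm, cnt)
  ir <- interruptRatio(gt, acc_junction(), "A", list(A = 1, B = 1))
  expect_equal(ir$ir_acceptor, 10, tolerance = 1e-9)
  # donor gene absent from the table: undefined-IR marker
  expect_true(is.na(ir$ir_donor))
})

test_that("IR is invariant to uniform library scaling via size factors", {
  gm <- acceptor_models()
  set.seed(84)
  cnt <- matrix(rpois(18, 6000), nrow = 9,
                dimnames = list(NULL, c("A", "B")))
  sf <- computeSizeFactors(cnt)
  ir1 <- interruptRatio(make_gene_table(gm, cnt), acc_junction(), "A",
                        as.list(sf))
  cnt2 <- cnt; cnt2[, "A"] <- cnt2[, "A"] * 2
  sf2 <- computeSizeFactors(cnt2)
  ir2 <- interruptRatio(make_gene_table(gm, cnt2), acc_junction(), "A",
                        as.list(sf2))
  expect_equal(ir1$ir_acceptor, ir2$ir_acceptor, tolerance = 1e-9)
})

test_that("the breakpoint-adjacent intron never contributes to the IR", {
  gm <- acceptor_models()
  cnt <- matrix(5000, nrow = 9, ncol = 2, dimnames = list(NULL, c("A", "B")))
  gt1 <- make_gene_table(gm, cnt)
  ir1 <- interruptRatio(gt1, acc_junction(), "A", list(A = 1, B = 1))
  # inflate the excluded intron (i2, immediately before the acceptor splice
  # site at 1201, i.e. the 1151-1200 feature) by 1000x: IR must not move
  feats <- allFeatures(gm)
  i2 <- which(S4Vectors::mcols(feats)$kind == "intron" &
                S4Vectors::mcols(feats)$ordinal == 2)
  cnt2 <- cnt; cnt2[i2, "A"] <- cnt2[i2, "A"] * 1000
  ir2 <- interruptRatio(make_gene_table(gm, cnt2), acc_junction(), "A",
                        list(A = 1, B = 1))
  expect_identical(ir1$ir_acceptor, ir2$ir_acceptor)
})

test_that("cohort nomination flags planted discontinuities only", {
  ir <- data.frame(junction = "j", sample = sprintf("S%02d", 1:10),
                   ir_donor = 1, ir_acceptor = c(rep(1, 9), 20),
                   stringsAsFactors = FALSE)
  ir$ir_donor <- ir$ir_donor * runif(10, 0.9, 1.1)
  nom <- nominateInterrupted(ir)
  expect_true(nom$interrupted[10])
  expect_equal(sum(nom$interrupted), 1L)
  expect_equal(nom$cohort_rank[10], 1L)
  # identical uniform samples: nothing is flagged
  ir2 <- data.frame(junction = "j", sample = sprintf("S%02d", 1:6),
                    ir_donor = 1.02, ir_acceptor = 0.97,
                    stringsAsFactors = FALSE)
  expect_false(any(nominateInterrupted(ir2)$interrupted))
})

test_that("center-scaled heatmap rows sum to zero", {
  gm <- acceptor_models()
  set.seed(85)
  cnt <- matrix(rpois(27, 4000), nrow = 9,
                dimnames = list(NULL, c("A", "B", "C")))
  m <- centerScaledMatrix(make_gene_table(gm, cnt), "ACC",
                          list(A = 1, B = 1.2, C = 0.8))
  expect_true(all(abs(rowSums(m)) < 1e-9))
})
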