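# Junction-read filtering, grouping/annotation and fusion candidacy rules.

dist_row <- function(id = "r1", b = 25, mis1 = "", mis2 = "",
                     chrom1 = "chrA", strand1 = "+", dpos = 1150,
                     chrom2 = "chrB", strand2 = "-", apos = 2300,
                     sample = "S01") {
  data.frame(read_id = id, kind = "distant", unique = TRUE,
             chrom1 = chrom1, strand1 = strand1,
             gstart1 = dpos - b + 1, gend1 = dpos, qstart1 = 1, qend1 = b,
             nmis1 = length(.gf_mis(mis1)), mis1 = mis1,
             chrom2 = chrom2, strand2 = strand2,
             gstart2 = apos, gend2 = apos + (50 - b) - 1,
             qstart2 = b + 1, qend2 = 50,
             nmis2 = length(.gf_mis(mis2)), mis2 = mis2,
             breakpoint = b, slide_lo = b, slide_hi = b,
             donor_pos = dpos, acceptor_pos = apos, sample = sample,
             stringsAsFactors = FALSE)
}
.gf_mis <- function(s) if (!nzchar(s)) integer(0) else
  as.integer(strsplit(s, ",")[[1]])

test_that("junction-read filter applies the 5 bp mismatch window", {
  gm <- collapseBySymbol(two_gene_models())
  # mismatch 3 bases before the donor junction (query 23 of breakpoint 25)
  drop3 <- dist_row(mis1 = "23")
  # mismatch 6 bases from the junction on the donor side: boundary kept
  keep6 <- dist_row(mis1 = "20")
  # mismatch 5 bases into the acceptor segment: dropped
  drop5a <- dist_row(mis2 = "30")
  keep6a <- dist_row(mis2 = "31")
  aln <- rbind(drop3, keep6, drop5a, keep6a)
  # donor inside GENEA (+, chrA), acceptor inside GENEB (-, chrB): sense
  expect_equal(junctionReadFilter(aln, gm), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("antisense segments are dropped, unannotated segments are not", {
  gm <- collapseBySymbol(two_gene_models())
  sense <- dist_row()
  anti <- dist_row(strand2 = "+")            # GENEB is a minus-strand gene
  nogene <- dist_row(chrom2 = "chrB", apos = 5500, strand2 = "+")  # intergenic
  aln <- rbind(sense, anti, nogene)
  expect_equal(junctionReadFilter(aln, gm), c(TRUE, FALSE, TRUE))
})

test_that("reads grouping shares one junction row and partitions reads", {
  gm <- collapseBySymbol(two_gene_models())
  aln <- rbind(dist_row("r1", b = 22), dist_row("r2", b = 26),
               dist_row("r3", b = 30),
               dist_row("r4", dpos = 1620, apos = 3050))
  aj <- groupAndAnnotate(aln, gm)
  expect_equal(nrow(aj), 2L)
  j1 <- aj[aj$donor_pos == 1150, ]
  expect_equal(j1$n_reads, 3L)
  expect_setequal(strsplit(j1$read_ids, ",")[[1]], c("r1", "r2", "r3"))
  expect_equal(j1$donor_gene, "GENEA")
  expect_equal(j1$acceptor_gene, "GENEB")
  # partition: every read appears in exactly one junction row
  ids <- unlist(strsplit(aj$read_ids, ","))
  expect_equal(sort(ids), sort(aln$read_id))
})

test_that("annotation rejects pseudogene, unannotated and ambiguous ends", {
  tx <- data.frame(
    name = c("GA", "GP", "GX", "GY"), symbol = c("GA", "GP", "GX", "GY"),
    chrom = "chr1", strand = "+",
    txStart = c(1000, 5000, 9000, 9100), txEnd = c(2000, 6000, 10000, 10100),
    cdsStart = NA, cdsEnd = NA,
    isPseudogene = c(FALSE, TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  ex <- list(IRanges::IRanges(1000, 2000), IRanges::IRanges(5000, 6000),
             IRanges::IRanges(9000, 10000), IRanges::IRanges(9100, 10100))
  gm <- GeneModelSet(tx, ex)
  mk <- function(apos) dist_row(chrom1 = "chr1", strand1 = "+", dpos = 1500,
                                chrom2 = "chr1", strand2 = "+", apos = apos)
  aj <- groupAndAnnotate(rbind(mk(5500), mk(3000), mk(9500)), gm)
  expect_setequal(aj$rejection_reason,
                  c("pseudogene", "unannotated", "ambiguous"))
})

test_that("candidacy follows the four criteria with read-through and
           same-gene rejection", {
  p <- gfuseParams()
  # co-directional pair, acceptor genomically upstream: a genuine candidate
  esr1_like <- aj_row(dchrom = "chr6", dpos = 152265643, dstrand = "+",
                      achrom = "chr6", apos = 151669846, astrand = "+",
                      dgene = "DONOR1", agene = "ACC1")
  v <- isCandidateFusion(esr1_like, p)
  expect_true(v$candidate)
  # opposite strands on one chromosome
  erbb2_like <- aj_row(dchrom = "chr17", dpos = 37868701, dstrand = "+",
                       achrom = "chr17", apos = 37949186, astrand = "-",
                       dgene = "DONOR2", agene = "ACC2")
  expect_true(isCandidateFusion(erbb2_like, p)$candidate)
  # different chromosomes
  inter <- aj_row(dchrom = "chr2", dpos = 100, dstrand = "-",
                  achrom = "chr9", apos = 200, astrand = "+",
                  dgene = "A", agene = "B")
  expect_equal(isCandidateFusion(inter, p)$reason, "different_chromosomes")
  # same gene: exon shuffling is rejected
  same <- aj_row(dchrom = "chr1", dpos = 5000, dstrand = "+",
                 achrom = "chr1", apos = 2000, astrand = "+",
                 dgene = "G1", agene = "G1")
  vs <- isCandidateFusion(same, p)
  expect_false(vs$candidate)
  expect_equal(vs$reason, "same_gene")
  # adjacent co-directional genes, transcription order, 50 kb: read-through
  rt <- aj_row(dchrom = "chr1", dpos = 10000, dstrand = "+",
               achrom = "chr1", apos = 60000, astrand = "+",
               dgene = "G1", agene = "G2")
  vr <- isCandidateFusion(rt, p)
  expect_false(vr$candidate)
  expect_equal(vr$reason, "read_through")
  # same pair but >= 1 Mb apart: kept
  far <- aj_row(dchrom = "chr1", dpos = 10000, dstrand = "+",
                achrom = "chr1", apos = 1010000, astrand = "+",
                dgene = "G1", agene = "G2")
  expect_true(isCandidateFusion(far, p)$candidate)
  # minus-strand read-through runs toward lower coordinates
  rtm <- aj_row(dchrom = "chr1", dpos = 60000, dstrand = "-",
                achrom = "chr1", apos = 10000, astrand = "-",
                dgene = "G1", agene = "G2")
  expect_equal(isCandidateFusion(rtm, p)$reason, "read_through")
})

test_that("the candidacy criteria act as a disjunction", {
  # verdicts agree with an independent restatement of the rule over random
  # junction geometries
  p <- gfuseParams()
  set.seed(77)
  for (i in 1:200) {
    dchrom <- sample(c("chr1", "chr2"), 1)
    achrom <- sample(c("chr1", "chr2"), 1)
    ds <- sample(c("+", "-"), 1); as_ <- sample(c("+", "-"), 1)
    dpos <- sample.int(3e6, 1); apos <- sample.int(3e6, 1)
    sameGene <- dchrom == achrom && runif(1) < 0.15
    dg <- "GD"; ag <- if (sameGene) "GD" else "GA"
    aj <- aj_row(dchrom = dchrom, dpos = dpos, dstrand = ds,
                 achrom = achrom, apos = apos, astrand = as_,
                 dgene = dg, agene = ag)
    v <- isCandidateFusion(aj, p)
    crit <- (dchrom != achrom) || (dg != ag) || (ds != as_) ||
      abs(dpos - apos) >= 1e6
    readThrough <- dchrom == achrom && ds == as_ && dg != ag &&
      abs(dpos - apos) < 1e6 &&
      (if (ds == "+") apos > dpos else apos < dpos)
    expected <- !sameGene && !readThrough && crit
    expect_equal(v$candidate, expected, info = i)
  }
})
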