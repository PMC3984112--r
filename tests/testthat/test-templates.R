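# Five-template set construction, duplicate/homology filters, template index.

make_set <- function(junction, seqs, width = 100, flankOk = TRUE) {
  new("TemplateSet", junction = junction, width = as.integer(width),
      sequences = setNames(seqs, c("fusion", "donor", "acceptor",
                                   "donor_pre", "acceptor_pre")),
      flankOk = flankOk, loci = GenomicRanges::GRanges())
}

sim_candidate <- function(co, fi = 1) {
  fus <- co$fusions[[fi]]
  j <- parseJunction(fus$junction)
  aj_row(junction = fus$junction, dchrom = j@donorChrom, dpos = j@donorPos,
         dstrand = j@donorStrand, achrom = j@acceptorChrom,
         apos = j@acceptorPos, astrand = j@acceptorStrand,
         dgene = fus$donorGene, agene = fus$acceptorGene)
}

test_that("the fusion template is the 100 bp of fusion mRNA centered on the
           junction", {
  cfg <- simConfig(seed = 61, nSamples = 1, nGenes = 4, nChroms = 1,
                   chromLen = 1.5e5, depth = 50,
                   fusions = list(fusionSpec("GENE02", 2, "GENE04", 2, "S01")))
  co <- buildToyCohort(cfg)
  aj <- sim_candidate(co)
  set100 <- buildTemplateSet(aj, co$genome, collapseBySymbol(co$models), 100)
  mrna <- oracle_fusion_mrna(co$genome, co$models, "GENE02", 2, "GENE04", 2)
  J <- co$fusions[[1]]$J
  expect_identical(templateSequences(set100)[["fusion"]],
                   substr(mrna, J - 49, J + 50))
  expect_true(set100@flankOk)
  # all five templates have the full width
  expect_true(all(nchar(templateSequences(set100)) == 100))
  # the wild-type mRNA templates track the unfused transcripts
  set300 <- buildTemplateSet(aj, co$genome, collapseBySymbol(co$models), 300)
  expect_true(all(nchar(templateSequences(set300)) == 300))
})

test_that("exonic flanks splice across exon boundaries (introns excluded)", {
  g <- tiny_genome(62)
  tx <- data.frame(name = c("GD", "GA"), symbol = c("GD", "GA"),
                   chrom = c("chrA", "chrA"), strand = "+",
                   txStart = c(1001, 5001), txEnd = c(1300, 5900),
                   cdsStart = NA, cdsEnd = NA, isPseudogene = FALSE,
                   stringsAsFactors = FALSE)
  ex <- list(IRanges::IRanges(c(1001, 1101, 1201), c(1040, 1130, 1300)),
             IRanges::IRanges(c(5001, 5301, 5601), c(5100, 5400, 5900)))
  gm <- GeneModelSet(tx, ex)
  # junction at the end of GD exon 2; upstream exonic sequence is only 70 bp
  # in exon 2 + exon 1, so the 50 bp flank must span the first splice
  aj <- aj_row(dchrom = "chrA", dpos = 1130, dstrand = "+",
               achrom = "chrA", apos = 5301, astrand = "+",
               dgene = "GD", agene = "GA")
  st <- buildTemplateSet(aj, g, gm, 100)
  expected_donor_flank <- paste0(fetchSequence(g, "chrA", 1021, 1040),
                                 fetchSequence(g, "chrA", 1101, 1130))
  expect_identical(substr(templateSequences(st)[["fusion"]], 1, 50),
                   expected_donor_flank)
  # pre-mRNA template is contiguous genomic sequence including the intron
  expect_identical(templateSequences(st)[["donor_pre"]],
                   fetchSequence(g, "chrA", 1081, 1180))
})

test_that("insufficient exonic sequence flags the set", {
  g <- tiny_genome(63)
  tx <- data.frame(name = c("GD", "GA"), symbol = c("GD", "GA"),
                   chrom = "chrA", strand = "+",
                   txStart = c(1001, 5001), txEnd = c(1400, 5430),
                   cdsStart = NA, cdsEnd = NA, isPseudogene = FALSE,
                   stringsAsFactors = FALSE)
  # GA has only 30 exonic bases after the junction at 5401
  ex <- list(IRanges::IRanges(c(1001, 1201), c(1100, 1400)),
             IRanges::IRanges(c(5001, 5401), c(5100, 5430)))
  gm <- GeneModelSet(tx, ex)
  aj <- aj_row(dchrom = "chrA", dpos = 1300, dstrand = "+",
               achrom = "chrA", apos = 5401, astrand = "+",
               dgene = "GD", agene = "GA")
  st <- buildTemplateSet(aj, g, gm, 100)
  expect_false(st@flankOk)
  hf <- homologyFilter(st, st)
  expect_false(hf$keep)
  expect_equal(hf$reason, "insufficient_exonic_flank")
})

test_that("sets sharing an identical template are both removed", {
  set.seed(64)
  a <- vapply(1:5, function(i) rand_dna(100), "")
  b <- vapply(1:5, function(i) rand_dna(100), "")
  c_ <- vapply(1:5, function(i) rand_dna(100), "")
  b[1] <- a[1]  # duplicated fusion template between sets A and B
  sets <- list(A = make_set("jA", a), B = make_set("jB", b),
               C = make_set("jC", c_))
  dd <- dedupeTemplateSets(sets)
  expect_setequal(names(dd$kept), "C")
  expect_setequal(dd$removed$junction, c("jA", "jB"))
  # identical templates WITHIN one set are not grounds for removal
  d <- vapply(1:5, function(i) rand_dna(100), "")
  d[4] <- d[2]   # donor_pre == donor (single-exon-like)
  dd2 <- dedupeTemplateSets(list(C = make_set("jC", c_),
                                 D = make_set("jD", d)))
  expect_equal(length(dd2$kept), 2L)
})

test_that("homology filter removes at 15 shared bases and keeps at 14", {
  set.seed(65)
  shared15 <- rand_dna(15)
  mk300 <- function(donor, acceptor) {
    make_set("j", c(rand_dna(300), donor, acceptor, rand_dna(300),
                    rand_dna(300)), width = 300)
  }
  s100 <- make_set("j", vapply(1:5, function(i) rand_dna(100), ""))
  hot <- mk300(paste0(rand_dna(140), shared15, rand_dna(145)),
               paste0(rand_dna(40), shared15, rand_dna(245)))
  expect_false(homologyFilter(hot, s100)$keep)
  expect_equal(homologyFilter(hot, s100)$reason, "mrna_homology")
  cold <- mk300(paste0(rand_dna(140), substr(shared15, 1, 14), rand_dna(146)),
                paste0(rand_dna(40), substr(shared15, 1, 14), rand_dna(246)))
  expect_true(homologyFilter(cold, s100)$keep)
  # symmetric in donor/acceptor
  swap <- function(s) {
    q <- s@sequences
    make_set(s@junction, unname(q[c(1, 3, 2, 5, 4)]), width = 300)
  }
  expect_false(homologyFilter(swap(hot), s100)$keep)
  # pre-mRNA homology is tested on the genomic templates
  pre <- make_set("j", c(rand_dna(300), rand_dna(300), rand_dna(300),
                         paste0(rand_dna(100), shared15, rand_dna(185)),
                         paste0(rand_dna(200), shared15, rand_dna(85))),
                  width = 300)
  expect_equal(homologyFilter(pre, s100)$reason, "premrna_homology")
})

test_that("a planted paralog pair with a 40 bp shared exon segment is
           removed", {
  set.seed(66)
  shared <- rand_dna(40)
  s <- make_set("j", c(rand_dna(300),
                       paste0(rand_dna(100), shared, rand_dna(160)),
                       paste0(rand_dna(200), shared, rand_dna(60)),
                       rand_dna(300), rand_dna(300)), width = 300)
  s100 <- make_set("j", vapply(1:5, function(i) rand_dna(100), ""))
  expect_false(homologyFilter(s, s100)$keep)
})

test_that("the template index resolves reads to their best template", {
  cfg <- simConfig(seed = 67, nSamples = 1, nGenes = 4, nChroms = 1,
                   chromLen = 1.5e5, depth = 50,
                   fusions = list(fusionSpec("GENE01", 2, "GENE03", 2, "S01")))
  co <- buildToyCohort(cfg)
  gm <- collapseBySymbol(co$models)
  aj <- sim_candidate(co)
  set100 <- buildTemplateSet(aj, co$genome, gm, 100)
  idx <- buildTemplateIndex(list(set100))
  fus <- templateSequences(set100)[["fusion"]]
  # junction-spanning read: only the fusion template matches in full
  spanning <- substr(fus, 26, 75)
  h <- remapToTemplates(Biostrings::DNAStringSet(c(r1 = spanning)), idx)
  expect_equal(nrow(h), 1L)
  expect_equal(h$role, "fusion")
  expect_true(h$unique_best)
  # read inside the donor preserved half: ambiguous between roles
  inside <- substr(fus, 1, 50)
  h2 <- remapToTemplates(Biostrings::DNAStringSet(c(r2 = inside)), idx)
  expect_false(h2$unique_best)
  # empty read set gives no hits
  h0 <- remapToTemplates(Biostrings::DNAStringSet(), idx)
  expect_equal(nrow(h0), 0L)
  # surviving sets keep fusion_t distinct from the wild-type templates
  s <- templateSequences(set100)
  expect_false(s[["fusion"]] == s[["donor"]])
  expect_false(s[["fusion"]] == s[["acceptor"]])
})

test_that("pooling cohorts yields a template superset of each cohort alone", {
  set.seed(68)
  mk <- function(tag) make_set(tag, vapply(1:5, function(i) rand_dna(100), ""))
  cohortA <- list(a1 = mk("a1"), a2 = mk("a2"))
  cohortB <- list(b1 = mk("b1"))
  pooled <- dedupeTemplateSets(c(cohortA, cohortB))$kept
  aloneA <- dedupeTemplateSets(cohortA)$kept
  aloneB <- dedupeTemplateSets(cohortB)$kept
  tpl <- function(sets) unlist(lapply(sets, templateSequences))
  expect_true(all(tpl(aloneA) %in% tpl(pooled)))
  expect_true(all(tpl(aloneB) %in% tpl(pooled)))
})
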