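test_that("codon changes classify by the genetic code", {
  expect_equal(codonConsequence("CGA", "TGA"), "NONSENSE")
  expect_equal(codonConsequence("ACG", "ACA"), "SILENT")
  expect_equal(codonConsequence("CGC", "TGC"), "MISSENSE")
  # stop-to-stop is silent; stop-loss counts as missense
  expect_equal(codonConsequence("TGA", "TAA"), "SILENT")
  expect_equal(codonConsequence("TGA", "CGA"), "MISSENSE")
})

test_that("primed-site enumeration finds every CDS CpG base with the
          projected substitution", {
  # plus-strand single-exon gene, CDS = ATG CGA TAC GTA A.. pad to %3
  g <- strGenome(chr1 = "ATGCGATACGTAAATAG")
  gene <- GeneModel("g", "chr1", "+", 1L, 17L, 1L, 15L, 1L, 17L)
  cgis <- GenomicRanges::GRanges()
  cgis$cgiClass <- factor(character(0), levels = CGI_CLASSES)
  primed <- enumeratePrimedSites(g, list(gene), cgis, siteBetas = NULL,
                                 betaMin = NULL)
  # CpGs in CDS: pos 4-5 (CGA codon) and pos 9-10 (C in TAC, G in GTA)
  expect_setequal(primed$pos, c(4L, 5L, 9L, 10L))
  expect_equal(primed$consequence[primed$pos == 4], "NONSENSE")  # CGA->TGA
  expect_equal(primed$ref[primed$pos == 5], "G")
  expect_equal(primed$alt[primed$pos == 5], "A")
  expect_true(all(primed$regionClass == "NON_CGI"))
})

test_that("consequence classification agrees with the full-transcript
          translate-and-diff oracle over randomized gene models", {
  set.seed(202)
  cgis <- GenomicRanges::GRanges()
  cgis$cgiClass <- factor(character(0), levels = CGI_CLASSES)
  nChecked <- 0
  for (rep in 1:60) {
    rg <- randomGeneModel()
    primed <- enumeratePrimedSites(rg$genome, list(rg$gene), cgis,
                                   siteBetas = NULL, betaMin = NULL)
    if (!nrow(primed)) next
    want <- vapply(seq_len(nrow(primed)), function(i)
      oracleConsequence(rg$genome, rg$gene, primed$pos[i], primed$alt[i]),
      character(1))
    expect_equal(primed$consequence, want,
                 info = sprintf("gene %s strand %s", rg$gene@name,
                                geneStrand(rg$gene)))
    nChecked <- nChecked + nrow(primed)
  }
  expect_gt(nChecked, 100)
})

test_that("strand duality: opposite-strand genes on the reverse complement
          give identical consequence counts", {
  set.seed(99)
  for (rep in 1:20) {
    rg <- randomGeneModel()
    cgis <- GenomicRanges::GRanges()
    cgis$cgiClass <- factor(character(0), levels = CGI_CLASSES)
    p1 <- enumeratePrimedSites(rg$genome, list(rg$gene), cgis,
                               siteBetas = NULL, betaMin = NULL)
    L <- nchar(as.character(rg$genome[[1]]))
    rcSeq <- rcStr(as.character(rg$genome[[1]]))
    g2 <- rg$gene
    mirror <- function(x) L + 1L - x
    gene2 <- GeneModel(g2@name, "chr1",
                       if (g2@strand == "+") "-" else "+",
                       mirror(g2@txEnd), mirror(g2@txStart),
                       mirror(g2@cdsEnd), mirror(g2@cdsStart),
                       rev(mirror(IRanges::end(g2@exons))),
                       rev(mirror(IRanges::start(g2@exons))), TRUE)
    p2 <- enumeratePrimedSites(strGenome(chr1 = rcSeq), list(gene2), cgis,
                               siteBetas = NULL, betaMin = NULL)
    expect_equal(table(factor(p1$consequence,
                              c("SILENT", "MISSENSE", "NONSENSE"))),
                 table(factor(p2$consequence,
                              c("SILENT", "MISSENSE", "NONSENSE"))))
  }
})

test_that("hyper-methylation filter and region pooling apply", {
  b <- smallBundle()
  g <- readGenome(b$paths$fasta)
  genes <- readGenePred(b$paths$genes)
  cgis <- classifyCGIs(loadCGIsBed(b$paths$cgi, g), genes)
  sites <- enumerateCpGSites(g)
  meth <- loadMethylation(b$paths$methylation, sites)
  primed <- enumeratePrimedSites(g, genes, cgis, siteBetas = meth,
                                 betaMin = 0.67)
  expect_true(all(primed$beta >= 0.67))
  expect_true(all(primed$regionClass %in% c("TSS_CGI", "INTRAGENIC_CGI",
                                            "NON_CGI")))
  # per-site dedup: one row per position
  expect_false(any(duplicated(paste(primed$chrom, primed$pos))))
  # matches generator truth where the truth site is covered and hyper
  truth <- b$truthPrimed
  key <- paste(truth$chrom, truth$pos)
  idx <- match(paste(primed$chrom, primed$pos), key)
  expect_false(anyNA(idx))
  expect_equal(primed$consequence, truth$consequence[idx])
})

test_that("observed crossing matches positions and alleles exactly", {
  primed <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                       cpgPos = c(10L, 19L, 30L),
                       ref = c("C", "G", "C"), alt = c("T", "A", "T"),
                       gene = "g", regionClass = "NON_CGI",
                       codonBefore = "CGA", codonAfter = "TGA",
                       consequence = "NONSENSE", beta = 0.8,
                       stringsAsFactors = FALSE)
  ev <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10L, 20L, 30L),
                                                        width = 1))
  ev$ref <- c("C", "G", "C"); ev$alt <- c("T", "A", "G")
  ev$ac <- c(1L, 7L, 2L)
  got <- crossWithObserved(primed, ev)
  expect_equal(got$observed, c(TRUE, TRUE, FALSE))
  expect_equal(got$ac, c(1L, 7L, NA_integer_))
  expect_equal(attr(got, "mismatched"), 1L)  # the C>G at pos 30
})

test_that("AC spectrum proportions sum to 1 and bin per definition", {
  primed <- data.frame(consequence = rep(c("SILENT", "NONSENSE"),
                                         each = 4),
                       observed = TRUE,
                       ac = c(1L, 1L, 6L, 6L, 1L, 2L, 3L, 5L))
  got <- acSpectrum(primed)
  sil <- got[got$consequence == "SILENT", ]
  expect_equal(sil$proportion[sil$bin == "AC=1"], 0.5)
  expect_equal(sil$proportion[sil$bin == "AC>5"], 0.5)
  non <- got[got$consequence == "NONSENSE", ]
  expect_equal(non$proportion[non$bin == "AC 3-5"], 0.5)
  for (cons in unique(got$consequence))
    expect_equal(sum(got$proportion[got$consequence == cons]), 1)
})

test_that("planted observation probabilities and the selection-shifted AC
          spectrum are recovered", {
  run <- demoPipeline()
  b <- demoBundle()
  primed <- run$primed
  truth <- b$truthPrimed
  idx <- match(paste(primed$chrom, primed$pos),
               paste(truth$chrom, truth$pos))
  expect_false(anyNA(idx))
  expect_equal(primed$observed, truth$observed[idx])
  # observation proportions per consequence within 3 binomial SE
  for (cons in c("SILENT", "MISSENSE", "NONSENSE")) {
    sel <- primed$consequence == cons
    p <- b$config$obsProb[cons]
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(primed$observed[sel]) - p), 3 * se + 0.02)
  }
  # nonsense sites have the largest singleton share (negative selection)
  ac <- run$acSpectrum
  singleton <- function(cons)
    ac$proportion[ac$consequence == cons & ac$bin == "AC=1"]
  expect_gt(singleton("NONSENSE"), singleton("SILENT"))
  expect_gt(singleton("NONSENSE"), singleton("MISSENSE"))
  expect_gt(singleton("MISSENSE"), singleton("SILENT"))
})
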