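test_that("saturated CG repeat is called as one island; poly-A is not", {
  g <- strGenome(chr1 = paste(rep("CG", 150), collapse = ""))
  got <- callCGIs(g)
  expect_equal(length(got), 1L)
  expect_equal(GenomicRanges::start(got), 1L)
  expect_equal(GenomicRanges::end(got), 300L)
  expect_equal(got$gcFraction, 1.0)
  expect_equal(got$obsExpRatio, 2.0)  # (150*300)/(150*150)
  expect_equal(length(callCGIs(strGenome(strrep("A", 300)))), 0L)
})

test_that("a planted island in low-GC background is recovered and the
          caller agrees with the brute-force window oracle", {
  set.seed(7)
  bg1 <- paste(sample(c("A", "T", "C", "G"), 400, TRUE,
                      c(0.3, 0.3, 0.2, 0.2)), collapse = "")
  bg2 <- paste(sample(c("A", "T", "C", "G"), 200, TRUE,
                      c(0.3, 0.3, 0.2, 0.2)), collapse = "")
  insert <- paste(replicate(100, sample(c("CG", "A", "C", "G", "T"), 1,
                                        prob = c(0.2, 0.15, 0.25, 0.25,
                                                 0.15))), collapse = "")
  insert <- substr(strrep(insert, 3), 1, 400)
  seq <- paste0(bg1, insert, bg2)
  g <- strGenome(seq)
  got <- callCGIs(g)
  oracle <- bruteCGI(seq)
  expect_equal(GenomicRanges::start(got), oracle$start)
  expect_equal(GenomicRanges::end(got), oracle$end)
  # the planted insert is recovered up to window-edge slack
  expect_equal(length(got), 1L)
  expect_lt(abs(GenomicRanges::start(got) - 401), 200)
  expect_lt(abs(GenomicRanges::end(got) - 800), 200)
})

test_that("short chromosomes are skipped with a warning", {
  g <- strGenome(chr1 = "ACGT")
  expect_warning(got <- callCGIs(g), "shorter than window")
  expect_equal(length(got), 0L)
})

test_that("BED ingestion sorts, merges overlaps and drops unknown
          chromosomes", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t300", "chr1\t500\t600",
               "chr9\t0\t100"), bed)
  g <- strGenome(chr1 = strrep("A", 1000))
  expect_warning(got <- loadCGIsBed(bed, g), "dropped")
  expect_equal(length(got), 2L)
  expect_equal(GenomicRanges::start(got), c(101L, 501L))
  expect_equal(GenomicRanges::end(got), c(300L, 600L))
})

test_that("classification implements TSS/body precedence and MISC", {
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(951, 5001, 8001), c(1300, 5400, 8400)))
  coding <- GeneModel("gA", "chr1", "+", 1000L, 6000L, 1100L, 5900L,
                      1000L, 6000L)
  got <- classifyCGIs(cgis, list(coding))
  expect_equal(as.character(got$cgiClass),
               c("TSS_CODING", "INTRAGENIC_CODING", "INTERGENIC"))
  # island overlapping a coding TSS AND a noncoding gene body -> MISC
  nc <- GeneModel("gB", "chr1", "+", 500L, 2000L, NA_integer_,
                  NA_integer_, 500L, 2000L, FALSE)
  got2 <- classifyCGIs(cgis, list(coding, nc))
  expect_equal(as.character(got2$cgiClass)[1], "MISC")
  # empty gene list -> everything intergenic
  got3 <- classifyCGIs(cgis, list())
  expect_true(all(got3$cgiClass == "INTERGENIC"))
  # classification is a partition
  expect_false(anyNA(got2$cgiClass))
})

test_that("minus-strand TSS is the transcript end", {
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5950, 6200))
  gene <- GeneModel("g", "chr1", "-", 1000L, 6000L, 1100L, 5900L,
                    1000L, 6000L)
  got <- classifyCGIs(cgis, list(gene))
  expect_equal(as.character(got$cgiClass), "TSS_CODING")
})

test_that("transcript isoforms sharing a TSS do not produce MISC", {
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(951, 1300))
  iso1 <- GeneModel("gA", "chr1", "+", 1000L, 6000L, 1100L, 5900L,
                    1000L, 6000L)
  iso2 <- GeneModel("gA", "chr1", "+", 1000L, 7000L, 1100L, 6900L,
                    1000L, 7000L)
  got <- classifyCGIs(cgis, list(iso1, iso2))
  expect_equal(as.character(got$cgiClass), "TSS_CODING")
})

test_that("signed distances follow the border convention with ties to the
          lower-coordinate island", {
  # island at 0-based [1000, 1500) = 1-based [1001, 1500]
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1500))
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(801, 1601, 1201), width = 2))
  d <- signedDistanceToCGI(sites, cgis)
  expect_equal(d$distance[1], -200L)
  expect_equal(d$distance[2], 100L)
  expect_true(d$inCGI[3])
  expect_true(is.na(d$distance[3]))
  # no islands on the chromosome -> missing distance
  sites2 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(10, 11))
  d2 <- signedDistanceToCGI(sites2, cgis)
  expect_true(is.na(d2$distance))
  expect_false(d2$inCGI)
  # equidistant between two islands: assign to the lower-coordinate one
  cgis2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 211), c(100, 300)))
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(156, 157))
  d3 <- signedDistanceToCGI(site, cgis2)
  expect_equal(d3$nearest, 1L)
  expect_gt(d3$distance, 0)
})

test_that("mirroring the chromosome negates signed distances", {
  set.seed(3)
  L <- 5000L
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(501, 2001, 4001), c(800, 2500, 4300)))
  pos <- sort(sample(setdiff(1:L, unlist(Map(seq, c(501, 2001, 4001),
                                             c(800, 2500, 4300)))), 200))
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos + 1))
  d <- signedDistanceToCGI(sites, cgis)
  # mirrored geometry: position p -> L + 1 - p, islands mirrored
  mposStart <- L + 1L - GenomicRanges::end(cgis)
  mposEnd <- L + 1L - GenomicRanges::start(cgis)
  mcgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    sort(mposStart), sort(mposEnd)))
  msites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    L + 1L - pos, width = 1))
  md <- signedDistanceToCGI(msites, mcgis)
  # exact antisymmetry of the closed-left/open-right border convention:
  # mirrored distance = -(d + 1); exclude exact inter-island midpoints
  # where the lower-coordinate tie-break differs between orientations
  gapMids <- c(mean(c(800, 2001)), mean(c(2500, 4001)))
  okPos <- abs(pos - gapMids[1]) > 2 & abs(pos - gapMids[2]) > 2
  expect_equal(md$distance[okPos], -(d$distance[okPos] + 1L))
})

test_that("shores flank islands without overlapping any island", {
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(3001, 6001), c(3500, 6800)),
    seqinfo = GenomeInfoDb::Seqinfo("chr1", 20000))
  sh <- cgiShores(cgis)
  expect_true(all(IRanges::width(sh) <= 2000))
  expect_equal(length(GenomicRanges::findOverlaps(sh, cgis)), 0L)
  # truncation at chromosome start
  cgis2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 900),
                                  seqinfo = GenomeInfoDb::Seqinfo("chr1",
                                                                  20000))
  sh2 <- cgiShores(cgis2)
  left <- sh2[sh2$side == "left"]
  expect_equal(GenomicRanges::start(left), 1L)
  expect_equal(IRanges::width(left), 500L)
})

test_that("internally called islands re-score as valid under the three
          criteria", {
  b <- smallBundle()
  g <- readGenome(b$paths$fasta)
  called <- callCGIs(g, chroms = "chr1")
  expect_gt(length(called), 0)
  rescored <- scoreCGIs(called, g)
  expect_true(all(rescored$gcFraction >= 0.5))
  expect_true(all(rescored$obsExpRatio > 0.6))
  expect_true(all(IRanges::width(rescored) > 200))
})

test_that("classification reproduces the generator's planted labels", {
  b <- smallBundle()
  g <- readGenome(b$paths$fasta)
  cgis <- loadCGIsBed(b$paths$cgi, g)
  genes <- readGenePred(b$paths$genes)
  got <- classifyCGIs(cgis, genes)
  truth <- b$truthIslands[order(b$truthIslands$chrom,
                                b$truthIslands$start), ]
  expect_equal(as.character(got$cgiClass), truth$class)
})
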