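test_that("methylation loading normalizes scale and averages strand
          duplicates", {
  g <- strGenome(chr1 = "AACGTTCGAA")
  sites <- enumerateCpGSites(g)  # C at 3 and 7
  bg <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t2\t4\t0.85\t30"), bg)
  got <- loadMethylation(bg, sites)
  expect_equal(got$pos, 3L)
  expect_equal(got$beta, 0.85)
  # 0-100 scale autodetect
  writeLines(c("chr1\t2\t4\t85\t30", "chr1\t6\t8\t40\t20"), bg)
  got2 <- loadMethylation(bg, sites)
  expect_equal(got2$beta, c(0.85, 0.40))
  # C-strand 0.8 and G-strand 0.6 average to 0.7 at the site
  writeLines(c("chr1\t2\t4\t0.8\t10", "chr1\t3\t5\t0.6\t10"), bg)
  got3 <- loadMethylation(bg, sites)
  expect_equal(got3$pos, 3L)
  expect_equal(got3$beta, 0.7)
  expect_equal(got3$coverage, 20)
  # orphan records are counted and warned
  writeLines(c("chr1\t2\t4\t0.8\t10", "chr1\t5\t7\t0.5\t10"), bg)
  expect_warning(got4 <- loadMethylation(bg, sites), "do not map")
  expect_equal(attr(got4, "orphans"), 1L)
  # beta outside range is an error
  writeLines(c("chr1\t2\t4\t120\t10", "chr1\t6\t8\t180\t10"), bg)
  expect_error(loadMethylation(bg, sites), "outside")
})

test_that("per-CGI means follow the displayed formula with strict A/B
          thresholds", {
  g <- strGenome(chr1 = paste0(strrep("CG", 10), strrep("A", 30),
                               strrep("CG", 10), strrep("A", 30),
                               strrep("CG", 10)))
  sites <- enumerateCpGSites(g)
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 51, 101), c(20, 70, 120)))
  betas <- rep(NA_real_, length(sites))
  pos <- GenomicRanges::start(sites)
  betas[pos <= 20] <- c(0.9, 0.8, 0.7, rep(NA, 7))
  betas[pos >= 51 & pos <= 70] <- c(0.1, 0.2, rep(NA, 8))
  betas[pos >= 101] <- 0.5
  sites$beta <- betas
  s <- meanMethylationPerCGI(sites, cgis, minCovered = 2)
  expect_equal(s$meanBeta, c(0.8, 0.15, 0.5), tolerance = 1e-12)
  expect_equal(s$group, c("A", "B", "intermediate"))
  expect_equal(s$nCovered, c(3L, 2L, 10L))
  # below the covered-CpG minimum: no group
  s2 <- meanMethylationPerCGI(sites, cgis, minCovered = 5)
  expect_true(is.na(s2$group[1]))
  # mean-beta brute force
  expect_equal(s$meanBeta[1], mean(c(0.9, 0.8, 0.7)), tolerance = 1e-12)
})

test_that("an island with zero covered CpGs yields a missing mean", {
  g <- strGenome(chr1 = strrep("CG", 20))
  sites <- enumerateCpGSites(g)
  sites$beta <- NA_real_
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 40))
  s <- meanMethylationPerCGI(sites, cgis)
  expect_true(is.na(s$meanBeta))
  expect_equal(s$nCovered, 0L)
})

test_that("methylation distance profile is flat for uniform beta and
          leaves empty distances missing", {
  b <- smallBundle()
  g <- readGenome(b$paths$fasta)
  sites <- enumerateCpGSites(g)
  cgis <- loadCGIsBed(b$paths$cgi, g)
  d <- signedDistanceToCGI(sites, cgis)
  sites$beta <- 0.5
  prof <- methylationDistanceProfile(sites, d, maxDist = 3000)
  expect_true(all(prof$meanBeta == 0.5))
  expect_false(any(prof$n == 0))
  # missing betas leave distances absent rather than zero
  sites$beta <- NA_real_
  prof2 <- methylationDistanceProfile(sites, d, maxDist = 3000)
  expect_equal(nrow(prof2), 0L)
})

test_that("the planted shore methylation ramp is recovered", {
  b <- smallBundle()
  g <- readGenome(b$paths$fasta)
  sites <- enumerateCpGSites(g)
  cgis <- loadCGIsBed(b$paths$cgi, g)
  d <- signedDistanceToCGI(sites, cgis)
  meth <- loadMethylation(b$paths$methylation, sites)
  sites <- annotateSiteBetas(sites, meth)
  prof <- methylationDistanceProfile(sites, d, maxDist = 4000)
  cfg <- b$config
  nearBorder <- prof$meanBeta[abs(prof$distance) <= 150]
  farSide <- prof$meanBeta[abs(prof$distance) >= 2500]
  expect_lt(mean(nearBorder), cfg$shoreBetaStart + 0.1)
  expect_gt(mean(farSide), cfg$bgBeta - 0.1)
  # monotone rise across the ramp (block means)
  sm <- smoothProfile(prof[prof$distance >= 0, ], 100, value = "meanBeta")
  ramp <- sm$meanBeta[sm$distance < 2000]
  expect_true(all(diff(ramp) > -0.05))
})

test_that("intragenic-coding islands split into planted hyper/hypo groups
          with shorter hyper islands", {
  run <- demoPipeline()
  b <- demoBundle()
  groups <- run$groups
  truth <- b$truthIslands[b$truthIslands$class == "INTRAGENIC_CODING", ]
  # group calls match the planted groups island by island
  gotA <- paste(groups$groupA$chrom, groups$groupA$start)
  expect_setequal(gotA, paste(truth$chrom[truth$group == "A"],
                              truth$start[truth$group == "A"]))
  gotB <- paste(groups$groupB$chrom, groups$groupB$start)
  expect_setequal(gotB, paste(truth$chrom[truth$group == "B"],
                              truth$start[truth$group == "B"]))
  # hyper group is shorter (planted); rank-sum oracle at alpha 0.05
  w <- stats::wilcox.test(groups$lengthsA, groups$lengthsB)
  expect_lt(w$p.value, 0.05)
  expect_lt(median(groups$lengthsA), median(groups$lengthsB))
  # hyper group has the higher mutation rate
  sites <- run$sites
  pos <- GenomicRanges::start(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  inA <- rep(FALSE, length(sites)); inB <- rep(FALSE, length(sites))
  for (i in seq_len(nrow(truth))) {
    hit <- chrom == truth$chrom[i] & pos >= truth$start[i] &
      pos <= truth$end[i]
    if (truth$group[i] == "A") inA <- inA | hit else inB <- inB | hit
  }
  expect_gt(mean(sites$mutated[inA]), mean(sites$mutated[inB]))
})

test_that("splitting an empty class yields empty groups without error", {
  s <- data.frame(chrom = "chr1", start = 1, end = 10,
                  cgiClass = "INTERGENIC", length = 10, meanBeta = 0.5,
                  nCovered = 10L, group = "intermediate")
  got <- splitIntragenicCoding(s)
  expect_equal(nrow(got$groupA), 0L)
  expect_equal(nrow(got$groupB), 0L)
  expect_true(is.na(got$fractionA))
})
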