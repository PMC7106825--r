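test_that("mutation rate equals the displayed-formula brute force with
          Wilson intervals", {
  mutated <- c(rep(TRUE, 4), rep(FALSE, 6))
  rt <- as.data.frame(mutationRate(list(mutated = mutated),
                                   rep("s", 10)))
  expect_equal(rt$rate, 0.4)
  expect_equal(rt$numerator, 4L)
  # zero successes: rate 0, CI lower bound 0
  rt0 <- as.data.frame(mutationRate(list(mutated = rep(FALSE, 10)),
                                    rep("s", 10)))
  expect_equal(rt0$rate, 0)
  expect_equal(rt0$ciLow, 0)
  # 260/1000 against the closed-form Wilson oracle (prop.test without
  # continuity correction computes the same interval)
  rt2 <- as.data.frame(mutationRate(
    list(mutated = c(rep(TRUE, 260), rep(FALSE, 740))), rep("s", 1000)))
  expect_equal(rt2$rate, 0.26)
  oracle <- stats::prop.test(260, 1000, correct = FALSE)$conf.int
  expect_equal(rt2$ciLow, oracle[1], tolerance = 1e-12)
  expect_equal(rt2$ciHigh, oracle[2], tolerance = 1e-12)
  expect_equal(c(rt2$ciLow, rt2$ciHigh), c(0.2336, 0.2882),
               tolerance = 1e-3)
})

test_that("rates match a per-site brute-force loop on the bundle, exactly", {
  b <- smallBundle()
  truth <- b$truthSites
  rt <- as.data.frame(mutationRate(list(mutated = truth$mutated),
                                   truth$stratum))
  for (i in seq_len(nrow(rt))) {
    idx <- truth$stratum == rt$stratum[i]
    expect_identical(rt$numerator[i], sum(truth$mutated[idx]))
    expect_identical(rt$denominator[i], sum(idx))
    expect_equal(rt$rate[i], sum(truth$mutated[idx]) / sum(idx))
  }
  # strata partition the sites
  expect_equal(sum(rt$denominator), nrow(truth))
})

test_that("empty strata yield a denominator-0 row with missing rate", {
  rt <- as.data.frame(mutationRate(
    list(mutated = c(TRUE, FALSE)),
    factor(c("a", "a"), levels = c("a", "b"))))
  expect_equal(rt$denominator, c(2L, 0L))
  expect_true(is.na(rt$rate[2]))
})

test_that("Af-weighted rate follows its formula and never exceeds the
          plain rate", {
  s <- list(mutated = c(TRUE, TRUE, rep(FALSE, 8)),
            af = c(0.1, 0.2, rep(NA, 8)))
  rt <- as.data.frame(afWeightedRate(s, rep("s", 10)))
  expect_equal(rt$rate, 0.03)
  # no mutated sites -> 0; all mutated at af 1 -> upper bound 1
  expect_equal(as.data.frame(afWeightedRate(
    list(mutated = rep(FALSE, 5), af = rep(NA_real_, 5)),
    rep("s", 5)))$rate, 0)
  expect_equal(as.data.frame(afWeightedRate(
    list(mutated = rep(TRUE, 10), af = rep(1, 10)), rep("s", 10)))$rate, 1)
  # dominance property on random strata
  set.seed(5)
  mut <- runif(2000) < 0.3
  af <- ifelse(mut, runif(2000), NA)
  strat <- sample(letters[1:4], 2000, TRUE)
  plain <- as.data.frame(mutationRate(list(mutated = mut), strat))
  wtd <- as.data.frame(afWeightedRate(list(mutated = mut, af = af), strat))
  expect_true(all(wtd$rate <= plain$rate + 1e-12))
  # missing af on a mutated site is excluded and counted
  w2 <- afWeightedRate(list(mutated = c(TRUE, TRUE),
                            af = c(0.5, NA)), rep("s", 2))
  expect_equal(attr(w2, "missingAF"), 1L)
})

test_that("Af-binned fractions sum to 1 within every stratum", {
  b <- smallBundle()
  truth <- b$truthSites
  rt <- as.data.frame(afBinnedRates(
    list(mutated = truth$mutated, af = truth$af), truth$stratum))
  parts <- do.call(rbind, strsplit(rt$stratum, "|", fixed = TRUE))
  for (s in unique(parts[, 1])) {
    expect_equal(sum(rt$rate[parts[, 1] == s]), 1, tolerance = 1e-12)
  }
  # af exactly 0.06 lands in [0.06, 0.12)
  one <- as.data.frame(afBinnedRates(
    list(mutated = TRUE, af = 0.06), "s"))
  expect_equal(one$numerator[one$stratum == "s|0.06<=Af<0.12"], 1L)
})

test_that("distance profile recovers the planted shore step and conserves
          global tallies", {
  b <- smallBundle()
  g <- readGenome(b$paths$fasta)
  sites <- enumerateCpGSites(g)
  cgis <- loadCGIsBed(b$paths$cgi, g)
  d <- signedDistanceToCGI(sites, cgis)
  ev <- attachToCpG(loadCTVariants(b$paths$wgsVcf, "wgs"), g)
  sites <- annotateSiteMutations(sites, mergeCatalogues(list(ev),
                                                        names(g)))
  prof <- distanceProfile(sites, d, maxDist = 5000)
  # conservation: per-distance tallies + in-CGI + beyond-window = total
  inWindow <- sum(prof$total)
  nIn <- sum(d$inCGI)
  nBeyond <- sum(!d$inCGI & abs(d$distance) > 5000)
  expect_equal(inWindow + nIn + nBeyond, length(sites))
  expect_equal(sum(prof$mutated),
               sum(sites$mutated[!d$inCGI & abs(d$distance) <= 5000]))
  # step recovery: shore band vs plateau within 3 binomial SE of the
  # pooled generator truth
  truth <- b$truthSites
  shoreT <- truth$trueP[startsWith(truth$stratum, "SHORE_")]
  bgT <- truth$trueP[truth$stratum == "BACKGROUND"]
  shore <- abs(prof$distance) <= 1950
  est1 <- sum(prof$mutated[shore]) / sum(prof$total[shore])
  est2 <- sum(prof$mutated[!shore]) / sum(prof$total[!shore])
  se1 <- sqrt(mean(shoreT) * (1 - mean(shoreT)) / sum(prof$total[shore]))
  se2 <- sqrt(mean(bgT) * (1 - mean(bgT)) / sum(prof$total[!shore]))
  expect_lt(abs(est1 - mean(shoreT)), 3 * se1 + 0.01)
  expect_lt(abs(est2 - mean(bgT)), 3 * se2 + 0.01)
  # a distance with zero sites is absent, not zero
  expect_false(any(prof$total == 0))
})

test_that("smoothing averages non-overlapping blocks with the class-
          specific windows", {
  prof <- data.frame(distance = c(-40:-1, 0:39), rate = 0.5)
  sm <- smoothProfile(prof, 20)
  expect_equal(nrow(sm), 4L)
  expect_true(all(sm$rate == 0.5))
  expect_equal(sm$n, rep(20L, 4))
  # linear ramp: block means equal the ramp at block midpoints
  prof2 <- data.frame(distance = 0:99, rate = (0:99) / 100)
  sm2 <- smoothProfile(prof2, 20)
  expect_equal(sm2$rate, sm2$distance / 100)
  # trailing partial block averaged over what exists
  prof3 <- data.frame(distance = 0:29, rate = 1)
  sm3 <- smoothProfile(prof3, 20)
  expect_equal(sm3$n, c(20L, 10L))
  # window selection by class
  expect_equal(smoothingWindow("TSS_NONCODING"), 100L)
  expect_equal(smoothingWindow("INTRAGENIC_NONCODING"), 100L)
  expect_equal(smoothingWindow("TSS_CODING"), 20L)
  expect_equal(smoothingWindow("INTERGENIC"), 20L)
})

test_that("region split separates coding-exon from noncoding CpGs", {
  g <- strGenome(chr1 = strrep("ACGT", 50))
  gene <- GeneModel("g", "chr1", "+", 11L, 100L, 21L, 80L,
                    exonStarts = c(11L, 61L), exonEnds = c(40L, 100L))
  sites <- enumerateCpGSites(g)
  sites$mutated <- FALSE
  sites$inCGI <- FALSE
  sites$cgiClass <- NA_character_
  rt <- as.data.frame(regionSplitRates(sites, list(gene)))
  # CDS exon intervals: [21,40] and [61,80]
  nCoding <- sum(GenomicRanges::start(sites) %in% c(21:40, 61:80))
  expect_equal(rt$denominator[rt$stratum == "non-CGI|coding-exon"],
               nCoding)
  expect_equal(sum(rt$denominator), length(sites))
})

test_that("region-split rates recover distinct planted coding and
          noncoding rates", {
  run <- demoPipeline()
  rt <- as.data.frame(run$regionSplit)
  # background CpGs mutate at the same planted rate in and out of exons
  nc <- rt[rt$stratum %in% c("non-CGI|coding-exon", "non-CGI|noncoding"), ]
  b <- demoBundle()
  for (i in seq_len(nrow(nc))) {
    se <- sqrt(0.25 / nc$denominator[i])
    # non-CGI pool mixes shore and background truth rates; both strata
    # must sit inside that envelope
    expect_gt(nc$rate[i], min(b$config$shoreRate) - 3 * se)
    expect_lt(nc$rate[i], b$config$bgRate + 3 * se)
  }
})
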