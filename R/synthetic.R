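# Closed-loop synthetic bundle generator: multi-chromosome genome with
# embedded CpG islands of each functional class, gene models realizing the
# classes (including MISC), per-stratum Bernoulli mutation draws, an
# allele-frequency mixture, a methylation track with island / shore-ramp /
# background regimes, and a consequence-primed coding catalogue. Every
# record is reproducible from (config, seed).

#' Synthetic bundle configuration
#'
#' Defaults produce the demonstration bundle: 2 chromosomes x 500 kb with
#' ~32 islands each, true per-class C:G>T:A site-mutation probabilities
#' mirroring the magnitudes seen in human population catalogues
#' (TSS-coding 0.036, TSS-noncoding 0.041, intergenic 0.062,
#' intragenic-noncoding 0.060, non-CGI background 0.276; intragenic-coding
#' realized as a hyper-methylated short group A at 0.2 and a
#' hypo-methylated long group B at 0.0533, averaging 0.112 at the
#' default 40\% group-A share), a 0.15 shore band rate within 2 kb of
#' island borders, and a 0.02 non-CpG control rate.
#'
#' @param seed integer RNG seed
#' @param nChroms,chromLength genome shape
#' @param islandsPerChrom named integer vector of island counts per class
#' @param islandLengthRange,groupALengthRange,groupBLengthRange island
#'   length ranges (bp); group ranges apply to intragenic-coding islands
#' @param groupAFraction share of intragenic-coding islands that are
#'   hyper-methylated (group A)
#' @param islandCpGStep probability of emitting a CG dinucleotide per
#'   island-construction step; \code{islandGC} the GC of the remaining bases
#' @param bgGC background GC fraction
#' @param classRates true mutation probability per island class (the
#'   intragenic-coding entry is replaced by \code{groupRates})
#' @param groupRates true rates for intragenic-coding group A / B islands
#' @param shoreRate true rate for shore-band CpGs (within
#'   \code{shoreWidth} of a border): a named per-class vector keyed by the
#'   class of the nearest island (default mirrors the observed ordering,
#'   intragenic-coding shores highest) or a single number for a uniform
#'   band
#' @param bgRate,nonCpGRate true rates for background CpGs and for the
#'   non-CpG C:G control
#' @param shoreWidth shore band width (bp)
#' @param afShape Beta parameters of the rare component of the allele
#'   frequency mixture; \code{afUniformWeight} the weight of the uniform
#'   tail; \code{an} total allele number of the WGS-like catalogue
#' @param cgiBeta noise-free island-interior beta per class (A/B for the
#'   two intragenic-coding groups)
#' @param tssHyperFraction fraction of TSS-island CpGs drawn from the
#'   hyper-methylated regime (\code{hyperBeta}) so the coding-consequence
#'   analysis sees hyper-methylated TSS-island sites
#' @param shoreBetaStart beta at the island border, ramping linearly to
#'   \code{bgBeta} at \code{shoreWidth}; \code{betaNoise} the truncation-
#'   clamped Gaussian noise SD
#' @param coverageMean mean bisulfite coverage (Poisson + 1);
#'   \code{missingBetaProb} the per-site dropout probability
#' @param obsProb probability that a primed site of each consequence class
#'   is observed in the exome-like catalogue; \code{acGeomProb} the
#'   geometric parameter of its allele-count distribution (larger =>
#'   more singletons); \code{exacAN} its total allele number
#' @return a list of class "syntheticConfig"
#' @export
syntheticConfig <- function(
    seed = 7L, nChroms = 2L, chromLength = 500000L,
    islandsPerChrom = c(TSS_CODING = 6L, TSS_NONCODING = 4L,
                        INTRAGENIC_CODING = 10L, INTRAGENIC_NONCODING = 4L,
                        INTERGENIC = 6L, MISC = 2L),
    islandLengthRange = c(400L, 900L),
    groupALengthRange = c(250L, 450L),
    groupBLengthRange = c(700L, 1100L),
    groupAFraction = 0.4,
    islandCpGStep = 0.18, islandGC = 0.55, bgGC = 0.38,
    classRates = c(TSS_CODING = 0.036, TSS_NONCODING = 0.041,
                   INTRAGENIC_NONCODING = 0.060, INTERGENIC = 0.062,
                   MISC = 0.05),
    groupRates = c(A = 0.2, B = 0.0533),
    shoreRate = c(TSS_CODING = 0.10, TSS_NONCODING = 0.10,
                  INTRAGENIC_CODING = 0.22, INTRAGENIC_NONCODING = 0.16,
                  INTERGENIC = 0.16, MISC = 0.15),
    bgRate = 0.276, nonCpGRate = 0.02,
    shoreWidth = 2000L,
    afShape = c(0.3, 8), afUniformWeight = 0.3, an = 5008L,
    cgiBeta = c(TSS_CODING = 0.018, TSS_NONCODING = 0.039,
                INTERGENIC = 0.139, INTRAGENIC_NONCODING = 0.154,
                MISC = 0.10, A = 0.80, B = 0.10),
    tssHyperFraction = 0.15, hyperBeta = 0.78,
    shoreBetaStart = 0.30, bgBeta = 0.80, betaNoise = 0.05,
    coverageMean = 25, missingBetaProb = 0.1,
    obsProb = c(SILENT = 0.8, MISSENSE = 0.7, NONSENSE = 0.5),
    acGeomProb = c(SILENT = 0.15, MISSENSE = 0.3, NONSENSE = 0.55),
    exacAN = 121412L) {
  cfg <- as.list(environment())
  probs <- c(cfg$classRates, cfg$groupRates, cfg$shoreRate, cfg$bgRate,
             cfg$nonCpGRate, cfg$obsProb, cfg$acGeomProb,
             cfg$groupAFraction, cfg$tssHyperFraction,
             cfg$missingBetaProb, cfg$afUniformWeight)
  if (any(probs < 0 | probs > 1)) .stopf("probabilities must lie in [0,1]")
  maxIsland <- max(cfg$islandLengthRange, cfg$groupBLengthRange)
  nSlots <- sum(cfg$islandsPerChrom)
  if ((maxIsland + 12000) * nSlots > cfg$chromLength)
    .stopf("infeasible config: %d islands of up to %d bp do not fit in %d bp",
           nSlots, maxIsland, cfg$chromLength)
  class(cfg) <- "syntheticConfig"
  cfg
}

.randBases <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# CpG-dense island sequence passing the Gardiner-Garden criteria
.islandSeq <- function(len, q, gc) {
  for (try in 1:25) {
    ntok <- ceiling(len / (1 + q)) + 25L
    isCG <- stats::runif(ntok) < q
    toks <- character(ntok)
    toks[isCG] <- "CG"
    toks[!isCG] <- .randBases(sum(!isCG), gc)
    chars <- strsplit(paste(toks, collapse = ""), "")[[1]][1:len]
    sc <- .cgScore(chars, 1L, len)
    if (sc$gc >= 0.5 && sc$oe > 0.6) return(chars)
  }
  .stopf("could not realize island composition (len %d)", len)
}

# CDS end at or just below `target` making total CDS length divisible by 3
.fitCdsEnd <- function(exons, cdsStart, target) {
  for (e in target:(target - 8L)) {
    ex <- IRanges::restrict(exons, start = cdsStart, end = e)
    if (sum(IRanges::width(ex)) %% 3L == 0L && sum(IRanges::width(ex)) > 0L)
      return(e)
  }
  .stopf("could not fit CDS end")
}

# gene models realizing one island's intended class; returns list of
# GeneModel (possibly empty)
.slotGenes <- function(class, chrom, is, ie, strand, counter) {
  nm <- function(tag) sprintf("%s_%s_%d", tag, chrom, counter)
  if (class == "INTERGENIC") return(list())
  if (class %in% c("TSS_CODING", "MISC")) {
    gs <- list()
    if (strand == "+") {
      tss <- is + 60L
      exS <- c(tss, tss + 1400L, tss + 3000L)
      exE <- c(tss + 999L, tss + 2599L, tss + 3599L)
      exons <- IRanges::IRanges(exS, exE)
      cdsStart <- tss + 11L
      cdsEnd <- .fitCdsEnd(exons, cdsStart, tss + 3500L)
      gs <- c(gs, list(GeneModel(nm("cod"), chrom, "+", tss, tss + 3599L,
                                 cdsStart, cdsEnd, exS, exE, TRUE)))
    } else {
      tss <- ie - 60L
      exS <- c(tss - 3599L, tss - 2599L, tss - 999L)
      exE <- c(tss - 3000L, tss - 1400L, tss)
      exons <- IRanges::IRanges(exS, exE)
      cdsEnd <- tss - 11L
      # mirror: trim the left (3') end for frame
      for (e in (tss - 3500L):(tss - 3492L)) {
        ex <- IRanges::restrict(exons, start = e, end = cdsEnd)
        if (sum(IRanges::width(ex)) %% 3L == 0L) { cdsStart <- e; break }
      }
      gs <- c(gs, list(GeneModel(nm("cod"), chrom, "-", tss - 3599L, tss,
                                 cdsStart, cdsEnd, exS, exE, TRUE)))
    }
    if (class == "MISC") {
      gs <- c(gs, list(GeneModel(nm("nc"), chrom, "+", is - 1500L,
                                 ie + 1500L, NA_integer_, NA_integer_,
                                 is - 1500L, ie + 1500L, FALSE)))
    }
    return(gs)
  }
  if (class == "TSS_NONCODING") {
    if (strand == "+") {
      tss <- is + 50L
      return(list(GeneModel(nm("nc"), chrom, "+", tss, tss + 1999L,
                            NA_integer_, NA_integer_, tss, tss + 1999L,
                            FALSE)))
    } else {
      tss <- ie - 50L
      return(list(GeneModel(nm("nc"), chrom, "-", tss - 1999L, tss,
                            NA_integer_, NA_integer_, tss - 1999L, tss,
                            FALSE)))
    }
  }
  if (class == "INTRAGENIC_CODING") {
    txS <- is - 2500L; txE <- ie + 2500L
    exS <- c(txS, is - 600L, txE - 300L)
    exE <- c(txS + 300L, ie + 600L, txE)
    exons <- IRanges::IRanges(exS, exE)
    cdsStart <- txS + 60L
    cdsEnd <- .fitCdsEnd(exons, cdsStart, txE - 60L)
    return(list(GeneModel(nm("cod"), chrom, strand, txS, txE, cdsStart,
                          cdsEnd, exS, exE, TRUE)))
  }
  if (class == "INTRAGENIC_NONCODING") {
    txS <- is - 2000L; txE <- ie + 2000L
    return(list(GeneModel(nm("nc"), chrom, strand, txS, txE, NA_integer_,
                          NA_integer_, txS, txE, FALSE)))
  }
  .stopf("unknown island class %s", class)
}

# allele frequency mixture: rare Beta mass + uniform tail, quantized to
# allele counts over `an` chromosomes
.drawAF <- function(n, cfg) {
  if (n == 0L) return(list(af = numeric(0), ac = integer(0)))
  tail <- stats::runif(n) < cfg$afUniformWeight
  af <- ifelse(tail, stats::runif(n),
               stats::rbeta(n, cfg$afShape[1], cfg$afShape[2]))
  ac <- pmax(1L, as.integer(round(af * cfg$an)))
  list(af = ac / cfg$an, ac = ac)
}

.vcfHeader <- function(chromLens, an = TRUE) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chromLens), chromLens),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total alleles\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

.vcfRecords <- function(chrom, pos, ref, alt, af, ac, an) {
  sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s;AC=%d;AN=%d",
          chrom, pos, ref, alt, sprintf("%.6g", af), ac, an)
}

# full-transcript consequence: substitute, translate, diff (generator
# ground truth; independent of the codon-table fast path)
.fullConsequence <- function(cdsChars, idx, altT) {
  aa0 <- paste(.GENETIC_CODE[
    apply(matrix(cdsChars, nrow = 3L), 2, paste, collapse = "")],
    collapse = "")
  mut <- cdsChars
  mut[idx] <- altT
  aa1 <- paste(.GENETIC_CODE[
    apply(matrix(mut, nrow = 3L), 2, paste, collapse = "")],
    collapse = "")
  if (aa0 == aa1) return("SILENT")
  ci <- (idx - 1L) %/% 3L + 1L
  if (substr(aa1, ci, ci) == "*") return("NONSENSE")
  "MISSENSE"
}

#' Generate a synthetic analysis bundle
#'
#' Writes genome.fa, genes.genePred, cgi.bed (with class labels),
#' methylation.bedgraph, wgs.vcf (population catalogue with AF/AC/AN),
#' exac.vcf (exome-like catalogue for the consequence analysis),
#' truth_sites.tsv, truth_islands.tsv, truth_primed.tsv and config.json
#' into \code{dir}. Identical (config, seed) yields a byte-identical
#' bundle.
#'
#' @param config a \code{syntheticConfig}
#' @param dir output directory (created if needed)
#' @return invisibly, a list with the in-memory truth tables and file paths
#' @export
generateBundle <- function(config = syntheticConfig(), dir) {
  if (!inherits(config, "syntheticConfig")) .stopf("need a syntheticConfig")
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  chroms <- paste0("chr", seq_len(cfg$nChroms))
  L <- cfg$chromLength
  classPlan <- rep(names(cfg$islandsPerChrom), cfg$islandsPerChrom)
  nSlots <- length(classPlan)
  spacing <- L %/% nSlots

  genomeChars <- list()
  islands <- list()      # per-island truth rows
  genes <- list()
  counter <- 0L
  nAtc <- 0L  # running count of intragenic-coding islands for group split

  for (ch in chroms) {
    chars <- .randBases(L, cfg$bgGC)
    plan <- classPlan
    for (k in seq_len(nSlots)) {
      cls <- plan[k]
      centre <- (k - 1L) * spacing + spacing %/% 2L
      group <- NA_character_
      if (cls == "INTRAGENIC_CODING") {
        nAtc <- nAtc + 1L
        group <- if (stats::runif(1) < cfg$groupAFraction) "A" else "B"
        rng <- if (group == "A") cfg$groupALengthRange else
          cfg$groupBLengthRange
      } else rng <- cfg$islandLengthRange
      len <- as.integer(round(stats::runif(1, rng[1], rng[2])))
      is <- centre - len %/% 2L
      ie <- is + len - 1L
      chars[is:ie] <- .islandSeq(len, cfg$islandCpGStep, cfg$islandGC)
      counter <- counter + 1L
      strand <- if (counter %% 2L == 0L) "-" else "+"
      genes <- c(genes, .slotGenes(cls, ch, is, ie, strand, counter))
      islands[[counter]] <- data.frame(chrom = ch, start = is, end = ie,
                                       class = cls, group = group,
                                       stringsAsFactors = FALSE)
    }
    genomeChars[[ch]] <- chars
  }
  islandDf <- do.call(rbind, islands)

  # --- per-site truth, mutations, methylation -------------------------
  siteRows <- list()
  vcfRows <- list()
  methRows <- list()
  for (ch in chroms) {
    chars <- genomeChars[[ch]]
    isl <- islandDf[islandDf$chrom == ch, , drop = FALSE]
    isl <- isl[order(isl$start), , drop = FALSE]
    cpgPos <- which(chars[-L] == "C" & chars[-1L] == "G")

    # island membership and signed-band geometry
    k <- findInterval(cpgPos, isl$start)
    inIsl <- k >= 1L & cpgPos <= isl$end[pmax(k, 1L)]
    # distance magnitude to nearest border for outside sites
    dLeft <- ifelse(k >= 1L, cpgPos - isl$end[pmax(k, 1L)] - 1L, NA_integer_)
    dRight <- ifelse(k < nrow(isl), isl$start[pmin(k + 1L, nrow(isl))] -
                       cpgPos, NA_integer_)
    dl <- ifelse(is.na(dLeft), .Machine$integer.max, dLeft)
    dr <- ifelse(is.na(dRight), .Machine$integer.max, dRight)
    mag <- pmin(dl, dr)
    # nearest planted island (tie toward the lower-coordinate one)
    nearestIdx <- ifelse(dl <= dr, pmax(k, 1L), pmin(k + 1L, nrow(isl)))
    shoreRates <- if (length(cfg$shoreRate) == 1L)
      stats::setNames(rep(unname(cfg$shoreRate), length(CGI_CLASSES)),
                      CGI_CLASSES) else cfg$shoreRate
    stratum <- ifelse(inIsl,
                      ifelse(isl$class[pmax(k, 1L)] == "INTRAGENIC_CODING",
                             paste0("INTRAGENIC_CODING_",
                                    isl$group[pmax(k, 1L)]),
                             isl$class[pmax(k, 1L)]),
                      ifelse(mag < cfg$shoreWidth,
                             paste0("SHORE_", isl$class[nearestIdx]),
                             "BACKGROUND"))
    rates <- c(cfg$classRates,
               INTRAGENIC_CODING_A = unname(cfg$groupRates["A"]),
               INTRAGENIC_CODING_B = unname(cfg$groupRates["B"]),
               stats::setNames(unname(shoreRates),
                               paste0("SHORE_", names(shoreRates))),
               BACKGROUND = cfg$bgRate)
    p <- rates[stratum]
    mutated <- stats::runif(length(cpgPos)) < p
    afd <- .drawAF(sum(mutated), cfg)

    # methylation regime
    betaClass <- c(cfg$cgiBeta,
                   INTRAGENIC_CODING_A = unname(cfg$cgiBeta["A"]),
                   INTRAGENIC_CODING_B = unname(cfg$cgiBeta["B"]))
    regime <- ifelse(inIsl, betaClass[stratum],
                     ifelse(mag < cfg$shoreWidth,
                            cfg$shoreBetaStart +
                              (cfg$bgBeta - cfg$shoreBetaStart) *
                              pmin(mag + 1L, cfg$shoreWidth) / cfg$shoreWidth,
                            cfg$bgBeta))
    # TSS islands: a fraction of interior CpGs sit in the hyper regime
    tssIsl <- inIsl & isl$class[pmax(k, 1L)] %in% c("TSS_CODING",
                                                    "TSS_NONCODING")
    hyperDraw <- stats::runif(length(cpgPos)) < cfg$tssHyperFraction
    regime[tssIsl & hyperDraw] <- cfg$hyperBeta
    betaObs <- pmin(1, pmax(0, regime + stats::rnorm(length(regime), 0,
                                                     cfg$betaNoise)))
    covered <- stats::runif(length(regime)) >= cfg$missingBetaProb
    coverage <- stats::rpois(length(regime), cfg$coverageMean) + 1L

    # VCF rows: mutated CpGs report C>T at the C (or G>A at the G) with
    # equal probability
    mutIdx <- which(mutated)
    gaSide <- stats::runif(length(mutIdx)) < 0.5
    vp <- ifelse(gaSide, cpgPos[mutIdx] + 1L, cpgPos[mutIdx])
    vref <- ifelse(gaSide, "G", "C")
    valt <- ifelse(gaSide, "A", "T")

    # non-CpG C:G control events
    isC <- chars == "C"; isG <- chars == "G"
    nonCpG_C <- setdiff(which(isC), cpgPos)
    nonCpG_C <- nonCpG_C[nonCpG_C > 1L & nonCpG_C < L]
    nonCpG_G <- setdiff(which(isG), cpgPos + 1L)
    nonCpG_G <- nonCpG_G[nonCpG_G > 1L & nonCpG_G < L]
    mutC <- nonCpG_C[stats::runif(length(nonCpG_C)) < cfg$nonCpGRate]
    mutG <- nonCpG_G[stats::runif(length(nonCpG_G)) < cfg$nonCpGRate]
    afC <- .drawAF(length(mutC), cfg)
    afG <- .drawAF(length(mutG), cfg)

    allPos <- c(vp, mutC, mutG)
    allRef <- c(vref, rep("C", length(mutC)), rep("G", length(mutG)))
    allAlt <- c(valt, rep("T", length(mutC)), rep("A", length(mutG)))
    allAF <- c(afd$af, afC$af, afG$af)
    allAC <- c(afd$ac, afC$ac, afG$ac)
    o <- order(allPos)
    if (length(allPos))
      vcfRows[[ch]] <- .vcfRecords(ch, allPos[o], allRef[o], allAlt[o],
                                   allAF[o], allAC[o], cfg$an)

    methRows[[ch]] <- sprintf("%s\t%d\t%d\t%s\t%d", ch,
                              cpgPos[covered] - 1L, cpgPos[covered] + 1L,
                              sprintf("%.4f", betaObs[covered]),
                              coverage[covered])

    siteRows[[ch]] <- data.frame(
      chrom = ch, pos = cpgPos, stratum = unname(stratum),
      trueP = unname(p), mutated = mutated,
      af = { a <- rep(NA_real_, length(cpgPos)); a[mutIdx] <- afd$af; a },
      ac = { a <- rep(NA_integer_, length(cpgPos)); a[mutIdx] <- afd$ac; a },
      regimeBeta = unname(regime), beta = ifelse(covered, betaObs, NA_real_),
      distanceMag = ifelse(inIsl, NA_integer_, mag),
      stringsAsFactors = FALSE)
  }
  truthSites <- do.call(rbind, siteRows)
  rownames(truthSites) <- NULL

  # --- consequence-primed truth and exome-like catalogue --------------
  genomeSet <- Biostrings::DNAStringSet(vapply(genomeChars, paste,
                                               character(1), collapse = ""))
  names(genomeSet) <- chroms
  primedRows <- list()
  for (g in genes) {
    if (!g@isCoding) next
    cds <- cdsGenomicPositions(g)
    stopifnot(length(cds) %% 3L == 0L)
    chars <- genomeChars[[g@chrom]]
    txChars <- chars[cds]
    if (g@strand == "-") txChars <- .complement(txChars)
    gpos <- sort(cds)
    base <- chars[gpos]
    nxt <- chars[pmin(gpos + 1L, length(chars))]
    prv <- chars[pmax(gpos - 1L, 1L)]
    isCpG_C <- base == "C" & nxt == "G" & gpos < length(chars)
    isCpG_G <- base == "G" & prv == "C" & gpos > 1L
    sel <- which(isCpG_C | isCpG_G)
    if (!length(sel)) next
    idxTx <- match(gpos[sel], cds)
    refT <- txChars[idxTx]
    altT <- ifelse(refT == "C", "T", "A")
    cons <- vapply(seq_along(sel), function(j)
      .fullConsequence(txChars, idxTx[j], altT[j]), character(1))
    primedRows[[length(primedRows) + 1L]] <- data.frame(
      chrom = g@chrom, pos = gpos[sel],
      cpgPos = ifelse(isCpG_C[sel], gpos[sel], gpos[sel] - 1L),
      ref = base[sel], alt = ifelse(base[sel] == "C", "T", "A"),
      gene = g@name, consequence = cons, stringsAsFactors = FALSE)
  }
  truthPrimed <- do.call(rbind, primedRows)
  if (is.null(truthPrimed))
    truthPrimed <- data.frame(chrom = character(0), pos = integer(0),
                              cpgPos = integer(0), ref = character(0),
                              alt = character(0), gene = character(0),
                              consequence = character(0))
  # region class from planted islands
  if (nrow(truthPrimed)) {
    regc <- rep("NON_CGI", nrow(truthPrimed))
    for (i in seq_len(nrow(islandDf))) {
      hit <- truthPrimed$chrom == islandDf$chrom[i] &
        truthPrimed$cpgPos >= islandDf$start[i] &
        truthPrimed$cpgPos <= islandDf$end[i]
      regc[hit] <- switch(islandDf$class[i],
                          TSS_CODING = , TSS_NONCODING = "TSS_CGI",
                          INTRAGENIC_CODING = ,
                          INTRAGENIC_NONCODING = "INTRAGENIC_CGI",
                          "OTHER_CGI")
    }
    truthPrimed$regionClass <- regc
    truthPrimed$trueObsProb <- unname(cfg$obsProb[truthPrimed$consequence])
    truthPrimed$observed <- stats::runif(nrow(truthPrimed)) <
      truthPrimed$trueObsProb
    truthPrimed$ac <- ifelse(
      truthPrimed$observed,
      stats::rgeom(nrow(truthPrimed),
                   cfg$acGeomProb[truthPrimed$consequence]) + 1L,
      NA_integer_)
    truthPrimed <- truthPrimed[order(truthPrimed$chrom, truthPrimed$pos), ,
                               drop = FALSE]
    rownames(truthPrimed) <- NULL
  } else {
    truthPrimed$regionClass <- character(0)
    truthPrimed$trueObsProb <- numeric(0)
    truthPrimed$observed <- logical(0)
    truthPrimed$ac <- integer(0)
  }

  # --- write bundle ---------------------------------------------------
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.genePred"),
    cgi = file.path(dir, "cgi.bed"),
    methylation = file.path(dir, "methylation.bedgraph"),
    wgsVcf = file.path(dir, "wgs.vcf"),
    exacVcf = file.path(dir, "exac.vcf"),
    truthSites = file.path(dir, "truth_sites.tsv"),
    truthIslands = file.path(dir, "truth_islands.tsv"),
    truthPrimed = file.path(dir, "truth_primed.tsv"),
    config = file.path(dir, "config.json"))

  fa <- unlist(lapply(chroms, function(ch) {
    s <- paste(genomeChars[[ch]], collapse = "")
    c(paste0(">", ch), substring(s, seq(1, nchar(s), 70),
                                 pmin(seq(1, nchar(s), 70) + 69, nchar(s))))
  }))
  writeLines(fa, paths$fasta)
  writeGenePred(genes, paths$genes)
  writeLines(sprintf("%s\t%d\t%d\t%s", islandDf$chrom, islandDf$start - 1L,
                     islandDf$end, islandDf$class), paths$cgi)
  writeLines(unlist(methRows), paths$methylation)
  chromLens <- stats::setNames(rep(L, length(chroms)), chroms)
  writeLines(c(.vcfHeader(chromLens), unlist(vcfRows)), paths$wgsVcf)
  exRows <- if (nrow(truthPrimed)) {
    obs <- truthPrimed[truthPrimed$observed, , drop = FALSE]
    .vcfRecords(obs$chrom, obs$pos, obs$ref, obs$alt,
                obs$ac / cfg$exacAN, obs$ac, cfg$exacAN)
  } else character(0)
  writeLines(c(.vcfHeader(chromLens), exRows), paths$exacVcf)
  .writeTSV(truthSites, paths$truthSites)
  .writeTSV(islandDf, paths$truthIslands)
  .writeTSV(truthPrimed, paths$truthPrimed)
  cfgOut <- cfg; class(cfgOut) <- NULL
  writeLines(jsonlite::toJSON(cfgOut, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths$config)

  invisible(list(paths = paths, truthSites = truthSites,
                 truthIslands = islandDf, truthPrimed = truthPrimed,
                 genes = genes, config = cfg))
}

#' Compare pipeline estimates with generator truth
#'
#' For each stratum the truth rate is the mean of the per-site true
#' probabilities and its standard error
#' \eqn{\sqrt{\sum p(1-p)}/n}; an estimate passes when within
#' \code{k} standard errors (plus an absolute floor for tiny strata).
#'
#' @param truthSites truth table from \code{generateBundle}
#' @param rateTable a \code{RateTable} whose strata match the truth
#'   \code{stratum} labels (or a data.frame with stratum/rate)
#' @param k tolerance in standard errors (default 3)
#' @return data.frame with truth, estimate, se, error and pass per stratum
#' @export
truthCompare <- function(truthSites, rateTable, k = 3) {
  est <- if (methods::is(rateTable, "RateTable")) as.data.frame(rateTable)
  else rateTable
  truth <- do.call(rbind, lapply(split(truthSites, truthSites$stratum),
                                 function(s) data.frame(
                                   stratum = s$stratum[1],
                                   truthRate = mean(s$trueP),
                                   se = sqrt(sum(s$trueP * (1 - s$trueP))) /
                                     nrow(s),
                                   n = nrow(s), stringsAsFactors = FALSE)))
  idx <- match(truth$stratum, est$stratum)
  if (anyNA(idx))
    .stopf("stratum '%s' missing from the estimates",
           truth$stratum[which(is.na(idx))[1]])
  truth$estimate <- est$rate[idx]
  truth$error <- abs(truth$estimate - truth$truthRate)
  truth$pass <- truth$error <= k * truth$se
  rownames(truth) <- NULL
  truth
}
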