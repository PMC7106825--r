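# End-to-end orchestration over a bundle directory: sites -> islands ->
# distances -> rates & methylation -> consequences -> signatures, with a
# deterministic TSV/JSON output tree and a checksummed manifest.

#' Run the full analysis pipeline on a bundle directory
#'
#' Expects the file layout written by \code{generateBundle} (any files may
#' be substituted by real data in the same formats). Stages depending on a
#' missing optional input (methylation, exome catalogue) are skipped with
#' an explicit SKIPPED marker; missing required inputs abort with the
#' stage name.
#'
#' @param bundleDir directory with genome.fa, genes.genePred, cgi.bed,
#'   wgs.vcf and optionally methylation.bedgraph, exac.vcf
#' @param outDir output directory
#' @param signatures 96 x K signature matrix (default: the packaged
#'   synthetic set)
#' @param afMax rare-variant threshold for the spectrum (default 0.01)
#' @param betaMin hyper-methylation threshold for the consequence analysis
#' @param maxDist profile half-width in bp
#' @param afExcludeChroms chromosomes excluded from allele-frequency
#'   analyses (the human Y by default; absent names are ignored)
#' @return invisibly, a list with every computed object
#' @export
runPipeline <- function(bundleDir, outDir,
                        signatures = syntheticSignatures(),
                        afMax = 0.01, betaMin = 0.67, maxDist = 5000L,
                        afExcludeChroms = c("chrY", "Y")) {
  need <- function(f, stage) {
    p <- file.path(bundleDir, f)
    if (!file.exists(p)) .stopf("stage '%s': required input %s missing",
                                stage, f)
    p
  }
  opt <- function(f) {
    p <- file.path(bundleDir, f)
    if (file.exists(p)) p else NULL
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  skipped <- character(0)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    .writeTSV(if (methods::is(df, "RateTable")) as.data.frame(df) else df, p)
    outputs <<- c(outputs, p)
  }

  # --- stage: sites ---------------------------------------------------
  genome <- readGenome(need("genome.fa", "sites"))
  sites <- enumerateCpGSites(genome)

  # --- stage: islands -------------------------------------------------
  genes <- readGenePred(need("genes.genePred", "islands"))
  cgis <- loadCGIsBed(need("cgi.bed", "islands"), genome)
  cgis <- scoreCGIs(cgis, genome)
  cgis <- classifyCGIs(cgis, genes)
  shores <- cgiShores(cgis)

  # --- stage: distances -----------------------------------------------
  dist <- signedDistanceToCGI(sites, cgis)
  S4Vectors::mcols(sites) <- cbind(S4Vectors::mcols(sites),
                                   S4Vectors::DataFrame(dist))
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::resize(sites, 1L, fix = "start"), cgis, select = "first")
  sites$cgiClass <- as.character(cgis$cgiClass)[ov]

  # --- stage: variants ------------------------------------------------
  events <- loadCTVariants(need("wgs.vcf", "variants"), source = "wgs",
                           allClasses = TRUE)
  ct <- events[(events$ref == "C" & events$alt == "T") |
                 (events$ref == "G" & events$alt == "A")]
  ct <- attachToCpG(ct, genome)
  siteMuts <- mergeCatalogues(list(ct), refNames = names(genome))
  sites <- annotateSiteMutations(sites, siteMuts)

  # --- stage: rates (Y excluded from AF-dependent tables) -------------
  afOK <- !as.character(GenomicRanges::seqnames(sites)) %in% afExcludeChroms
  s <- sites[afOK]
  stratClass <- ifelse(s$inCGI, as.character(s$cgiClass), "nonCGI")
  classRates <- mutationRate(s, stratClass)
  cgiVsNon <- mutationRate(s, ifelse(s$inCGI, "CGI", "nonCGI"))
  afw <- afWeightedRate(s, stratClass)
  afb <- afBinnedRates(s, stratClass)
  emit(classRates, "rates_by_class.tsv")
  emit(cgiVsNon, "rates_cgi_vs_noncgi.tsv")
  emit(afw, "rates_af_weighted.tsv")
  emit(afb, "rates_af_binned.tsv")
  regSplit <- regionSplitRates(s, genes)
  emit(regSplit, "rates_region_split.tsv")

  # --- stage: profiles ------------------------------------------------
  prof <- distanceProfile(s, maxDist = maxDist)
  profClass <- distanceProfile(s, maxDist = maxDist, byClass = TRUE)
  emit(prof, "profile_cpg.tsv")
  emit(profClass, "profile_cpg_by_class.tsv")
  smoothed <- do.call(rbind, lapply(split(profClass, profClass$class),
                                    function(pc) {
    sm <- smoothProfile(pc, smoothingWindow(pc$class[1]))
    sm$class <- pc$class[1]
    sm
  }))
  rownames(smoothed) <- NULL
  emit(smoothed, "profile_cpg_by_class_smoothed.tsv")

  # non-CpG control: C (and reverse-strand C = G) positions outside CpG
  nonCpG <- nonCpGControlSites(genome)
  nd <- signedDistanceToCGI(nonCpG, cgis)
  evKey <- paste(as.character(GenomicRanges::seqnames(events)),
                 GenomicRanges::start(events), events$ref, events$alt,
                 sep = "\r")
  ncKey <- paste(as.character(GenomicRanges::seqnames(nonCpG)),
                 GenomicRanges::start(nonCpG), nonCpG$ref,
                 ifelse(nonCpG$ref == "C", "T", "A"), sep = "\r")
  nonCpG$mutated <- ncKey %in% evKey
  ncOK <- !as.character(GenomicRanges::seqnames(nonCpG)) %in% afExcludeChroms
  profNC <- distanceProfile(nonCpG[ncOK], nd[ncOK, , drop = FALSE],
                            maxDist = maxDist)
  emit(profNC, "profile_noncpg_control.tsv")

  # --- stage: methylation (optional) ----------------------------------
  methPath <- opt("methylation.bedgraph")
  methSummaries <- NULL; groups <- NULL; methProf <- NULL
  if (is.null(methPath)) {
    skipped <- c(skipped, "methylation: SKIPPED (no methylation.bedgraph)")
  } else {
    meth <- loadMethylation(methPath, sites, format = "bedgraph")
    sites <- annotateSiteBetas(sites, meth)
    methSummaries <- meanMethylationPerCGI(sites, cgis)
    emit(methSummaries, "methylation_per_cgi.tsv")
    methProf <- methylationDistanceProfile(sites, dist, maxDist = maxDist,
                                           byClass = TRUE)
    emit(methProf, "methylation_profile_by_class.tsv")
    groups <- splitIntragenicCoding(methSummaries)
    gdf <- data.frame(group = c("A", "B"),
                      n = c(nrow(groups$groupA), nrow(groups$groupB)),
                      meanLength = c(mean(groups$lengthsA),
                                     mean(groups$lengthsB)),
                      fractionA = groups$fractionA)
    emit(gdf, "methylation_intragenic_groups.tsv")
  }

  # --- stage: consequences (needs methylation + exome catalogue) ------
  primed <- NULL; obsProp <- NULL; acTab <- NULL
  exacPath <- opt("exac.vcf")
  if (is.null(exacPath) || is.null(methPath)) {
    skipped <- c(skipped, "consequence: SKIPPED (needs exac.vcf and methylation)")
  } else {
    siteBetas <- data.frame(chrom = as.character(
      GenomicRanges::seqnames(sites)), pos = GenomicRanges::start(sites),
      beta = sites$beta, stringsAsFactors = FALSE)
    primed <- enumeratePrimedSites(genome, genes, cgis, siteBetas, betaMin)
    exac <- loadCTVariants(exacPath, source = "exac")
    primed <- crossWithObserved(primed, exac)
    obsProp <- observedProportions(primed)
    acTab <- acSpectrum(primed)
    emit(primed, "primed_sites.tsv")
    emit(obsProp, "primed_observed_proportions.tsv")
    emit(acTab, "primed_ac_spectrum.tsv")
  }

  # --- stage: signatures ----------------------------------------------
  evOK <- !as.character(GenomicRanges::seqnames(events)) %in% afExcludeChroms
  rare <- rareFilter(events[evOK], afMax)
  spectrum <- buildSpectrum(rare, genome)
  decomp <- decomposeSpectrum(spectrum, signatures)
  specDf <- data.frame(channel = names(spectrumCounts(spectrum)),
                       count = as.integer(spectrumCounts(spectrum)))
  emit(specDf, "spectrum_96.tsv")
  sigJson <- file.path(outDir, "signature_weights.json")
  jsonlite::write_json(list(weights = as.list(signatureWeights(decomp)),
                            residual = residualNorm(decomp)),
                       sigJson, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, sigJson)

  # --- stage: statistics ----------------------------------------------
  stats <- list()
  cvn <- as.data.frame(cgiVsNon)
  if (all(cvn$denominator > 0) && nrow(cvn) == 2) {
    tab <- rbind(cvn$numerator, cvn$denominator - cvn$numerator)
    colnames(tab) <- cvn$stratum
    stats$cgi_vs_noncgi <- chi2Contingency(t(tab))
  }
  lenByClass <- data.frame(length = IRanges::width(cgis),
                           class = as.character(cgis$cgiClass))
  lenByClass <- lenByClass[lenByClass$class != "MISC", , drop = FALSE]
  if (length(unique(lenByClass$class)) >= 3) {
    stats$length_kruskal <- kruskalWallisTest(lenByClass$length,
                                              lenByClass$class)
    if (stats$length_kruskal$p_value < 0.05) {
      dn <- dunnTest(lenByClass$length, lenByClass$class)
      emit(dn, "stats_dunn_length.tsv")
    }
  }
  if (!is.null(groups) && length(groups$lengthsA) && length(groups$lengthsB))
    stats$groupAB_length <- wilcoxonRankSum(groups$lengthsA,
                                            groups$lengthsB)
  pcA <- profClass[profClass$class == "INTRAGENIC_CODING", , drop = FALSE]
  pcB <- profClass[profClass$class == "TSS_CODING", , drop = FALSE]
  if (nrow(pcA) && nrow(pcB))
    stats$shore_intragenic_vs_tss <- pairedTShores(pcA, pcB)
  if (length(stats)) {
    statDf <- do.call(rbind, stats)
    statDf <- cbind(name = rownames(statDf), statDf)
    rownames(statDf) <- NULL
    emit(statDf, "stats_tests.tsv")
  }
  if (length(skipped))
    writeLines(skipped, file.path(outDir, "SKIPPED"))

  # --- manifest -------------------------------------------------------
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  .writeTSV(manifest, file.path(outDir, "MANIFEST.tsv"))

  invisible(list(genome = genome, sites = sites, cgis = cgis,
                 shores = shores, events = events, classRates = classRates,
                 cgiVsNon = cgiVsNon, afWeighted = afw, afBinned = afb,
                 regionSplit = regSplit, profile = prof,
                 profileByClass = profClass, profileNonCpG = profNC,
                 methSummaries = methSummaries, methProfile = methProf,
                 groups = groups, primed = primed,
                 observedProportions = obsProp, acSpectrum = acTab,
                 spectrum = spectrum, decomposition = decomp,
                 stats = stats, skipped = skipped))
}

#' Enumerate the non-CpG C:G control universe
#'
#' All plus-strand C positions not followed by G, and all G positions not
#' preceded by C (a reverse-strand C outside a CpG), excluding the first
#' and last base of each chromosome.
#'
#' @param genome DNAStringSet
#' @return GRanges of width-1 positions with a \code{ref} metadata column
#'   ("C" or "G")
#' @export
nonCpGControlSites <- function(genome) {
  grl <- lapply(names(genome), function(ch) {
    chars <- strsplit(as.character(genome[[ch]]), "")[[1]]
    L <- length(chars)
    isC <- chars == "C"; isG <- chars == "G"
    cpgC <- isC & c(isG[-1L], FALSE)
    cpgG <- isG & c(FALSE, isC[-L])
    posC <- which(isC & !cpgC)
    posG <- which(isG & !cpgG)
    posC <- posC[posC > 1L & posC < L]
    posG <- posG[posG > 1L & posG < L]
    pos <- sort(c(posC, posG))
    gr <- GenomicRanges::GRanges(factor(rep(ch, length(pos)),
                                        levels = names(genome)),
                                 IRanges::IRanges(pos, pos))
    gr$ref <- chars[pos]
    gr
  })
  do.call(c, grl)
}

#' Plot a distance profile
#'
#' Simple base-graphics rendering of one or more (smoothed) profiles.
#'
#' @param profiles named list of data.frames with distance and a value
#'   column
#' @param value column to plot (default "rate")
#' @param ... passed to \code{plot}
#' @return invisibly NULL
#' @export
plotProfile <- function(profiles, value = "rate", ...) {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  xl <- range(unlist(lapply(profiles, `[[`, "distance")))
  yl <- range(unlist(lapply(profiles, `[[`, value)), na.rm = TRUE)
  graphics::plot(NA, xlim = xl, ylim = yl, xlab = "distance from CGI border (bp)",
                 ylab = value, ...)
  for (i in seq_along(profiles))
    graphics::lines(profiles[[i]]$distance, profiles[[i]][[value]], col = i)
  graphics::legend("topleft", legend = names(profiles), col =
                     seq_along(profiles), lty = 1, bty = "n", cex = 0.8)
  invisible(NULL)
}
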