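# Rate statistics: per-stratum mutation rates, Af-weighted and Af-binned
# rates, distance-resolved profiles around CGI borders, smoothing, and
# coding/noncoding region splits.

# extract a logical/numeric column from GRanges or use the vector directly
.col <- function(sites, what) {
  if (methods::is(sites, "GRanges")) GenomicRanges::mcols(sites)[[what]]
  else sites[[what]]
}

.asStratum <- function(sites, stratifier, n) {
  if (is.character(stratifier) && length(stratifier) == 1L &&
      !is.null(.col(sites, stratifier)))
    stratifier <- .col(sites, stratifier)
  if (length(stratifier) == 1L && n > 1L)
    stratifier <- rep(stratifier, n)
  if (is.factor(stratifier)) stratifier else factor(stratifier)
}

#' Per-stratum CpG mutation rate with Wilson confidence intervals
#'
#' rate = (number of mutated CpG dinucleotides in the stratum) /
#' (number of all CpG dinucleotides in the stratum). Empty strata yield a
#' row with denominator 0 and missing rate.
#'
#' @param sites GRanges with a logical \code{mutated} metadata column, or a
#'   list/data.frame with element \code{mutated}
#' @param stratifier a factor (or the name of a metadata column) assigning
#'   each site to a stratum
#' @param conf confidence level for the Wilson interval (default 0.95)
#' @return a \code{RateTable}
#' @export
mutationRate <- function(sites, stratifier, conf = 0.95) {
  mutated <- .col(sites, "mutated")
  stratum <- .asStratum(sites, stratifier, length(mutated))
  num <- tapply(mutated, stratum, sum, default = 0L)
  den <- tapply(rep(1L, length(mutated)), stratum, sum, default = 0L)
  rate <- ifelse(den > 0, num / den, NA_real_)
  ci <- wilsonCI(as.numeric(num), as.numeric(den), conf)
  ci[den == 0, ] <- NA_real_
  new("RateTable", kind = "mutation_rate",
      table = data.frame(stratum = names(num), numerator = as.integer(num),
                         denominator = as.integer(den), rate = as.numeric(rate),
                         ciLow = ci[, 1], ciHigh = ci[, 2],
                         stringsAsFactors = FALSE, row.names = NULL))
}

#' Allele-frequency-weighted mutation rate
#'
#' rate = (sum of allele frequencies of mutated sites in the stratum) /
#' (number of all sites in the stratum). Mutated sites with missing af are
#' excluded from the numerator and counted in the "missingAF" attribute.
#'
#' @inheritParams mutationRate
#' @return a \code{RateTable} (confidence intervals NA; the numerator is
#'   not a count)
#' @export
afWeightedRate <- function(sites, stratifier) {
  mutated <- .col(sites, "mutated")
  af <- .col(sites, "af")
  stratum <- .asStratum(sites, stratifier, length(mutated))
  w <- ifelse(mutated & !is.na(af), af, 0)
  num <- tapply(w, stratum, sum, default = 0)
  den <- tapply(rep(1L, length(w)), stratum, sum, default = 0L)
  rate <- ifelse(den > 0, num / den, NA_real_)
  out <- new("RateTable", kind = "af_weighted",
             table = data.frame(stratum = names(num),
                                numerator = as.numeric(num),
                                denominator = as.integer(den),
                                rate = as.numeric(rate),
                                ciLow = NA_real_, ciHigh = NA_real_,
                                stringsAsFactors = FALSE, row.names = NULL))
  attr(out, "missingAF") <- sum(mutated & is.na(af))
  out
}

#' Allele-frequency-binned site fractions per stratum
#'
#' Within each stratum, the fraction of sites whose allele frequency falls
#' in each of the six bins; unmutated sites populate the Af = 0 bin, so the
#' six fractions sum to 1 within a stratum.
#'
#' @inheritParams mutationRate
#' @param bins bin definition from \code{afBins}
#' @return a \code{RateTable} with stratum labels "<stratum>|<bin>"
#' @export
afBinnedRates <- function(sites, stratifier, bins = afBins()) {
  if (any(duplicated(bins$label))) .stopf("duplicate bin labels")
  mutated <- .col(sites, "mutated")
  af <- .col(sites, "af")
  stratum <- .asStratum(sites, stratifier, length(mutated))
  binLab <- afBinAssign(ifelse(mutated, af, NA_real_), bins)
  if (anyNA(binLab)) .stopf("allele frequency outside all bins")
  tab <- table(stratum, binLab)
  den <- rowSums(tab)
  rows <- expand.grid(bin = colnames(tab), stratum = rownames(tab),
                      stringsAsFactors = FALSE)[, 2:1]
  num <- mapply(function(s, b) tab[s, b], rows$stratum, rows$bin)
  denv <- den[rows$stratum]
  rate <- ifelse(denv > 0, num / denv, NA_real_)
  ci <- wilsonCI(as.numeric(num), as.numeric(denv))
  ci[denv == 0, ] <- NA_real_
  new("RateTable", kind = "af_binned",
      table = data.frame(stratum = paste(rows$stratum, rows$bin, sep = "|"),
                         numerator = as.integer(num),
                         denominator = as.integer(denv),
                         rate = as.numeric(rate), ciLow = ci[, 1],
                         ciHigh = ci[, 2], stringsAsFactors = FALSE,
                         row.names = NULL))
}

#' Distance-resolved mutation rate around CGI borders
#'
#' For sites outside islands with |signed distance| <= \code{maxDist}, the
#' per-distance rate mutated/total, pooled over all islands or split by
#' the class of each site's nearest island. Distances with zero sites are
#' absent from the result (missing, not 0).
#'
#' @param sites GRanges/list with metadata \code{mutated}, plus the columns
#'   produced by \code{signedDistanceToCGI} (inCGI, distance, nearestClass)
#'   either as metadata or supplied via \code{dist}
#' @param dist optional data.frame from \code{signedDistanceToCGI}
#' @param maxDist maximum |distance| in bp (default 5000)
#' @param byClass split by nearest-island class
#' @return data.frame with columns distance, mutated, total, rate (and
#'   class when \code{byClass})
#' @export
distanceProfile <- function(sites, dist = NULL, maxDist = 5000L,
                            byClass = FALSE) {
  mutated <- .col(sites, "mutated")
  if (is.null(dist)) {
    dist <- data.frame(inCGI = .col(sites, "inCGI"),
                       distance = .col(sites, "distance"))
    if (byClass) dist$nearestClass <- .col(sites, "nearestClass")
  }
  keep <- !dist$inCGI & !is.na(dist$distance) & abs(dist$distance) <= maxDist
  d <- dist$distance[keep]
  m <- mutated[keep]
  if (byClass) {
    cl <- as.character(dist$nearestClass[keep])
    key <- split(seq_along(d), list(class = cl, distance = d), drop = TRUE)
    out <- do.call(rbind, lapply(names(key), function(k) {
      i <- key[[k]]
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      data.frame(class = parts[1],
                 distance = as.integer(paste(parts[-1], collapse = ".")),
                 mutated = sum(m[i]), total = length(i),
                 rate = mean(m[i]), stringsAsFactors = FALSE)
    }))
    out <- out[order(out$class, out$distance), , drop = FALSE]
  } else {
    num <- tapply(m, d, sum)
    den <- tapply(rep(1L, length(d)), d, sum)
    out <- data.frame(distance = as.integer(names(num)),
                      mutated = as.integer(num), total = as.integer(den),
                      rate = as.numeric(num / den), row.names = NULL)
    out <- out[order(out$distance), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# block index for distances: blocks count outward from the border on each
# side; left side covers [-window, -1], [-2*window, -window-1], ...; right
# side [0, window-1], [window, 2*window-1], ...
.blockIndex <- function(d, window) {
  ifelse(d >= 0, d %/% window, -((-d - 1L) %/% window) - 1L)
}

#' Smooth a distance profile in non-overlapping blocks
#'
#' Averages the per-position rates over non-overlapping blocks of
#' \code{window} consecutive distance positions on each side of the border
#' (20 positions for the TSS-coding, intragenic-coding and intergenic
#' classes; 100 for the noncoding classes). A trailing partial block is
#' averaged over its available positions.
#'
#' @param profile data.frame from \code{distanceProfile} (single class)
#' @param window block width in positions, or a CGI class name from which
#'   the conventional width is derived
#' @param value name of the column to average (default "rate")
#' @return data.frame with columns distance (block midpoint), value (block
#'   mean), n (positions averaged)
#' @export
smoothProfile <- function(profile, window = 20L, value = "rate") {
  if (is.character(window))
    window <- smoothingWindow(window)
  b <- .blockIndex(profile$distance, window)
  v <- tapply(profile[[value]], b, mean)
  n <- tapply(rep(1L, nrow(profile)), b, sum)
  bi <- as.integer(names(v))
  mid <- ifelse(bi >= 0, bi * window + (window - 1) / 2,
                (bi + 1) * window - 1 - (window - 1) / 2)
  out <- data.frame(distance = mid, value = as.numeric(v),
                    n = as.integer(n), row.names = NULL)
  names(out)[2] <- value
  out[order(out$distance), , drop = FALSE]
}

#' Conventional smoothing window for a CGI class
#'
#' 20 positions for TSS-coding, intragenic-coding and intergenic islands;
#' 100 for the sparser TSS-noncoding and intragenic-noncoding classes.
#'
#' @param cgiClass a CGI class name
#' @return integer window size
#' @export
smoothingWindow <- function(cgiClass) {
  ifelse(cgiClass %in% c("TSS_NONCODING", "INTRAGENIC_NONCODING"), 100L, 20L)
}

#' Mutation rates split by coding-exon overlap
#'
#' Crosses a region grouping (TSS-coding CGI, intragenic-coding CGI,
#' non-CGI) with coding-exon membership of each site's C position.
#'
#' @param sites GRanges of CpG sites with \code{mutated} metadata and CGI
#'   annotation columns \code{inCGI}, \code{cgiClass} (class of the
#'   containing island, NA outside islands)
#' @param genes list of \code{GeneModel} for CDS intervals
#' @return a \code{RateTable} with strata "<region>|<coding|noncoding>"
#' @export
regionSplitRates <- function(sites, genes) {
  cds <- codingExonRanges(genes)
  inCDS <- GenomicRanges::countOverlaps(
    GenomicRanges::resize(sites, 1L, fix = "start"), cds) > 0
  inCGI <- .col(sites, "inCGI")
  cls <- as.character(.col(sites, "cgiClass"))
  region <- ifelse(!inCGI, "non-CGI",
                   ifelse(cls == "TSS_CODING", "TSS_CODING",
                          ifelse(cls == "INTRAGENIC_CODING",
                                 "INTRAGENIC_CODING", NA_character_)))
  keep <- !is.na(region)
  strat <- paste(region[keep],
                 ifelse(inCDS[keep], "coding-exon", "noncoding"), sep = "|")
  rt <- mutationRate(list(mutated = .col(sites, "mutated")[keep]), strat)
  rt@kind <- "region_split"
  rt
}
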