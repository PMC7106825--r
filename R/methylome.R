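# Per-CpG methylation track ingestion and summaries

#' Load a per-CpG methylation track
#'
#' Supports 4-column bedGraph (chrom, start, end, beta) and MethBase-style
#' TSV (chrom, pos, strand, context, beta, coverage). Values on a 0-100
#' scale are detected (any value > 1) and normalized to [0, 1]. Records on
#' the G strand of a dinucleotide (position = C position + 1, or strand
#' "-") are averaged with the C-strand record into one site-level beta.
#'
#' @param path track file
#' @param sites GRanges of CpG sites from \code{enumerateCpGSites}; used to
#'   resolve strand-duplicated records and to flag orphans
#' @param format "bedgraph" or "methbase"
#' @return data.frame with columns chrom, pos (1-based C position), beta,
#'   coverage (NA when absent); attribute "orphans" counts records not
#'   matching any CpG site
#' @export
loadMethylation <- function(path, sites, format = c("bedgraph", "methbase")) {
  format <- match.arg(format)
  if (format == "bedgraph") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    rec <- data.frame(chrom = df[[1]], pos = df[[2]] + 1L, beta = df[[4]],
                      coverage = if (ncol(df) >= 5) df[[5]] else NA_integer_,
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    rec <- data.frame(chrom = df[[1]], pos = df[[2]] + 1L, beta = df[[5]],
                      coverage = if (ncol(df) >= 6) df[[6]] else NA_integer_,
                      stringsAsFactors = FALSE)
  }
  if (any(rec$beta > 1, na.rm = TRUE)) rec$beta <- rec$beta / 100
  bad <- which(rec$beta < 0 | rec$beta > 1)
  if (length(bad))
    .stopf("beta outside [0,1] after normalization at line %d", bad[1])

  siteKey <- paste(as.character(GenomicRanges::seqnames(sites)),
                   GenomicRanges::start(sites), sep = "\r")
  # a record is C-strand if its position is a site C; G-strand if pos-1 is
  keyC <- paste(rec$chrom, rec$pos, sep = "\r")
  keyG <- paste(rec$chrom, rec$pos - 1L, sep = "\r")
  isC <- keyC %in% siteKey
  isG <- !isC & keyG %in% siteKey
  orphans <- sum(!isC & !isG)
  if (orphans > 0)
    .warnf("%d methylation record(s) do not map onto a CpG site", orphans)
  sitePos <- ifelse(isC, rec$pos, ifelse(isG, rec$pos - 1L, NA_integer_))
  keep <- !is.na(sitePos)
  key <- paste(rec$chrom[keep], sitePos[keep], sep = "\r")
  beta <- tapply(rec$beta[keep], key, mean)
  cov <- tapply(rec$coverage[keep], key, function(x)
    if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
  parts <- strsplit(names(beta), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                    pos = as.integer(vapply(parts, `[`, character(1), 2)),
                    beta = as.numeric(beta), coverage = as.numeric(cov),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "orphans") <- orphans
  out
}

#' Attach site-level betas to a CpG site catalogue
#'
#' @param sites GRanges of CpG sites
#' @param meth data.frame from \code{loadMethylation}
#' @param minCoverage minimum read coverage for a beta to count (default 1;
#'   records without coverage information always count)
#' @return sites with a \code{beta} metadata column (NA = not covered)
#' @export
annotateSiteBetas <- function(sites, meth, minCoverage = 1L) {
  ok <- is.na(meth$coverage) | meth$coverage >= minCoverage
  meth <- meth[ok, , drop = FALSE]
  key <- paste(as.character(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites), sep = "\r")
  idx <- match(key, paste(meth$chrom, meth$pos, sep = "\r"))
  sites$beta <- meth$beta[idx]
  sites
}

#' Mean methylation per CGI with hyper/hypo grouping
#'
#' mean beta over covered CpGs inside each island; islands with at least
#' \code{minCovered} covered CpGs are grouped: A when mean beta >
#' \code{hyper}, B when mean beta < \code{hypo}, otherwise intermediate.
#'
#' @param sites CpG sites with \code{beta} metadata
#' @param cgis GRanges of (classified) islands
#' @param minCovered minimum covered CpGs for grouping (default 5)
#' @param hyper,hypo group thresholds (defaults 0.67 / 0.33, strict)
#' @return data.frame, one row per island: chrom, start, end, cgiClass,
#'   length, meanBeta, nCovered, group
#' @export
meanMethylationPerCGI <- function(sites, cgis, minCovered = 5L,
                                  hyper = 0.67, hypo = 0.33) {
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::resize(sites, 1L, fix = "start"), cgis)
  beta <- sites$beta[S4Vectors::queryHits(ov)]
  isl <- S4Vectors::subjectHits(ov)
  meanBeta <- rep(NA_real_, length(cgis))
  nCov <- integer(length(cgis))
  agg <- tapply(beta, isl, function(b) c(mean(b, na.rm = TRUE),
                                         sum(!is.na(b))))
  for (k in names(agg)) {
    i <- as.integer(k)
    nCov[i] <- agg[[k]][2]
    if (agg[[k]][2] > 0) meanBeta[i] <- agg[[k]][1]
  }
  group <- ifelse(nCov < minCovered | is.na(meanBeta), NA_character_,
                  ifelse(meanBeta > hyper, "A",
                         ifelse(meanBeta < hypo, "B", "intermediate")))
  data.frame(chrom = as.character(GenomicRanges::seqnames(cgis)),
             start = GenomicRanges::start(cgis),
             end = GenomicRanges::end(cgis),
             cgiClass = if (!is.null(cgis$cgiClass))
               as.character(cgis$cgiClass) else NA_character_,
             length = IRanges::width(cgis),
             meanBeta = meanBeta, nCovered = nCov, group = group,
             stringsAsFactors = FALSE)
}

#' Distance-resolved mean methylation around CGI borders
#'
#' Per signed distance from the nearest island border (within
#' \code{maxDist}), the mean beta over covered CpGs at that distance,
#' pooled or split by nearest-island class. Distances with no covered CpG
#' are absent (missing, not 0).
#'
#' @param sites CpG sites with \code{beta} metadata
#' @param dist data.frame from \code{signedDistanceToCGI}
#' @param maxDist maximum |distance| (default 5000)
#' @param byClass split by nearest-island class
#' @return data.frame with columns distance, meanBeta, n (and class)
#' @export
methylationDistanceProfile <- function(sites, dist, maxDist = 5000L,
                                       byClass = FALSE) {
  beta <- sites$beta
  keep <- !dist$inCGI & !is.na(dist$distance) &
    abs(dist$distance) <= maxDist & !is.na(beta)
  d <- dist$distance[keep]
  b <- beta[keep]
  if (byClass) {
    cl <- as.character(dist$nearestClass[keep])
    key <- split(seq_along(d), list(cl, d), drop = TRUE)
    out <- do.call(rbind, lapply(names(key), function(k) {
      i <- key[[k]]
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      data.frame(class = parts[1],
                 distance = as.integer(paste(parts[-1], collapse = ".")),
                 meanBeta = mean(b[i]), n = length(i),
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$class, out$distance), , drop = FALSE]
  } else {
    mb <- tapply(b, d, mean)
    n <- tapply(rep(1L, length(d)), d, sum)
    out <- data.frame(distance = as.integer(names(mb)),
                      meanBeta = as.numeric(mb), n = as.integer(n),
                      row.names = NULL)
    out <- out[order(out$distance), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Split intragenic-coding islands into hyper/hypo-methylated groups
#'
#' @param summaries data.frame from \code{meanMethylationPerCGI}
#' @return list with elements groupA, groupB (data.frames), lengthsA,
#'   lengthsB (island length vectors for the rank-sum comparison), and
#'   fractionA (share of grouped islands that are hyper-methylated)
#' @export
splitIntragenicCoding <- function(summaries) {
  s <- summaries[!is.na(summaries$cgiClass) &
                   summaries$cgiClass == "INTRAGENIC_CODING", , drop = FALSE]
  a <- s[!is.na(s$group) & s$group == "A", , drop = FALSE]
  b <- s[!is.na(s$group) & s$group == "B", , drop = FALSE]
  grouped <- sum(!is.na(s$group) & s$group %in% c("A", "B", "intermediate"))
  list(groupA = a, groupB = b,
       lengthsA = a$length, lengthsB = b$length,
       fractionA = if (grouped > 0) nrow(a) / grouped else NA_real_)
}
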