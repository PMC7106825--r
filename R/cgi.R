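# CpG island calling, classification, shores, signed distances

# composition of a segment: nC, nG, nCpG (CpG counted when its C lies in
# the segment and its G as well), GC fraction and observed/expected ratio
.cgScore <- function(chars, start, end) {
  seg <- chars[start:end]
  L <- end - start + 1L
  nC <- sum(seg == "C")
  nG <- sum(seg == "G")
  nCpG <- sum(seg[-L] == "C" & seg[-1L] == "G")
  gc <- (nC + nG) / L
  oe <- if (nC > 0 && nG > 0) nCpG * L / (nC * nG) else 0
  list(nC = nC, nG = nG, nCpG = nCpG, gc = gc, oe = oe, length = L)
}

#' Call CpG islands by the Gardiner-Garden criteria
#'
#' Slides a window (default 200 bp, step 1) along each chromosome; windows
#' with GC fraction >= 0.5 and observed/expected CpG ratio
#' (#CpG x L / (#C x #G)) > 0.6 are merged when overlapping or adjacent.
#' Each merged segment is then re-scored and retained only if it itself
#' satisfies GC >= 0.5, obs/exp > 0.6 and length > 200 bp. With
#' \code{recheck = FALSE} the raw merged unions are returned unfiltered.
#'
#' @param genome a DNAStringSet
#' @param window window size in bp (default 200)
#' @param step window step in bp (default 1)
#' @param minGC minimum GC fraction (default 0.5)
#' @param minOE minimum observed/expected CpG ratio, exclusive (default 0.6)
#' @param minLength minimum merged-segment length, exclusive (default 200)
#' @param recheck re-score merged segments against all criteria
#' @param chroms optional chromosome subset
#' @return GRanges of islands with metadata columns gcFraction, obsExpRatio
#' @export
callCGIs <- function(genome, window = 200L, step = 1L, minGC = 0.5,
                     minOE = 0.6, minLength = 200L, recheck = TRUE,
                     chroms = NULL) {
  if (is.null(chroms)) chroms <- names(genome)
  res <- list()
  for (ch in chroms) {
    s <- .chromSeq(genome, ch)
    L <- length(s)
    if (window > L) {
      .warnf("chromosome %s shorter than window; skipped", ch)
      next
    }
    chars <- strsplit(as.character(s), "")[[1]]
    isC <- chars == "C"
    isG <- chars == "G"
    isCpG <- isC & c(isG[-1L], FALSE)
    cC <- c(0L, cumsum(isC)); cG <- c(0L, cumsum(isG))
    cCpG <- c(0L, cumsum(isCpG))
    starts <- seq.int(1L, L - window + 1L, by = step)
    ends <- starts + window - 1L
    nC <- cC[ends + 1L] - cC[starts]
    nG <- cG[ends + 1L] - cG[starts]
    # CpGs fully inside the window: C at positions start..end-1
    nCpG <- cCpG[ends] - cCpG[starts]
    gcOK <- (nC + nG) / window >= minGC
    oe <- ifelse(nC > 0 & nG > 0, nCpG * window / (nC * nG), 0)
    qual <- which(gcOK & oe > minOE)
    if (length(qual) == 0L) next
    merged <- IRanges::reduce(IRanges::IRanges(starts[qual], ends[qual]))
    keep <- logical(length(merged))
    gcv <- oev <- numeric(length(merged))
    for (i in seq_along(merged)) {
      sc <- .cgScore(chars, IRanges::start(merged)[i], IRanges::end(merged)[i])
      gcv[i] <- sc$gc; oev[i] <- sc$oe
      keep[i] <- !recheck ||
        (sc$gc >= minGC && sc$oe > minOE && sc$length > minLength)
    }
    if (!any(keep)) next
    gr <- GenomicRanges::GRanges(factor(rep(ch, sum(keep)), levels = chroms),
                                 merged[keep])
    gr$gcFraction <- gcv[keep]
    gr$obsExpRatio <- oev[keep]
    res[[ch]] <- gr
  }
  if (length(res) == 0) {
    out <- GenomicRanges::GRanges()
    out$gcFraction <- numeric(0); out$obsExpRatio <- numeric(0)
    return(out)
  }
  out <- sort(do.call(c, unname(res)))
  sl <- Biostrings::width(genome)[match(GenomeInfoDb::seqlevels(out),
                                        names(genome))]
  GenomeInfoDb::seqlengths(out) <- stats::setNames(sl,
                                                   GenomeInfoDb::seqlevels(out))
  out
}

#' Load CpG islands from a BED file
#'
#' Intervals are sorted and overlap-merged. The Gardiner-Garden composition
#' invariants are not enforced on ingested records (pre-computed tracks may
#' use a different caller).
#'
#' @param path BED3+ file
#' @param genome optional DNAStringSet; records on chromosomes absent from
#'   the genome are dropped with a warning, and seqlengths are set
#' @return GRanges of islands
#' @export
loadCGIsBed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::mcols(gr) <- NULL
  if (!is.null(genome)) {
    bad <- !as.character(GenomicRanges::seqnames(gr)) %in% names(genome)
    if (any(bad)) {
      .warnf("%d CGI record(s) on chromosomes absent from the genome dropped",
             sum(bad))
      gr <- gr[!bad]
      GenomeInfoDb::seqlevels(gr) <- as.character(unique(
        GenomicRanges::seqnames(gr)))
    }
  }
  gr <- GenomicRanges::reduce(sort(gr))
  if (!is.null(genome) && length(gr)) {
    sl <- Biostrings::width(genome)[match(GenomeInfoDb::seqlevels(gr),
                                          names(genome))]
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(
      sl, GenomeInfoDb::seqlevels(gr))
  }
  gr
}

#' Re-score islands from sequence
#'
#' Adds/overwrites gcFraction and obsExpRatio metadata computed from the
#' genome, e.g. after loading a BED without composition columns.
#'
#' @param cgis GRanges of islands
#' @param genome DNAStringSet
#' @return the islands with composition metadata
#' @export
scoreCGIs <- function(cgis, genome) {
  gcv <- oev <- numeric(length(cgis))
  for (ch in unique(as.character(GenomicRanges::seqnames(cgis)))) {
    idx <- which(as.character(GenomicRanges::seqnames(cgis)) == ch)
    chars <- strsplit(as.character(.chromSeq(genome, ch)), "")[[1]]
    for (i in idx) {
      sc <- .cgScore(chars, GenomicRanges::start(cgis)[i],
                     GenomicRanges::end(cgis)[i])
      gcv[i] <- sc$gc; oev[i] <- sc$oe
    }
  }
  cgis$gcFraction <- gcv
  cgis$obsExpRatio <- oev
  cgis
}

#' Classify CpG islands by functional context
#'
#' Per collapsed gene, an island receives a candidate label: TSS_CODING or
#' TSS_NONCODING when the island intersects the closed window TSS +/-
#' \code{tssWindow}; otherwise INTRAGENIC_CODING/INTRAGENIC_NONCODING when
#' it intersects the transcript body. A TSS hit takes priority over a body
#' hit from the same gene. Islands collecting more than one distinct label
#' from different genes become MISC; islands touching nothing are
#' INTERGENIC.
#'
#' @param cgis GRanges of islands
#' @param genes list of \code{GeneModel} (transcripts are collapsed per
#'   gene key internally)
#' @param tssWindow half-width of the TSS window in bp (default 100)
#' @return the islands with a \code{cgiClass} metadata column (factor over
#'   \code{CGI_CLASSES})
#' @export
classifyCGIs <- function(cgis, genes, tssWindow = 100L) {
  gn <- collapseGenes(genes)
  labels <- vector("list", length(cgis))
  if (nrow(gn)) {
    cgiStart <- GenomicRanges::start(cgis)
    cgiEnd <- GenomicRanges::end(cgis)
    cgiChrom <- as.character(GenomicRanges::seqnames(cgis))
    for (j in seq_len(nrow(gn))) {
      onChrom <- which(cgiChrom == gn$chrom[j])
      if (!length(onChrom)) next
      tssLo <- gn$tss[j] - tssWindow
      tssHi <- gn$tss[j] + tssWindow
      hitsTSS <- cgiStart[onChrom] <= tssHi & cgiEnd[onChrom] >= tssLo
      hitsBody <- cgiStart[onChrom] <= gn$txEnd[j] &
        cgiEnd[onChrom] >= gn$txStart[j]
      lbl <- ifelse(hitsTSS,
                    if (gn$isCoding[j]) "TSS_CODING" else "TSS_NONCODING",
                    if (gn$isCoding[j]) "INTRAGENIC_CODING"
                    else "INTRAGENIC_NONCODING")
      hit <- hitsTSS | hitsBody
      for (k in which(hit))
        labels[[onChrom[k]]] <- c(labels[[onChrom[k]]], lbl[k])
    }
  }
  cls <- vapply(labels, function(ls) {
    u <- unique(ls)
    if (length(u) == 0L) "INTERGENIC"
    else if (length(u) == 1L) u
    else "MISC"
  }, character(1))
  cgis$cgiClass <- factor(cls, levels = CGI_CLASSES)
  cgis
}

#' Derive CGI shores
#'
#' The up-to-2000-bp flanks on each side of every island, truncated at
#' chromosome ends and clipped against all islands so no base is both
#' shore and island.
#'
#' @param cgis GRanges of islands (seqlengths set for end-clipping)
#' @param width shore width in bp (default 2000)
#' @return GRanges of shores with metadata columns parent (island index)
#'   and side ("left"/"right")
#' @export
cgiShores <- function(cgis, width = 2000L) {
  if (length(cgis) == 0) return(GenomicRanges::GRanges())
  # flank may momentarily leave chromosome bounds; trim clips it back
  shores <- suppressWarnings({
    left <- GenomicRanges::flank(cgis, width, start = TRUE)
    right <- GenomicRanges::flank(cgis, width, start = FALSE)
    both <- c(left, right)
    both$parent <- rep(seq_along(cgis), 2)
    both$side <- rep(c("left", "right"), each = length(cgis))
    GenomicRanges::trim(both)
  })
  shores <- shores[IRanges::width(shores) > 0]
  # clip each shore individually against all islands (shores of distinct
  # islands may overlap each other; island bases never stay shore)
  pieces <- lapply(seq_along(shores), function(i) {
    piece <- GenomicRanges::setdiff(shores[i], cgis, ignore.strand = TRUE)
    if (length(piece)) {
      piece$parent <- shores$parent[i]
      piece$side <- shores$side[i]
    }
    piece
  })
  pieces <- pieces[lengths(pieces) > 0]
  if (!length(pieces)) return(GenomicRanges::GRanges())
  sort(do.call(c, pieces))
}

#' Signed distance from sites to the nearest CGI border
#'
#' Sites inside an island get \code{inCGI = TRUE} and NA distance. For
#' outside sites the distance runs to the nearest border of the nearest
#' island: negative when the site lies at a lower coordinate than that
#' island (upstream on the plus strand), positive when higher. Ties between
#' two equidistant islands are broken toward the lower-coordinate island.
#' Chromosomes without any island yield NA distances.
#'
#' @param sites GRanges of CpG sites (position = start) or integer
#'   positions with \code{chrom}
#' @param cgis GRanges of islands, non-overlapping
#' @return data.frame with columns inCGI, distance, nearest (island index
#'   within \code{cgis}), nearestClass (if the islands carry cgiClass)
#' @export
signedDistanceToCGI <- function(sites, cgis) {
  pos <- GenomicRanges::start(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  n <- length(pos)
  inCGI <- logical(n)
  dist <- rep(NA_integer_, n)
  nearest <- rep(NA_integer_, n)
  cgiChrom <- as.character(GenomicRanges::seqnames(cgis))
  for (ch in unique(chrom)) {
    si <- which(chrom == ch)
    ci <- which(cgiChrom == ch)
    if (!length(ci)) next
    st <- GenomicRanges::start(cgis)[ci]
    en <- GenomicRanges::end(cgis)[ci]
    o <- order(st)
    st <- st[o]; en <- en[o]; ci <- ci[o]
    p <- pos[si]
    # island to the left of or containing p: last start <= p
    k <- findInterval(p, st)
    inside <- k >= 1L & p <= ifelse(k >= 1L, en[pmax(k, 1L)], -1L)
    inCGI[si[inside]] <- TRUE
    nearest[si[inside]] <- ci[pmax(k, 1L)][inside]
    outIdx <- which(!inside)
    if (length(outIdx)) {
      pk <- p[outIdx]; kk <- k[outIdx]
      # distance from the left island (positive, site right of it)
      dLeft <- ifelse(kk >= 1L, pk - en[pmax(kk, 1L)] - 1L, NA_integer_)
      # distance to the right island (site left of it, negative sign)
      hasRight <- kk < length(st)
      dRight <- ifelse(hasRight, st[pmin(kk + 1L, length(st))] - pk,
                       NA_integer_)
      # choose nearer border; tie -> lower-coordinate (left) island
      useLeft <- !is.na(dLeft) & (is.na(dRight) | dLeft <= dRight)
      d <- ifelse(useLeft, dLeft, -dRight)
      nr <- ifelse(useLeft, ci[pmax(kk, 1L)], ci[pmin(kk + 1L, length(st))])
      dist[si[outIdx]] <- d
      nearest[si[outIdx]] <- nr
    }
  }
  out <- data.frame(inCGI = inCGI, distance = dist, nearest = nearest)
  if (!is.null(cgis$cgiClass))
    out$nearestClass <- cgis$cgiClass[nearest]
  out
}
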