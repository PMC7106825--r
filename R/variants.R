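# Variant catalogue ingestion: C:G>T:A SNVs with allele-frequency metadata

#' Load C:G>T:A single-nucleotide variants from a VCF
#'
#' Multiallelic records are expanded to allele-level events; only SNVs with
#' (ref, alt) in {(C,T), (G,A)} are kept (set \code{allClasses = TRUE} to
#' keep every SNV, e.g. to feed the 96-channel spectrum). When the FILTER
#' column is populated with anything other than "." , non-PASS records are
#' dropped; an entirely "." column bypasses the filter. AF is taken from
#' the AF info field, else computed as AC/AN.
#'
#' @param path VCF or VCF.gz file
#' @param source catalogue label stored on every event
#' @param allClasses keep all SNV substitution classes (default FALSE:
#'   C>T / G>A only)
#' @return GRanges of events with metadata columns ref, alt, af, ac, an,
#'   source; attribute "dropped" counts non-PASS records removed
#' @export
loadCTVariants <- function(path, source = "catalogue", allClasses = FALSE) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  filt <- rr$FILTER
  info <- VariantAnnotation::info(vcf)

  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES
  filterActive <- any(!filt %in% c(".", ""))
  passOK <- if (filterActive) filt %in% c("PASS", ".", "") else rep(TRUE, length(filt))
  dropped <- sum(snv & !passOK)
  classOK <- if (allClasses) rep(TRUE, length(ref)) else
    (ref == "C" & alt == "T") | (ref == "G" & alt == "A")
  keep <- snv & passOK & classOK

  af <- if ("AF" %in% names(info)) as.numeric(info$AF) else rep(NA_real_, length(ref))
  ac <- if ("AC" %in% names(info)) suppressWarnings(as.integer(info$AC)) else
    rep(NA_integer_, length(ref))
  an <- if ("AN" %in% names(info)) suppressWarnings(as.integer(info$AN)) else
    rep(NA_integer_, length(ref))
  af <- ifelse(is.na(af) & !is.na(ac) & !is.na(an) & an > 0, ac / an, af)

  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rr)[keep],
                               IRanges::ranges(rr)[keep])
  gr$ref <- ref[keep]; gr$alt <- alt[keep]
  gr$af <- af[keep]; gr$ac <- ac[keep]; gr$an <- an[keep]
  gr$source <- rep(source, sum(keep))
  attr(gr, "dropped") <- dropped
  attr(gr, "missingAF") <- sum(is.na(af[keep]))
  gr
}

#' Attach events to CpG sites
#'
#' A C>T event at position p belongs to the CpG dinucleotide whose C is at
#' p when the genome reads "CG" at p..p+1; a G>A event at p belongs to the
#' site at p-1 when the genome reads "CG" at p-1..p. Other events keep
#' \code{cpgPos = NA} and form the non-CpG control pool.
#'
#' @param events GRanges from \code{loadCTVariants}
#' @param genome DNAStringSet
#' @return the events with a \code{cpgPos} metadata column (1-based C
#'   position of the owning CpG site, or NA)
#' @export
attachToCpG <- function(events, genome) {
  n <- length(events)
  cpgPos <- rep(NA_integer_, n)
  chrom <- as.character(GenomicRanges::seqnames(events))
  pos <- GenomicRanges::start(events)
  for (ch in unique(chrom)) {
    s <- .chromSeq(genome, ch)
    L <- length(s)
    idx <- which(chrom == ch)
    p <- pos[idx]
    isCT <- events$ref[idx] == "C" & events$alt[idx] == "T"
    isGA <- events$ref[idx] == "G" & events$alt[idx] == "A"
    okCT <- isCT & p < L
    if (any(okCT)) {
      nxt <- as.character(Biostrings::Views(s, p[okCT], p[okCT] + 1L))
      cpgPos[idx[okCT]][nxt == "CG"] <- p[okCT][nxt == "CG"]
    }
    okGA <- isGA & p > 1L
    if (any(okGA)) {
      prv <- as.character(Biostrings::Views(s, p[okGA] - 1L, p[okGA]))
      cpgPos[idx[okGA]][prv == "CG"] <- p[okGA][prv == "CG"] - 1L
    }
  }
  events$cpgPos <- cpgPos
  events
}

# normalize chr naming to that of the reference names
.normalizeChrom <- function(chrom, refNames) {
  if (all(chrom %in% refNames)) return(chrom)
  mapped <- ifelse(chrom %in% refNames, chrom,
                   ifelse(paste0("chr", chrom) %in% refNames,
                          paste0("chr", chrom),
                          ifelse(sub("^chr", "", chrom) %in% refNames,
                                 sub("^chr", "", chrom), NA_character_)))
  if (anyNA(mapped))
    .stopf("unmappable chromosome name(s): %s",
           paste(unique(chrom[is.na(mapped)]), collapse = ", "))
  mapped
}

#' Merge CpG-attached catalogues into a site-level mutation table
#'
#' A site is mutated when at least one catalogue reports a C>T or G>A
#' event on either strand of the dinucleotide; a site hit by both its C>T
#' and G>A event counts once. AFs are reconciled across catalogues by
#' maximum (\code{policy = "max"}) or kept per source
#' (\code{policy = "per-source"}).
#'
#' @param catalogues list of CpG-attached event GRanges
#' @param refNames chromosome names of the reference, used to reconcile
#'   "chr1" vs "1" naming; unmappable names are an error
#' @param policy "max" (default) or "per-source"
#' @return data.frame with columns chrom, cpgPos, af, ac, an, sources (or
#'   one row per source under "per-source")
#' @export
mergeCatalogues <- function(catalogues, refNames = NULL,
                            policy = c("max", "per-source")) {
  policy <- match.arg(policy)
  rows <- lapply(catalogues, function(ev) {
    keep <- !is.na(ev$cpgPos)
    chrom <- as.character(GenomicRanges::seqnames(ev))[keep]
    if (!is.null(refNames)) chrom <- .normalizeChrom(chrom, refNames)
    data.frame(chrom = chrom, cpgPos = ev$cpgPos[keep], af = ev$af[keep],
               ac = ev$ac[keep], an = ev$an[keep],
               source = ev$source[keep], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(chrom = character(0), cpgPos = integer(0),
                      af = numeric(0), ac = integer(0), an = integer(0),
                      sources = character(0)))
  if (policy == "per-source") {
    key <- paste(df$chrom, df$cpgPos, df$source, sep = "\r")
  } else {
    key <- paste(df$chrom, df$cpgPos, sep = "\r")
  }
  o <- order(key, -ifelse(is.na(df$af), -Inf, df$af))
  df <- df[o, ]
  first <- !duplicated(key[o])
  agg <- df[first, ]
  agg$sources <- vapply(split(df$source, key[o]), function(s)
    paste(sort(unique(s)), collapse = ","), character(1))[unique(key[o])]
  agg$source <- NULL
  rownames(agg) <- NULL
  agg[order(agg$chrom, agg$cpgPos), , drop = FALSE]
}

#' Annotate a CpG site catalogue with mutation status
#'
#' @param sites GRanges of CpG sites (from \code{enumerateCpGSites})
#' @param siteMuts merged site-level mutation table
#' @return the sites with metadata columns mutated, af, ac, an (af is NA
#'   for unmutated sites)
#' @export
annotateSiteMutations <- function(sites, siteMuts) {
  key <- paste(as.character(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites), sep = "\r")
  mkey <- paste(siteMuts$chrom, siteMuts$cpgPos, sep = "\r")
  idx <- match(key, mkey)
  sites$mutated <- !is.na(idx)
  sites$af <- siteMuts$af[idx]
  sites$ac <- siteMuts$ac[idx]
  sites$an <- siteMuts$an[idx]
  sites
}

#' Filter events to rare allele frequency
#'
#' Retains events with af <= \code{afMax} (inclusive). Events with missing
#' af are dropped and counted in the "droppedMissing" attribute.
#'
#' @param events GRanges of events with af
#' @param afMax maximum allele frequency (default 0.01)
#' @return the rare subset
#' @export
rareFilter <- function(events, afMax = 0.01) {
  missing <- is.na(events$af)
  out <- events[!missing & events$af <= afMax]
  attr(out, "droppedMissing") <- sum(missing)
  out
}

#' The six allele-frequency bins
#'
#' Af = 0 holds CpG sites with no reported variant; reported variants fall
#' in (0, 0.06), [0.06, 0.12), [0.12, 0.18), [0.18, 0.24) or [0.24, 1].
#'
#' @return data.frame with columns label, lower, upper, lowerClosed,
#'   upperClosed
#' @export
afBins <- function() {
  data.frame(
    label = c("Af=0", "0<Af<0.06", "0.06<=Af<0.12", "0.12<=Af<0.18",
              "0.18<=Af<0.24", "Af>=0.24"),
    lower = c(0, 0, 0.06, 0.12, 0.18, 0.24),
    upper = c(0, 0.06, 0.12, 0.18, 0.24, 1),
    lowerClosed = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    upperClosed = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Assign allele frequencies to bins
#'
#' @param af numeric allele frequencies (NA = unmutated, mapped to "Af=0")
#' @param bins bin definition from \code{afBins}
#' @return factor of bin labels
#' @export
afBinAssign <- function(af, bins = afBins()) {
  lab <- rep(NA_character_, length(af))
  af0 <- ifelse(is.na(af), 0, af)
  for (i in seq_len(nrow(bins))) {
    lo <- bins$lower[i]; hi <- bins$upper[i]
    inBin <- if (lo == hi) af0 == lo else
      (if (bins$lowerClosed[i]) af0 >= lo else af0 > lo) &
      (if (bins$upperClosed[i]) af0 <= hi else af0 < hi)
    lab[inBin & is.na(lab)] <- bins$label[i]
  }
  factor(lab, levels = bins$label)
}
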