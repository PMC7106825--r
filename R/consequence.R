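# Consequence-primed coding CpG analysis: every CDS base that is the C or
# G of a CpG dinucleotide, the codon change its C:G>T:A substitution would
# cause, and the cross with observed population variants.

.GENETIC_CODE <- Biostrings::GENETIC_CODE

# translate one codon; "*" for stop
.aa <- function(codon) unname(.GENETIC_CODE[codon])

#' Consequence of a single-base codon change
#'
#' Stop-to-stop is SILENT; stop-loss is counted as MISSENSE; a gained stop
#' is NONSENSE.
#'
#' @param before,after 3-mer codons in transcript orientation
#' @return "SILENT", "MISSENSE" or "NONSENSE"
#' @export
codonConsequence <- function(before, after) {
  a1 <- .aa(before); a2 <- .aa(after)
  ifelse(a1 == a2, "SILENT",
         ifelse(a2 == "*", "NONSENSE", "MISSENSE"))
}

.SEVERITY <- c(SILENT = 1L, MISSENSE = 2L, NONSENSE = 3L)

#' Enumerate consequence-primed coding CpG sites
#'
#' Every CDS base that is the C of a plus-strand CpG (substitution C>T) or
#' the G of a plus-strand CpG (substitution G>A) is projected into
#' transcript orientation, its codon mutated and translated, and the
#' consequence assigned. Sites are then restricted to hyper-methylated
#' CpGs (site beta >= \code{betaMin}) when betas are supplied. Genes whose
#' CDS length is not divisible by 3 are skipped with a warning.
#'
#' Region classes pool the island classes into the three panels used for
#' consequence analysis: TSS_CGI (TSS-coding/TSS-noncoding islands),
#' INTRAGENIC_CGI (intragenic islands) and NON_CGI; sites inside intergenic
#' or miscellaneous islands are excluded (counted in the "excludedCGI"
#' attribute).
#'
#' Overlapping transcripts: the per-site table keeps the most severe
#' consequence (NONSENSE > MISSENSE > SILENT); the per-transcript long
#' table is returned as the "byTranscript" attribute.
#'
#' @param genome DNAStringSet
#' @param genes list of \code{GeneModel}
#' @param cgis classified islands (GRanges with cgiClass)
#' @param siteBetas optional named beta lookup: data.frame with chrom, pos
#'   (1-based C position of the CpG), beta — e.g. from
#'   \code{loadMethylation}
#' @param betaMin hyper-methylation threshold, inclusive (default 0.67);
#'   NULL disables the filter
#' @return data.frame, one row per primed site: chrom, pos (1-based
#'   genomic position of the mutable base), cpgPos (C of the dinucleotide),
#'   ref, alt (genomic alleles), gene, regionClass, codonBefore,
#'   codonAfter, consequence, beta
#' @export
enumeratePrimedSites <- function(genome, genes, cgis, siteBetas = NULL,
                                 betaMin = 0.67) {
  coding <- Filter(function(g) g@isCoding, genes)
  rows <- list()
  for (g in coding) {
    cds <- cdsGenomicPositions(g)
    if (length(cds) %% 3L != 0L) {
      .warnf("gene %s: CDS length %d not divisible by 3; skipped",
             g@name, length(cds))
      next
    }
    s <- .chromSeq(genome, g@chrom)
    L <- length(s)
    gpos <- sort(cds)
    base <- as.character(Biostrings::Views(s, gpos, gpos))
    nxt <- ifelse(gpos < L,
                  as.character(Biostrings::Views(s, pmin(gpos + 1L, L),
                                                 pmin(gpos + 1L, L))), "")
    prv <- ifelse(gpos > 1L,
                  as.character(Biostrings::Views(s, pmax(gpos - 1L, 1L),
                                                 pmax(gpos - 1L, 1L))), "")
    isCpG_C <- base == "C" & nxt == "G"
    isCpG_G <- base == "G" & prv == "C"
    sel <- which(isCpG_C | isCpG_G)
    if (!length(sel)) next
    # whole-CDS codon table in transcript orientation
    txBase <- as.character(Biostrings::Views(s, cds, cds))
    if (g@strand == "-") txBase <- .complement(txBase)
    codMat <- matrix(txBase, nrow = 3L)
    codStr <- apply(codMat, 2, paste, collapse = "")
    idx <- match(gpos[sel], cds)
    ci <- (idx - 1L) %/% 3L
    offset <- (idx - 1L) %% 3L
    before <- codStr[ci + 1L]
    # genomic C>T maps to transcript C>T (+) or G>A (-); either way the
    # transcript base is C or G and mutates C->T / G->A
    refT <- substring(before, offset + 1L, offset + 1L)
    altT <- ifelse(refT == "C", "T", "A")
    after <- before
    substring(after, offset + 1L, offset + 1L) <- altT
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g@chrom, pos = gpos[sel],
      cpgPos = ifelse(isCpG_C[sel], gpos[sel], gpos[sel] - 1L),
      ref = base[sel], alt = ifelse(base[sel] == "C", "T", "A"),
      gene = g@name, codonBefore = before, codonAfter = after,
      consequence = codonConsequence(before, after),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        cpgPos = integer(0), ref = character(0),
                        alt = character(0), gene = character(0),
                        regionClass = character(0), codonBefore = character(0),
                        codonAfter = character(0), consequence = character(0),
                        beta = numeric(0))
    attr(empty, "byTranscript") <- empty
    return(empty)
  }
  long <- do.call(rbind, rows)

  # region class from the CpG site's island membership
  siteGR <- GenomicRanges::GRanges(long$chrom, IRanges::IRanges(long$cpgPos,
                                                                long$cpgPos))
  ov <- GenomicRanges::findOverlaps(siteGR, cgis, select = "first")
  cls <- as.character(cgis$cgiClass)[ov]
  long$regionClass <- ifelse(is.na(cls), "NON_CGI",
                             ifelse(cls %in% c("TSS_CODING", "TSS_NONCODING"),
                                    "TSS_CGI",
                                    ifelse(cls %in% c("INTRAGENIC_CODING",
                                                      "INTRAGENIC_NONCODING"),
                                           "INTRAGENIC_CGI", "OTHER_CGI")))
  excludedCGI <- sum(long$regionClass == "OTHER_CGI")
  long <- long[long$regionClass != "OTHER_CGI", , drop = FALSE]

  if (!is.null(siteBetas)) {
    idx <- match(paste(long$chrom, long$cpgPos, sep = "\r"),
                 paste(siteBetas$chrom, siteBetas$pos, sep = "\r"))
    long$beta <- siteBetas$beta[idx]
  } else {
    long$beta <- NA_real_
  }
  if (!is.null(betaMin) && !is.null(siteBetas))
    long <- long[!is.na(long$beta) & long$beta >= betaMin, , drop = FALSE]

  # per-site severity-max dedup
  key <- paste(long$chrom, long$pos, sep = "\r")
  o <- order(key, -.SEVERITY[long$consequence])
  perSite <- long[o, ][!duplicated(key[o]), , drop = FALSE]
  perSite <- perSite[order(perSite$chrom, perSite$pos), , drop = FALSE]
  rownames(perSite) <- NULL
  attr(perSite, "byTranscript") <- long
  attr(perSite, "excludedCGI") <- excludedCGI
  perSite
}

#' Cross primed sites with an observed variant catalogue
#'
#' A primed site is observed iff an event exists at exactly its genomic
#' position with the matching ref and alt alleles. Events at a primed
#' position with a mismatching alt are ignored and counted.
#'
#' @param primed data.frame from \code{enumeratePrimedSites}
#' @param events GRanges of variant events with ref, alt, ac
#' @return primed with columns observed (logical) and ac (NA when
#'   unobserved); attribute "mismatched" counts positional hits with the
#'   wrong allele
#' @export
crossWithObserved <- function(primed, events) {
  evKey <- paste(as.character(GenomicRanges::seqnames(events)),
                 GenomicRanges::start(events), events$ref, events$alt,
                 sep = "\r")
  pKey <- paste(primed$chrom, primed$pos, primed$ref, primed$alt, sep = "\r")
  idx <- match(pKey, evKey)
  primed$observed <- !is.na(idx)
  primed$ac <- events$ac[idx]
  posOnly <- match(paste(primed$chrom, primed$pos, sep = "\r"),
                   paste(as.character(GenomicRanges::seqnames(events)),
                         GenomicRanges::start(events), sep = "\r"))
  attr(primed, "mismatched") <- sum(!is.na(posOnly) & is.na(idx))
  primed
}

#' Observed proportion per consequence and region class
#'
#' @param primed data.frame from \code{crossWithObserved}
#' @return a \code{RateTable} with strata "<region>|<consequence>", rate =
#'   fraction of primed sites observed as variants
#' @export
observedProportions <- function(primed) {
  strat <- paste(primed$regionClass, primed$consequence, sep = "|")
  rt <- mutationRate(list(mutated = primed$observed), strat)
  rt@kind <- "observed_proportion"
  rt
}

#' Allele-count bins for the consequence spectrum
#'
#' @return data.frame with columns label, lower, upper (closed bounds over
#'   positive allele counts)
#' @export
acBins <- function() {
  data.frame(label = c("AC=1", "AC=2", "AC 3-5", "AC>5"),
             lower = c(1L, 2L, 3L, 6L),
             upper = c(1L, 2L, 5L, .Machine$integer.max),
             stringsAsFactors = FALSE)
}

#' Allele-count spectrum per consequence class
#'
#' Within each consequence class, the proportions of observed sites per
#' allele-count bin (summing to 1).
#'
#' @param primed data.frame from \code{crossWithObserved}
#' @param bins bin definition from \code{acBins}
#' @param by additionally split by region class
#' @return data.frame with columns (regionClass,) consequence, bin, count,
#'   proportion
#' @export
acSpectrum <- function(primed, bins = acBins(), by = NULL) {
  obs <- primed[primed$observed & !is.na(primed$ac), , drop = FALSE]
  binOf <- function(ac) {
    lab <- rep(NA_character_, length(ac))
    for (i in seq_len(nrow(bins)))
      lab[ac >= bins$lower[i] & ac <= bins$upper[i] & is.na(lab)] <-
        bins$label[i]
    factor(lab, levels = bins$label)
  }
  grp <- if (is.null(by)) obs$consequence else
    paste(obs[[by]], obs$consequence, sep = "|")
  tab <- table(grp, binOf(obs$ac))
  out <- do.call(rbind, lapply(rownames(tab), function(g) {
    cnt <- tab[g, ]
    data.frame(consequence = g, bin = colnames(tab),
               count = as.integer(cnt),
               proportion = if (sum(cnt) > 0) as.numeric(cnt / sum(cnt))
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
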