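# genePred-style gene model I/O
#
# Columns: name chrom strand txStart txEnd cdsStart cdsEnd exonCount
# exonStarts exonEnds [isCoding]. File coordinates are 0-based half-open
# (UCSC convention); in memory everything is 1-based closed. A noncoding
# transcript has cdsStart == cdsEnd in the file.

#' Read gene models from a genePred file
#'
#' @param path tab-separated genePred file (no header), UCSC column order:
#'   name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount,
#'   exonStarts, exonEnds (comma-separated lists)
#' @return list of \code{GeneModel}
#' @export
readGenePred <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 10) .stopf("genePred file needs >= 10 columns, got %d", ncol(df))
  names(df)[1:10] <- c("name", "chrom", "strand", "txStart", "txEnd",
                       "cdsStart", "cdsEnd", "exonCount", "exonStarts",
                       "exonEnds")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    es <- as.integer(strsplit(r$exonStarts, ",")[[1]]) + 1L
    ee <- as.integer(strsplit(r$exonEnds, ",")[[1]])
    coding <- r$cdsEnd > r$cdsStart
    GeneModel(name = r$name, chrom = r$chrom, strand = r$strand,
              txStart = r$txStart + 1L, txEnd = r$txEnd,
              cdsStart = if (coding) r$cdsStart + 1L else NA_integer_,
              cdsEnd = if (coding) r$cdsEnd else NA_integer_,
              exonStarts = es, exonEnds = ee, isCoding = coding)
  })
}

#' Write gene models to a genePred file
#'
#' @param genes list of \code{GeneModel}
#' @param path output path
#' @return the path, invisibly
#' @export
writeGenePred <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    cs <- if (g@isCoding) g@cdsStart - 1L else g@txEnd
    ce <- if (g@isCoding) g@cdsEnd else g@txEnd
    paste(g@name, g@chrom, g@strand, g@txStart - 1L, g@txEnd, cs, ce,
          length(g@exons),
          paste0(paste(IRanges::start(g@exons) - 1L, collapse = ","), ","),
          paste0(paste(IRanges::end(g@exons), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse transcript records sharing a gene key
#'
#' RefSeq-style annotation carries several transcripts per gene symbol;
#' for CGI classification these are collapsed to one record per
#' (name, chrom, strand) by the union of transcript intervals, coding if
#' any transcript is coding. This avoids isoforms that share a TSS pushing
#' their island into the miscellaneous class.
#'
#' @param genes list of \code{GeneModel}
#' @return data.frame with one row per collapsed gene: name, chrom, strand,
#'   txStart, txEnd, isCoding, tss (1-based position of the TSS)
#' @export
collapseGenes <- function(genes) {
  if (length(genes) == 0)
    return(data.frame(name = character(0), chrom = character(0),
                      strand = character(0), txStart = integer(0),
                      txEnd = integer(0), isCoding = logical(0),
                      tss = integer(0)))
  key <- vapply(genes, function(g) paste(g@name, g@chrom, g@strand, sep = "\r"),
                character(1))
  out <- lapply(split(genes, key), function(gs) {
    g1 <- gs[[1]]
    txStart <- min(vapply(gs, function(g) g@txStart, integer(1)))
    txEnd <- max(vapply(gs, function(g) g@txEnd, integer(1)))
    data.frame(name = g1@name, chrom = g1@chrom, strand = g1@strand,
               txStart = txStart, txEnd = txEnd,
               isCoding = any(vapply(gs, function(g) g@isCoding, logical(1))),
               tss = if (g1@strand == "+") txStart else txEnd,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$txStart), , drop = FALSE]
}

#' Union of CDS exon intervals across genes
#'
#' @param genes list of \code{GeneModel}
#' @return a \link[GenomicRanges]{GRanges} of merged coding-exon intervals
#' @export
codingExonRanges <- function(genes) {
  coding <- Filter(function(g) g@isCoding, genes)
  if (length(coding) == 0)
    return(GenomicRanges::GRanges())
  grl <- lapply(coding, function(g) {
    ex <- IRanges::restrict(g@exons, start = g@cdsStart, end = g@cdsEnd)
    ex <- ex[IRanges::width(ex) > 0]
    GenomicRanges::GRanges(g@chrom, ex)
  })
  GenomicRanges::reduce(do.call(c, grl))
}
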