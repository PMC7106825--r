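#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' The five functional CGI classes plus the miscellaneous bucket
#'
#' Islands overlapping a transcription start site (within +/-100 bp) are
#' TSS-coding or TSS-noncoding depending on the gene biotype; islands inside
#' a transcript body but away from its TSS are intragenic; islands touching
#' no gene are intergenic; islands collecting more than one distinct label
#' from different genes are miscellaneous.
#'
#' @export
CGI_CLASSES <- c("TSS_CODING", "TSS_NONCODING", "INTRAGENIC_CODING",
                 "INTRAGENIC_NONCODING", "INTERGENIC", "MISC")

#' Gene model (genePred-style transcript)
#'
#' A single transcript with its exon structure and coding-region bounds.
#' Coordinates are 1-based closed (Bioconductor convention); genePred input
#' (0-based half-open) is converted on read.
#'
#' @slot name transcript or gene identifier
#' @slot chrom chromosome name
#' @slot strand "+" or "-"
#' @slot txStart,txEnd transcript bounds, 1-based closed
#' @slot cdsStart,cdsEnd coding-region bounds (NA for noncoding genes)
#' @slot exons an \link[IRanges]{IRanges} of exon intervals, sorted
#' @slot isCoding TRUE for protein-coding transcripts
#' @export
setClass("GeneModel", representation(
  name = "character", chrom = "character", strand = "character",
  txStart = "integer", txEnd = "integer",
  cdsStart = "integer", cdsEnd = "integer",
  exons = "IRanges", isCoding = "logical"))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  st <- IRanges::start(object@exons); en <- IRanges::end(object@exons)
  if (length(st) == 0L) msg <- c(msg, "at least one exon required")
  if (is.unsorted(st, strictly = TRUE) && length(st) > 1L)
    msg <- c(msg, "exons must be sorted by start")
  if (length(st) > 1L && any(st[-1L] <= en[-length(en)]))
    msg <- c(msg, "exons must not overlap")
  if (length(st) && (min(st) < object@txStart || max(en) > object@txEnd))
    msg <- c(msg, "exons must lie within transcript bounds")
  if (object@isCoding) {
    if (is.na(object@cdsStart) || is.na(object@cdsEnd))
      msg <- c(msg, "coding gene requires CDS bounds")
    else if (object@cdsStart < object@txStart || object@cdsEnd > object@txEnd)
      msg <- c(msg, "CDS bounds must lie within transcript bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param name,chrom,strand transcript identifier, chromosome and strand
#' @param txStart,txEnd transcript bounds (1-based closed)
#' @param cdsStart,cdsEnd CDS bounds (1-based closed); NA for noncoding
#' @param exonStarts,exonEnds integer vectors of exon bounds (1-based closed)
#' @param isCoding logical; defaults to TRUE when CDS bounds are given
#' @return a \code{GeneModel}
#' @export
GeneModel <- function(name, chrom, strand, txStart, txEnd,
                      cdsStart = NA_integer_, cdsEnd = NA_integer_,
                      exonStarts = txStart, exonEnds = txEnd,
                      isCoding = !is.na(cdsStart)) {
  new("GeneModel", name = as.character(name), chrom = as.character(chrom),
      strand = strand, txStart = as.integer(txStart), txEnd = as.integer(txEnd),
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
      exons = IRanges::IRanges(as.integer(exonStarts), as.integer(exonEnds)),
      isCoding = isCoding)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s %s:%d-%d(%s) %s, %d exon(s)\n",
              object@name, object@chrom, object@txStart, object@txEnd,
              object@strand, if (object@isCoding) "coding" else "noncoding",
              length(object@exons)))
})

#' Accessors for GeneModel
#' @param x a GeneModel
#' @name GeneModel-accessors
#' @export
geneName <- function(x) x@name
#' @rdname GeneModel-accessors
#' @export
geneStrand <- function(x) x@strand
#' @rdname GeneModel-accessors
#' @export
geneIsCoding <- function(x) x@isCoding
#' @rdname GeneModel-accessors
#' @export
geneExons <- function(x) x@exons

#' Stratified rate table
#'
#' Rows keyed by stratum; each row carries the numerator (mutated-site count
#' or allele-frequency sum), the denominator (total sites), the rate and a
#' 95\% confidence interval (Wilson score for count-based rates; NA for
#' weighted rates).
#'
#' @slot table a data.frame with columns stratum, numerator, denominator,
#'   rate, ciLow, ciHigh
#' @slot kind a label such as "mutation_rate" or "af_weighted"
#' @export
setClass("RateTable", representation(table = "data.frame", kind = "character"))

setValidity("RateTable", function(object) {
  tb <- object@table
  need <- c("stratum", "numerator", "denominator", "rate", "ciLow", "ciHigh")
  if (!all(need %in% names(tb))) return("missing rate-table columns")
  ok <- is.na(tb$rate) | (tb$rate >= 0 & tb$rate <= 1)
  if (!all(ok)) return("rates must lie in [0, 1]")
  TRUE
})

setMethod("show", "RateTable", function(object) {
  cat(sprintf("RateTable (%s) with %d strata\n", object@kind,
              nrow(object@table)))
  print(utils::head(object@table, 10))
  if (nrow(object@table) > 10) cat("...\n")
})

#' Coerce a RateTable to data.frame
#' @param x a RateTable
#' @param ... ignored
#' @return the underlying data.frame
#' @method as.data.frame RateTable
#' @export
as.data.frame.RateTable <- function(x, ...) x@table

setMethod("as.data.frame", "RateTable",
          function(x, ...) x@table)

#' @param x a RateTable
#' @rdname RateTable-class
#' @export
rateKind <- function(x) x@kind

#' 96-channel trinucleotide substitution spectrum
#'
#' Counts indexed by the six pyrimidine substitution classes crossed with
#' the 16 flanking-base combinations, in the conventional channel order
#' (A[C>A]A, A[C>A]C, ...).
#'
#' @slot counts named numeric vector of length 96
#' @slot skipped number of events dropped for N-containing contexts
#' @export
setClass("MutationSpectrum",
         representation(counts = "numeric", skipped = "integer"))

setValidity("MutationSpectrum", function(object) {
  if (length(object@counts) != 96L) return("spectrum must have 96 channels")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (!identical(names(object@counts), spectrumChannels()))
    return("channel names must follow the canonical 96-channel order")
  TRUE
})

setMethod("show", "MutationSpectrum", function(object) {
  tot <- sum(object@counts)
  cls <- substr(names(object@counts), 3, 5)
  cat(sprintf("MutationSpectrum: %d events (%d skipped for N-context)\n",
              tot, object@skipped))
  print(round(tapply(object@counts, cls, sum) / max(tot, 1), 4))
})

#' @param x a MutationSpectrum
#' @rdname MutationSpectrum-class
#' @export
spectrumCounts <- function(x) x@counts

#' @rdname MutationSpectrum-class
#' @export
spectrumTotal <- function(x) sum(x@counts)

#' Signature decomposition result
#'
#' Nonnegative signature weights (summing to 1 over retained signatures)
#' fitted to a normalized 96-channel spectrum, after pruning signatures
#' explaining less than the threshold fraction and refitting.
#'
#' @slot weights named weights of the retained signatures (sum to 1)
#' @slot fullWeights weights of the initial (unpruned) fit
#' @slot residualNorm L2 residual of the final (pruned, refit) model
#' @slot fullResidualNorm L2 residual of the initial full fit
#' @slot pruneThreshold the pruning threshold applied
#' @export
setClass("DecompositionResult", representation(
  weights = "numeric", fullWeights = "numeric",
  residualNorm = "numeric", fullResidualNorm = "numeric",
  pruneThreshold = "numeric"))

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf("DecompositionResult: %d signature(s) retained (threshold %.3g)\n",
              length(object@weights), object@pruneThreshold))
  print(round(sort(object@weights, decreasing = TRUE), 4))
  cat(sprintf("residual %.4g (full fit %.4g)\n", object@residualNorm,
              object@fullResidualNorm))
})

#' @param x a DecompositionResult
#' @rdname DecompositionResult-class
#' @export
signatureWeights <- function(x) x@weights

#' @rdname DecompositionResult-class
#' @export
residualNorm <- function(x) x@residualNorm
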