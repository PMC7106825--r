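# 96-channel spectrum construction and signature decomposition by
# non-negative least squares with >=1% pruning and refit.

#' Build a 96-channel spectrum from rare events
#'
#' Each event is assigned to a channel via its trinucleotide context in the
#' pyrimidine convention (the reference allele of a rare variant is taken
#' as ancestral). Events whose context contains N are skipped and counted.
#'
#' @param events GRanges of SNV events with ref/alt metadata (typically
#'   after \code{rareFilter})
#' @param genome DNAStringSet
#' @return a \code{MutationSpectrum}
#' @export
buildSpectrum <- function(events, genome) {
  channels <- spectrumChannels()
  counts <- stats::setNames(numeric(96), channels)
  skipped <- 0L
  chrom <- as.character(GenomicRanges::seqnames(events))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ctx <- trinucleotideContext(genome, ch, GenomicRanges::start(events)[idx],
                                events$ref[idx], events$alt[idx])
    skipped <- skipped + sum(!ctx$ok)
    tab <- table(ctx$channel[ctx$ok])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  new("MutationSpectrum", counts = counts, skipped = skipped)
}

#' Construct a spectrum from raw channel counts
#'
#' @param counts numeric vector of 96 counts, named by channel (any order)
#'   or unnamed in the canonical order
#' @return a \code{MutationSpectrum}
#' @export
asSpectrum <- function(counts) {
  channels <- spectrumChannels()
  if (is.null(names(counts))) {
    names(counts) <- channels
  } else {
    if (!setequal(names(counts), channels))
      .stopf("counts must be named by the 96 canonical channels")
    counts <- counts[channels]
  }
  new("MutationSpectrum",
      counts = stats::setNames(as.numeric(counts), channels),
      skipped = 0L)
}

#' Read a signature matrix from TSV
#'
#' Expected layout: first column the 96 context labels ("A[C>T]G" style),
#' remaining columns one signature each, header row with signature names.
#'
#' @param path TSV file
#' @return 96 x K numeric matrix, rows in canonical channel order, columns
#'   renormalized to sum to 1
#' @export
readSignatureMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  lab <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != 96L) .stopf("signature matrix must have 96 rows, got %d",
                             nrow(m))
  rownames(m) <- lab
  channels <- spectrumChannels()
  if (!setequal(lab, channels))
    .stopf("signature matrix row labels must be the 96 canonical channels")
  m <- m[channels, , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Write a signature matrix to TSV
#' @param m 96 x K matrix with canonical rownames
#' @param path output path
#' @return the path, invisibly
#' @export
writeSignatureMatrix <- function(m, path) {
  df <- data.frame(Context = rownames(m), m, check.names = FALSE)
  .writeTSV(df, path)
}

#' Synthetic signature matrix
#'
#' A deterministic 96 x K probability matrix for demonstrations and
#' closed-loop tests (this is a synthetic stand-in, not the COSMIC
#' catalogue). Signature 1 emulates 5-methylcytosine deamination: most of
#' its mass sits on the four N[C>T]G channels. The remaining columns are
#' sparse random profiles drawn from a fixed internal RNG stream, so the
#' matrix depends only on \code{K} and \code{seed}.
#'
#' @param K number of signatures (default 30)
#' @param seed internal RNG seed (default 20201)
#' @return 96 x K matrix, columns summing to 1, named "Signature 1" ...
#' @export
syntheticSignatures <- function(K = 30L, seed = 20201L) {
  channels <- spectrumChannels()
  m <- matrix(0, 96L, K, dimnames = list(channels,
                                         paste("Signature", seq_len(K))))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # deamination-like column: 76% of mass on N[C>T]G
  s1 <- rep(0.08 / 92, 96)
  ncg <- grep("\\[C>T\\]G$", channels)
  s1[ncg] <- 0.19
  s1[setdiff(grep("\\[C>T\\]", channels), ncg)] <- 0.16 / 12
  m[, 1] <- s1 / sum(s1)
  for (k in seq_len(K)[-1]) {
    x <- stats::rgamma(96, shape = 0.15)
    m[, k] <- x / sum(x)
  }
  m
}

# nonnegative least squares of b on columns of A
.nnls <- function(A, b) {
  fit <- pracma::lsqnonneg(A, b)
  x <- fit$x
  res <- sqrt(sum((A %*% x - b)^2))
  list(x = x, residual = res)
}

#' Decompose a spectrum against a signature matrix
#'
#' The spectrum is normalized to a probability vector and fitted to the
#' signature columns by nonnegativity-constrained least squares; weights
#' are renormalized to sum to 1. Signatures explaining less than
#' \code{pruneThreshold} of the total are dropped and the model refit on
#' the retained subset, iterating to a fixed point. An unconstrained
#' ordinary-least-squares mode (weights may be negative) is available for
#' comparison via \code{constrained = FALSE}.
#'
#' @param spectrum a \code{MutationSpectrum} (or numeric 96-vector)
#' @param signatures 96 x K signature matrix (columns sum to 1)
#' @param pruneThreshold minimum retained weight (default 0.01)
#' @param constrained use NNLS (default TRUE)
#' @return a \code{DecompositionResult}
#' @export
decomposeSpectrum <- function(spectrum, signatures, pruneThreshold = 0.01,
                              constrained = TRUE) {
  counts <- if (methods::is(spectrum, "MutationSpectrum"))
    spectrumCounts(spectrum) else spectrum
  if (sum(counts) <= 0) .stopf("all-zero spectrum cannot be decomposed")
  if (is.null(dim(signatures)) || ncol(signatures) == 0L)
    .stopf("signature matrix must have at least one column")
  p <- counts / sum(counts)
  A <- as.matrix(signatures)

  solve1 <- function(Asub) {
    if (constrained) .nnls(Asub, p)
    else {
      x <- stats::lm.fit(Asub, p)$coefficients
      x[is.na(x)] <- 0
      list(x = unname(x), residual = sqrt(sum((Asub %*% x - p)^2)))
    }
  }

  full <- solve1(A)
  if (sum(full$x) <= 0) .stopf("degenerate fit: all weights zero")
  fullW <- stats::setNames(full$x / sum(full$x), colnames(A))

  keep <- seq_len(ncol(A))
  w <- fullW
  res <- full$residual
  repeat {
    retain <- which(abs(w) >= pruneThreshold)
    if (length(retain) == 0L) {
      retain <- which.max(abs(w))  # always keep the dominant signature
    }
    if (length(retain) == length(w)) break
    keep <- keep[retain]
    fit <- solve1(A[, keep, drop = FALSE])
    res <- fit$residual
    w <- stats::setNames(fit$x / sum(fit$x), colnames(A)[keep])
  }
  new("DecompositionResult", weights = w, fullWeights = fullW,
      residualNorm = res, fullResidualNorm = full$residual,
      pruneThreshold = pruneThreshold)
}
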