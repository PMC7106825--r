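#' Load a reference genome from FASTA
#'
#' Reads a (optionally indexed) FASTA into a \link[Biostrings]{DNAStringSet}.
#' Sequence names are truncated at the first whitespace. Soft-masked
#' (lowercase) bases are uppercased so repeat sequence participates in
#' matching like any other sequence; hard-masked N remains unmatchable.
#'
#' @param path FASTA file
#' @param chroms optional character vector restricting (and ordering) the
#'   chromosomes kept, e.g. the 24 conventional human chromosomes. Unknown
#'   names are an error.
#' @return a \code{DNAStringSet}
#' @export
readGenome <- function(path, chroms = NULL) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (!is.null(chroms)) {
    missing <- setdiff(chroms, names(g))
    if (length(missing))
      .stopf("chromosome(s) not in FASTA: %s", paste(missing, collapse = ", "))
    g <- g[chroms]
  }
  # uppercase soft-masked sequence
  Biostrings::DNAStringSet(toupper(as.character(g)))
}

#' Names of the conventional human chromosomes
#'
#' @param present chromosome names available in a genome
#' @param includeY keep chrY (dropped for allele-frequency analyses)
#' @return the subset of \code{present} that is a conventional autosome or
#'   sex chromosome, in karyotype order; both "chr1" and "1" styles accepted
#' @export
conventionalChroms <- function(present, includeY = TRUE) {
  base <- c(as.character(1:22), "X", if (includeY) "Y")
  wanted <- c(paste0("chr", base), base)
  keep <- wanted[wanted %in% present]
  keep
}

# character sequence of one chromosome, validated
.chromSeq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    .stopf("unknown chromosome '%s'", chrom)
  genome[[chrom]]
}

#' Substring of a chromosome (1-based closed coordinates)
#' @param genome a DNAStringSet
#' @param chrom chromosome name
#' @param start,end 1-based closed bounds
#' @return uppercase nucleotide string
#' @export
genomeSlice <- function(genome, chrom, start, end) {
  s <- .chromSeq(genome, chrom)
  if (start < 1L || end > length(s) || start > end)
    .stopf("slice %s:%d-%d outside chromosome bounds (length %d)",
           chrom, start, end, length(s))
  as.character(Biostrings::subseq(s, start, end))
}

#' Enumerate CpG dinucleotides
#'
#' Emits one record per plus-strand "CG" occurrence; the palindromic G on
#' the reverse strand is part of the same site, not a second one. Positions
#' containing N never match. Sites are returned in coordinate order.
#'
#' @param genome a \code{DNAStringSet}
#' @param chroms optional chromosome subset; unknown names are an error
#' @return a \link[GenomicRanges]{GRanges} of width-2 ranges whose start is
#'   the C of each CpG (1-based)
#' @export
enumerateCpGSites <- function(genome, chroms = NULL) {
  if (is.null(chroms)) chroms <- names(genome)
  bad <- setdiff(chroms, names(genome))
  if (length(bad))
    .stopf("unknown chromosome '%s'", bad[1])
  grl <- lapply(chroms, function(ch) {
    m <- Biostrings::matchPattern("CG", genome[[ch]])
    GenomicRanges::GRanges(factor(rep(ch, length(m)), levels = chroms),
                           IRanges::ranges(m))
  })
  gr <- do.call(c, grl)
  GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(Biostrings::width(genome)[match(
      GenomeInfoDb::seqlevels(gr), names(genome))],
      GenomeInfoDb::seqlevels(gr))
  gr
}

#' Canonical 96-channel labels
#'
#' Channel order: the six pyrimidine substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G), within each class the 16 flanking combinations ordered
#' by 5' then 3' base (A[C>A]A, A[C>A]C, ...).
#'
#' @return character vector of 96 labels like "A[C>T]G"
#' @export
spectrumChannels <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(classes, function(cl)
    as.vector(t(outer(.BASES, .BASES,
                      function(p5, p3) sprintf("%s[%s]%s", p5, cl, p3))))))
}

#' Trinucleotide context and pyrimidine substitution class
#'
#' Returns the 3-mer centred on the mutated base and the substitution in
#' the standard 96-channel convention: when the reference base is a purine,
#' context and substitution are reverse-complemented so the mutated base is
#' reported as a pyrimidine.
#'
#' @param genome a DNAStringSet
#' @param chrom chromosome (scalar)
#' @param pos 1-based positions of the mutated bases
#' @param ref,alt single reference/alternate bases (vectorized)
#' @return data.frame with columns context, class, channel, ok (FALSE when
#'   the context contains N; such events carry NA context and should be
#'   skipped, not raised)
#' @export
trinucleotideContext <- function(genome, chrom, pos, ref, alt) {
  s <- .chromSeq(genome, chrom)
  if (any(pos < 2L) || any(pos > length(s) - 1L))
    .stopf("position without full trinucleotide context on %s", chrom)
  ctx <- as.character(Biostrings::Views(s, start = pos - 1L, end = pos + 1L))
  centre <- substr(ctx, 2, 2)
  mism <- centre != ref & centre != "N"
  if (any(mism))
    .stopf("reference mismatch at %s:%d (genome %s, stated %s)",
           chrom, pos[which(mism)[1]], centre[which(mism)[1]],
           ref[which(mism)[1]])
  ok <- !grepl("N", ctx, fixed = TRUE)
  flip <- ref %in% c("A", "G")
  ctx2 <- ifelse(flip, revcomp(ctx), ctx)
  ref2 <- ifelse(flip, .complement(ref), ref)
  alt2 <- ifelse(flip, .complement(alt), alt)
  cls <- paste0(ref2, ">", alt2)
  channel <- sprintf("%s[%s]%s", substr(ctx2, 1, 1), cls, substr(ctx2, 3, 3))
  data.frame(context = ifelse(ok, ctx2, NA_character_),
             class = ifelse(ok, cls, NA_character_),
             channel = ifelse(ok, channel, NA_character_),
             ok = ok, stringsAsFactors = FALSE)
}

#' Genomic positions of a gene's CDS in transcript (5'->3') order
#'
#' @param gene a \code{GeneModel} (coding)
#' @return integer vector of 1-based genomic positions; for minus-strand
#'   genes the vector runs from the rightmost CDS base leftwards
#' @export
cdsGenomicPositions <- function(gene) {
  if (!gene@isCoding) .stopf("gene %s has no CDS", gene@name)
  ex <- IRanges::restrict(gene@exons, start = gene@cdsStart, end = gene@cdsEnd)
  ex <- ex[IRanges::width(ex) > 0]
  pos <- unlist(lapply(seq_along(ex), function(i)
    seq.int(IRanges::start(ex)[i], IRanges::end(ex)[i])))
  if (gene@strand == "-") rev(pos) else pos
}

#' Codon containing a genomic position, in transcript orientation
#'
#' Codons are read across exon junctions on the coding strand. For
#' minus-strand genes bases are complemented and read right-to-left.
#'
#' @param genome a DNAStringSet
#' @param gene a coding \code{GeneModel} with CDS length divisible by 3
#'   (otherwise a warning is raised and NULL returned)
#' @param pos 1-based genomic position inside the CDS (scalar)
#' @return list(codon = 3-mer, offset = 0..2 position of \code{pos} within
#'   the codon, codonIndex = 0-based codon number)
#' @export
codonAt <- function(genome, gene, pos) {
  cds <- cdsGenomicPositions(gene)
  if (length(cds) %% 3L != 0L) {
    .warnf("gene %s: CDS length %d not divisible by 3; skipped",
           gene@name, length(cds))
    return(NULL)
  }
  idx <- match(pos, cds)
  if (is.na(idx))
    .stopf("position %s:%d outside the CDS of %s", gene@chrom, pos, gene@name)
  ci <- (idx - 1L) %/% 3L
  offset <- (idx - 1L) %% 3L
  codPos <- cds[(ci * 3L + 1L):(ci * 3L + 3L)]
  s <- .chromSeq(genome, gene@chrom)
  bases <- as.character(Biostrings::Views(s, start = codPos, end = codPos))
  if (gene@strand == "-") bases <- .complement(bases)
  list(codon = paste(bases, collapse = ""), offset = offset, codonIndex = ci)
}
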