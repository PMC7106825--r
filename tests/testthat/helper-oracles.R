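# Independent oracles, deliberately naive: these recompute expected values
# by direct definition, separate from the package's code paths.

# genome from plain strings
strGenome <- function(...) {
  s <- c(...)
  g <- Biostrings::DNAStringSet(unlist(s))
  if (is.null(names(s))) names(g) <- paste0("chr", seq_along(s))
  g
}

# naive CG scan: positions (1-based) of "CG" by substring comparison
naiveCpGScan <- function(seq) {
  n <- nchar(seq)
  if (n < 2) return(integer(0))
  which(vapply(seq_len(n - 1),
               function(i) substr(seq, i, i + 1) == "CG", logical(1)))
}

# reverse complement of a string, base R only
rcStr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# brute-force Gardiner-Garden caller: score every window by explicit
# per-window counting over the character vector (no running sums), merge
# qualifying windows, re-score merged segments
bruteCGI <- function(seq, window = 200, minGC = 0.5, minOE = 0.6,
                     minLength = 200) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  score <- function(a, b) {
    seg <- chars[a:b]
    L <- b - a + 1
    nC <- sum(seg == "C")
    nG <- sum(seg == "G")
    nCpG <- sum(seg[-L] == "C" & seg[-1] == "G")
    gc <- (nC + nG) / L
    oe <- if (nC > 0 && nG > 0) nCpG * L / (nC * nG) else 0
    c(gc = gc, oe = oe)
  }
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  qual <- integer(0)
  for (i in seq_len(n - window + 1)) {
    sc <- score(i, i + window - 1)
    if (sc["gc"] >= minGC && sc["oe"] > minOE) qual <- c(qual, i)
  }
  if (!length(qual)) return(data.frame(start = integer(0), end = integer(0)))
  # merge overlapping/adjacent qualifying windows
  st <- qual[1]; en <- qual[1] + window - 1
  out <- NULL
  for (i in qual[-1]) {
    if (i <= en + 1) en <- max(en, i + window - 1)
    else { out <- rbind(out, c(st, en)); st <- i; en <- i + window - 1 }
  }
  out <- rbind(out, c(st, en))
  keep <- apply(out, 1, function(r) {
    sc <- score(r[1], r[2])
    sc["gc"] >= minGC && sc["oe"] > minOE && (r[2] - r[1] + 1) > minLength
  })
  data.frame(start = out[keep, 1, drop = TRUE], end = out[keep, 2, drop = TRUE])
}

# full-transcript translate-and-diff consequence oracle: splice the CDS,
# substitute the base, translate both proteins end to end, compare
oracleConsequence <- function(genome, gene, pos, altPlus) {
  chrom <- as.character(genome[[gene@chrom]])
  ex <- IRanges::restrict(geneExons(gene), start = gene@cdsStart,
                          end = gene@cdsEnd)
  ex <- ex[IRanges::width(ex) > 0]
  splice <- function(seqStr) {
    parts <- vapply(seq_along(ex), function(i)
      substr(seqStr, IRanges::start(ex)[i], IRanges::end(ex)[i]),
      character(1))
    cds <- paste(parts, collapse = "")
    if (geneStrand(gene) == "-") cds <- rcStr(cds)
    cds
  }
  mutChrom <- chrom
  substr(mutChrom, pos, pos) <- altPlus
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(splice(chrom)),
                                           no.init.codon = TRUE))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(splice(mutChrom)),
                                           no.init.codon = TRUE))
  if (p0 == p1) return("SILENT")
  diffAt <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
  if (substr(p1, diffAt, diffAt) == "*") return("NONSENSE")
  "MISSENSE"
}

# random multi-exon gene over a random genome; returns list(genome, gene)
randomGeneModel <- function(chromLen = 600, maxExons = 3) {
  seq <- paste(sample(c("A", "C", "G", "T"), chromLen, replace = TRUE,
                      prob = c(0.25, 0.22, 0.28, 0.25)), collapse = "")
  genome <- strGenome(chr1 = seq)
  strand <- sample(c("+", "-"), 1)
  nEx <- sample(seq_len(maxExons), 1)
  # lay exons left to right with gaps
  cur <- sample(20:60, 1)
  exS <- exE <- integer(nEx)
  for (i in seq_len(nEx)) {
    exS[i] <- cur
    exE[i] <- cur + sample(30:120, 1)
    cur <- exE[i] + sample(10:40, 1)
  }
  if (exE[nEx] > chromLen - 10) return(randomGeneModel(chromLen, maxExons))
  cdsStart <- exS[1] + sample(0:10, 1)
  # choose cdsEnd for CDS %% 3 == 0
  for (cdsEnd in (exE[nEx] - sample(0:5, 1)):(cdsStart + 6)) {
    ex <- IRanges::restrict(IRanges::IRanges(exS, exE), cdsStart, cdsEnd)
    w <- sum(IRanges::width(ex))
    if (w %% 3 == 0 && w >= 9) break
  }
  gene <- GeneModel("g", "chr1", strand, exS[1], exE[nEx], cdsStart, cdsEnd,
                    exS, exE, TRUE)
  list(genome = genome, gene = gene)
}

# exhaustive constrained least squares for K = 2 columns: check the
# unconstrained solution and both single-column boundary fits
nnlsOracle2 <- function(A, b) {
  cand <- list()
  x <- tryCatch(solve(crossprod(A), crossprod(A, b)), error = function(e) NULL)
  if (!is.null(x) && all(x >= -1e-12)) cand <- c(cand, list(pmax(x, 0)))
  for (j in 1:2) {
    xj <- max(0, sum(A[, j] * b) / sum(A[, j]^2))
    v <- c(0, 0); v[j] <- xj
    cand <- c(cand, list(matrix(v)))
  }
  resid <- vapply(cand, function(x) sum((A %*% x - b)^2), numeric(1))
  as.numeric(cand[[which.min(resid)]])
}

# hand Dunn z statistic for a pair, no ties assumed
dunnOracleZ <- function(values, groups, a, b) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  ra <- mean(r[groups == a]); rb <- mean(r[groups == b])
  na <- sum(groups == a); nb <- sum(groups == b)
  (ra - rb) / sqrt((N * (N + 1) / 12 - tc) * (1 / na + 1 / nb))
}
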