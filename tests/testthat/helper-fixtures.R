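# Shared fixtures, built lazily and cached for the whole run.

.fixtureCache <- new.env(parent = emptyenv())

# small bundle for unit-level closed-loop tests (fast)
smallConfig <- function(seed = 11L) {
  syntheticConfig(
    seed = seed, nChroms = 1L, chromLength = 120000L,
    islandsPerChrom = c(TSS_CODING = 2L, TSS_NONCODING = 1L,
                        INTRAGENIC_CODING = 2L, INTRAGENIC_NONCODING = 1L,
                        INTERGENIC = 1L, MISC = 1L))
}

smallBundle <- function() {
  if (is.null(.fixtureCache$small)) {
    dir <- file.path(tempdir(), "cpgscape_small")
    .fixtureCache$small <- generateBundle(smallConfig(), dir)
  }
  .fixtureCache$small
}

# the default demonstration bundle (2 x 500 kb) and its pipeline run
demoBundle <- function() {
  if (is.null(.fixtureCache$demo)) {
    dir <- file.path(tempdir(), "cpgscape_demo")
    .fixtureCache$demo <- generateBundle(syntheticConfig(), dir)
  }
  .fixtureCache$demo
}

demoPipeline <- function() {
  if (is.null(.fixtureCache$demoRun)) {
    b <- demoBundle()
    out <- file.path(tempdir(), "cpgscape_demo_out")
    t0 <- proc.time()[["elapsed"]]
    .fixtureCache$demoRun <- suppressWarnings(
      runPipeline(dirname(b$paths$fasta), out))
    .fixtureCache$demoElapsed <- proc.time()[["elapsed"]] - t0
  }
  .fixtureCache$demoRun
}

demoElapsed <- function() {
  demoPipeline()
  .fixtureCache$demoElapsed
}

# write a minimal VCF for loader tests
writeTestVcf <- function(lines, chromLens = c(chr1 = 1000L),
                         filterDot = FALSE) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chromLens),
                   chromLens),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"ac\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"an\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, lines), path)
  path
}
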