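---
title: "Methods: CpG deamination landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpG deamination landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Methylated cytosines at CpG dinucleotides deaminate spontaneously to
thymine; unrepaired events fix as C:G>T:A transitions, the dominant
single-base process in germline genome evolution. The package treats each
CpG dinucleotide as one mutable unit keyed by the plus-strand C position:
a C>T observation at the C and a G>A observation at the paired G describe
the same underlying event on opposite strands and collapse onto one site.
This dinucleotide counting unit is a deliberate choice (a per-strand-base
unit would double every denominator without changing any rate ordering)
and is applied consistently in numerators and denominators.

Per-site mutation status is a Bernoulli outcome; a stratum rate is the
binomial point estimate mutated/total with a Wilson score interval. The
Wilson interval is preferred over the normal approximation because many
strata of interest (TSS islands) have rates of a few percent where the
Wald interval undercovers; the normal approximation is available via the
`conf` machinery but not used anywhere. The allele-frequency-weighted
rate replaces the 0/1 numerator by the site's population allele
frequency, giving a drift/selection-sensitive companion statistic; it is
bounded above by the plain rate whenever all frequencies are at most 1.

## Island calling and classification

Islands are called by the composition criteria (GC >= 0.5,
observed/expected CpG > 0.6, length > 200 bp) on a 200-bp window sliding
by 1 bp. The window predicate tests the two composition criteria;
qualifying windows are merged when overlapping or adjacent, and each
merged segment is re-scored and kept only if the segment itself passes
all three criteria including length. Re-checking the merged segment is a
design decision: plain unions of qualifying windows can dip below the
thresholds at their extremes. `recheck = FALSE` preserves the raw unions
for comparison. The segmentation is deliberately simple and transparent —
the hidden-Markov variants used by some genome browsers are out of scope,
and ingested BED tracks bypass the criteria entirely.

Classification assigns, per collapsed gene (transcripts united per gene
key so isoform sets sharing a TSS do not inflate the miscellaneous
class): a TSS label when the island intersects the closed ±100 bp window
around the strand-dependent TSS, else a body label when it intersects the
transcript span. The TSS label takes precedence over a body hit from the
same gene — otherwise every TSS island would also be "intragenic" and
degenerate to MISC. Distinct labels from different genes produce MISC;
no gene contact produces INTERGENIC. MISC islands are reported separately
and excluded from five-class tables and from the three consequence
panels.

Signed distances run from a site to the nearest border of the nearest
island: negative at coordinates below the island, positive above, ties
broken toward the lower-coordinate island. The underlying convention is
closed-left/open-right, so the first base after an island sits at
distance 0 and the first base before it at −1; mirroring a chromosome
maps distance d to −(d+1), which the tests assert exactly. Shores are
the up-to-2000-bp flanks, clipped at chromosome ends and at islands so
no base is simultaneously shore and island.

## Rates around borders

The distance-resolved profile is the per-distance rate mutated/total
among sites at that exact signed distance, pooled per CpG (not per
island) over all islands or per nearest-island class. No additional
normalization constant is applied: the "normalized incidence" is the raw
per-site rate, which is already scale-free; the non-CpG control (all C
and reverse-strand-C positions outside CpG context) uses the same
estimator, making the two curves directly comparable. Profiles are
smoothed in non-overlapping blocks counted outward from the border — 20
positions for TSS-coding, intragenic-coding and intergenic islands, 100
for the two noncoding classes whose island counts are small — averaging
the per-position rates with partial trailing blocks averaged over what
exists. Distances with zero sites are missing, never zero.

## Allele-frequency handling

The six Af bins are {0}, (0, 0.06), [0.06, 0.12), [0.12, 0.18),
[0.18, 0.24), [0.24, 1]. The Af = 0 bin is interpreted as CpG sites with
no reported variant: any reported variant has allele count >= 1, so an
observed Af of exactly zero cannot occur, and the complement is the only
coherent reading. Within a stratum the six bin fractions therefore sum
to 1. Across catalogues a site's Af is reconciled by maximum by default
(union presence for the mutated flag; a per-source mode reproduces
per-project views). The rare-variant filter is inclusive at the 0.01
boundary; events with missing Af are dropped from rare-variant analyses
and counted. The Y chromosome is excluded from allele-frequency-dependent
tables (inconsistent allele numbers in consortium call sets make its AF
denominators unreliable); site enumeration keeps it.

## Coding consequence

Every CDS base that is the C or G of a CpG is a primed site. The codon
containing it is read across exon junctions in transcript orientation;
on minus-strand genes the genomic C>T appears as a transcript G>A and
vice versa, so the mutated transcript base is always C→T or G→A.
Consequences come from the standard genetic code: unchanged amino acid is
SILENT (including stop-to-stop), a gained stop is NONSENSE, everything
else including stop-loss is MISSENSE (stop-loss is rare, never separated
in the headline tables, and countable from the long table). Overlapping
transcripts each contribute a row to the per-transcript table; the
per-site table keeps the most severe consequence
(NONSENSE > MISSENSE > SILENT), the common convention when a single call
per locus is needed. The hyper-methylation filter (per-site beta >= 0.67,
inclusive, distinct from the strict > 0.67 of island group A — the two
thresholds serve different definitions and both are configurable) uses
the site's own beta rather than its island's mean, switchable by passing
island-level betas.

## Signature decomposition

Rare variants populate the 96-channel spectrum (six pyrimidine
substitution classes × 16 flank combinations; purine-reference events are
reverse-complemented; the reference allele of a rare variant is taken as
ancestral, which is the rationale for restricting to rare variants in the
first place). Decomposition solves the nonnegativity-constrained least
squares problem on the normalized spectrum — unconstrained regression can
return negative exposures, which have no meaning as mixture weights; an
unconstrained mode exists behind `constrained = FALSE` for comparison.
Signatures with weight below 0.01 are pruned and the model refit,
iterated to a fixed point (at most K steps); iterating is the
conservative closure of a single prune pass and cannot lower the
residual below the full fit, which is reported alongside. The packaged
signature matrix is a deterministic synthetic stand-in in the COSMIC v2
layout whose first column concentrates mass on the N[C>T]G channels as a
deamination emulator; any 96 × K matrix in that layout is accepted via
`readSignatureMatrix()`.

## The synthetic study

`generateBundle()` writes a complete miniature study: by default 2
chromosomes × 500 kb, ~32 planted islands per chromosome covering all six
classes (including MISC, realized by a coding TSS overlapping a
noncoding gene body), genes on both strands with multi-exon structures
and junction-spanning codons, a methylation track, a WGS-like VCF with
AF/AC/AN and an exome-like VCF for the consequence analysis, plus
per-site truth tables.

True per-site mutation probabilities: 0.036 TSS-coding, 0.041
TSS-noncoding, 0.062 intergenic, 0.060 intragenic-noncoding, with
intragenic-coding split into a hyper-methylated short group A at 0.20
(40% of islands) and a hypo-methylated long group B at 0.0533, averaging
0.112; shore bands within 2 kb of a border mutate at class-resolved
rates (0.10/0.10/0.22/0.16/0.16/0.15, intragenic-coding highest) so the
class-wise shore comparisons have planted signal; background CpGs at
0.276 and the non-CpG control at 0.02. These magnitudes mirror the
ordering and scale reported for human population catalogues; they are
demonstration parameters, not claims about any dataset. Allele
frequencies come from a 0.7/0.3 mixture of Beta(0.3, 8) (rare mass) and
Uniform(0,1) (tail) quantized to counts over 5008 alleles, so all six Af
bins populate. Methylation regimes: island-interior betas of
0.018/0.039/0.139/0.154 for TSS-coding/TSS-noncoding/intergenic/
intragenic-noncoding, 0.80/0.10 for intragenic-coding groups A/B, a
linear 0.30 → 0.80 shore ramp over 2 kb (the simplest shape consistent
with the rising profiles seen in sperm methylomes), background 0.80,
truncated Gaussian noise (sd 0.05), 10% dropout. A fraction (0.15) of
TSS-island CpGs is drawn from the hyper regime so the TSS consequence
panel is populated at all — without it, uniformly hypo-methylated TSS
islands would contribute nothing after the beta >= 0.67 filter.
Consequence observation probabilities are 0.8/0.7/0.5 for
silent/missense/nonsense with geometric allele-count parameters
0.15/0.3/0.55, emulating negative selection as an excess of singletons
among nonsense-primed sites. Background GC is 0.38: at 0.40 the expected
number of >250 bp chance Gardiner-Garden segments in a megabase of
background is no longer negligible, and clean background is a generator
invariant.

What the generator does **not** emulate: linkage and coalescent structure
in allele frequencies, context-dependent background mutation beyond the
CpG/non-CpG split, repeat families, chromatin- or replication-timing
covariates, per-individual or per-population stratification, and any
correlation between methylation noise and coverage. Passing closed-loop
tests therefore demonstrates that the estimators recover planted
parameters under the stated sampling model — not that real data meet
that model.

## Numerical and engineering choices

Coordinates are 1-based closed in memory (GRanges native); BED, genePred
and bedGraph convert at the boundary, VCF is natively 1-based. All
tabular output is TSV, UTF-8, '.' decimal, written with a fixed 10-digit
`%g` format so reruns are byte-identical; the generator seeds R's
Mersenne-Twister with fixed normal/sample kinds, making bundles
byte-identical per (config, seed). Degenerate inputs: empty strata emit
denominator-0 rows with missing rates; genes whose CDS length is not a
multiple of 3 are skipped with a warning; N-containing trinucleotide
contexts are skipped and counted rather than raised; a zero-variance
paired difference short-circuits the t-test to ±Inf/p=0 (or 0/p=1 when
also zero-mean); chromosomes shorter than the calling window are skipped
with a warning. Dunn's post-hoc uses tie-corrected rank variances with
Bonferroni adjustment over pairs and is gated on a significant
Kruskal-Wallis; all tests are two-tailed at alpha 0.05 with no correction
across the battery's separate questions.

Problem sizes in the shipped tests: the oracle comparisons use 50 random
10-kb sequences (caller) and 200 random gene models (consequence); the
closed-loop demonstration uses the default 2 × 500 kb bundle, whose full
pipeline run completes in well under two minutes on one CPU; signature
recovery uses 10^6-event multinomial draws over three seeds. These sizes
were chosen to put estimator standard errors well inside the planted
effect sizes.

## Known limitations

The caller's 1-bp-step window scan is exact but O(genome × window) in
simple vector arithmetic — fine for desk-scale genomes and minutes-scale
for a human genome, but not optimized further. Shore pieces from distinct
islands may overlap each other (only island bases are subtracted), so
summing shore widths double-counts inter-island gaps narrower than 4 kb.
The per-site severity-max convention means per-transcript and per-site
consequence tables disagree wherever transcripts overlap; both are
emitted. The distance convention's 0/−1 asymmetry at the two borders is
inherent to half-open intervals and documented rather than hidden.
Methylation ingestion averages duplicate strand records without
coverage weighting. The pipeline holds whole chromosomes as character
vectors; genomes far beyond human scale would need a streaming rewrite.
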