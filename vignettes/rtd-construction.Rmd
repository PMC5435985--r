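---
title: "Building and validating reference transcript datasets with rtdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating reference transcript datasets with rtdkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdkit)
```

## The problem

Short-read transcript assemblers (Cufflinks, StringTie and kin) produce
large numbers of false transcript models: isoforms built on splice
junctions that no read actually supports, fragments of real transcripts,
antisense artefacts and models assigned to loci that do not exist.
Quantifying isoforms and alternative splicing (AS) against such an
annotation propagates those errors into every downstream ratio. A
*reference transcript dataset* (RTD) addresses this by aggressively
filtering assemblies before merging them into a single non-redundant
transcript set that lightweight quantifiers (Salmon, kallisto) can use.

`rtdkit` implements that construction as a reusable toolkit: junction
quality control, transcript-level filters, step-wise merging with
redundancy removal, end-coordinate normalisation ("QUASI" padding) for
isoform quantification, position-weight-matrix (PWM) scoring of U2/U12
splice-site signals, gene-fixed AUG translation with in-silico trypsin
digestion, and AS/FS splicing-ratio computation with concordance
statistics against experimental peak-area measurements.

## Pipeline model

The pipeline applies, in order:

1. **Junction filtering.** Junction evidence from one or more aligner
   tables is pooled per sample. A junction passes iff its intron-terminal
   dinucleotides are canonical (GT..AG, GC..AG, AT..AC, strand-aware) *and*
   it has at least `min_reads = 10` unique reads in at least
   `min_samples = 3` samples.
2. **Transcript filters.** A multi-exon transcript is kept only if every
   intron is a passing junction (mono-exonic transcripts pass vacuously).
   Antisense transcripts completely contained in an annotated gene's span
   on the opposite strand are removed. Transcripts from unknown loci are
   removed unless at least 1 bp of same-strand exon overlap with a known
   gene rescues them (they are then reassigned to that gene). Finally,
   transcripts lacking a TPM strictly above `min_tpm = 1` in at least
   `tpm_min_samples = 3` samples are removed.
3. **Merge and redundancy removal.** Transcriptomes are merged step-wise.
   The identity key for a multi-exon transcript is its *intron chain*
   (chromosome, strand, ordered intron coordinates); per gene, one
   transcript per chain is retained. Mono-exonic transcripts are redundant
   only on exact span identity.
4. **QUASI padding / trimming.** Padding extends every isoform of a gene
   to the span of the longest isoform by growing the terminal exons with
   cognate genomic sequence (no new junctions); trimming clips all
   isoforms to the shortest region. Padding is the variant intended for
   isoform quantification.
5. **Translation and peptides.** Per gene, the AUG of the transcript with
   the longest ATG-initiated ORF becomes the gene anchor; all isoforms are
   translated from that genomic AUG when its three bases are exonic and
   contiguous in their mRNA, and fall back to their own longest ORF
   otherwise. Proteins are digested with trypsin rules (cut after K/R not
   followed by P, no missed cleavages, peptides ≥ 7 residues) and indexed
   for isoform uniqueness.
6. **AS quantification.** A simplified pairwise classifier labels local
   structural differences between two isoforms as intron retention (IR),
   alternative 5'/3' splice site (Alt5/Alt3) or exon skipping (ES); the
   AS/FS ratio of an event in a sample is the TPM sum of the AS isoform
   set over that of the event-local fully spliced (FS) set. Pearson and
   Spearman correlations against HR RT-PCR-style peak-area ratios pool all
   events and samples into one vector pair.

## Design choices where the design was open

* **Coordinates.** All internals use the Bioconductor convention (1-based,
  closed `GRanges` intervals); the GTF and SJ-table readers/writers perform
  the explicit, bijective dialect conversions. This keeps every interval
  operation on `GenomicRanges`/`IRanges` primitives rather than a second,
  parallel arithmetic.
* **Pooling duplicate junction evidence** from two aligners takes the
  per-sample *maximum* unique-read count, never the sum — the same reads
  mapped twice are not independent evidence.
* **PWM score scaling.** Raw scores are per-position log2 likelihood
  ratios against a uniform background; they are min-max scaled so the
  column-consensus 13-mer scores exactly 100 and the anti-consensus 0,
  which makes the published-style thresholds (75/65 for U12, 60 for U2)
  act on a bounded, percentage-like scale. Absolute scores are therefore
  comparable only within this implementation. The packaged default
  matrices are *synthetic*, derived from the same consensus model the data
  generator uses; users with curated intron sets should train their own
  via `build_pwm()`.
* **U12 precedence.** When an intron passes both threshold sets it is
  called U12 — the restrictive special case wins.
* **Redundancy representative.** Among transcripts sharing an intron
  chain, the one with the longest genomic span is kept (maximal UTR
  extent preserves the most sequence for quantification); ties fall back
  to merge priority (the earlier transcriptome in a step-wise merge) and
  then the lexicographically smallest id, so results are deterministic.
* **Trim boundaries inside introns** truncate a transcript at the last
  complete exon boundary inside the window: no partial introns are ever
  created, at the cost of sometimes removing whole exons (the documented
  pathology of trimming).
* **Anchor ties** are broken toward the 5'-most AUG within the winning
  transcript, then the lexicographically smallest transcript id. ORFs
  without an in-frame stop are translated to the last complete codon and
  flagged `ran_off_end`.
* **FS designation is structural, never abundance-based**: the FS set of
  an event consists of the isoforms carrying the spliced (reference) form
  at that locus, regardless of expression.
* **Undefined ratios** (FS total of zero) are flagged and excluded
  pairwise from correlations, as are events whose isoforms are absent from
  the quantification on one side.

## The synthetic data generator

`fixture_spec()`/`simulate_rtd()` generate the study conditions the
package is tested under: by default 200 genes × 8 samples, 3–5 exons per
gene, introns of 60–120 nt carrying sampled consensus splice sites
(donor `GTAAGT…`, acceptor `…GCAG`), and up to two AS isoforms per gene
with event-type frequencies 40% IR, 25% Alt3, 20% Alt5, 15% ES (the
field's canonical ordering for plants). Disjoint gene subsets carry one
artefact each: an isoform with a non-canonical novel junction (6%), a
canonical but unsupported junction (6%), a low-expression isoform (8%), a
contained antisense fragment (5%), an unknown intergenic locus (5%), a
novel-gene-id isoform rescuable by exon overlap (5%) and a redundant
UTR-variant twin (8%) — so every generated transcript has exactly one
expected fate, and the end-to-end test can require exact recovery.

Every gene carries a designed ATG-initiated ORF (safe codons, scrubbed
upstream ATGs) so translation is exercised; ground-truth anchors are
computed by an independent frame-wise ORF scanner, not the package's
per-ATG walk. Supported junctions receive `10 + Poisson(20)` unique reads
in every sample; unsupported ones at most 9 anywhere. Gene expression
(20–200 TPM total) is split across isoforms by a per-sample Dirichlet
draw floored at 12%, written at 4 decimals, and the true AS/FS ratios are
recomputed from exactly those rounded values, which is why tests can
demand agreement to 1e−9. Peak areas equal `true ratio × FS area ×`
log-normal noise (σ = 0.15), giving concordance near 0.95 by design.

What the generator does *not* emulate: realistic sequence composition
beyond splice motifs and ORFs, read-level noise (junction counts and TPMs
are drawn, not inferred from reads), alternative transcription starts or
polyadenylation, overlapping genes, and intron signal strength matching
real genomes (the exonic halves of the splice-site windows are random, so
the share of introns scoring > 60 at both sites is lower than in a real
plant transcriptome). Passing tests therefore demonstrate correctness of
the machinery under controlled conditions, not assembly accuracy on real
read data.

## Numerical and degenerate-input conventions

* TPM thresholds are strict (`> 1`), matching the construction rule; a
  transcript absent from a quantification table counts as all-zero and is
  removed with a warning.
* PWM scoring of any window containing `N` returns `NA`, which fails every
  threshold comparison; undetermined-strand junctions (`SJ` strand code 0)
  are retained but can never be canonical.
* An empty trim window (max start beyond min end) skips the gene with a
  warning; a transcript left without exons is dropped with a warning.
* Padding beyond a chromosome end is an error (no clamping); no cap is
  applied near neighbouring genes.
* All randomness in the generator flows from one master seed through
  per-file-type streams, so adding a file type never perturbs existing
  fixtures, and equal seeds give byte-identical outputs.

## Problem sizes in the test suite

Unit and property tests run on hand-built micro-fixtures and a shared
24-gene × 6-sample simulation; the end-to-end acceptance test and
`scripts/acceptance.R` use the generator defaults (200 genes × 8
samples), which run the whole pipeline in about a minute on one CPU.

## Known limitations

The pairwise AS classifier covers the four simple event types only;
complex combinations are reported as `unclassified` and excluded from
ratios. Exitron detection, BED12 junction input, GFF3 annotation, NMD/PTC
target classification and spectral matching of the peptide database are
out of scope. QUASI padding assumes UTR variation reflects incomplete
models; for genes with bona fide alternative transcription start or
polyadenylation sites the padded coordinates misrepresent the biology.

## A worked example

```{r example, eval = FALSE}
library(rtdkit)

sim <- simulate_rtd(fixture_spec(seed = 1, n_genes = 50, n_samples = 6),
                    "rtd-demo")
cfg <- pipeline_config(
  assembly_gtf = sim$files$assembly_gtf, genome_fa = sim$files$genome,
  sj_tabs = sim$files$sj, sj_samples = sim$samples,
  quant_files = sim$files$quant, quant_samples = sim$samples,
  reference_gtf = sim$files$reference_gtf, outdir = "rtd-demo/out")
res <- run_pipeline(cfg)

res$rtd                      # the final non-redundant transcriptome
table(res$fates$fate)        # kept / per-reason removed counts
res$peptides$summary         # peptide database uniqueness
concordance(res$ratios,
            splicing_ratios_from_peaks(read.delim(sim$files$peaks)))
```
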