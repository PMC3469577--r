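---
title: "Methods: homology-seeded miRNA discovery and drought-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-seeded miRNA discovery and drought-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseed)
```

## The problem

Sugarcane has no assembled reference genome, yet its miRNA complement —
and how that complement shifts under drought — can be characterized from
small RNA deep sequencing by leaning on conservation: reads are mapped
to the genome of a close relative (sorghum), candidate precursor loci
are folded and filtered by hairpin criteria, and surviving matures are
named by homology to the relative's annotated miRNAs. mirseed
implements that strategy as a reusable, fully tested pipeline:
preprocess, classify, map, discover, name, quantify, test for
differential expression, and scan for targets. A seeded synthetic-data
generator stands in for raw sequencing libraries, which for the
motivating study were never deposited, so every stage can be validated
against planted truth.

## Read preprocessing

Reads are trimmed of the 3' adapter (longest exact read-suffix /
adapter-prefix overlap of at least 6 nt, or a full internal adapter
occurrence), reads containing `N` are dropped (an ambiguous base breaks
all downstream exact-match and mismatch accounting), reads outside
18–27 nt are discarded, and survivors are collapsed to unique sequences
with counts. The 18 nt floor is the usual software cutoff below which
genome matches become uninformative; the 27 nt ceiling mirrors the gel
size selection of small-RNA protocols. Both bounds are exposed as
arguments. The retained total `N` of a library is used both as the TPM
denominator and as the library size of the count test, so one number
drives all normalization.

Collapsed sets round-trip through FASTA with `>seq<rank>_x<count>`
headers, the dialect miRDeep-style tools expect.

## Read classification

Each unique read is assigned to the first category in a configurable
precedence order whose annotation set contains it as an exact,
full-read-length substring (reverse complement for the antisense exon
category); everything else is unannotated. The default order — rRNA,
tRNA, snRNA, snoRNA, miRNA, siRNA, sense exon, antisense exon — puts
structural RNA first so that rRNA/tRNA fragments can never inflate the
miRNA counts. Matching is deliberately exact: mismatch tolerance
belongs to the homology-naming stage, not to annotation. Because
assignment stops at the first hit, the categories partition the
library, and the pipeline asserts that partition on every run.

## Mapping

Collapsed reads are placed on the reference with a k-mer-indexed search
(default seed `k = 12`), both strands, requiring a full-length match
with at most `max_mismatches` substitutions. The default of zero
mismatches follows the convention of homology-seeded precursor
discovery: the two-mismatch allowance quoted for naming applies to the
comparison against mature references, not to genomic placement. Reads
with more than 15 placements are flagged multi-mapped and never
nominate precursor loci. Exact matching uses a vectorized per-length
substring table; with mismatches, pigeonhole seeding (one of
`max_mismatches + 1` disjoint seeds must be exact) is used, falling
back to a full scan for reads too short to guarantee a seed. The mapper
is tested for exact equality against brute-force scanning, including a
50 kb reference.

## Hairpin discovery

A 250 nt window is excised around each mapped locus, centered on the
read and truncated at reference ends; minus-strand loci yield
reverse-complemented windows with recomputed mature offsets.

Windows are folded with an energy-minimizing dynamic program under a
simple pair-sum model: GC −3.0, AU −2.0, GU −1.0 per pair, minimum
hairpin loop of 3, no pseudoknots. This model is a deliberate design
choice over nearest-neighbor thermodynamics: it is deterministic,
dependency-free, and desk-verifiable — the DP optimum is checked
against exhaustive enumeration of every structure for sequences up to
18 nt. The cost is that absolute energies are not comparable with
RNAfold-grade values; published absolute MFE values of real precursors
are therefore out of scope for validation, and only the sign criterion
(MFE < 0) enters the verdict. Traceback ties prefer pairing the
outermost base, then the smallest partner, making reported structures
platform-independent. One consequence of a loop-penalty-free model
worth knowing: a "perfect" duplex hairpin may fold with one pair
diverted into a pairable loop base when that is energetically better,
so the generator validates its plants through the same folding path the
pipeline uses.

Four criteria decide the verdict, each individually switchable, the
verdict being their conjunction:

1. **Stem-loop with the mature in one arm** — operationalized as: at
   least 60% of mature positions paired, all partners on one side of
   the mature, and strictly monotone partners along the mature (a
   single duplex path, i.e. exactly one terminal loop between mature
   and star). The qualitative "characteristic stem-loop" phrase had to
   be quantified somewhere; these three conditions are that reading.
2. **Star mismatches** — the number of mature positions left unpaired
   in the structure, at most 6. Bulges and loop asymmetry are counted
   the same way (an unpaired mature position is an unpaired mature
   position); this is the documented reading of "mismatches with the
   star".
3. **Negative folding energy.**
4. **G/C content between 30 and 70 percent.**

The star span is reported as the positions pairing with the mature
extended by the customary 2 nt 3' overhang at the star's 3' end.

## Homology naming

Candidate matures are compared ungapped against a bundled
sorghum-style reference mature set at every offset within a length
difference of 2, counting candidate overhang as mismatches; references
at the minimum mismatch count ≤ 2 win. Families with one distinct
sequence are named `ssp-miR<fam>`; multi-sequence families get
`seq1..seqN` suffixes ordered by descending total count then sequence,
so naming is deterministic. A candidate within bounds of two families
is named by the lower-mismatch family and flagged ambiguous on an
exact tie — ambiguity is made visible rather than silently resolved.

## Expression and differential calls

TPM is `count × 10^6 / N`. Between two libraries the Audic–Claverie
test is used: the conditional kernel

\[ p(y\,|\,x) = \left(\frac{N_2}{N_1}\right)^{\!y}
   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}} \]

is summed in log space (via `lgamma`) over both inclusive tails, and
the two-sided p-value doubles the smaller tail, capped at 1. Both
tails are summed directly — the upper tail is never formed as
`1 - lower` — so small p-values keep full relative precision; the
implementation agrees with an independent oracle (the kernel is the
negative-binomial pmf with size `x + 1` and probability
`N1/(N1+N2)`, so `pnbinom` tails serve as reference) to 1e-9 relative
error. One subtlety: with the inclusive-tail convention the two-sided
value is *not* exactly invariant under swapping the libraries — the two
orientations differ by at most the boundary point mass. The exact
identity that does hold, and that the tests assert, is tail
complementarity: \(P(Y \le y\,|\,x; N_1, N_2) + P(X \le x\,|\,y; N_2,
N_1) = 1\).

Fold changes follow the signed convention of the drought tables: the
treated/control ratio `r` is reported as `r` if `r ≥ 1`, else `−1/r`,
and a record is significant when `|FC| > 2.00` and `p < 0.05`, both
strict. Zero counts give `±Inf` sentinels that are excluded from
calling unless a pseudo-TPM floor is enabled. No multiple-testing
correction is applied by default (matching the per-miRNA convention of
two-library count studies); Benjamini–Hochberg is available via
`p_adjust = "BH"`. All report rounding is centralized, half-up to two
decimals, applied only at write time.

## Target prediction

A miRNA is paired antiparallel and ungapped against every transcript
window of its length and scored with an expectation penalty:
Watson–Crick 0, G:U wobble 0.5, mismatch 1.0, penalties doubled at
miRNA positions 2–13 (the psRNATarget-style seed emphasis). Sites with
expectation at most 3.0 — the configurable default — are reported.
Inhibition is called by the central-site rule: any non-Watson–Crick
position facing miRNA positions 9–11 means translational inhibition,
otherwise cleavage. Target-site accessibility energies (UPE) require a
partition-function model and are intentionally not computed; the
column is absent rather than approximated. The transcript sense strand
is taken as authoritative from the input FASTA.

## The synthetic-data generator

`make_reference()` builds the study conditions the pipeline is
validated against:

* **Precursors** (default 30): each planted mature is a bundled
  reference mature with 0–1 substitutions (second variants of a family
  carry one, keeping every plant within the 2-mismatch homology bound
  of exactly one reference). Precursors are mature + 8–12 nt loop +
  reverse-complement star with 0–3 engineered non-pairing star
  positions, embedded at recorded loci and strands in a random
  background genome (G/C 42%, plant-like). Every plant is re-validated
  through the actual discovery path — 250 nt window excision plus the
  four criteria — during generation, with rejection and retry, so
  downstream recovery failures indicate pipeline defects.
* **Baselines**: log-uniform 100–10000 TPM (responsive miRNAs
  200–5000). The ranges echo the reported library composition: the
  miRNA category is roughly 15–26% of reads spread over ~21 species,
  i.e. average abundances in the thousands of TPM, and the reported
  responsive miRNAs sit at hundreds to thousands of TPM.
* **Fold changes**: 8 responsive miRNAs per genotype with planted
  |FC| from 2.5 to 18, signs drawn per genotype — the 2–19× span of
  the reported drought responses.
* **Counts**: Poisson thinning of depth × TPM/10^6, the sampling model
  the Audic–Claverie test assumes; a negative-binomial option with
  explicit dispersion is a robustness knob, not the default.
* **Libraries**: insert + 3' adapter prefix truncated to a 36 nt
  machine read. Decoy reads (rRNA, tRNA, sn/snoRNA, exon sense and
  antisense, 24 nt siRNA) at fixed expected fractions; unannotated
  background (uniform random 16–27-mers) at 50% of depth, mirroring
  the reported ~46–55% unannotated fraction qualitatively. Background
  lengths mode at 21 nt with a secondary 24 nt mode, and 21-mers start
  with U or A 80% of the time — the first-nucleotide signature of
  plant libraries. Adapters are appended only at the 3' end: reads are
  sequenced from the insert start, so the 5' adapter never appears.

What the generator does **not** emulate: sequencing errors, quality
variation, genotype sequence divergence (genotype is a label only —
whether cultivars should differ in sequence is not decidable from the
study design), chromatin-scale genome structure, or expression
correlation between miRNAs. Passing the end-to-end tests therefore
demonstrates correctness of the pipeline's bookkeeping, folding,
testing and naming logic under the stated sampling model — not
robustness to base-calling noise or reference divergence.

All generator randomness flows through explicit integer seeds via one
internal wrapper that restores the caller's RNG state; identical seeds
give byte-identical outputs.

## Problem sizes used in validation

The test suite validates end to end at 30 planted precursors, 50
decoys, and four libraries (2 genotypes × 2 conditions) of 2×10^5
reads each — recovery of at least 90% of planted matures and 100% of
planted |FC| ≥ 3 directions is asserted, and in practice recovery is
complete. The null calibration uses 200 replicate library pairs at
depth 10^5 with all fold changes at 1, asserting a significant-call
rate within [0.03, 0.07] at α = 0.05; the exact test is mildly
conservative at low counts, which is why the band is not centered on
0.05. Folding is verified against full enumeration on 200 random
sequences up to 18 nt, and the mapper against brute force up to 50 kb.
These sizes keep the whole suite in a few minutes while exercising
every code path at depths where the count statistics are
representative.

## Design choices that were genuinely open

* **Classification precedence** (unstated in the motivating analysis):
  structural RNA before miRNA, exact matching only. Exposed as a
  config knob.
* **Mapping policy** (unstated): zero mismatches, 15-placement
  multi-map cap, both configurable and logged in provenance.
* **Window centering**: the window is centered on the mapped read;
  asymmetric excision variants can be emulated by adjusting loci.
* **seqN ordering**: by abundance, then lexicographic — the ordering
  basis of published multi-sequence families is unstated, and
  abundance is the reproducible choice.
* **Zero-count fold changes**: ±Inf sentinels excluded from calling by
  default; a pseudo-TPM floor is available but off, since inventing
  pseudocounts changes the test's meaning.
* **Length bounds**: both the 16–27 nt physical selection and the
  18 nt software floor exist in the protocol; the pipeline filters at
  18–27 and exposes both bounds.

## Known limitations

* The pair-sum energy model ranks structures differently from
  nearest-neighbor thermodynamics; absolute energies are not
  comparable with RNAfold, and marginal hairpins may fold differently.
  An external folder can be slotted in wherever `fold()`'s contract
  (dot-bracket + energy) is met.
* Ungapped homology matching cannot name matures with indels relative
  to the reference set.
* The Audic–Claverie test models sampling noise only; with biological
  replicates a dispersion-aware test would be preferable, but the
  pooled-library design this pipeline mirrors offers none.
* Target scanning is complementarity-only; accessibility (UPE) is not
  computed.
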