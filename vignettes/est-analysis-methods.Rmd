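---
title: "Methods: EST clustering, digital expression and marker discovery"
author: "ESTpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EST clustering, digital expression and marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ESTpipe implements the downstream computation of a classic Sanger EST
project on full-length enriched cDNA libraries: single-pass reads from
the 5' and 3' ends of cDNA clones are cleaned, clustered into unigenes,
mined for full-length transcripts, digital expression differences, and
SSR/SNP markers. This vignette documents the models, the parameters
that matter, and the design decisions taken where the underlying
procedures are genuinely open.

## Read preprocessing

Per-base error probabilities come from Phred qualities,
$e_i = 10^{-Q_i/10}$. A window of `window = 20` bases is *bad* when its
mean error exceeds `maxError = 0.01` — strictly: a window at exactly
0.01 is clean, so all-Q20 reads survive untouched. The kept region of a
read is the longest contiguous clean interval (leftmost on ties), where
an interval is clean when it contains no complete bad window and, if
shorter than the window, its own mean error passes the threshold — the
second clause judges short stretches at their own scale and makes
trimming idempotent. Reads no longer than the window are judged as a
single window, kept whole or dropped. This "longest clean region" rule
is deterministic and
exactly testable against an exhaustive window enumerator; it is this
package's documented behaviour, not a reimplementation of any
particular trace-trimming tool. Trimming is idempotent and always
returns a contiguous substring.

Reads shorter than `minLength = 100` bases after trimming are
discarded (strictly shorter: a 100-base read is kept). Contaminant
screening is an exact `k = 31`-mer membership test against both strands
of the contaminant set — adequate for synthetic fixtures and free of
external aligner dependencies; it is not a local-alignment vector
screen.

## Unigene clustering

The clusterer is a deliberately simple stand-in for a dedicated EST
assembler. Overlaps are *ungapped*: the best dovetail/containment
offset of one read against another, in FF or FR orientation, scored by
`overlap_length * identity` and accepted when the overlap is at least
`minOverlap = 40` bases with identity at least `minIdentity = 0.97`
(N matches nothing). Ties prefer the longer overlap, then FF, then the
smaller offset. Clusters are the single-linkage transitive closure of
accepted overlaps.

Candidate pairs are proposed by shared canonical seeds of
`seedLength` bases (default `minOverlap`); the seed also implies the
candidate offsets, so verification is a single vector comparison per
offset. Two consequences are documented behaviour: (i) reads can only
be linked directly when they share an exact seed — for reads with
appreciable error rates a shorter `seedLength` should be used; (ii)
because accepted overlaps form a spanning tree, member offsets are
consistent by construction, and the error path for conflicting layouts
is realized as a post-hoc check: any member whose ungapped identity to
the final consensus falls below `minIdentity` is demoted to a singleton
with a warning. Reads are processed in lexicographic read-id order, so
results do not depend on input order.

The consensus is a per-column majority vote. Ties between bases break
in the fixed order A < C < G < T; N never wins a tie; columns in which
gaps hold a strict majority are removed from the consensus but retained
in the padded alignment (relevant only for externally supplied gapped
alignments — the built-in clusterer produces none). Layouts are
oriented so that the majority of 5' reads point forward, which puts
consensus sequences in transcript orientation.

Because overlaps are ungapped, haplotypes differing by indels inside a
read would corrupt the layout; the synthetic-data generator therefore
plants substitution SNPs only by default (see below). Indel
*observations* are fully supported downstream through gapped padded
alignments.

## Full-length transcripts, CDS, UTRs, codon usage

A clone is *concordant* when its 5' and 3' reads land in the same
unigene. A unigene yields one full-length transcript when at least one
clone from a full-length enriched library is concordant; the transcript
is the consensus span from that clone's 5'-read start column to its
3'-read end column. When several clones qualify, the single widest
clone span is used (ties to the smallest clone id) — a simple,
reproducible redundancy-removal rule; the alternative of unioning
clone spans would mix evidence from different clones.

CDS prediction is a longest-ORF search on the forward strand only:
full-length cDNA clones are directionally cloned and layouts are
orientation-fixed, so reverse-strand ORFs are out of scope. The
longest ATG-to-stop ORF (stop included) of at least `minOrf = 90`
bases (30 codons; configurable — the choice is conventional for plant
EST projects) wins, ties to the leftmost start. If none exists, the
longest stop-free ATG-initiated tail of at least `minOrf` bases is
used and flagged `NO_STOP`; otherwise the transcript is `NON_CODING`.
UTRs are the flanks of the CDS, so UTR5 + CDS + UTR3 partitions every
coding transcript exactly. Codon usage reports counts, per-1000
frequencies, within-family fractions (which sum to 1 per observed
amino acid), the composition of terminal stop codons, and coding GC
content.

## Digital expression

Counts of ESTs per unigene per tissue, restricted to libraries that
are neither normalized nor subtracted, approximate relative expression.
Heterogeneity of a gene's counts $x_i$ across tissues with totals
$N_i$ is scored with the log-likelihood statistic

$$R = \sum_i x_i \ln \frac{x_i}{N_i f}, \qquad
  f = \frac{\sum_i x_i}{\sum_i N_i}, \qquad 0 \ln 0 \equiv 0 .$$

$R \ge 0$ with equality exactly at equal proportions. $2R$ is
*exactly* the Poisson (log-linear) likelihood-ratio deviance for a
common proportion — the package's tests verify this identity against
an independent GLM fit — and only asymptotically equal to the binomial
LRT. The default p-value is therefore the $\chi^2_{m-1}$ upper tail at
$2R$ (df = 1 for pairwise tests); a Monte-Carlo option re-splits the
pair total under the pooled proportion for small counts, with the
add-one correction. Simulation shows the chi-square rejection rate at
$\alpha = 0.05$ sits inside the binomial 99% interval once expected
counts reach ~5-10.

Tissue-specificity follows the classic rule: for every unigene and
tissue pair with at least `minPairTotal = 5` ESTs, compute R and its
p-value; adjust with Benjamini-Hochberg *jointly across all tests in
the run* (the family definition is an open choice; one pooled family
is the most conservative reproducible option). The abundance ratio is
taken on library-size-normalized proportions
$(x_a/N_a)/(x_b/N_b)$ — tissues differ widely in EST totals, so raw
count ratios would be biased — with zero denominators mapping to
infinity. A unigene is called specific to tissue *t* only when *every*
comparison against the other tissues exists, has ratio strictly above
`minRatio = 2` with *t* up, and adjusted FDR strictly below
`maxFDR = 0.05`; a comparison blocked by the count filter vetoes the
call. Singleton unigenes participate; the 5-EST pair filter removes
almost all of them anyway.

## SSR scanning

Perfect tandem repeats of unit sizes 2-6 are reported when they reach
the conventional minimum repeat numbers (six for dinucleotides, five
for tri- through hexanucleotides; mononucleotide runs are not
scanned). Loci are maximal — not extendable by one more full unit —
and a run reportable at several unit sizes appears once, at the
smallest unit, enforced by rejecting motifs that are themselves
tandems of a shorter unit. N breaks runs. Compound/interrupted SSRs
are *not* merged: each perfect run is an independent locus, which can
make counts differ from scanners that merge nearby repeats. Motifs are
grouped by their canonical label: the lexicographically smallest
rotation of the motif or its reverse complement (CTT, TCT, GAA ... all
report as AAG), reproducing the conventional "AAG/CTT" group labels.
Primer-readiness is a plain two-sided flank check (`minFlank = 50`
bases; "sufficient flank" is not standardized, so this is
configurable).

## SNP discovery

For each unigene, alignment columns are piled up per cultivar (via the
library metadata). A column is a candidate for a cultivar pair when
both cultivars observe it (N excluded) and their majority bases
differ. A candidate passes when (1) each cultivar has at least
`minCov = 2` non-N observations, and (2) the two cultivars' observed
base *sets* — gaps included — are disjoint: any shared observed base
fails, the strictest reading of "no same bases at the site". Coverage
is checked before disjointness, and the failure reason is recorded.
Passing variants classify as transition ({A,G} or {C,T}),
transversion (other base pairs), or indel (gap allele). Multi-cultivar
data are analyzed as all unordered cultivar pairs, reported with the
alphabetically first cultivar on the left. No base-quality-aware
genotype likelihood is computed — the two explicit filters are the
point — so the caller is only as good as the alignment it is given.

## The synthetic study generator

The generator produces the study conditions the package is validated
under, with every feature recorded in truth tables: 2,000 genes built
as UTR5 + ATG...stop + UTR3 with log-normal lengths (mean UTR5 167
bases, UTR3 254 bases, CDS ~814 bases, hence transcripts ~1,230
bases), coding GC 45.6% (the codon sampler solves for the per-base GC
that hits the target after excluding stop codons), stop-codon usage
TGA/TAA/TAG = 44.9/37.2/17.9%; 7 tissues and 4 cultivars across 16
libraries (full-length fruit/flower panels per cultivar, one-cultivar
full-length leaf/root/cotyledon, standard callus and phloem); 3,000
clones per tissue with log-normal (sdlog 1) abundance skew; 20 planted
tissue-specific genes at 20-fold over a moderate baseline weight (1.5,
on a scale where the median gene is 1 — planted at moderate abundance
so the planted signal is identifiable at these library sizes, roughly
25 ESTs in the target tissue); ~100 planted SSR loci inserted into 5'
UTRs with guard bases that make the planted run maximal and
coordinate-exact; 300 planted fixed cultivar differences at
transition:transversion = 2:1 and no indels by default (ungapped
clustering cannot lay out indel-bearing haplotypes; the indel planting
path exists and can be enabled when supplying gapped alignments);
Sanger-like reads of 650 ± 60 bases, 5'-anchored with small Poisson
jitter, a 15% both-end sequencing fraction for full-length clones, and
error-free bases (constant Q40) by default. An optional low-quality
3' tail (`tailLength`, `tailErrorRate`) emulates decaying Sanger trace
quality so the trimmer can be exercised meaningfully; quality strings
always encode the true error process.

All randomness derives from one seed (the three stages use seed,
seed+1, seed+2), so a seed reproduces the study byte for byte.

What the generator does *not* emulate — and hence what green tests do
not show about real data: chromatogram-level artefacts, vector and
adapter chemistry, chimeric clones, alternative splicing, paralogy
(each gene is a single isolated transcript), indel sequencing errors,
and the compositional quirks of real genomes. Recovery rates on this
scenario are upper bounds on real-data behaviour.

## Problem sizes and numerical choices

The validation suite runs the full default scenario (2,000 genes,
21,000 clones, ~23,000 reads) once — about four to five minutes on a
single core — plus oracle-equivalence sweeps (1,000 random sequences
for the SSR scanner and ORF predictor, 1,000 random tables for the
likelihood-ratio identity, exhaustive interval enumeration for the
trimmer) and a 1,000-replicate null calibration of the chi-square
p-value. Floating-point comparisons in the R-statistic tests use
tolerances of 1e-8 (the identity is exact in exact arithmetic);
Monte-Carlo agreement is judged at three Monte-Carlo standard errors.
Degenerate inputs are defined behaviour throughout: empty read sets,
empty contaminant and feature sets, all-gap columns (removed),
uncovered consensus columns (N), zero-count matrices (no tests, no
calls), and empty SSR/SNP candidate sets (zero-filled summaries).

## Known limitations

The clusterer is not an assembler: no gapped alignment, no chimera
detection, no handling of deep next-generation read sets. CDS calling
is longest-ORF only, with no homology or HMM support, and reports at
most one ORF per transcript. The expression model has no replicates
and no overdispersion — EST counts are treated as exact multinomial
draws. SNP discovery has no quality-aware error model and will report
systematic alignment artefacts as variants on real data. These are
faithful simplifications of the classic EST-era toolchain this package
models, kept simple so that every stage is exactly testable.
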