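---
title: "Models and methods behind polyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyte)
library(dplyr)
```

polyte implements the quantitative arm of a polysome-profiling study of
translational control: spike-in-anchored translation efficiency (TE) with
fold-change classification, a minimal exact negative-binomial (NB)
differential-expression (DE) test, uORF discovery and mutagenesis in
5'UTRs, relative ribosome-occupancy profiles, and dual-luciferase
statistics. This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where the
procedure was genuinely open.

## The count model and what the simulator emulates

`generate_fraction_counts()` draws gene × library counts for a
two-genotype (control vs mutant) design over total / monosome / polysome
fractions with replicated libraries. The expected count of gene $g$ in a
library is

$$\mu_{gj} = D \cdot 2^{r_g \cdot \mathbb{1}[\text{mut}]} \cdot
  L_{f}(g) \cdot s_j,$$

where $D$ is the baseline depth per gene (`mean_depth`, default 500
counts), $r_g$ a planted transcript-abundance log2 effect, $s_j$ a
per-library scale factor (emulating depth and input differences that
spike-in normalization must undo), and $L_f$ the fraction loading. A
planted TE log2 fold-change $\delta_g$ is split symmetrically —
polysome loading $2^{+\delta_g/2}$, monosome $2^{-\delta_g/2}$ in the
mutant — so that the TE fold-change equals $\delta_g$ while transcript
abundance is untouched unless `rna_effects` says otherwise. Counts are
NB with the quadratic mean–variance law
$\mathrm{Var} = \mu + \alpha\mu^2$ (`dispersion`, default
$\alpha = 0.05$, a typical bulk-RNA-seq biological-replicate value);
$\alpha = 0$ yields the rounded means exactly, and a Poisson option
covers pure counting noise. Spike-in rows get
$\mu = c \cdot a_i \cdot s_j$ with known amounts $a_i$ (92 species,
log2-spaced — the real mix's amounts are proprietary-ish and span a wider
range; six octaves keep every species countable at simulated depths) and
are independent of genotype by construction.

The generator emulates the statistical structure the analysis relies on —
planted effects, NB noise, library-scale confounding, spike-in anchoring
— and deliberately not the sequencing process itself: no reads, no
alignment ambiguity, no GC or length bias, no spike-in pipetting error.
Passing tests therefore demonstrate that the estimators recover truth
under the assumed model, not that the model captures every artifact of
real libraries.

## Spike-in size factors

For library $j$, `compute_size_factors()` takes the median over spike-in
species of $k_{ij}/a_i$, restricted to spikes with at least `min_count`
(default 5) counts in that library, then rescales all factors to
geometric mean 1. The median is robust to individual spike dropouts; the
count floor guards ratio stability where expected counts are a handful;
geometric-mean anchoring makes factors comparable across runs without
electing a reference library. A library-total variant
(`method = "library_total"`) is provided for comparison. The exact
procedure used with the original data ("according to the manufacturer's
instructions") is not reproducible from the text, so numerical equality
with that pipeline is not claimed — the planted-truth recovery tests are
the correctness standard.

## Translation efficiency and classification

TE is polysome over monosome abundance with a pseudocount:
$(P + c)/(M + c)$, $c$ = 1 normalized count by default (the sources are
silent on stabilization; $c$ only matters near zero). Within a genotype,
replicate TEs are combined as the geometric mean of per-replicate ratios
(replicates paired by number); pooling means before the ratio is
available via `combine = "pooled"` and agrees on noise-free data. The
classification applies the scatter-plot rule with strict inequalities —
`TE_up` iff TE log2FC $> 1$ and |RNA log2FC| $< 1$ — so values exactly at
a threshold are `unchanged`; the printed rule uses strict comparison
signs, and ties have measure zero under noise anyway.

A consequence worth stating plainly: with $\alpha = 0.05$ the coefficient
of variation of a single count never falls below $\sqrt{\alpha}$, so the
TE log2FC point estimate from 2 vs 2 replicates has a standard deviation
of about $\sqrt{2(1/D + \alpha)}/\ln 2 \approx 0.47$ at depth 500
regardless of sequencing deeper. Thresholding such an estimate at 1 then
necessarily mislabels a few percent of null genes. The classifier is the
procedure being reproduced, so we report this property rather than
shrinking estimates or gating on a test statistic, which would be a
different method.

## The exact NB differential-expression test

`differential_expression()` rounds normalized total-fraction counts,
drops all-zero genes, and estimates one common dispersion by method of
moments, $\hat\alpha = \sum(v - m)/\sum m^2$ pooled over genes and
groups (truncated at 0) — sharing dispersion across genes is what makes
a 2 vs 2 design testable. Per gene, the group-A sum given the total is
free of the unknown mean when the replicate counts are i.i.d. NB with
common mean and dispersion (group sums are NB with sizes $n_A/\alpha$,
$n_B/\alpha$ and a shared success probability), so the two-sided p-value
sums the conditional probabilities of all outcomes no more likely than
the observed one; the $\alpha \to 0$ limit is the binomial exact test.
Calls require FDR < 0.05 (Benjamini–Hochberg) and |log2FC| > 1, with a
0.5 pseudocount on group means for the fold-change.

Two deliberate departures from the established edgeR route: no
tagwise/empirical-Bayes dispersion (a single MoM dispersion keeps the
test self-contained and transparent), and no library-size equalization of
the gene counts — columns arrive on a common absolute scale from spike-in
normalization, so a composition shift (many genes up) is signal, not
depth. The test suite cross-checks against `edgeR::exactTest` on a
composition-balanced fixture, where the two agree on evidence strength,
fold-changes and the significant set.

## uORF discovery, mutagenesis and frameshift translation

`find_uorfs()` considers every AUG with start in $[0, \text{cds\_start})$
(near-cognate CUG/GUG starts behind a flag, off by default — the source
material names no start-codon set beyond "putative uORFs"), walks
triplets to the first UAA/UAG/UGA, past the main start codon if
necessary, and classifies: contained in the UTR, or overlapping the CDS
out of frame / in frame via $(\text{start} - \text{cds\_start}) \bmod 3$.
No minimum length is imposed (an AUG directly followed by a stop counts),
and a uORF reaching the transcript end without an in-frame stop is
reported with a sentinel rather than dropped. Coordinates are 0-based
half-open internally; GFF3 export converts to 1-based inclusive. DNA
input is transcribed on read.

`mutate_start_codon()` replaces the AUG (UAA by default, the reporter
mutagenesis construct). One subtlety the implementation surfaced: even a
G-free replacement can create a new start at the edit boundary, because
the codon's trailing A can combine with a downstream UG
(`AUGUG…` → `UAAUG…`). The guaranteed closure is therefore: the targeted
uORF disappears, every other uORF is untouched, and any new start lies
within two bases of the edit; the property tests assert exactly that.

`apply_indel_and_translate()` models the frameshift mechanism of a 1-bp
deletion: remove `del_len` bases, translate from the initiator with the
standard genetic code, report the first stop's 1-based codon index.
Deletions touching the initiator AUG are refused. Both this walk and uORF
discovery are verified against independent brute-force oracles (a plain
substr scan; seqinr's codon table) on hundreds to a thousand random
transcripts.

## Ribosome occupancy

`filter_rpf_by_length()` keeps 28–32 nt footprints (inclusive), the
monosome-protected size range; the simulator's default read-length
distribution is uniform on 25–35 nt so the filter is exercised
non-trivially. `occupancy_profile()` counts, at each base, the number of
footprints covering it ("accumulated reads density per base"), then
divides by the summed counts over all positions, giving a relative
occupancy that sums to exactly 1; 5'-end assignment is available via
`mode = "end5"` since the counting rule for the original figures is not
stated. Zero-read profiles are flagged empty and refused by
`compare_occupancy()` instead of propagating NaNs. Region proportions sum
the density over a region's bases; overlapping regions (an out-of-frame
uORF running into the CDS) are summed independently and may double-count
shared bases — documented, and exercised by the partition-conservation
tests.

For occupancy comparisons, the substrate matters.
`synthetic_uorf_transcript()` builds the two-uORF architecture with fixed
geometry — uORF2's AUG 40 nt upstream of the main start, its
shifted-frame stop 15–60 nt inside the CDS — because a redistribution of
footprints from uORF2 to the CDS is only visible in region proportions
when uORF2 footprints place substantial mass on 5'UTR bases. With an
arbitrarily placed overlapping uORF lying almost wholly within the CDS,
uORF2-planted and CDS-planted footprints cover CDS bases near-equally
and the CDS proportion difference is pure noise. The demo comparison
plants start-position weights 0.5/0.5 (control) vs 0.2/0.8 (mutant) over
uORF2/CDS with 2000 reads per condition before length filtering.

## Reporter statistics

Per well, relative activity is Renilla/Firefly (Firefly is the
transfection control, so well-to-well transfection scale cancels),
normalized to the mean control-construct ratio — normalization after the
per-well ratio, since wells are independent transfections rather than
paired channels across constructs. Group comparison uses Student's
pooled-variance two-tailed unpaired t-test ($df = n_x + n_y - 2$), the
test named in the source figure legends; Welch's form is available via
`var_equal = FALSE`.

## Numerical and reproducibility choices

All generators are seeded and byte-reproducible (`withr::with_seed`; the
pipeline derives stage seeds from one root seed with fixed offsets). The
NB exact test normalizes conditional probabilities in log space and
compares against the observed probability with a $1 + 10^{-7}$ slack so
ties survive floating-point noise. The log2-ratio of occupancy
proportions uses a $10^{-6}$ pseudo-proportion. Degenerate inputs error
early and name the offender: libraries with all spike-ins below the count
floor, reads out of transcript bounds, non-integer count cells (file,
row and column), single-replicate DE designs, deletions into the
initiator codon.

## Problem sizes

The test and acceptance runs use the study-scale conditions throughout:
2000 genes with 100 planted TE effects of ±2 at depth 500 and
$\alpha = 0.05$ for TE recovery; 2000 null genes for DE calibration; 92
spike-ins at total spike depth $10^4$ for size-factor recovery; 1000
random transcripts for the uORF oracle scan; 500 random indel cases for
frameshift translation; 100 seeded runs of 2000 reads for the occupancy
sign pattern. The full suite runs in well under a minute on one CPU.

## Limitations

The package consumes counts and transcript-space alignments; read
alignment, rRNA depletion, P-site offsetting, codon periodicity,
metagene aggregation, GO enrichment and all wet-lab processing are out of
scope. The DE stage is a minimal common-dispersion exact test, not a
replacement for edgeR/DESeq2 on real data. uORF calling is purely
sequence-based (no Kozak scoring, no reinitiation model). Synthetic data
carry none of the gene-length, GC or batch structure of real libraries,
so passing recovery tests certifies the estimators under the stated
model only.
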