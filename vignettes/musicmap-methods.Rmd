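---
title: "musicmap: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{musicmap: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `musicmap`, the
conventions it fixes where the assay description leaves latitude, and the
limits of what its synthetic-data tests demonstrate.

## The read architecture and demultiplexing

Each sequenced molecule yields one read triple: R1 (28 bp) = 16-nt GEM
barcode + 12-nt GEM UMI; I1 (8 bp) = I7 library index; R2 (150 bp) = cell
barcode 3, spacer, cell barcode 2, spacer, cell barcode 1, the RNA or DNA
linker, then the insert. The linker decides modality: both linkers begin
`CGAGGAG`; RNA continues `CGCTT` + 5-nt UMI + `ATAGCATTGC`, DNA continues
5-nt UMI + `ACAACGCACAGTGTCTAGT`.

Conventions fixed here:

* **Spacers.** The constant bases between R2 barcode blocks are not part of
  the published main text; the layout is therefore parameterized
  (`music_layout(spacer1 =, spacer2 =)`) with a canonical 7-nt default per
  block, matching the 7-nt ligation overhang of the barcode sets. A real
  data dialect can be configured without code changes.
* **Mismatch tolerances.** Whitelists are generated with minimum pairwise
  Hamming distance 3, so one substitution is always uniquely correctable.
  We allow 1 mismatch per cell barcode, exact GEM with a 1-mismatch
  whitelist rescue, exact I7, 1 mismatch per fixed RNA-linker segment and 2
  over the DNA signature. A read equidistant from two whitelist entries is
  *never* assigned (`match_barcode()` returns `NA`); reads matching both or
  neither linker are `unknown`. Rationale: barcode assignment must not be
  ambiguous, and the published text names no tolerances.
* **Trimming.** DNA inserts lose a 3'-terminal A- or G-homopolymer run
  strictly longer than 20 bp (poly(dA)-tailing artifact); RNA inserts are
  truncated at the first occurrence of the RNA-linker ssDNA
  `CGAGGAGCGCTT` (read-through). Both are then 3'-quality-trimmed at Q15
  with the cutadapt running-sum rule — the published parameter is `-q 15`,
  and the running-sum algorithm is that tool's documented behavior — and
  dropped below 20 bp.
* **Accounting.** Every input read is exactly one of tagged or rejected,
  with a machine-readable reason. "Barcode-complete" (all five barcodes
  plus a linker) is reported separately from the final UMNDBC count, which
  additionally requires unique mapping and duplicate survival.

## Mapping and deduplication

Synthetic genomes are random sequence, so the built-in mapper is an exact
seed-and-verify lookup (20-mer seeds on both strands via Biostrings,
full-length exact verification): on such genomes this is a complete
replacement for an external aligner, and it classifies reads as
unique/multi/unmapped. Real, externally aligned data enters through
`import_alignments()` (primary alignments, MAPQ ≥ 30 as the conventional
proxy for "uniquely mapped", documented tag set for the barcodes).

Duplicates are removed with a three-criterion scan over
coordinate-sorted reads: a read is a duplicate iff an already-retained
read on the same chromosome **and strand** lies within 8 bp of its 5'
start, shares all five barcodes, and has UMI Levenshtein distance < 2.
Two interpretations were fixed deliberately:

* **Which UMI?** The assay carries a 12-nt GEM UMI and a 5-nt linker UMI;
  the rule compares their 17-nt concatenation. The `< 2` threshold then
  tolerates one sequencing error anywhere in either UMI.
* **"Within 8 bp."** Same chromosome and same strand, |Δ 5' start| ≤ 8.
  Opposite-strand reads at the same locus are distinct ligation events.
* The scan retains the first read of each duplicate group and compares
  candidates against *retained* reads (not merely the immediately
  preceding record), which makes deduplication idempotent.

## Clusters, decomposition and normalization

A cluster is the read set sharing (cb1, cb2, cb3, GEM, I7). Homotypic
clusters of size $N$ decompose into all $\binom{N}{2}$ unordered pairs at
weight $1/N$ each (total $(N-1)/2$); heterotypic clusters with $M$ RNA and
$N$ DNA reads into all $M \times N$ RNA–DNA pairs at weight $1/(M+N)$
(total $MN/(M+N)$). "All non-overlapping pairs" is read as all unordered
pair combinations — the only reading under which $1/N$ acts as a per-pair
normalizer in the SPRITE style and which matches the heterotypic "all
DNA–RNA pairs" phrasing. RNA-only clusters use $1/N$ with $N$ the RNA
count.

For distance-decay analyses, DNA–DNA pairs may be drawn from DNA-only
clusters only, or from all clusters (`dna_source`); in the latter case a
pair from a mixed cluster carries that cluster's own factor $1/(M+N)$, so
each cluster type keeps a single normalization constant. The default is
all clusters for $P_c(s)$ and DNA-only exclusion behavior for the XIST
negative set (below). When a genomic region is specified, cluster
membership and size are recomputed on region-restricted reads before
decomposition, and the size classes for stratified maps are small = 2–10,
medium = 11–50, large = 51–100 reads.

Species QC: a cell is called for a species when ≥ 95% of its DNA reads map
there, ambient below 1,000 DNA reads; a cluster when > 99% of its reads
come from one species.

## Distance-decay statistics

* $P_c(s)$ bins the distance range 10 bp – 150 Mb into 500,000
  **equal-width linear** bins (≈ 300 bp each): "equally sized" is taken at
  face value, with log spacing applied only at display and fitting time.
  Pairs must be intrachromosomal, and an optional arm table confines both
  ends to one chromosomal arm (synthetic references declare an arm
  boundary; real centromere positions are external inputs).
* Per-cell aggregation: each cell's curve is normalized to unit mass
  before summation (`per_cell_then_sum`, the default for single-cell
  figures); a `pool_all` mode sums raw weights. Both are exposed because
  the ensemble description is ambiguous about the order of normalization
  and aggregation.
* The per-cell log-binned profile uses 150 bins whose edges follow
  $2^{\log_2 5000 + k\,(\log_2 1.5\times10^8 - \log_2 5000)/150}$,
  $k = 0..150$. The prose count of "149 bins" conflicts with the indexing
  of the accompanying formula ($n = 1..150$); the formula is taken as
  operative, giving 150 bins and 151 edges (5,000 bp to 150 Mb exactly).
  Frequencies are divided by bin width and normalized to unit sum per
  cell.
* Slope fitting (`fit_pc_slope()`) aggregates the fine linear bins into
  log-spaced windows (frequency per bp) before regressing on
  log-distance; fitting on raw 300-bp bins would give the sparse far tail
  one point per bin and bias the fit.

## Compartment scores

Observed/expected (expected = distance-stratified mean over informative
bins), correlation matrix, first eigenvector. PC1's sign is arbitrary, so
it is oriented to correlate positively with a caller-supplied reference —
by convention a gene-density track, since the A compartment is gene dense.
Degenerate (flat-correlation) matrices raise an error rather than return
noise; map pairs are compared after log-scaling and division by each map's
own maximum, constraining both to [0, 1].

## RNA-side analytics

Pre-mRNA calls require ≥ 15 bp of same-strand overlap with a
protein-coding intron. RAL tracks take every cluster with at least one
selected RNA read (and total size ≤ 1,000), and add $1/(\text{cluster
size})$ per selected-RNA × DNA pair at the DNA end's bin; the denominator
is the full cluster size, keeping one constant per cluster. XAL is the
number of distinct 1-Mb chromosome X bins with positive XIST attachment in
a cell — any positive weight counts, since no minimum is published; the
threshold is configurable. Stratification puts XAL = 0 cells in group
"zero" and splits the rest, sorted by XAL with cell-id tie-breaks, into
three equal-count groups (sizes differ by ≤ 1).

The XIST⁻ set includes DNA-only clusters by default (it is defined as
RNA–DNA *and* DNA–DNA clusters without an XIST read); an option excludes
them for sensitivity analysis. The any-RNA split serves as the control
contrast.

## Per-cell state

* QC keeps cells with ≥ 100 RNA and ≥ 5,000 DNA reads (inclusive).
* Expression: library-size log-normalization
  $x \mapsto \ln(1 + 10^4 x / \text{libsize})$. "Expressing" means raw
  count > 0; "average expression" uses normalized values. Both are
  configurable.
* Cell-type assignment score: $2\times$ mean marker expression + fraction
  of cluster cells expressing ≥ 1 marker; argmax with a deterministic
  lexicographic tie-break (logged). Graph clustering itself is out of
  scope — cluster labels are inputs.
* LCS-erosion score: the ten most contact-rich profile bins (ties toward
  smaller distance), midpoint = geometric mean of the bin edges (the bins
  are log-spaced, so the geometric mean is the natural "middle"), score =
  median of the ten midpoints; > 3×10⁵ bp ⇒ eroded. Cells with fewer than
  ten non-empty bins use all of them and are flagged low-confidence.
* Transcriptomic age: gene direction = sign of the correlation between
  per-sample mean expression and sample chronological age (computed
  globally; a per-cell-type variant would only need subsetting), weight =
  expressing-fraction × direction, age = z-scored expression · weights.
  Zero-variance genes are skipped and counted. The score is invariant to
  per-gene affine rescaling by construction.
* LCS-associated genes: the published "ANOVA between expression and
  LCS-erosion score" with a *continuous* score is implemented as the
  F-test of a univariate linear regression (the two coincide only for
  grouped predictors, and only the regression reading yields both an F
  and a Spearman ρ on the same inputs); pass = P < 0.01, F > 1,
  |ρ| > 0.1.

## eQTL–contact association

A contact supports an eQTL–target pair when one fragment end overlaps the
variant (1-bp interval, 1-based input converted to the package's 0-based
internals) and the other overlaps the promoter (TSS ± 2,500 bp, closed);
both end assignments are tried. Contacts are typed by their cell of
origin's label (unassigned cells excluded); rows of the 6×6 table are
contact types, columns eQTL types (the global test is symmetric in this
choice). The global test is Pearson's chi-square (df = 25 for six types);
each type's 2×2 reduction gives OR = ad/bc with
SELOR = √(1/a+1/b+1/c+1/d) and CI exp(log OR ± 1.96·SELOR);
zero cells trigger the Haldane–Anscombe +0.5 correction, flagged.

The calibration generator draws each supporting contact's cell type with
odds $K$ for its pair's own type; the per-type true odds ratio is then
$K(K+k-2)/(k-1)$ for $k$ types, which the coverage tests use as the
oracle.

## The synthetic-data generator

The generator is the package's study-conditions definition, not a tuning
knob. Defaults: non-singleton cluster sizes are 2 with probability
0.7226 — the size-2 share observed among non-singleton DNA-only clusters
in deep ensemble data — and otherwise follow a truncated power law
$k^{-2.5}$ on 3..100; 10% singletons; RNA fraction 0.2 per member;
intra-complex distances follow $s^{-1}$ on 1–200 kb within one arm; insert
lengths 30–60 bp; XIST attachment in 15% of female-cell complexes; PCR
duplicates are Poisson-distributed copies sharing molecule UMIs. The
desk-scale end-to-end condition is 200 cells × 20–60 complexes (≈ 50,000
read triples with 50% duplicates), which one CPU processes in under two
minutes. Within a cell, complexes receive distinct (GEM, I7) pairs; the
real assay also relies on the complex-barcode space being much larger than
the per-cell complex count, and sampling without replacement makes the
zero-noise partition-recovery check exact rather than
probabilistic. (A note on that space: the published description multiplies
8 I7 indices by 3.5 million GEM barcodes but prints a total of ~83.5
million; the product is 28 million. The simulator's space is
whitelist-configurable and the discrepancy is simply noted.)

Focused generators plant the recovery scenarios: power-law contact sets
(slope recovery), log-normal two-population distance mixtures centered at
$10^{4.5}$ and $10^{6.5}$ bp with σ = 0.4 decades, straddling the 3×10⁵
threshold by a decade on each side (classification recovery), 2-fold
ageing-modulated Poisson expression over four donor ages 62–89
(age recovery), block-confined multiplex versus distance-law pairwise
clusters (TAD-mass property), and the match-odds eQTL model above.

What the generator does **not** emulate: realistic base-quality and
instrument error profiles, spliced RNA inserts (RNA molecules stay within
a contiguous gene segment, so the exact mapper remains valid), copy-number
structure, chromatin-state-dependent coverage, barcode hopping, and real
genome repeat structure. Passing tests therefore demonstrate the
correctness of the algorithms under their stated models — exact recovery
where exactness is the claim, statistical recovery at planted effect
sizes elsewhere — not end-to-end performance on real libraries.

## Known limitations

* The exact mapper requires synthetic (repeat-poor) references; real data
  must be aligned externally and imported from BAM.
* Spliced alignment and escape-gene calling are out of scope.
* The compartment score needs ≥ 10 informative bins at ≥ 100 kb-scale
  resolution and a user-supplied orientation reference.
* Iterative matrix balancing, TAD calling and `.hic`/`.mcool` parsing are
  intentionally absent; plain matrices are accepted for map comparisons.
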