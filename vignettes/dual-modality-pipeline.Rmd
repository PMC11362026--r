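---
title: "Models and methods behind the dual-modality chromatin pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the dual-modality chromatin pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and its computational problem

A dual-modality tagmentation assay loads two Tn5 transposases into the same
cell: a protein-G–Tn5 fusion tethered to an antibody against a histone mark
(typically the Polycomb-associated repressive mark H3K27me3, or the
enhancer mark H3K4me1), and a free Tn5 that cuts accessible chromatin. Each
transposase carries adapters with a distinct 8-bp tag, so a sequenced
fragment records three things: where it came from (its alignment), which
transposase made it (the modality tag, embedded at the start of both
genomic reads), and which droplet it came from (a cell barcode on a
separate 48-bp barcode read; reads are 50 + 50 + 48 bp). The computational
task is to turn the raw trio into two per-cell fragment sets — a
histone-modification profile and an accessibility profile for the *same*
cells — and then exploit the pairing: which genes have open promoters yet
sit under repressive domains, which alternative TSS a cell type uses, and
whether the two modalities see the same cell populations.

# Barcode scheme and error correction

The scheme object pins the whole read architecture: the tag table
(8 histone tags B1–B8 for the pG-Tn5 side, 8 accessibility tags B9–B16 for
the free Tn5), the tag window on read1/read2, and the two 10-bp cell
segments at offsets 0 and 20 of the barcode read (a droplet-platform
convention; everything is overridable through a YAML config). Published
adapter sequences are not available, so the default tag set is generated
deterministically: candidate 8-mers are drawn from a fixed
linear-congruential stream and kept greedily whenever they differ from all
accepted tags at ≥ 3 positions. Minimum pairwise Hamming distance
$d_{\min} \ge 2m + 1$ guarantees that correcting up to $m$ substitutions
can never be ambiguous; the shipped set supports $m = 1$, and an exhaustive
test mutates every base of every tag to confirm recovery. `N` counts as a
mismatch against every base. When both genomic reads carry a tag the two
ends must agree on modality; disagreement is recorded as `tag_conflict` and
the read goes to the `unassigned` bin rather than being dropped — the three
output bins always partition the input, which is the property the fuzz
tests assert. Separately amplified libraries (the C1/C2 route) are handled
by a `library_tag` that forces the run's modality while per-read tags
remain a QC cross-check.

# The synthetic data generator

Every downstream stage is tested against planted truth, so the generator is
first-class code. It emulates:

* **Genome and layout.** Two 2-Mb contigs; genes and distal regulatory
  elements occupy a 10-kb grid so broad domains never collide by accident.
* **Regulatory states.** Each gene, per cell type, is planted as
  `active_accessible` (promoter peak only), `accessible_silenced` (promoter
  peak *inside* a broad repressive domain — the state the joint assay
  exists to detect), `repressed_closed` (domain only) or `inactive`.
  Default fractions 0.10 / 0.15 / 0.10 / 0.65 are allocated by `ceiling`,
  so planted counts are exact; the accessible total (0.25) and repressed
  total (0.25) match the classifier's default 0.75 quantile thresholds, so
  recovery is a fair round trip rather than a calibration exercise.
* **Distal elements.** Promoter accessibility peaks are 500 bp; repressive
  domains 5 kb. Distal slots carry one mark each except for a configurable
  fraction (`overlap_fraction`, default 0.027) carrying both — co-marked
  chromatin is a small minority of the regulatory landscape. Half of the
  distal slots (`distal_type_specific_fraction = 0.5`) belong to a single
  cell type. This last knob exists because enhancer-like distal elements
  are the most cell-type-specific part of real chromatin landscapes; with
  fully shared distal elements the planted types differ at only ~100 of
  8,000 tiles and no LSI-class embedding separates them at realistic
  depth — a simulation artifact, not a property of the assay.
  `overlap_fraction = 0` together with a nonzero `accessible_silenced`
  fraction is rejected at config time: that state is co-marked by
  definition.
* **Depth and sizes.** Per-cell fragment counts are negative binomial
  (droplet data are overdispersed; the defaults mirror the assay's
  published per-cell depths — means of 1724 histone and 3129 accessibility
  fragments per cell — and are scaled down in tests). Fragment sizes come from a truncated-normal mixture at 80 / 200 /
  400 / 600 bp (weights 0.15 / 0.50 / 0.20 / 0.15), reproducing the
  sub-nucleosomal + mono/di/tri-nucleosome ladder.
* **Nuisance processes.** PCR duplicates (default rate 0.3) copy an
  *original* molecule drawn earlier in the same cell and modality — never
  another duplicate, so the planted unique count is well defined. Ambient
  fragments (default 5%) are uniform on the genome with a barcode sampled
  from real cells. In-peak fractions default to 0.53 (histone, matching the
  reported FRiP) and 0.60 (accessibility).

What the generator does **not** emulate: sequence-dependent Tn5 bias,
doublets, copy-number variation, mappability gaps, or chromatin-state
autocorrelation along the genome. Passing tests therefore demonstrate
correctness of the *computations* under a faithful statistical skeleton,
not performance on every pathology of real libraries.

Reads are written with the tag and cell barcode embedded per the scheme;
genomic read content is filler from a fixed pseudo-random per-contig
sequence, because alignment is out of scope and coordinates travel through
an emitted aligned table (`read_id, contig, start, end, strand, mapq`)
whose outer coordinates exactly undo the Tn5 correction.

# Fragments, cells, QC

Tn5 inserts in pairs 9 bp apart, so the plus-strand start is shifted +4 and
the minus-strand end −5; records that invert after shifting are discarded
and itemized, negative starts clamp to 0, records without a barcode go to a
counted bin, and MAPQ < 30 is dropped when a `mapq` column exists.
Deduplication is exact collapse on (contig, start, end, barcode) — verified
against a brute-force hash oracle — and the fragment file is the standard
sorted five-column TSV.

Cell calling is a strict threshold (≥ 500 fragments; a 499-fragment barcode
is excluded, a 500-fragment one kept) or a knee: the point of maximum
distance from the chord of the log-rank/log-count curve.

The TSS enrichment score treats both fragment ends as insertions. For each
cell, score = (insertions per bp within ±50 bp of any TSS) / ((flank
insertions + 1) per bp over the outermost 100 bp at each edge of the ±2 kb
window). The +1 pseudocount keeps the score finite when flanks are empty;
under a uniform null the score is $c/(c + 1/200) \approx 1$ at realistic
densities, which the tests assert within ±0.1 at 100,000 insertions. Cell
filters keep a cell iff TSS score ≥ {histone: 0, accessibility: 2} **and**
fragments ≥ 500, both comparisons strict on the "below" side, so a histone
cell with score exactly 0 passes. The filter is monotone in both
thresholds.

The size-distribution module histograms sizes at 1 bp, smooths with an
11-bp running mean, and reports local maxima by topographic prominence
(≥ 5% of the global maximum; plateaus report their centre); the periodicity
score is the positive autocorrelation peak nearest the 180–220-bp
nucleosomal band, reported as 0 with a flag when no positive peak exists.
Signal-to-noise is defined operationally — mean per-bp coverage in peaks
over the mean across seed-deterministic, size-matched random non-peak
placements — because the published ratios derive from metagene plot heights
with no stated formula.

# Two peak callers, two signal classes

**Punctate (accessibility/H3K4me1-like).** Insertions are binned at 50 bp;
each bin count is tested one-sided against Poisson with the genome-wide
rate λ·bin; Benjamini–Hochberg across *all* bins; q ≤ 0.01 bins are merged
across gaps ≤ 150 bp, and peaks narrower than 100 bp are dropped. Under a
pure Poisson null the empirical significant-bin fraction stays ≤ 0.01
across 10 seeds, and isolated false bins fall to the width filter. On
planted 10× enrichment over 1% of a 2-Mb genome at 100,000 fragments the
caller reaches recall and precision 1.0 against truth.

**Broad (H3K27me3-like).** Contiguous blocks of nonzero coverage are
enumerated; block signal is the area under the coverage curve; blocks whose
signal reaches the 95th percentile (type-1 quantile, ties kept — the
deterministic, conservative choice) are retained, and "stringent" mode also
requires the block maximum to reach the same percentile of block maxima.
This retention rule keeps the top 5% of blocks *whatever the data*, exactly
like the fraction parameter of sparse-enrichment callers it simplifies; it
therefore resolves individual domains only when background coverage has
zero-gaps (blocks exist) and the true domain count is near 5% of all
blocks. The evaluation simulation encodes that regime — 100 × 2-kb domains,
~4,000 scattered background fragments producing ~1,950 isolated background
blocks — and the caller then recovers domains with recall and precision
≥ 0.99. A dense 10×-enrichment library has no zero-coverage gaps at all,
hence no block structure; that regime belongs to the insertion caller.

Both callers are translation-equivariant when the genome is held fixed
(changing contig lengths changes λ and the number of BH tests, which
legitimately changes calls). Peak annotation uses the midpoint rule with
precedence promoter (strand-aware TSS ± 3 kb) > genic > distal; overlap
between peak sets is interval-only (≥ 1 bp after merging); signal
quantification counts fragments per peak, converts to counts per million of
the sample total, and correlates samples on log1p(CPM).

# Tiles, LSI, clustering

Tile matrices count fragment midpoints into 500-bp (accessibility) or
5000-bp (histone) windows — the midpoint rule makes each fragment count
exactly once. The embedding is single-pass LSI: binarize, keep the
`top_features` most prevalent tiles, weight TF × log(1 + N/df), exact
truncated SVD via the cells × cells Gram matrix (cell counts here are far
below feature counts), drop the depth-dominated first component, fix signs
deterministically. Single-pass LSI replaces the original two-iteration
refinement; the iteration's job (re-selecting features where variation
lives) is done here by scaling the feature cut to the genome: 25,000 tiles
against a human genome keeps the signal-dense minority, and the same
role on the 4-Mb toy genome (8,000 tiles) is played by a 2,000-tile cut,
which is what the end-to-end tests use. Clustering is seeded k-means
(deterministic; an SNN-graph option exists behind a flag) with mean
silhouette reported. On two planted cell types × 300 cells the per-modality
ARI is ≥ 0.98 and the cross-modality correspondence ≥ 0.99.

# Joint analyses

**Gene scores.** A fragment contributes weight 1 when its midpoint lies in
the gene body extended 2 kb promoter-side, and $e^{-d/5000}$ (capped) for
continuum distance $d$ up to 100 kb; scores are depth-normalized per cell
to 10,000. The formula is verified against a per-fragment loop oracle and
is additive over fragment subsets before normalization.

**Regulatory states.** Within each cell group, a gene is *accessible* when
its group-mean accessibility score reaches the group's 0.75 quantile and
*repressed* analogously for the histone score; quantile ties are kept
(≥), but a score of exactly 0 never makes a positive call — absent signal
is not evidence. The four combinations give the state table; the quantile
formulation is scale-free (invariant to positive rescaling of either
matrix, which the tests assert) and every call records the thresholds used.
With expression supplied, the summary reports the fraction of accessible
genes not expressed and the fraction of those carrying repression — the
assay's explanation for silenced-yet-open genes — without asserting any
particular published percentage, since the thresholds behind those
percentages are unstated.

**Co-occupancy, TSS choice, PSI, correspondence.** Base-pair co-occupancy
partitions the union of the two merged peak sets into both /
accessibility-only / repression-only (verified against a per-bp bitmap).
Alternative-TSS preference scores each TSS window (±500 bp) as
$S = A/(1+R)$ — accessibility density discounted by repression density — so
an accessible TSS free of repressive signal beats an equally accessible one
buried in it; ties go to the lower coordinate and are flagged. PSI divides
a junction's count by its donor-site family total (the standard
competing-junction convention), undefined when the family total is 0.
Cluster correspondence builds the confusion matrix over barcode-paired
cells and finds the exact maximum-agreement one-to-one label mapping by
bitmask dynamic programming (exact to ~20 labels; verified against a
factorial search). Marker features use Wilcoxon rank-sum with BH
adjustment, significant at adjusted p ≤ 0.05 and log2 fold change ≥ 0.5.

# Numerical choices and degenerate inputs

Coordinates are 0-based half-open throughout; interval joins subtract one
from ends so book-ended intervals do not overlap. Quantiles: type 1 in the
block caller (clean tie semantics), type 7 in the state classifier
(continuous scores). Empty inputs return empty, flagged results rather than
errors wherever the spec of the operation makes that meaningful (empty peak
sets, zero-read demux runs, all-zero coverage); truly malformed input
(mismatched trio lengths, unknown modality, negative counts) errors with a
named cause. All stochastic components take explicit seeds and the
simulator restores nothing to the global RNG that tests depend on; repeated
runs are byte-identical.

# Test problem sizes

The suite runs the demultiplexing round trip at 50,000 reads, dedup oracles
at 10,000 records, QC nulls at 100,000 insertions, each peak-caller
evaluation at 100,000 fragments on a 2-Mb genome, state recovery at
120 cells × 100 genes, clustering at 600 cells, and the replicate-CPM
property at 400,000 fragments over a 2,000-peak universe with lognormal
(sd 1.5 in log) peak intensities — deep enough that Poisson counting noise
does not mask the replicate property being tested. These sizes are the
package's chosen study conditions for a laptop-scale, fully reproducible
validation; published headline numbers from the deposited sequencing data
(cell counts, FRiP values, overlap percentages) depend on that data and are
deliberately not asserted.

# Known limitations

One barcode is treated as one cell: bead-to-droplet deconvolution
(multiple beads per droplet) is not reimplemented. The callers are
contract-pinned simplifications, not drop-in replacements for the external
tools they mirror. The simulator's independence assumptions (states i.i.d.
across genes, no genomic autocorrelation) make recovery cleaner than real
tissue; treat the round-trip guarantees as necessary, not sufficient,
evidence for real-data performance. bigWig output is out of scope
(bedGraph text only), as are motif enrichment, GO analysis, and survival
modelling.
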