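---
title: "Methods: combinatorial segmentation and SOM compression of epigenetic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial segmentation and SOM compression of epigenetic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `episegsom`, the
parameters that matter, the numerical choices made where the design was
genuinely open, what the synthetic-data generator does and does not
emulate, and the known limitations. It states no empirical result that the
package's tests do not themselves compute.

## The model

### Discretization

For one histone mark in one cell type, the input is a per-position read
count track plus a whole-cell-extract (WCE) control track. The enrichment
at position $p$ is $r(p) = n_\text{mod}(p) / n_\text{WCE}(p)$, defined
only where $n_\text{mod}(p) > 0$. Binary modified regions are called by
scanning each chromosome: positions with $r \ge \theta$ (threshold
$\theta = 3$, inclusive) are joined into one region while consecutive kept
positions are strictly closer than 100 nt (about one nucleosome); a region
spans `[first_kept, last_kept + 1)`; candidate regions shorter than 100 nt
are discarded as likely mapping noise. The binary representation trades
intensity information for robustness to the heavy-tailed noise of
ChIP-seq enrichment values and for a drastic reduction of input
dimensionality. Where an H3-occupancy control is available, modification
counts are zeroed at positions with no H3 reads before the ratio is
taken.

Choices the recipe does not pin down, and what this package does:

* **WCE count of zero at a position with modification reads.** Default
  policy `exclude` (the ratio is undefined, the position never enters a
  region) — the conservative reading of an undefined $x/0$; a
  `pseudocount` policy (divide by a configurable pseudocount, default 1)
  is available for sparse controls.
* **Windowing.** Enrichment is strictly per base; no smoothing window.
* **Normalization.** The ratio uses raw counts (no library-size scaling);
  optional per-track scale factors default to 1.

### Combinatorial segmentation

Given the $m \times n_\text{cells}$ panel of modification states, a
reference list of $n$ states is selected: all $m$ marks of a reference
cell type (**ES** mode, $n = m$) or one reference mark in every cell type
(**EV** mode, $n = n_\text{cells}$). Per chromosome, the boundary set is
$\{0, L\}$ plus every region start and end of every reference state;
consecutive boundaries delimit candidate segments; segments shorter than
200 bp (strictly) are omitted as below the discretization limit of
roughly one nucleosome's worth of DNA plus linker, and are written to a
side table for audit. Because all reference boundaries are projected,
every retained segment is covered exactly 0% or 100% by each reference
state — the implementation asserts this rather than assuming it — and the
$k$-th bit of the segment's CEP records which. The complementary
$m n_\text{cells} - n$ states contribute fractional coverages
(overlapped bases / segment length $\in [0,1]$). The training vector (EP)
is the CEP followed by $w \cdot$ coverage; the weight $w$ (default 1)
tunes whether the SOM texture is governed by the combinatorial part or by
the coverage part. Canonical state order is marks in panel declaration
order, then cell types in declaration order; it is recorded in the EP
column names so CEP strings like `ES110` are reproducible.

Chromosome ends count as boundaries so flanking unmodified chromatin
forms segments; this is what makes the all-zero CEP (`ES000`/`EV000`) —
typically the vast majority of chromatin — appear as ordinary segments.

One inconsistency in the build contract is worth recording: its worked
segmentation example drops a 100 bp candidate `[200,300)` but keeps an
equally short `[500,600)`. The rule (strictly `< 200` dropped) is applied
uniformly here; the example's segment count was corrected accordingly in
the tests.

### Deterministic SOM

The EPs are compressed onto a rectangular grid (default $40 \times 40$,
i.e. 1600 meta-EPs; smaller grids are used throughout the tests for
runtime). Everything is deterministic:

* **Linear initialization.** With data mean $\mu$ and leading
  eigenpairs $(\lambda_1, u_1), (\lambda_2, u_2)$ of the EP covariance,
  the meta-EP at grid row $r$, column $c$ is
  $\mu + a(c)\,2\sqrt{\lambda_1}\,u_1 + b(r)\,2\sqrt{\lambda_2}\,u_2$
  with $a, b$ linear maps onto $[-1, 1]$. The mean sits in the center of
  the map and the dominant variation spans the sides. The $\pm 2\sqrt\lambda$
  span is the conventional choice and is configurable. If
  $\lambda_2 \approx 0$ the second axis is an arbitrary orthogonal unit
  vector with zero amplitude, with a warning.
* **Training.** Per epoch $e$ of $E$, gain and radius are linear
  interpolations $\alpha_e, \sigma_e$ between their endpoints (defaults
  $\alpha: 0.05 \to 0.005$, $\sigma: \text{width}/4 \to 1$ — declared
  package choices, not published values, since the original endpoint
  numerals are not recoverable). Profiles are presented in input order
  (no shuffling — shuffling would break determinism); the best-matching
  node minimizes squared Euclidean distance with ties to the lowest node
  index; every meta-EP is updated as
  $x_j' = x_j + \alpha_e\, h(j, \text{winner}; \sigma_e)\,(e - x_j)$
  with Gaussian neighborhood $h = \exp(-d^2 / 2\sigma^2)$ ($d$ =
  Euclidean grid distance). The update rule is the canonical Kohonen
  form; the source text's equation image is unreadable and the rule is
  reconstructed from its prose ("adaptation gain", Gaussian
  "neighborhood function", convergence behavior) — at $\sigma \to 0$ it
  reduces to winner-only online k-means, which the tests verify against
  an independent reference implementation.
* **Epochs.** `default_epochs()` targets roughly 200,000 profile
  presentations total (epochs $\approx 2\cdot10^5 / N$, minimum 1 with a
  warning when $N$ alone exceeds the target). "Iterations" are read as
  profile presentations, not epochs.
* The neighborhood value at the winner itself is 1: the Gaussian taken
  literally peaks at $d = 0$; prose saying it is "maximal for adjacent
  nodes" is treated as informal.

After the final epoch, assignments are recomputed once against the frozen
codebook.

### Maps

All maps are one scalar per node, written as TSV matrices with JSON
sidecars (scale hint, inversion flag, legend); mosaic PNGs are derived
artifacts. Specifics:

* **Islands** are 4-connected components (8-connectivity is available;
  which one the original analysis used is unstated) of nodes with
  occupancy strictly greater than 10. Each island is labeled by the CEP
  of its member segments; a mixed island is labeled `"mixed"` with a
  warning rather than an error, because CEP-homogeneity is an empirical
  finding, not an invariant. CEPs spanning several islands get postfixes
  `a`, `b`, … by decreasing node count — the original `a`/`b` naming is
  data-semantic and not computable in general.
* **The coverage atlas uses unweighted data coverage** (reference states
  contribute their 0/1 bit), never the trained codebook: tiles are
  colored "by the average coverage of the segments assigned", i.e. from
  the data. $w$ affects training only.
* **CpG density** counts plus-strand `CG` dinucleotides fully inside the
  segment divided by segment length; `N` never matches; matching is
  case-insensitive.
* **Present-call map:** transcripts are extended 2000 nt upstream of
  their 5′ end (strand-aware, clipped); a gene is "present" when flagged
  present in every cell type of the panel; a segment's score is the mean
  present value over overlapping genes (≥ 1 bp against the extended
  span); segments overlapping no gene are excluded; "active" means score
  ≥ 1.0 by default, i.e. exclusive overlap with all-present genes — the
  original threshold numeral is unrecoverable and the "exclusively
  overlap" phrasing motivates 1.0, exposed as `active_threshold`.
* **Chromosomal enrichment:** $E_{kc} = N_k N_c / N$ (hypergeometric
  expectation), map value $\log_2 (n_{kc} / E_{kc})$, masked (not
  $\pm\infty$, no pseudocount) where $n_{kc} = 0$ or $N_k = 0$ —
  published color scales for these maps are strictly positive,
  suggesting masked zeros.
* The default color ramp is blue → green → red; the segment-length map
  inverts it so short segments read warm. Log-scaled rendering uses
  $\log_{10}(v + 1)$ for count-like maps containing zeros and
  $\log_{10} v$ otherwise.

## The synthetic-data generator

`synthetic_spec()` describes a stated toy world: by default two 100 kb
chromosomes, 3 marks × 3 cell types, and per chromosome one 600 bp block
for each of the 7 non-zero CEPs, 2.5 kb apart (wider than the 2 kb gene
extension so planted genes never reach a neighboring block). The all-zero
CEP arises from the gaps — all-zero blocks are rejected as unrepresentable
(they create no reference boundaries). Complementary-state coverage
targets are realized as leading sub-intervals rounded to whole bases, so
region-level ground truth is exact and `make_region_panel()`'s truth table
is recovered bit-for-bit by the segmentation.

Read counts are Poisson per position: WCE at rate 1 (`background`),
modification tracks at `background * enrichment_rate` (default 10) inside
planted regions and `background * low_rate` (default 0.1) outside, H3 at
`3 * background` so the H3 validation step discards only the Poisson-zero
tail. With these defaults the called regions recover ≥ 95% of planted
bases and base-level Jaccard ≥ 0.9 (verified over seeds in the tests);
planted blocks total a few percent of the genome, mirroring the situation
where almost all chromatin is unmodified. Genes are planted one per block
plus one per gap; genes in blocks whose CEP marks only the first
reference state are present in every cell type, other block genes only in
the first. The genome sequence is a first-order Markov chain whose
`CG`-dinucleotide density hits `cpg_background` (0.01/bp, a CpG-depleted
baseline) genome-wide and `cpg_target` (0.06/bp) inside blocks carrying
the first mark, emulating CpG islands at active chromatin.

What the generator does **not** emulate — and hence what a green test does
not establish: fragment-length and duplicate-read structure, mappability
or GC bias, chromosome-scale heterogeneity, intensity gradients within
regions, and genome-scale data volumes. Green tests establish that the
algorithms are implemented correctly (oracle equivalence, ground-truth
recovery, determinism), not that the defaults are optimal for any real
data set.

## Numerical and testing choices

* Coordinates are 0-based half-open everywhere internally (GTF converted
  on read); chromosome names match by exact string equality.
* Overlapping bedGraph count records are an error, never summed.
* BMU ties and boundary deduplication are resolved deterministically;
  two runs on identical inputs produce byte-identical grids,
  assignments and TSV outputs (asserted in the tests).
* Interval coverage is computed with a prefix-sum function over the
  sorted disjoint region sets; the test suite checks it against an
  independent per-base labeling oracle on 1,000 random panels.
* The SOM inner loop is C++ (Rcpp); at the ~200,000-presentation target a
  pure-R loop would be orders of magnitude too slow.
* The acceptance criterion on SOM purity fixes 600 profiles and 20 seeds
  but not the grid; a 10 × 10 grid keeps 20 training runs within the
  stated runtime budget while leaving ample room for three clusters.
* `training_schedule()` accepts $\alpha = 0$ (null learning) even though
  a strictly positive gain is the normal regime — the zero case is the
  natural control for testing that training only ever reduces
  quantization error.

## Limitations

* No HMM-style state inference, motif discovery, batch or toroidal SOMs,
  or second-level SOM-of-SOM analysis.
* Region calling consumes per-position counts or pre-called regions; read
  mapping and read-level filtering are out of scope.
* Island postfix letters are assigned by size, not by modification
  semantics; users may relabel.
* The hypergeometric enrichment map is biased slightly below zero at low
  expected counts (Jensen's inequality on $\log$ of a small count); the
  tests bound it at |mean| < 0.1 for $N_c \ge 5000$ on a 40 × 40 grid.
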