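# episegsom

Annotation-independent exploration of combinatorial histone-modification
patterns from multi-sample ChIP-seq data.

## The problem

Genome-wide ChIP-seq experiments routinely measure several histone marks
(e.g. H3K4me3, H3K27me3, H3K9me3) across several cell types. Most analysis
tools view such data gene-by-gene along the linear genome, which makes
global questions — how do *combinations* of marks co-occur, and how do they
reorganize during differentiation? — hard to ask. `episegsom` takes the
opposite, annotation-free route:

1. **Discretize.** Per-position read counts are divided by a whole-cell-
   extract (WCE) control to get an enrichment ratio. Positions with ratio
   ≥ 3 are joined into *modified regions* when consecutive kept positions
   are closer than 100 nt (less than one nucleosome); candidate regions
   shorter than 100 nt are treated as unmodified. The resulting region set
   is the *modification state* (MS) of one mark in one cell type.
2. **Segment.** A reference set of *n* states is chosen: all *m* marks of
   one cell type (**ES**-segmentation, "epigenome state") or one mark in
   all cell types (**EV**-segmentation, "epigenome variation"). All region
   boundaries of the reference states are projected onto the genome; the
   superposition partitions each chromosome into segments, and segments
   shorter than 200 bp are omitted. By construction each retained segment
   is covered 0% or 100% by every reference state, giving an *n*-bit
   **combinatorial epigenetic profile** (CEP, e.g. `ES110` = H3K4me3 and
   H3K27me3 but not H3K9me3 in the reference cell type). The remaining
   m·n − n states contribute fractional coverages in [0, 1], which —
   scaled by a weight *w* (default 1) and appended to the CEP — form the
   m·n-dimensional **epigenetic profile** (EP) of the segment.
3. **Compress and visualize.** The EPs are clustered on a Kohonen
   self-organizing map (default 40 × 40 = 1600 "meta-EPs"). Initialization
   is linear (the two leading principal axes span the grid), training is
   sequential with a Gaussian neighborhood
   h(j, winner) = exp(−d²/2σ²) and linearly decaying gain α(t) and radius
   σ(t), and iteration order is the input order — the whole procedure is
   deterministic. The trained map is rendered as mosaic *SOM-images*:
   population map, CEP-island map (connected components of nodes with
   > 10 EPs, empirically CEP-homogeneous), per-state coverage atlas, and
   supporting maps (mean segment length, CpG density, expression
   present-call fraction, gene-set fraction, and per-chromosome
   hypergeometric enrichment log₂ n_kc/E_kc with E_kc = N_k·N_c/N).

A fully seeded synthetic-data generator (`synthetic_spec()`,
`make_region_panel()`, `make_count_tracks()`,
`make_genes_and_expression()`) plants blocks with known CEPs, coverage
levels, Poisson read depths, CpG-rich intervals and genes with declared
present/absent calls, so the entire pipeline is testable offline with
known ground truth.

## Worked example

```r
library(episegsom)

spec <- synthetic_spec(seed = 17)            # 2 x 100 kb toy chromosomes
rp   <- make_region_panel(spec)              # 3 marks x 3 cell types
segs <- segment_genome(rp$panel, segmentation_config("ES", "ESC"))
segs
#> epi_segmentation (ES, ref: ESC): 30 segment(s), 0 dropped (< 200 bp)

table(segs$cep_labels)[1:6]
#> ES000 ES001 ES010 ES011 ES100 ES101
#>    16     2     2     2     2     2

grid0   <- linear_initialize(segs$profiles, 10, 10)
trained <- som_train(segs$profiles, grid0,
                     training_schedule(default_epochs(nrow(segs$profiles)),
                                       0.05, 0.005, 2.5, 1))
quantization_error(segs$profiles, trained$grid, trained$assignment)
#> 0.0067

island_labeling(trained$assignment, segs$cep_labels, trained$grid, 10)
#> island_labeling: 1 island(s) (occupancy > 10)
#>    island  label n_nodes n_segments
#> 1:      1  ES000       1         16
```

The 30 segments carry all 8 possible CEPs; the 16 unmodified (`ES000`)
segments — the gaps between planted blocks, i.e. the bulk of the toy
chromatin — form the single island that clears the > 10 EPs/node
threshold, while each planted CEP occupies its own node. The quantization
error is the mean Euclidean distance between each EP and its meta-EP.

`run_pipeline()` executes the whole chain (optional discretization →
segmentation → SOM → maps → PNG mosaics) from a JSON config and writes
TSV matrices, JSON sidecars and a manifest; the `exec/episegsom` script
exposes `synth`, `discretize`, `segment`, `train`, `maps`, `render` and
`run` subcommands.

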