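test_that("region panel generation recovers its ground truth exactly", {
  spec <- synthetic_spec(seed = 21)
  rp <- make_region_panel(spec)
  segs <- segment_genome(rp$panel, segmentation_config("ES", spec$reference))
  expect_equal(as.data.frame(segs$segments),
               as.data.frame(rp$truth$segments[, c("chrom", "start", "end")]))
  expect_equal(segs$cep_labels, paste0("ES", rp$truth$segments$cep))
  expect_equal(unname(segs$coverage), unname(rp$truth$coverage),
               tolerance = 1e-12)
  # every non-zero CEP planted once per chromosome, zeros from the gaps
  expect_setequal(unique(segs$cep_labels),
                  paste0("ES", apply(expand.grid(0:1, 0:1, 0:1)[, 3:1], 1,
                                     paste, collapse = "")))
})

test_that("a block below the length filter vanishes from retained segments", {
  blocks <- data.frame(chrom = "chrS1", start = c(5000, 10000),
                       end = c(5150, 10600), cep = c("111", "100"))
  spec <- synthetic_spec(seed = 1, chrom_sizes = c(chrS1 = 50000L),
                         blocks = blocks)
  rp <- make_region_panel(spec)
  expect_false("111" %in% rp$truth$segments$cep)
  segs <- segment_genome(rp$panel, segmentation_config("ES", "ESC"))
  expect_false("ES111" %in% segs$cep_labels)
  expect_true("ES100" %in% segs$cep_labels)
})

test_that("generator validation rejects bad block specs", {
  expect_error(synthetic_spec(blocks = data.frame(
    chrom = "chrS1", start = 1000, end = 1500, cep = "000")), "all-zero")
  blocks <- data.frame(chrom = "chrS1", start = c(1000, 1600),
                       end = c(1500, 2100), cep = c("100", "010"))
  expect_error(synthetic_spec(blocks = blocks), "min_gap")
  b2 <- data.frame(chrom = "chrS1", start = 1000, end = 1500, cep = "100",
                   x = 1.2)
  names(b2)[5] <- "H3K4me3:MEF"
  expect_error(synthetic_spec(blocks = b2), "coverage fraction")
})

test_that("count tracks are seed-deterministic", {
  spec <- synthetic_spec(seed = 5, chrom_sizes = c(chrS1 = 30000L))
  t1 <- make_count_tracks(spec)
  t2 <- make_count_tracks(spec)
  expect_identical(as.data.frame(t1$wce), as.data.frame(t2$wce))
  expect_identical(as.data.frame(t1$mod[[1]]), as.data.frame(t2$mod[[1]]))
  t3 <- make_count_tracks(synthetic_spec(seed = 6,
                                         chrom_sizes = c(chrS1 = 30000L)))
  expect_false(identical(as.data.frame(t1$wce), as.data.frame(t3$wce)))
})

test_that("default rates recover planted regions; flat rates call almost nothing", {
  # scaled-down version of the 20-seed simulation: 3 seeds, one state
  cfg <- discretization_config()
  for (seed in 1:3) {
    spec <- synthetic_spec(seed = seed, chrom_sizes = c(chrS1 = 50000L))
    ct <- make_count_tracks(spec)
    planted <- make_region_panel(spec)$panel$states[["H3K4me3:ESC"]]
    called <- discretize_track(ct$mod[["H3K4me3:ESC"]], ct$wce, cfg = cfg)
    pm <- region_mask(planted, "chrS1")
    cm <- region_mask(called, "chrS1")
    expect_gte(sum(pm & cm) / sum(pm), 0.95)
    expect_gte(sum(pm & cm) / sum(pm | cm), 0.90)

    # enrichment_rate = background: inside rate indistinguishable from WCE
    spec_flat <- synthetic_spec(seed = seed, enrichment_rate = 1,
                                chrom_sizes = c(chrS1 = 50000L))
    ctf <- make_count_tracks(spec_flat)
    called_flat <- discretize_track(ctf$mod[["H3K4me3:ESC"]], ctf$wce,
                                    cfg = cfg)
    expect_lt(n_bases(called_flat) / 50000, 0.05)
  }
})

test_that("H3 validation discards little under the synthetic read model", {
  spec <- synthetic_spec(seed = 2, chrom_sizes = c(chrS1 = 30000L))
  ct <- make_count_tracks(spec)
  mod <- ct$mod[["H3K9me3:ESC"]]
  kept <- validate_against_h3(mod, ct$h3)
  expect_gte(nrow(kept) / nrow(mod), 0.9)
})

test_that("CpG-rich intervals realize the target density within 0.01", {
  blocks <- data.frame(chrom = "chrS1", start = 5000, end = 11000,
                       cep = "100")
  spec <- synthetic_spec(seed = 4, chrom_sizes = c(chrS1 = 30000L),
                         blocks = blocks)
  ge <- make_genes_and_expression(spec)
  rich <- cpg_density(data.frame(chrom = "chrS1", start = 5000, end = 11000),
                      ge$genome)
  expect_lt(abs(rich - spec$cpg_target), 0.01)
  bg <- cpg_density(data.frame(chrom = "chrS1", start = 15000, end = 30000),
                    ge$genome)
  expect_lt(abs(bg - spec$cpg_background), 0.01)
  # determinism
  ge2 <- make_genes_and_expression(spec)
  expect_identical(as.character(ge$genome), as.character(ge2$genome))
})

test_that("genes planted in active blocks drive the present-call map", {
  spec <- synthetic_spec(seed = 8)
  rp <- make_region_panel(spec)
  ge <- make_genes_and_expression(spec)
  segs <- segment_genome(rp$panel, segmentation_config("ES", spec$reference))
  # trivial identity assignment on a grid large enough for all segments
  n <- nrow(segs$segments)
  grid <- som_grid(n, 1, matrix(0, n, 1))
  pm <- present_call_map(seq_len(n), segs, ge$genes, ge$expression, grid)
  es100 <- which(segs$cep_labels == "ES100")
  expect_true(all(pm$values[es100] == 1))
  # blocks with other CEPs carry genes absent somewhere -> never active
  other <- which(!segs$cep_labels %in% c("ES100", "ES000"))
  expect_true(all(pm$values[other] == 0, na.rm = TRUE))
})

test_that("fixtures write out as plain text and round-trip", {
  spec <- synthetic_spec(seed = 12, chrom_sizes = c(chrS1 = 30000L))
  dir <- file.path(tempdir(), "fix12")
  write_synthetic_fixtures(spec, dir)
  expect_true(file.exists(file.path(dir, "panel", "panel.tsv")))
  layout <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(unclass(layout), c(chrS1 = 30000L))
  panel <- read_panel(file.path(dir, "panel", "panel.tsv"), layout)
  rp <- make_region_panel(spec)
  expect_equal(as.data.frame(panel$states[["H3K27me3:MEF"]]),
               as.data.frame(rp$panel$states[["H3K27me3:MEF"]]))
  gm <- read_gene_models(file.path(dir, "genes.bed"), layout, "bed12")
  expect_gt(nrow(gm), 0)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_true(all(c("ESC", "MEF", "NPC") %in% names(expr)))
})
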