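test_that("select_reference_states picks ES and EV references in canonical order", {
  gl <- toy_layout(1000)
  marks <- c("H3K4me3", "H3K27me3", "H3K9me3")
  cells <- c("ESC", "MEF", "NPC")
  states <- setNames(rep(list(region_set(layout = gl)), 9),
                     as.vector(t(outer(marks, cells, paste, sep = ":"))))
  panel <- state_panel(states, marks, cells)

  es <- select_reference_states(panel, segmentation_config("ES", "ESC"))
  expect_equal(es$ref_ids, paste(marks, "ESC", sep = ":"))
  expect_length(es$complementary, 6)

  ev <- select_reference_states(panel, segmentation_config("EV", "H3K4me3"))
  expect_equal(ev$ref_ids, paste("H3K4me3", cells, sep = ":"))
  expect_length(ev$complementary, 6)
  # complementary canonical order: marks in panel order, then cell types
  expect_equal(ev$comp_ids[1:3], paste("H3K27me3", cells, sep = ":"))

  expect_error(select_reference_states(panel, segmentation_config("ES", "HeLa")),
               "unknown reference")

  # degenerate 1x1 panel
  p1 <- state_panel(list("M:C" = region_set(layout = gl)), "M", "C")
  s1 <- select_reference_states(p1, segmentation_config("ES", "C"))
  expect_length(s1$reference, 1)
  expect_length(s1$complementary, 0)
})

test_that("build_segments reproduces the worked boundary example", {
  gl <- genome_layout(c(chr1 = 600))
  a <- region_set("chr1", 0, 300, gl)
  b <- region_set("chr1", 200, 500, gl)
  cfg <- segmentation_config("ES", "ref")
  segs <- build_segments(list("A:ref" = a, "B:ref" = b), gl, cfg)
  # candidates [0,200) 10, [200,300) 11, [300,500) 01, [500,600) 00;
  # [200,300) and [500,600) are 100 bp < 200 and are dropped
  expect_equal(segs$segments$start, c(0L, 300L))
  expect_equal(segs$segments$end, c(200L, 500L))
  expect_equal(unname(segs$cep), matrix(c(1L, 0L, 0L, 1L), ncol = 2))
  expect_equal(plain_df(segs$dropped),
               data.frame(chrom = "chr1", start = c(200L, 500L),
                          end = c(300L, 600L)))
})

test_that("build_segments handles empty and too-short chromosomes", {
  gl <- genome_layout(c(chr1 = 1000))
  cfg <- segmentation_config("ES", "ref")
  segs <- build_segments(list("A:ref" = region_set(layout = gl)), gl, cfg)
  expect_equal(plain_df(segs$segments),
               data.frame(chrom = "chr1", start = 0L, end = 1000L))
  expect_equal(unname(segs$cep), matrix(0L, 1, 1))

  gs <- genome_layout(c(chr1 = 150))
  segs2 <- build_segments(list("A:ref" = region_set(layout = gs)), gs, cfg)
  expect_equal(nrow(segs2$segments), 0L)
  expect_equal(nrow(segs2$dropped), 1L)
})

test_that("compute_coverage counts overlapped bases per segment", {
  gl <- genome_layout(c(chr1 = 400))
  cfg <- segmentation_config("ES", "ref", min_segment_length = 100)
  segs <- build_segments(list("A:ref" = region_set(layout = gl)), gl, cfg)
  comp <- list("X:oth" = region_set("chr1", c(100, 300), c(200, 350), gl),
               "Y:oth" = region_set(layout = gl),
               "Z:oth" = region_set("chr1", 0, 400, gl))
  segs <- compute_coverage(segs, comp)
  expect_equal(unname(segs$coverage[1, ]), c(0.375, 0, 1))
})

test_that("assemble_profiles concatenates CEP bits and weighted coverage", {
  gl <- genome_layout(c(chr1 = 1000))
  p <- tiny_panel()
  for (w in c(1, 0, 2)) {
    cfg <- segmentation_config("ES", "ref", min_segment_length = 100,
                               coverage_weight = w)
    segs <- segment_genome(p, cfg)
    ep <- segs$profiles
    expect_equal(ncol(ep), 4)
    expect_equal(unname(ep[, 1:2]), unname(segs$cep) + 0)
    expect_equal(unname(ep[, 3:4]), unname(w * segs$coverage))
  }
})

test_that("cep_label formats mode prefix plus bits", {
  expect_equal(cep_label(c(0, 0, 0), "ES"), "ES000")
  expect_equal(cep_label(c(1, 1, 1), "EV"), "EV111")
  expect_equal(cep_label(c(1, 0, 0), "ES"), "ES100")
  expect_equal(cep_label(rbind(c(1, 1, 0), c(0, 1, 0)), "ES"),
               c("ES110", "ES010"))
})

test_that("retained plus dropped segments tile each chromosome exactly", {
  gl <- toy_layout(50000)
  set.seed(23)
  for (i in 1:10) {
    panel <- random_panel(gl)
    segs <- segment_genome(panel, segmentation_config("ES", "C1"))
    all_iv <- rbind(as.data.frame(segs$segments),
                    as.data.frame(segs$dropped))
    all_iv <- all_iv[order(all_iv$start), ]
    expect_equal(all_iv$start[1], 0L)
    expect_equal(all_iv$end[nrow(all_iv)], 50000L)
    expect_true(all(all_iv$start[-1] == all_iv$end[-nrow(all_iv)]))
  }
})

test_that("segmentation equals the per-base oracle on random panels", {
  gl <- toy_layout(100000)
  set.seed(31)
  for (i in 1:20) {
    panel <- random_panel(gl)
    for (cfg in list(segmentation_config("ES", "C2"),
                     segmentation_config("EV", "M1"))) {
      segs <- segment_genome(panel, cfg)
      expect_matches_oracle(segs, panel, cfg)
    }
  }
})

test_that("at most 2^n CEPs occur and reference coverage is binary", {
  gl <- toy_layout(100000)
  set.seed(37)
  panel <- random_panel(gl)
  segs <- segment_genome(panel, segmentation_config("ES", "C1"))
  expect_lte(length(unique(segs$cep_labels)), 8)
  expect_true(all(segs$cep %in% c(0L, 1L)))
})

test_that("segments and profiles write out as documented", {
  p <- tiny_panel()
  segs <- segment_genome(p, segmentation_config("ES", "ref",
                                                min_segment_length = 100))
  f <- tempfile(fileext = ".bed")
  write_segments(segs, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V4, segs$cep_labels)
  fp <- tempfile(fileext = ".tsv")
  write_profiles(segs, fp)
  prof <- read.delim(fp, check.names = FALSE)
  expect_equal(as.matrix(prof[, 4:7]), segs$profiles, ignore_attr = TRUE)
})
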