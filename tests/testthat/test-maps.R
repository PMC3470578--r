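# assemble a minimal epi_segmentation-shaped object for map unit tests
fake_segs <- function(n, chrom = rep("chr1", n), len = rep(500L, n),
                      cep = matrix(1L, n, 1, dimnames = list(NULL, "A:ref")),
                      coverage = matrix(0, n, 0)) {
  start <- cumsum(c(0L, len))[seq_len(n)]
  structure(list(segments = data.table::data.table(chrom = chrom,
                                                   start = start,
                                                   end = start + len),
                 cep = cep, coverage = coverage,
                 ref_ids = colnames(cep), comp_ids = colnames(coverage),
                 mode = "ES",
                 cep_labels = cep_label(cep, "ES")),
            class = "epi_segmentation")
}

grid66 <- som_grid(6, 6, matrix(0, 36, 2))

test_that("population map counts EPs per node and conserves the total", {
  segs <- fake_segs(10)
  pm <- population_map(rep(1L, 10), grid66)
  expect_equal(pm$values[1], 10)
  expect_equal(sum(pm$values), 10)
  expect_equal(pm$scale, "log")

  set.seed(13)
  asg <- sample(1:36, 500, TRUE)
  expect_equal(sum(population_map(asg, grid66)$values), 500)
  expect_error(population_map(integer(), grid66), "empty")
})

test_that("island labeling finds components, postfixes and mixed islands", {
  # blob A: nodes 1,2 (row 1) with CEP ES10; blob B: nodes 25,26,31,32
  # with CEP ES01; blob C: node 6 with CEP ES01 again but smaller
  cepA <- matrix(rep(c(1L, 0L), each = 24), 24,
                 dimnames = list(NULL, NULL))
  asg <- c(rep(1L, 12), rep(2L, 12),           # A
           rep(c(25L, 26L, 31L, 32L), each = 12),  # B
           rep(6L, 12))                         # C
  labs <- c(rep("ES10", 24), rep("ES01", 48), rep("ES01", 12))
  il <- island_labeling(asg, labs, grid66, occupancy_threshold = 10)
  expect_equal(nrow(il$islands), 3)
  expect_setequal(il$islands$label, c("ES10", "ES01a", "ES01b"))
  # larger ES01 island gets postfix a
  expect_equal(il$islands[il$islands$n_nodes == 4, ]$label, "ES01a")
  expect_equal(il$islands[il$islands$n_nodes == 1 &
                            grepl("ES01", il$islands$label), ]$label, "ES01b")

  # occupancy at the threshold (10) is a border, strictly > required
  il2 <- island_labeling(rep(1L, 10), rep("ES10", 10), grid66)
  expect_equal(nrow(il2$islands), 0)
  expect_true(all(is.na(il2$node_island)))

  # mixed island warns and is labeled 'mixed'
  expect_warning(
    il3 <- island_labeling(rep(1L, 20), rep(c("ES10", "ES01"), 10), grid66),
    "mixed")
  expect_equal(il3$islands$label, "mixed")
})

test_that("island connectivity respects 4- vs 8-neighborhood", {
  # nodes 1 and 8 touch diagonally only (6-wide grid)
  asg <- c(rep(1L, 12), rep(8L, 12))
  labs <- rep("ES10", 24)
  il4 <- island_labeling(asg, labs, grid66, connectivity = 4)
  expect_equal(nrow(il4$islands), 2)
  il8 <- island_labeling(asg, labs, grid66, connectivity = 8)
  expect_equal(nrow(il8$islands), 1)
})

test_that("coverage atlas averages data coverage, masking empty nodes", {
  cep <- matrix(c(1L, 1L, 0L), 3, dimnames = list(NULL, "A:ref"))
  cov <- matrix(c(0.2, 0.4, 0.9), 3, dimnames = list(NULL, "B:oth"))
  segs <- fake_segs(3, cep = cep, coverage = cov)
  atlas <- coverage_atlas(c(1L, 1L, 2L), segs, grid66)
  expect_named(atlas, c("A:ref", "B:oth"))
  expect_equal(atlas[["A:ref"]]$values[1], 1.0)   # reference bit
  expect_equal(atlas[["B:oth"]]$values[1], 0.3)   # mean(0.2, 0.4)
  expect_equal(atlas[["B:oth"]]$values[2], 0.9)
  expect_true(is.na(atlas[["A:ref"]]$values[3]))  # empty node masked
})

test_that("segment length map averages lengths with inverted scale", {
  segs <- fake_segs(3, len = c(200L, 400L, 1000L))
  lm <- segment_length_map(c(1L, 1L, 2L), segs, grid66)
  expect_equal(lm$values[1], 300)
  expect_equal(lm$values[2], 1000)
  expect_true(lm$inverted)
  expect_true(is.na(lm$values[3]))
})

test_that("cpg_density matches hand examples and never counts straddlers", {
  gl <- genome_layout(c(c1 = 4, c2 = 4, c3 = 3))
  genome <- Biostrings::DNAStringSet(c(c1 = "CGCG", c2 = "AAAA", c3 = "CGC"))
  segs <- data.frame(chrom = c("c1", "c2", "c3"), start = 0L,
                     end = c(4L, 4L, 3L))
  expect_equal(cpg_density(segs, genome), c(0.5, 0, 1 / 3))
  # N never matches; lower case counts
  g2 <- Biostrings::DNAStringSet(c(x = "CNGcgT"))
  expect_equal(cpg_density(data.frame(chrom = "x", start = 0, end = 6), g2),
               1 / 6)
  expect_error(cpg_density(data.frame(chrom = "c1", start = 0, end = 9),
                           genome), "bounds")
})

test_that("cpg_density equals the exhaustive scan oracle", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:60, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                      prob = c(.3, .25, .25, .15, .05)), collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(s, "z"))
    got <- cpg_density(data.frame(chrom = "z", start = 0, end = n), genome)
    expect_equal(got, oracle_cpg_density(s))
  }
})

test_that("upstream extension is strand-aware and clipped", {
  gl <- genome_layout(c(chr1 = 10000))
  gm <- gene_models(c("gp", "gm"), c("gp.1", "gm.1"), c("chr1", "chr1"),
                    c(5000, 5000), c(8000, 8000), c("+", "-"), gl)
  ext <- extend_upstream(gm, 2000)
  expect_equal(ext$start, c(3000L, 5000L))
  expect_equal(ext$end, c(8000L, 10000L))
  # clipping at the chromosome edge
  gm2 <- gene_models("g", "g.1", "chr1", 500, 900, "+", gl)
  expect_equal(extend_upstream(gm2, 2000)$start, 0L)
})

test_that("present-call map applies the exclusive-overlap threshold", {
  gl <- genome_layout(c(chr1 = 10000))
  # three segments: s1 overlaps an all-present gene; s2 overlaps one
  # all-present and one absent gene; s3 overlaps nothing
  segs <- fake_segs(3, len = c(1000L, 1000L, 1000L))
  segs$segments$start <- c(0L, 3000L, 6000L)
  segs$segments$end <- c(1000L, 4000L, 7000L)
  gm <- gene_models(c("g1", "g2", "g3"), c("t1", "t2", "t3"),
                    rep("chr1", 3), c(2500, 3200, 3300), c(2900, 3900, 3950),
                    c("+", "+", "+"), gl)
  # g1 extends upstream into s1's [0,1000)? no: use extension 2000 ->
  # g1 span [500, 2900) overlaps s1? s1 = [0,1000): yes
  expr <- expression_table(data.frame(gene_id = c("g1", "g2", "g3"),
                                      A = c(1, 1, 0), B = c(1, 1, 1)))
  pm <- present_call_map(c(1L, 2L, 3L), segs, gm, expr, grid66)
  expect_equal(pm$values[1], 1)    # score 1 -> active
  expect_equal(pm$values[2], 0)    # score 0.5 < 1 -> not active
  expect_true(is.na(pm$values[3])) # no gene overlap -> masked
  # lowering the threshold flips s2 to active
  pm2 <- present_call_map(c(1L, 2L, 3L), segs, gm, expr, grid66,
                          active_threshold = 0.5)
  expect_equal(pm2$values[2], 1)
})

test_that("gene-set fraction map normalizes per assigned gene", {
  gl <- genome_layout(c(chr1 = 10000))
  segs <- fake_segs(2, len = c(1000L, 1000L))
  segs$segments$start <- c(3000L, 8000L)
  segs$segments$end <- c(4000L, 9000L)
  gm <- gene_models(c("g1", "g2"), c("t1", "t2"), rep("chr1", 2),
                    c(3100, 3300), c(3600, 3800), c("+", "+"), gl)
  m <- gene_set_fraction_map(c(1L, 5L), segs, gm, gene_set = "g1", grid66)
  expect_equal(m$values[1], 0.5)     # {g1 in set, g2 not}
  expect_true(is.na(m$values[5]))    # no genes -> masked
  m_all <- gene_set_fraction_map(c(1L, 5L), segs, gm,
                                 gene_set = c("g1", "g2"), grid66)
  expect_equal(m_all$values[1], 1.0)
})

test_that("chromosome maps implement the hypergeometric expectation", {
  # N=100, node 1 has N_k=10 of which n_kc=4 from chrC; N_c=20
  chrom <- c(rep("chrC", 4), rep("chrO", 6),     # node 1
             rep("chrC", 16), rep("chrO", 74))   # elsewhere
  asg <- c(rep(1L, 10), rep(2:31, 3))
  segs <- fake_segs(100, chrom = chrom)
  cm <- chromosome_maps(asg, segs, "chrC", grid66)
  expect_equal(cm$enrichment$values[1], 1)           # log2(4 / 2)
  expect_equal(cm$population$values[1], 4 / 20)
  # conservation identities
  N_k <- tabulate(asg, 36)
  expect_equal(sum(N_k * 20 / 100), 20)
  expect_equal(sum(cm$population$values) * 20, 20)
  expect_error(chromosome_maps(asg, segs, "chrZ", grid66), "no segments")
})

test_that("all-from-one-chromosome gives log-ratio 0 at occupied nodes", {
  segs <- fake_segs(30, chrom = rep("chr1", 30))
  asg <- rep(c(1L, 2L, 3L), 10)
  cm <- chromosome_maps(asg, segs, "chr1", grid66)
  occ <- !is.na(cm$enrichment$values)
  expect_equal(which(occ), 1:3)
  expect_equal(cm$enrichment$values[occ], rep(0, 3))
  expect_true(all(is.na(cm$enrichment$values[4:36])))  # n_kc = 0 masked
})

test_that("chromosome-specific populations sum to the population map", {
  gl <- genome_layout(c(chr1 = 50000, chr2 = 50000))
  set.seed(19)
  chrom <- sample(c("chr1", "chr2"), 200, TRUE)
  segs <- fake_segs(200, chrom = chrom)
  asg <- sample(1:36, 200, TRUE)
  pm <- population_map(asg, grid66)
  tot <- rep(0, 36)
  for (chr in c("chr1", "chr2")) {
    cm <- chromosome_maps(asg, segs, chr, grid66)
    tot <- tot + cm$population$values * sum(chrom == chr)
  }
  expect_equal(tot, pm$values)
})
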