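# Independent brute-force oracles used to verify the interval machinery.
# These deliberately work per base on toy chromosomes and share no code
# with the implementation under test.

# region calling oracle: label every base lying between distance-joined
# kept positions, extract maximal runs, filter by length
oracle_call_regions <- function(pos, ratio, chrom_len, threshold = 3,
                                max_gap = 100, min_len = 100) {
  kept <- sort(pos[ratio >= threshold])
  mask <- logical(chrom_len)
  if (length(kept)) {
    mask[kept + 1L] <- TRUE
    if (length(kept) > 1) {
      for (i in seq_len(length(kept) - 1)) {
        if (kept[i + 1] - kept[i] < max_gap)
          mask[(kept[i] + 1L):(kept[i + 1] + 1L)] <- TRUE
      }
    }
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & (r$lengths >= min_len)
  data.frame(start = starts[keep], end = ends[keep])
}

# per-base segmentation oracle: label every base by the tuple of covering
# reference states, group into maximal constant-label runs, filter by
# length, then average complementary masks over each run
oracle_segmentation <- function(ref_masks, comp_masks, min_len = 200) {
  L <- length(ref_masks[[1]])
  code <- rep(0L, L)
  for (k in seq_along(ref_masks))
    code <- code * 2L + as.integer(ref_masks[[k]])
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len
  segs <- data.frame(start = starts[keep], end = ends[keep])
  n_ref <- length(ref_masks)
  cep <- t(vapply(which(keep), function(i) {
    bits <- integer(n_ref)
    v <- r$values[i]
    for (k in n_ref:1) { bits[k] <- v %% 2L; v <- v %/% 2L }
    bits
  }, integer(n_ref)))
  cov <- t(vapply(seq_len(nrow(segs)), function(i) {
    idx <- (segs$start[i] + 1L):segs$end[i]
    vapply(comp_masks, function(m) mean(m[idx]), numeric(1))
  }, numeric(length(comp_masks))))
  if (!length(comp_masks)) cov <- matrix(0, nrow(segs), 0)
  list(segments = segs, cep = cep, coverage = cov)
}

# exhaustive CpG scan: count i with substr == "CG", i in [1, n-1]
oracle_cpg_density <- function(seq_string) {
  n <- nchar(seq_string)
  if (n < 2) return(0)
  hits <- 0L
  s <- toupper(seq_string)
  for (i in seq_len(n - 1L))
    if (substr(s, i, i + 1L) == "CG") hits <- hits + 1L
  hits / n
}

# random sparse region set on one toy chromosome (0-based half-open)
random_regions <- function(chrom, chrom_len, layout, n_max = 8,
                           len_max = 5000) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(region_set(layout = layout))
  start <- sort(sample.int(chrom_len - len_max, n))
  width <- sample.int(len_max, n)
  region_set(rep(chrom, n), start, pmin(start + width, chrom_len), layout)
}

# random 3 marks x 3 cell types panel on one toy chromosome
random_panel <- function(layout, chrom = names(layout)[1]) {
  marks <- c("M1", "M2", "M3")
  cells <- c("C1", "C2", "C3")
  states <- list()
  for (m in marks) for (ct in cells)
    states[[paste(m, ct, sep = ":")]] <-
      random_regions(chrom, unclass(layout)[[chrom]], layout)
  state_panel(states, marks, cells)
}

# compare an epi_segmentation on a single-chromosome panel with the
# per-base oracle
expect_matches_oracle <- function(segs, panel, cfg, chrom = "chr1") {
  sel <- select_reference_states(panel, cfg)
  ref_masks <- lapply(sel$reference, region_mask, chrom = chrom)
  comp_masks <- lapply(sel$complementary, region_mask, chrom = chrom)
  orc <- oracle_segmentation(ref_masks, comp_masks, cfg$min_segment_length)
  expect_equal(segs$segments$start, orc$segments$start)
  expect_equal(segs$segments$end, orc$segments$end)
  expect_equal(unname(segs$cep), unname(orc$cep))
  expect_equal(unname(segs$coverage), unname(orc$coverage), tolerance = 1e-12)
}
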