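# Small shared fixtures built in code.

toy_layout <- function(len = 100000L, chrom = "chr1")
  genome_layout(setNames(as.integer(len), chrom))

# a deliberately simple 2x2 panel on a 600 bp chromosome used in several
# segmentation unit tests
tiny_panel <- function() {
  gl <- genome_layout(c(chr1 = 600))
  sts <- list(
    "A:ref" = region_set("chr1", 0, 300, gl),
    "B:ref" = region_set("chr1", 200, 500, gl),
    "A:oth" = region_set("chr1", c(100, 300), c(200, 350), gl),
    "B:oth" = region_set(layout = gl))
  state_panel(sts, marks = c("A", "B"), cell_types = c("ref", "oth"))
}

# profiles with three well-separated planted clusters; returns matrix and
# true labels
planted_clusters <- function(n_per = 200, d = 6, sep = 4, sd = 0.05,
                             seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, d), c(rep(sep, d %/% 2), rep(0, d - d %/% 2)),
                   rep(-sep, d))
  X <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(n_per * d, 0, sd), ncol = d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)))
  list(X = X, labels = rep(1:3, each = n_per))
}

# strip class/attributes for comparison against plain data.frames
plain_df <- function(x)
  data.frame(chrom = as.character(x$chrom), start = as.integer(x$start),
             end = as.integer(x$end))

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
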