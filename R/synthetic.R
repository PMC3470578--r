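#' Specification for the synthetic-data generator
#'
#' A fully seeded description of a toy epigenome with planted combinatorial
#' structure: blocks with known CEPs and coverage levels, Poisson read
#' depths, CpG-rich intervals and genes with declared present/absent flags.
#' Every generator output is reproducible from `seed`.
#'
#' @param seed integer seed governing all generators.
#' @param chrom_sizes named vector of chromosome lengths (default: two
#'   100 kb toy chromosomes).
#' @param marks,cell_types identifiers (defaults: 3 marks x 3 cell types,
#'   reference cell first).
#' @param reference reference cell type for ES-mode ground truth (default:
#'   first cell type).
#' @param blocks `data.frame` of planted blocks with columns `chrom`,
#'   `start`, `end`, `cep` (bit string over the reference states, not all
#'   zero -- the unmodified CEP arises from the gaps between blocks) and
#'   one numeric column per complementary state (target coverage fraction
#'   in `[0, 1]`). `NULL` uses a default layout planting every non-zero
#'   CEP on each chromosome.
#' @param background Poisson rate of the whole-cell-extract control per
#'   position (default 1).
#' @param enrichment_rate multiplier on `background` for modification reads
#'   inside planted regions (default 10; clears the enrichment threshold 3
#'   with high probability).
#' @param low_rate multiplier for modification reads outside planted
#'   regions (default 0.1).
#' @param cpg_target,cpg_background CG-dinucleotide density targets inside
#'   CpG-rich intervals and elsewhere (defaults 0.06 and 0.01 CpGs/bp).
#' @param min_gap minimal gap enforced between planted blocks (default
#'   500 bp, so gap chromatin survives the 200 bp segment filter).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, chrom_sizes = c(chrS1 = 100000L,
                                                      chrS2 = 100000L),
                           marks = c("H3K4me3", "H3K27me3", "H3K9me3"),
                           cell_types = c("ESC", "MEF", "NPC"),
                           reference = cell_types[1],
                           blocks = NULL,
                           background = 1, enrichment_rate = 10,
                           low_rate = 0.1,
                           cpg_target = 0.06, cpg_background = 0.01,
                           min_gap = 500L) {
  layout <- genome_layout(chrom_sizes)
  cfg <- segmentation_config("ES", reference)
  n_ref <- length(marks)
  ref_ids <- paste(marks, reference, sep = ":")
  all_ids <- as.vector(t(outer(marks, cell_types, paste, sep = ":")))
  comp_ids <- setdiff(all_ids, ref_ids)
  if (is.null(blocks)) blocks <- .default_blocks(layout, n_ref, comp_ids)
  blocks <- data.table::as.data.table(blocks)
  stopifnot(all(c("chrom", "start", "end", "cep") %in% names(blocks)))
  for (id in comp_ids) if (!id %in% names(blocks)) blocks[, (id) := 0]
  if (any(nchar(blocks$cep) != n_ref))
    stop("synthetic_spec: cep strings must have ", n_ref, " bits")
  if (any(blocks$cep == strrep("0", n_ref)))
    stop("synthetic_spec: all-zero CEP blocks are not representable ",
         "(the unmodified CEP arises from gaps)")
  covm <- as.matrix(blocks[, comp_ids, with = FALSE])
  if (any(covm < 0) || any(covm > 1))
    stop("synthetic_spec: validation error: coverage fraction outside [0,1]")
  data.table::setorder(blocks, chrom, start)
  if (any(blocks$start < 0) ||
      any(blocks$end > unclass(layout)[blocks$chrom]))
    stop("synthetic_spec: block outside chromosome bounds")
  gaps <- blocks[, .(gap = start[-1] - end[-.N]), by = chrom]$gap
  if (length(gaps) && any(gaps < min_gap))
    stop("synthetic_spec: blocks closer than min_gap (", min_gap, " bp)")
  structure(list(seed = as.integer(seed), layout = layout, marks = marks,
                 cell_types = cell_types, reference = reference,
                 ref_ids = ref_ids, comp_ids = comp_ids, blocks = blocks,
                 background = background, enrichment_rate = enrichment_rate,
                 low_rate = low_rate, cpg_target = cpg_target,
                 cpg_background = cpg_background),
            class = "synthetic_spec")
}

# one block per non-zero CEP per chromosome, 600 bp each, 2.5 kb apart
# (wider than the 2 kb upstream gene extension so planted genes never
# reach into a neighboring block),
# with a spread of coverage levels so SOM training sees structure.
# Planted modified bases stay a small fraction of the toy genome,
# mimicking the situation where the vast majority of chromatin is
# unmodified.
.default_blocks <- function(layout, n_ref, comp_ids) {
  ceps <- setdiff(apply(expand.grid(rep(list(0:1), n_ref))[, n_ref:1,
                                                           drop = FALSE],
                        1, paste, collapse = ""), strrep("0", n_ref))
  ceps <- sort(ceps, decreasing = TRUE)
  rows <- list()
  for (chr in names(layout)) {
    for (i in seq_along(ceps)) {
      st <- 5000L + (i - 1L) * 3100L
      b <- data.table::data.table(chrom = chr, start = st, end = st + 600L,
                                  cep = ceps[i])
      for (j in seq_along(comp_ids))
        b[, (comp_ids[j]) := if ((i + j) %% 3 == 0) 0 else
          round(0.2 + 0.8 * ((i * 7 + j * 3) %% 5) / 5, 2)]
      rows[[paste(chr, i)]] <- b
    }
  }
  data.table::rbindlist(rows)
}

#' Generate the region-level panel plus its ground-truth segment table
#'
#' Reference states contain every planted block whose CEP bit is set;
#' complementary states contain a leading sub-interval of each block whose
#' length realizes the block's target coverage fraction (rounded to whole
#' bases). The ground truth lists the segments expected from ES
#' segmentation at the spec's reference and default minimum length:
#' planted blocks with their CEPs and realized coverages, interleaved with
#' all-zero gap segments.
#'
#' @param spec a [synthetic_spec()].
#' @param min_segment_length retention threshold assumed for the truth
#'   table (default 200).
#' @return list with `panel` (a [state_panel()]) and `truth` (list with
#'   `segments` = `data.table(chrom, start, end, cep)` and `coverage` =
#'   matrix over complementary states).
#' @export
make_region_panel <- function(spec, min_segment_length = 200L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  blocks <- spec$blocks
  n_ref <- length(spec$marks)
  bits <- do.call(rbind, lapply(strsplit(blocks$cep, ""), as.integer))
  states <- list()
  # reference states: full blocks where the bit is set
  for (k in seq_len(n_ref)) {
    sel <- bits[, k] == 1L
    states[[spec$ref_ids[k]]] <- region_set(blocks$chrom[sel],
                                            blocks$start[sel],
                                            blocks$end[sel], spec$layout,
                                            label = spec$ref_ids[k])
  }
  # complementary states: leading sub-intervals realizing the fractions
  len <- blocks$end - blocks$start
  for (id in spec$comp_ids) {
    f <- blocks[[id]]
    w <- as.integer(round(f * len))
    sel <- w > 0L
    states[[id]] <- region_set(blocks$chrom[sel], blocks$start[sel],
                               blocks$start[sel] + w[sel], spec$layout,
                               label = id)
  }
  panel <- state_panel(states, spec$marks, spec$cell_types)
  # ground truth: blocks + gaps, length-filtered
  rows <- list()
  covs <- list()
  covm <- as.matrix(blocks[, spec$comp_ids, with = FALSE])
  for (chr in names(spec$layout)) {
    L <- unclass(spec$layout)[[chr]]
    sel <- which(blocks$chrom == chr)
    bnd_s <- c(0L, blocks$end[sel])
    bnd_e <- c(blocks$start[sel], L)
    for (i in seq_along(bnd_s)) { # gaps
      if (bnd_e[i] - bnd_s[i] >= min_segment_length) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = chr, start = bnd_s[i], end = bnd_e[i],
          cep = strrep("0", n_ref))
        covs[[length(covs) + 1L]] <- rep(0, length(spec$comp_ids))
      }
    }
    for (i in sel) { # blocks
      if (blocks$end[i] - blocks$start[i] >= min_segment_length) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = chr, start = blocks$start[i], end = blocks$end[i],
          cep = blocks$cep[i])
        covs[[length(covs) + 1L]] <-
          round(covm[i, ] * len[i]) / len[i]
      }
    }
  }
  segments <- data.table::rbindlist(rows)
  coverage <- do.call(rbind, covs)
  colnames(coverage) <- spec$comp_ids
  ord <- order(segments$chrom, segments$start)
  segments <- segments[ord]
  coverage <- coverage[ord, , drop = FALSE]
  list(panel = panel, truth = list(segments = segments, coverage = coverage))
}

#' Simulate per-position count tracks (modification, WCE, H3)
#'
#' Reads per genomic position are Poisson: the whole-cell-extract control
#' has rate `background` everywhere; each modification track has rate
#' `background * enrichment_rate` inside its planted regions and
#' `background * low_rate` outside; the H3 control has rate
#' `3 * background` everywhere (dense, so H3 validation discards little).
#' Only non-zero counts are stored. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `mod` (named list of [count_track()]s, one per state),
#'   `wce` and `h3` count tracks.
#' @export
make_count_tracks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  panel <- make_region_panel(spec)$panel
  layout <- spec$layout
  sample_track <- function(lambda_fun) {
    chroms <- character(); poss <- integer(); cnts <- integer()
    for (chr in names(layout)) {
      L <- unclass(layout)[[chr]]
      lam <- lambda_fun(chr, L)
      cnt <- stats::rpois(L, lam)
      nz <- which(cnt > 0L)
      chroms <- c(chroms, rep(chr, length(nz)))
      poss <- c(poss, nz - 1L)
      cnts <- c(cnts, cnt[nz])
    }
    count_track(chroms, poss, cnts, layout)
  }
  wce <- sample_track(function(chr, L) rep(spec$background, L))
  h3 <- sample_track(function(chr, L) rep(3 * spec$background, L))
  mod <- list()
  for (id in names(panel$states)) {
    rs <- panel$states[[id]]
    mod[[id]] <- sample_track(function(chr, L) {
      lam <- rep(spec$background * spec$low_rate, L)
      sub <- rs[rs$chrom == chr, ]
      for (i in seq_len(nrow(sub)))
        lam[(sub$start[i] + 1L):sub$end[i]] <-
          spec$background * spec$enrichment_rate
      lam
    })
  }
  list(mod = mod, wce = wce, h3 = h3)
}

# solve for P(G | previous base C) giving a stationary CG-dinucleotide
# density of `target` under the generator's Markov chain
.g_for_cpg_target <- function(target) {
  dens <- function(g) g * 0.25 / (1.25 - (1 - g) / 3)
  stats::uniroot(function(g) dens(g) - target, c(1e-6, 0.95))$root
}

.markov_seq <- function(len, gvec) {
  u <- stats::runif(len)
  bases <- c("A", "C", "G", "T")
  pick <- integer(len)
  prevC <- FALSE
  for (i in seq_len(len)) {
    if (prevC) {
      g <- gvec[i]
      if (u[i] < g) b <- 3L
      else {
        r <- (u[i] - g) / (1 - g)
        b <- c(1L, 2L, 4L)[pmin(3L, pmax(1L, ceiling(r * 3)))]
      }
    } else {
      b <- pmin(4L, pmax(1L, ceiling(u[i] * 4)))
    }
    pick[i] <- b
    prevC <- b == 2L
  }
  paste(bases[pick], collapse = "")
}

#' Generate gene models, expression flags and a genome FASTA
#'
#' One gene is placed inside each planted block (strands alternating) and
#' one in a gap on each chromosome. Genes inside blocks whose CEP marks
#' only the first reference state (the "active" combination) are flagged
#' present in every cell type; gap genes are present everywhere too; all
#' other genes are present only in the first cell type. The genome
#' sequence is a first-order Markov chain whose CG-dinucleotide density is
#' `cpg_background` genome-wide and `cpg_target` inside blocks carrying the
#' first reference mark. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genes` ([gene_models()]), `expression`
#'   ([expression_table()]), `genome` (`DNAStringSet`), `gene_set`
#'   (character: the genes planted in blocks, a stand-in for e.g. a
#'   developmental gene set) and `cpg_rich` (`data.table` of CpG-rich
#'   intervals).
#' @export
make_genes_and_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  blocks <- spec$blocks
  n_ref <- length(spec$marks)
  active_cep <- paste0("1", strrep("0", n_ref - 1))
  g_rows <- list()
  pres <- list()
  idx <- 0L
  for (i in seq_len(nrow(blocks))) {
    idx <- idx + 1L
    gid <- sprintf("gene%03d", idx)
    g_rows[[idx]] <- data.table::data.table(
      gene_id = gid, transcript_id = paste0(gid, ".1"),
      chrom = blocks$chrom[i],
      start = blocks$start[i] + 10L, end = blocks$end[i] - 10L,
      strand = if (i %% 2 == 0) "-" else "+")
    pres[[idx]] <- if (blocks$cep[i] == active_cep)
      rep(1L, length(spec$cell_types)) else
        c(1L, rep(0L, length(spec$cell_types) - 1L))
  }
  block_genes <- vapply(g_rows, function(r) r$gene_id, "")
  for (chr in names(spec$layout)) { # one gap gene per chromosome
    idx <- idx + 1L
    gid <- sprintf("gene%03d", idx)
    L <- unclass(spec$layout)[[chr]]
    g_rows[[idx]] <- data.table::data.table(
      gene_id = gid, transcript_id = paste0(gid, ".1"), chrom = chr,
      start = L - 3000L, end = L - 1000L, strand = "+")
    pres[[idx]] <- rep(1L, length(spec$cell_types))
  }
  gdt <- data.table::rbindlist(g_rows)
  genes <- gene_models(gdt$gene_id, gdt$transcript_id, gdt$chrom,
                       gdt$start, gdt$end, gdt$strand, spec$layout)
  pm <- do.call(rbind, pres)
  colnames(pm) <- spec$cell_types
  expr <- expression_table(cbind(data.table::data.table(gene_id = gdt$gene_id),
                                 data.table::as.data.table(pm)))
  # CpG-rich intervals: blocks carrying the first reference mark
  rich <- blocks[substr(cep, 1, 1) == "1", .(chrom, start, end)]
  g_bg <- .g_for_cpg_target(spec$cpg_background)
  g_hi <- .g_for_cpg_target(spec$cpg_target)
  seqs <- character(length(spec$layout))
  names(seqs) <- names(spec$layout)
  for (chr in names(spec$layout)) {
    L <- unclass(spec$layout)[[chr]]
    gvec <- rep(g_bg, L)
    sub <- rich[chrom == chr]
    for (i in seq_len(nrow(sub)))
      gvec[(sub$start[i] + 1L):sub$end[i]] <- g_hi
    seqs[chr] <- .markov_seq(L, gvec)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  list(genes = genes, expression = expr, genome = genome,
       gene_set = block_genes, cpg_rich = rich)
}

#' Write all synthetic fixtures to a directory
#'
#' Emits the panel BEDs plus manifest, per-state bedGraphs, WCE and H3
#' bedGraphs, genome FASTA, gene BED (6-column, `gene|transcript` names),
#' expression TSV, gene-set list and chromosome sizes. All plain text.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created).
#' @param counts also write count tracks (default FALSE; they are large).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(spec, dir, counts = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rp <- make_region_panel(spec)
  write_panel(rp$panel, file.path(dir, "panel"))
  ge <- make_genes_and_expression(spec)
  write_chrom_sizes(spec$layout, file.path(dir, "chrom.sizes"))
  Biostrings::writeXStringSet(ge$genome, file.path(dir, "genome.fa"))
  gdt <- data.table::as.data.table(ge$genes)
  bed <- gdt[, .(chrom, start, end,
                 name = paste(gene_id, transcript_id, sep = "|"),
                 score = 0L, strand)]
  data.table::fwrite(bed, file.path(dir, "genes.bed"), sep = "\t",
                     col.names = FALSE, scipen = 12)
  write_expression(ge$expression, file.path(dir, "expression.tsv"))
  writeLines(ge$gene_set, file.path(dir, "gene_set.txt"))
  jsonlite::write_json(list(seed = spec$seed), file.path(dir, "seed.json"),
                       auto_unbox = TRUE)
  if (counts) {
    ct <- make_count_tracks(spec)
    write_count_track(ct$wce, file.path(dir, "wce.bedGraph"))
    write_count_track(ct$h3, file.path(dir, "h3.bedGraph"))
    for (id in names(ct$mod))
      write_count_track(ct$mod[[id]],
                        file.path(dir, paste0(gsub(":", "_", id),
                                              ".bedGraph")))
  }
  invisible(dir)
}
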