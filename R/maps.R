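#' Population map: number of EPs per node
#'
#' @param assignment integer node indices (one per segment).
#' @param grid a [som_grid()].
#' @return a [node_map()] with log scale hint (empty nodes carry 0, not
#'   `NA`: an unoccupied node is a real observation here).
#' @export
population_map <- function(assignment, grid) {
  if (!length(assignment)) stop("population_map: empty assignment")
  K <- grid$width * grid$height
  node_map(tabulate(assignment, nbins = K), grid$width, grid$height,
           scale = "log", label = "EPs per node")
}

#' Detect and label CEP islands on the SOM
#'
#' Nodes whose occupancy exceeds `occupancy_threshold` (strictly) are
#' island nodes; islands are their connected components (4-neighborhood by
#' default). Each island is labeled by the CEP of its member segments;
#' empirically islands are CEP-homogeneous, but an island mixing several
#' CEPs is labeled `"mixed"` with a warning rather than failing. When one
#' CEP spans several islands the labels get postfixes `a`, `b`, ... in
#' order of decreasing island size (node count).
#'
#' @param assignment integer node indices per segment.
#' @param cep_labels character CEP label per segment (see [cep_label()]).
#' @param grid a [som_grid()].
#' @param occupancy_threshold islands need `> threshold` EPs per node
#'   (default 10).
#' @param connectivity 4 or 8.
#' @return object of class `island_labeling`: list with `node_island`
#'   (integer island id per node, `NA` = border), `islands` (`data.table`
#'   with `island`, `label`, `n_nodes`, `n_segments`), and `node_label`
#'   (character per node).
#' @export
island_labeling <- function(assignment, cep_labels, grid,
                            occupancy_threshold = 10, connectivity = 4) {
  stopifnot(length(assignment) == length(cep_labels),
            connectivity %in% c(4, 8))
  K <- grid$width * grid$height
  occ <- tabulate(assignment, nbins = K)
  is_island <- occ > occupancy_threshold
  comp <- .grid_components(is_island, grid$width, grid$height, connectivity)
  ids <- sort(unique(comp[!is.na(comp)]))
  rows <- list()
  for (id in ids) {
    nodes <- which(comp == id)
    segs <- which(assignment %in% nodes)
    ceps <- unique(cep_labels[segs])
    lab <- if (length(ceps) == 1) ceps else {
      warning("island_labeling: island ", id, " contains ", length(ceps),
              " distinct CEPs; labeled 'mixed'")
      "mixed"
    }
    rows[[as.character(id)]] <- data.table::data.table(
      island = id, label = lab, n_nodes = length(nodes),
      n_segments = length(segs))
  }
  islands <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(island = integer(), label = character(),
                           n_nodes = integer(), n_segments = integer())
  # postfix a, b, ... for CEPs spanning several islands, by descending size
  if (nrow(islands)) {
    data.table::setorder(islands, label, -n_nodes, island)
    islands[, label := {
      if (.N > 1 && label[1] != "mixed")
        paste0(label, letters[seq_len(.N)]) else label
    }, by = label]
    data.table::setorder(islands, island)
  }
  node_label <- rep(NA_character_, K)
  for (i in seq_len(nrow(islands)))
    node_label[which(comp == islands$island[i])] <- islands$label[i]
  structure(list(node_island = comp, islands = islands,
                 node_label = node_label,
                 occupancy_threshold = occupancy_threshold,
                 width = grid$width, height = grid$height),
            class = "island_labeling")
}

# connected components of TRUE cells on a row-major grid
.grid_components <- function(mask, width, height, connectivity = 4) {
  K <- width * height
  comp <- rep(NA_integer_, K)
  nid <- 0L
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), times = 3)[-5]
    dc <- rep(c(-1L, 0L, 1L), each = 3)[-5]
  }
  for (s in seq_len(K)) {
    if (!mask[s] || !is.na(comp[s])) next
    nid <- nid + 1L
    queue <- s
    comp[s] <- nid
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      r <- (k - 1L) %/% width + 1L
      c <- (k - 1L) %% width + 1L
      for (t in seq_along(dr)) {
        rr <- r + dr[t]; cc <- c + dc[t]
        if (rr < 1 || rr > height || cc < 1 || cc > width) next
        kk <- (rr - 1L) * width + cc
        if (mask[kk] && is.na(comp[kk])) {
          comp[kk] <- nid
          queue <- c(queue, kk)
        }
      }
    }
  }
  comp
}

#' @export
print.island_labeling <- function(x, ...) {
  cat(sprintf("island_labeling: %d island(s) (occupancy > %g)\n",
              nrow(x$islands), x$occupancy_threshold))
  if (nrow(x$islands)) print(x$islands)
  invisible(x)
}

# full (unweighted) per-segment coverage across all m*n states:
# reference states contribute their CEP bit, complementary states their
# fractional coverage
.full_state_coverage <- function(segs) {
  if (is.null(segs$coverage))
    stop("coverage not computed; run compute_coverage() first")
  cbind(segs$cep, segs$coverage)
}

#' Coverage atlas: one SOM-image per modification state
#'
#' Each tile is colored by the average coverage of the segments assigned to
#' that node by the respective modification state -- always the unweighted
#' data coverage (reference states contribute their 0/1 CEP bit), never the
#' trained codebook values.
#'
#' @param assignment integer node indices per segment.
#' @param segs an `epi_segmentation` with coverage filled.
#' @param grid a [som_grid()].
#' @return named list of [node_map()]s (one per state, reference states
#'   first); empty nodes are masked.
#' @export
coverage_atlas <- function(assignment, segs, grid) {
  cov <- .full_state_coverage(segs)
  ids <- c(segs$ref_ids, segs$comp_ids)
  out <- vector("list", ncol(cov))
  names(out) <- ids
  for (j in seq_len(ncol(cov))) {
    out[[j]] <- node_map(.node_mean(cov[, j], assignment, grid),
                         grid$width, grid$height, scale = "linear",
                         label = paste0("mean coverage: ", ids[j]))
  }
  out
}

.node_mean <- function(x, assignment, grid) {
  K <- grid$width * grid$height
  s <- rep(NA_real_, K)
  agg <- tapply(x, assignment, mean)
  s[as.integer(names(agg))] <- as.numeric(agg)
  s
}

#' Mean segment length per node
#'
#' Rendered with an inverted color scale so that small lengths (near the
#' 200 bp retention limit) show up warm.
#'
#' @inheritParams coverage_atlas
#' @return a [node_map()] (bp; empty nodes masked).
#' @export
segment_length_map <- function(assignment, segs, grid) {
  len <- segs$segments$end - segs$segments$start
  node_map(.node_mean(len, assignment, grid), grid$width, grid$height,
           scale = "linear", inverted = TRUE, label = "mean segment length (bp)")
}

#' CpG density of segments
#'
#' Number of CG dinucleotides on the plus strand within the segment,
#' divided by segment length. A dinucleotide straddling the segment end is
#' not counted; ambiguous bases (N) never match. Case-insensitive.
#'
#' @param segments `data.table`-like with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genome a `Biostrings::DNAStringSet` (names = chromosomes) or a
#'   FASTA path.
#' @return numeric vector of densities, one per segment.
#' @export
cpg_density <- function(segments, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  names(genome) <- nm
  unknown <- setdiff(unique(segments$chrom), nm)
  if (length(unknown))
    stop("cpg_density: chromosome(s) missing from FASTA: ",
         paste(unknown, collapse = ", "))
  if (any(segments$end > Biostrings::width(genome)[match(segments$chrom, nm)]))
    stop("cpg_density: segment beyond FASTA sequence bounds")
  seqs <- Biostrings::DNAStringSet(genome[segments$chrom],
                                   start = segments$start + 1L,
                                   end = segments$end)
  ncg <- Biostrings::vcountPattern("CG", seqs, fixed = TRUE)
  ncg / (segments$end - segments$start)
}

#' Mean CpG density per node
#'
#' @inheritParams coverage_atlas
#' @param genome `DNAStringSet` or FASTA path covering all segments.
#' @return a [node_map()] (CpGs/bp; empty nodes masked).
#' @export
cpg_density_map <- function(assignment, segs, genome, grid) {
  dens <- cpg_density(segs$segments, genome)
  node_map(.node_mean(dens, assignment, grid), grid$width, grid$height,
           scale = "linear", label = "mean CpG density (CpGs/bp)")
}

# gene <-> segment overlap table used by the present-call and gene-set maps.
# Transcripts are extended `extension` bp upstream (strand-aware); a gene
# overlaps a segment when any of its extended transcripts intersects it by
# >= 1 bp. Returns data.table(seg = segment index, gene_id).
.gene_segment_overlaps <- function(segs, genes, extension = 2000L) {
  ext <- extend_upstream(genes, extension)
  seg_gr <- GenomicRanges::GRanges(segs$segments$chrom,
                                   IRanges::IRanges(segs$segments$start + 1L,
                                                    segs$segments$end))
  tx_gr <- GenomicRanges::GRanges(ext$chrom,
                                  IRanges::IRanges(ext$start + 1L, ext$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, tx_gr)
  dt <- data.table::data.table(seg = S4Vectors::queryHits(hits),
                               gene_id = ext$gene_id[S4Vectors::subjectHits(hits)])
  unique(dt)
}

#' Present-call map: fraction of "active" segments per node
#'
#' A gene counts as present when it is flagged present in every cell type
#' of the panel. Each segment overlapping at least one (upstream-extended)
#' gene receives the mean present value of its genes; segments overlapping
#' no gene are excluded. A segment is "active" when its score reaches
#' `active_threshold` (default 1, i.e. it overlaps exclusively
#' all-present genes). The node value is active / gene-overlapping
#' segments.
#'
#' @inheritParams coverage_atlas
#' @param genes a [gene_models()] table.
#' @param expr an [expression_table()] with one 0/1 column per cell type.
#' @param extension upstream extension in bp (default 2000).
#' @param active_threshold score needed for a segment to count as active
#'   (default 1.0).
#' @return a [node_map()]; nodes without gene-overlapping segments are
#'   masked.
#' @export
present_call_map <- function(assignment, segs, genes, expr, grid,
                             extension = 2000L, active_threshold = 1.0) {
  ov <- .gene_segment_overlaps(segs, genes, extension)
  flags <- data.table::as.data.table(expr)
  cells <- setdiff(names(flags), "gene_id")
  flags[, present := as.integer(rowSums(.SD) == length(cells)),
        .SDcols = cells]
  ov <- flags[, .(gene_id, present)][ov, on = "gene_id"]
  ov[is.na(present), present := 0L] # gene absent from table: not present
  seg_score <- ov[, .(score = mean(present)), by = seg]
  seg_score[, active := score >= active_threshold]
  seg_score[, node := assignment[seg]]
  agg <- seg_score[, .(value = mean(active)), by = node]
  K <- grid$width * grid$height
  v <- rep(NA_real_, K)
  v[agg$node] <- agg$value
  node_map(v, grid$width, grid$height, scale = "linear",
           label = "fraction of active segments")
}

#' Gene-set fraction map
#'
#' A gene is assigned to a node when it overlaps at least one segment
#' assigned there (counted once per node). The node value is the number of
#' assigned genes belonging to `gene_set` divided by all assigned genes;
#' nodes with no assigned genes are masked (rendered white).
#'
#' @inheritParams present_call_map
#' @param gene_set character vector of gene ids (e.g. developmental genes).
#' @return a [node_map()].
#' @export
gene_set_fraction_map <- function(assignment, segs, genes, gene_set, grid,
                                  extension = 2000L) {
  ov <- .gene_segment_overlaps(segs, genes, extension)
  ov[, node := assignment[seg]]
  per_node <- unique(ov[, .(node, gene_id)])
  agg <- per_node[, .(value = mean(gene_id %in% gene_set)), by = node]
  K <- grid$width * grid$height
  v <- rep(NA_real_, K)
  v[agg$node] <- agg$value
  node_map(v, grid$width, grid$height, scale = "log",
           label = "fraction of gene-set genes")
}

#' Chromosome-specific population and enrichment maps
#'
#' With `N` segments in total, `N_k` at node `k`, `N_c` from chromosome `c`
#' and `n_kc` observed at node `k` from chromosome `c`, the expected count
#' under random assignment is the hypergeometric expectation
#' `E_kc = N_k * N_c / N`. The population map holds `n_kc / N_c`; the
#' enrichment map holds `log2(n_kc / E_kc)`, masked where `n_kc = 0` or
#' `N_k = 0`.
#'
#' @inheritParams coverage_atlas
#' @param chromosome chromosome name `c`.
#' @return list with `population` and `enrichment` [node_map()]s.
#' @export
chromosome_maps <- function(assignment, segs, chromosome, grid) {
  K <- grid$width * grid$height
  from_c <- segs$segments$chrom == chromosome
  N <- length(assignment)
  N_c <- sum(from_c)
  if (N_c == 0)
    stop("chromosome_maps: validation error: no segments from ", chromosome)
  N_k <- tabulate(assignment, nbins = K)
  n_kc <- tabulate(assignment[from_c], nbins = K)
  E_kc <- N_k * N_c / N
  pop <- node_map(n_kc / N_c, grid$width, grid$height, scale = "log",
                  label = paste0("fraction of ", chromosome, " segments"))
  enr_v <- rep(NA_real_, K)
  ok <- n_kc > 0 & N_k > 0
  enr_v[ok] <- log2(n_kc[ok] / E_kc[ok])
  enr <- node_map(enr_v, grid$width, grid$height, scale = "linear",
                  label = paste0("log2 obs/exp: ", chromosome))
  list(population = pop, enrichment = enr)
}

utils::globalVariables(c("seg", "active", ".SD", ".N"))
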