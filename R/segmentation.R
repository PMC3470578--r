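#' Segmentation configuration
#'
#' @param mode `"ES"` (epigenome state: reference = one cell type, CEP bits
#'   are its marks) or `"EV"` (epigenome variation: reference = one mark,
#'   CEP bits are the cell types).
#' @param reference cell type id (ES) or mark id (EV).
#' @param min_segment_length segments shorter than this are omitted
#'   (strictly `<`; default 200 bp, the discretization limit of roughly one
#'   nucleosome's worth of DNA).
#' @param coverage_weight weighting factor `w >= 0` applied to the coverage
#'   part of the epigenetic profile used for SOM training (default 1).
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(mode = c("ES", "EV"), reference,
                                min_segment_length = 200L,
                                coverage_weight = 1) {
  mode <- match.arg(mode)
  if (min_segment_length <= 0) stop("segmentation_config: min_segment_length must be > 0")
  if (coverage_weight < 0) stop("segmentation_config: coverage_weight must be >= 0")
  structure(list(mode = mode, reference = reference,
                 min_segment_length = as.integer(min_segment_length),
                 coverage_weight = coverage_weight),
            class = "segmentation_config")
}

#' Select reference and complementary modification states
#'
#' ES mode selects all marks of the reference cell type (n := m reference
#' states); EV mode selects the reference mark in every cell type (n :=
#' number of cell types). The remaining states are the complementary list.
#' Both lists follow the canonical order: marks in panel declaration order,
#' then cell types in panel declaration order (mark-major).
#'
#' @param panel a [state_panel()].
#' @param cfg a [segmentation_config()].
#' @return list with elements `reference` and `complementary` (named lists
#'   of [region_set()]s) plus `ref_ids`, `comp_ids`.
#' @export
select_reference_states <- function(panel, cfg) {
  if (cfg$mode == "ES") {
    if (!cfg$reference %in% panel$cell_types)
      stop("select_reference_states: unknown reference cell type ", cfg$reference)
    ref_ids <- paste(panel$marks, cfg$reference, sep = ":")
  } else {
    if (!cfg$reference %in% panel$marks)
      stop("select_reference_states: unknown reference mark ", cfg$reference)
    ref_ids <- paste(cfg$reference, panel$cell_types, sep = ":")
  }
  all_ids <- as.vector(t(outer(panel$marks, panel$cell_types, paste, sep = ":")))
  comp_ids <- setdiff(all_ids, ref_ids)
  list(reference = panel$states[ref_ids],
       complementary = panel$states[comp_ids],
       ref_ids = ref_ids, comp_ids = comp_ids)
}

#' Build segments by projecting reference-state boundaries onto the genome
#'
#' Per chromosome, the boundary set is `{0, length}` plus every region
#' start and end of every reference state; consecutive boundary pairs are
#' candidate segments. Segments shorter than `cfg$min_segment_length` are
#' discarded (kept in `$dropped` for auditability). Because all reference
#' boundaries are projected, every retained segment is covered either 0% or
#' 100% by each reference state; the k-th CEP bit records which. An
#' internal assertion verifies this binarity.
#'
#' @param reference_states named list of reference [region_set()]s in
#'   canonical order (see [select_reference_states()]).
#' @param layout a [genome_layout()].
#' @param cfg a [segmentation_config()].
#' @return object of class `epi_segmentation`: list with `segments`
#'   (`data.table(chrom, start, end)`), `cep` (segments x n binary matrix),
#'   `coverage` (`NULL` until [compute_coverage()]), `dropped`, `ref_ids`,
#'   `mode`, `cfg`, `layout`.
#' @export
build_segments <- function(reference_states, layout, cfg) {
  ref_ids <- names(reference_states)
  for (rs in reference_states)
    .check_same_layout(layout, attr(rs, "layout"), "reference states")
  seg_list <- list()
  drop_list <- list()
  for (chr in names(layout)) {
    len <- unclass(layout)[[chr]]
    bnd <- c(0L, len)
    for (rs in reference_states) {
      sub <- rs[rs$chrom == chr, ]
      bnd <- c(bnd, sub$start, sub$end)
    }
    bnd <- sort(unique(bnd))
    s <- bnd[-length(bnd)]
    e <- bnd[-1]
    keep <- (e - s) >= cfg$min_segment_length
    seg_list[[chr]] <- data.table::data.table(chrom = chr, start = s[keep],
                                              end = e[keep])
    drop_list[[chr]] <- data.table::data.table(chrom = chr, start = s[!keep],
                                               end = e[!keep])
  }
  segments <- data.table::rbindlist(seg_list)
  dropped <- data.table::rbindlist(drop_list)
  cep <- matrix(0L, nrow = nrow(segments), ncol = length(reference_states),
                dimnames = list(NULL, ref_ids))
  if (nrow(segments)) {
    for (k in seq_along(reference_states)) {
      cov <- .interval_coverage(segments, reference_states[[k]])
      frac <- cov / (segments$end - segments$start)
      if (any(frac > 0 & frac < 1))
        stop("build_segments: internal assertion failure: fractional ",
             "reference coverage for state ", ref_ids[k],
             " (boundary projection bug)")
      cep[, k] <- as.integer(frac == 1)
    }
  }
  structure(list(segments = segments, cep = cep, coverage = NULL,
                 dropped = dropped, ref_ids = ref_ids, comp_ids = NULL,
                 mode = cfg$mode, cfg = cfg, layout = layout),
            class = "epi_segmentation")
}

# bases of each segment (data.table chrom/start/end) overlapped by a
# region_set; returns numeric vector per segment. Regions are sorted and
# disjoint (region_set invariant), so covered bases in [0, x) form a
# prefix-sum function evaluated with findInterval -- much faster than
# range-join machinery at this scale.
.interval_coverage <- function(segments, rs) {
  out <- numeric(nrow(segments))
  if (!nrow(segments) || !nrow(rs)) return(out)
  for (chr in unique(segments$chrom)) {
    sub <- rs[rs$chrom == chr, ]
    if (!nrow(sub)) next
    si <- which(segments$chrom == chr)
    st <- sub$start; en <- sub$end
    cum <- c(0, cumsum(as.numeric(en - st)))
    covered_upto <- function(x) { # total region bases in [0, x)
      j <- findInterval(x, st)
      v <- numeric(length(x))
      nz <- j > 0L
      jj <- j[nz]
      v[nz] <- cum[jj] + pmax(0, pmin(x[nz], en[jj]) - st[jj])
      v
    }
    out[si] <- covered_upto(segments$end[si]) -
      covered_upto(segments$start[si])
  }
  out
}

#' Fill fractional coverages by the complementary modification states
#'
#' For each retained segment and each complementary state, the coverage is
#' the number of segment bases overlapped by that state's regions divided
#' by the segment length -- a value in `[0, 1]`.
#'
#' @param segs an `epi_segmentation` from [build_segments()].
#' @param complementary_states named list of [region_set()]s in canonical
#'   order.
#' @return `segs` with `$coverage` (segments x (m*n - n) matrix) and
#'   `$comp_ids` filled.
#' @export
compute_coverage <- function(segs, complementary_states) {
  stopifnot(inherits(segs, "epi_segmentation"))
  comp_ids <- names(complementary_states)
  cov <- matrix(0, nrow = nrow(segs$segments),
                ncol = length(complementary_states),
                dimnames = list(NULL, comp_ids))
  seg_len <- segs$segments$end - segs$segments$start
  for (j in seq_along(complementary_states))
    cov[, j] <- .interval_coverage(segs$segments,
                                   complementary_states[[j]]) / seg_len
  if (length(cov) && (any(cov < 0) || any(cov > 1)))
    stop("compute_coverage: coverage outside [0,1]")
  segs$coverage <- cov
  segs$comp_ids <- comp_ids
  segs
}

#' Assemble epigenetic profiles (EPs) for SOM training
#'
#' The EP of a segment is its CEP bit vector followed by the coverage
#' values multiplied by the weighting factor `w` (`cfg$coverage_weight`).
#' Column order (CEP states first, complementary states after, each in
#' canonical order) is identical for all segments and recorded in the
#' column names.
#'
#' @param segs an `epi_segmentation` with coverage filled.
#' @param cfg a [segmentation_config()] (defaults to the one stored in
#'   `segs`).
#' @return numeric matrix, one row per segment, `m*n` columns.
#' @export
assemble_profiles <- function(segs, cfg = segs$cfg) {
  stopifnot(inherits(segs, "epi_segmentation"))
  if (is.null(segs$coverage))
    stop("assemble_profiles: coverage not computed yet")
  ep <- cbind(segs$cep, cfg$coverage_weight * segs$coverage)
  colnames(ep) <- c(segs$ref_ids, segs$comp_ids)
  attr(ep, "coverage_weight") <- cfg$coverage_weight
  attr(ep, "mode") <- segs$mode
  ep
}

#' CEP label string for segments
#'
#' Mode prefix plus the CEP bits concatenated in canonical state order,
#' e.g. bits `(1,1,0)` in ES mode give `"ES110"`; `"ES000"` is the
#' unmodified state.
#'
#' @param cep binary vector, or matrix with one row per segment.
#' @param mode `"ES"` or `"EV"`.
#' @return character vector of labels.
#' @export
cep_label <- function(cep, mode = c("ES", "EV")) {
  mode <- match.arg(mode)
  if (is.matrix(cep))
    paste0(mode, apply(cep, 1, paste, collapse = ""))
  else
    paste0(mode, paste(cep, collapse = ""))
}

#' Segment the genome and assemble profiles in one call
#'
#' @param panel a [state_panel()].
#' @param cfg a [segmentation_config()].
#' @return an `epi_segmentation` with `$profiles` (EP matrix) and
#'   `$cep_labels` filled in addition to the [build_segments()] /
#'   [compute_coverage()] fields.
#' @export
segment_genome <- function(panel, cfg) {
  sel <- select_reference_states(panel, cfg)
  segs <- build_segments(sel$reference, panel$layout, cfg)
  segs <- compute_coverage(segs, sel$complementary)
  segs$profiles <- assemble_profiles(segs, cfg)
  segs$cep_labels <- cep_label(segs$cep, cfg$mode)
  segs
}

#' @export
print.epi_segmentation <- function(x, ...) {
  cat(sprintf("epi_segmentation (%s, ref: %s): %d segment(s), %d dropped (< %d bp)\n",
              x$mode, x$cfg$reference, nrow(x$segments), nrow(x$dropped),
              x$cfg$min_segment_length))
  invisible(x)
}

#' Write segments as BED (chrom, start, end, CEP label)
#' @param segs an `epi_segmentation` (after [segment_genome()] or with cep
#'   filled).
#' @param path output BED path.
#' @param dropped_path optional BED for the discarded short segments.
#' @export
write_segments <- function(segs, path, dropped_path = NULL) {
  dt <- data.table::copy(segs$segments)
  dt[, name := cep_label(segs$cep, segs$mode)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 12)
  if (!is.null(dropped_path))
    data.table::fwrite(segs$dropped, dropped_path, sep = "\t",
                       col.names = FALSE, scipen = 12)
  invisible(path)
}

#' Write the EP matrix as TSV (one row per segment, ordered state columns)
#' @param segs an `epi_segmentation` with profiles.
#' @param path output TSV.
#' @export
write_profiles <- function(segs, path) {
  dt <- data.table::data.table(chrom = segs$segments$chrom,
                               start = segs$segments$start,
                               end = segs$segments$end)
  dt <- cbind(dt, data.table::as.data.table(segs$profiles))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
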