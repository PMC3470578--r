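#' Region set: the modified regions of one mark in one cell type
#'
#' A `region_set` stores sorted, merged genomic intervals in 0-based
#' half-open coordinates on a fixed [genome_layout()]. Overlapping or
#' adjacent input intervals are unioned on construction, so the stored
#' intervals are the canonical representation of the underlying base set
#' (the discretized "modification state" of one data set).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`end` exclusive).
#' @param layout a [genome_layout()].
#' @param label optional label, conventionally `"<mark>:<cell_type>"`.
#' @return object of class `region_set`: a `data.table` with columns
#'   `chrom`, `start`, `end` and attributes `layout`, `label`.
#' @examples
#' gl <- genome_layout(c(chr1 = 100))
#' region_set("chr1", c(10, 20), c(20, 30), gl)  # merges to [10,30)
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), layout, label = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("region_set: chrom/start/end lengths differ")
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = as.integer(start),
                               end = as.integer(end))
  if (nrow(dt)) {
    unknown <- setdiff(dt$chrom, names(layout))
    if (length(unknown))
      stop("region_set: unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(dt$start < 0))
      stop("region_set: negative start coordinate")
    if (any(dt$end <= dt$start))
      stop("region_set: intervals must satisfy start < end (0-based half-open)")
    if (any(dt$end > unclass(layout)[dt$chrom]))
      stop("region_set: interval beyond chromosome length")
    dt <- .merge_intervals(dt)
  }
  data.table::setattr(dt, "layout", layout)
  data.table::setattr(dt, "label", label)
  data.table::setattr(dt, "class", c("region_set", class(dt)))
  dt[]
}

# union of 0-based half-open intervals via IRanges::reduce
# (adjacent intervals merge: reduce() default min.gapwidth = 1)
.merge_intervals <- function(dt) {
  out <- dt[, {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
    list(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
  }, by = chrom]
  data.table::setorder(out, chrom, start)
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set%s: %d interval(s), %d base(s)\n",
              if (is.null(attr(x, "label"))) "" else paste0(" [", attr(x, "label"), "]"),
              nrow(x), n_bases(x)))
  if (nrow(x)) print(data.table::as.data.table(x), ...)
  invisible(x)
}

#' Total number of bases covered by a region set
#' @param rs a [region_set()].
#' @return integer base count.
#' @export
n_bases <- function(rs) {
  if (!nrow(rs)) return(0L)
  sum(rs$end - rs$start)
}

#' Convert a region set to a per-base logical vector for one chromosome
#'
#' Mostly useful for oracle-style checks on toy genomes.
#' @param rs a [region_set()].
#' @param chrom chromosome name.
#' @return logical vector of length `layout[chrom]`; element `i` refers to
#'   0-based position `i - 1`.
#' @export
region_mask <- function(rs, chrom) {
  layout <- attr(rs, "layout")
  if (!chrom %in% names(layout)) stop("region_mask: unknown chromosome ", chrom)
  v <- logical(unclass(layout)[[chrom]])
  sub <- rs[rs$chrom == chrom, ]
  if (nrow(sub))
    for (i in seq_len(nrow(sub))) v[(sub$start[i] + 1L):sub$end[i]] <- TRUE
  v
}

#' Build a region set from a per-base logical mask (inverse of region_mask)
#' @param mask logical vector for one chromosome.
#' @param chrom chromosome name.
#' @param layout a [genome_layout()].
#' @param label optional label.
#' @return a [region_set()].
#' @export
mask_to_regions <- function(mask, chrom, layout, label = NULL) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  region_set(rep(chrom, sum(keep)), starts[keep], ends[keep], layout, label)
}

#' Read a BED3+ file into a region set
#'
#' Overlapping and adjacent intervals are unioned. Coordinates are used
#' as-is (BED is already 0-based half-open).
#'
#' @param path BED file with at least 3 columns.
#' @param layout a [genome_layout()].
#' @param label optional label attached to the result.
#' @return a [region_set()].
#' @export
read_regions <- function(path, layout, label = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("read_regions: parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (any(BiocGenerics::width(gr) < 1))
    stop("read_regions: validation error: interval with start >= end in ", path)
  region_set(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
             layout, label)
}

#' Write a region set (or segment table) as BED
#' @param rs a [region_set()] or any data.frame with chrom/start/end
#'   (plus optional `name` column).
#' @param path output path.
#' @export
write_regions <- function(rs, path) {
  dt <- data.table::as.data.table(rs)[, c("chrom", "start", "end"),
                                      with = FALSE]
  if (!is.null(rs$name)) dt[, name := rs$name]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 12)
  invisible(path)
}

utils::globalVariables("name")
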