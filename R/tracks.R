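#' Per-position read-count track
#'
#' Sparse non-negative integer counts per 0-based genomic position.
#' Positions absent from the table have count 0.
#'
#' @param chrom character vector.
#' @param pos integer vector of 0-based positions.
#' @param count non-negative integer vector.
#' @param layout a [genome_layout()].
#' @return object of class `count_track`: keyed `data.table(chrom, pos,
#'   count)` with a `layout` attribute. Zero counts are dropped.
#' @export
count_track <- function(chrom = character(), pos = integer(),
                        count = integer(), layout) {
  stopifnot(inherits(layout, "genome_layout"))
  dt <- data.table::data.table(chrom = as.character(chrom),
                               pos = as.integer(pos),
                               count = count)
  if (nrow(dt)) {
    if (any(!is.finite(dt$count)) || any(dt$count < 0) ||
        any(dt$count != round(dt$count)))
      stop("count_track: counts must be non-negative integers")
    dt[, count := as.integer(count)]
    unknown <- setdiff(dt$chrom, names(layout))
    if (length(unknown))
      stop("count_track: unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(dt$pos < 0) || any(dt$pos >= unclass(layout)[dt$chrom]))
      stop("count_track: position outside chromosome bounds")
    if (anyDuplicated(dt, by = c("chrom", "pos")))
      stop("count_track: duplicated positions")
    dt <- dt[count > 0L]
  }
  data.table::setkey(dt, chrom, pos)
  data.table::setattr(dt, "layout", layout)
  data.table::setattr(dt, "class", c("count_track", class(dt)))
  dt[]
}

#' Read a 4-column bedGraph file into a count track
#'
#' Every base covered by an interval receives the interval's value.
#' Values must be integral and non-negative; records whose intervals
#' overlap are an error (ambiguous counts should fail loudly, not be
#' summed).
#'
#' @param path bedGraph file (track/browser/comment lines are skipped).
#' @param layout a [genome_layout()].
#' @return a [count_track()].
#' @export
read_count_track <- function(path, layout) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(count_track(layout = layout))
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop("read_count_track: parse error at line ", lineno[which(nf != 4L)[1]],
         ": expected 4 bedGraph columns")
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  val <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != round(start) | end != round(end) | start >= end)
  if (length(bad))
    stop("read_count_track: parse error at line ", lineno[bad[1]],
         ": malformed interval")
  if (any(!is.finite(val) | val != round(val)))
    stop("read_count_track: type error: non-integer count value at line ",
         lineno[which(!is.finite(val) | val != round(val))[1]])
  chromv <- m[, 1]
  unknown <- setdiff(chromv, names(layout))
  if (length(unknown))
    stop("read_count_track: bounds error: unknown chromosome(s) ",
         paste(unknown, collapse = ", "))
  if (any(end > unclass(layout)[chromv]))
    stop("read_count_track: bounds error: interval beyond chromosome at line ",
         lineno[which(end > unclass(layout)[chromv])[1]])
  # expand intervals to per-base positions
  w <- as.integer(end - start)
  chrom <- rep(chromv, w)
  pos <- unlist(lapply(seq_along(w),
                       function(i) seq.int(start[i], length.out = w[i])))
  count <- rep(as.integer(val), w)
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               count = count)
  if (anyDuplicated(dt, by = c("chrom", "pos")))
    stop("read_count_track: overlapping count records (ambiguous counts)")
  count_track(dt$chrom, dt$pos, dt$count, layout)
}

#' Write a count track as bedGraph (runs of equal counts are collapsed)
#' @param track a [count_track()].
#' @param path output path.
#' @export
write_count_track <- function(track, path) {
  if (!nrow(track)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  dt <- data.table::as.data.table(track)
  data.table::setorder(dt, chrom, pos)
  # collapse consecutive positions with the same count into intervals
  dt[, run := cumsum(c(1L, diff(pos) != 1L)) , by = chrom]
  dt[, grp := data.table::rleid(run, count), by = chrom]
  out <- dt[, .(start = pos[1], end = pos[.N] + 1L, value = count[1]),
            by = .(chrom, grp)][, grp := NULL]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 12)
  invisible(path)
}

utils::globalVariables(c("run", "grp"))

#' Look up counts at given positions (absent means 0)
#' @param track a [count_track()].
#' @param chrom chromosome name.
#' @param pos 0-based positions.
#' @return integer vector of counts.
#' @export
track_counts_at <- function(track, chrom, pos) {
  q <- data.table::data.table(chrom = chrom, pos = as.integer(pos))
  res <- data.table::as.data.table(track)[q, on = c("chrom", "pos")]
  ifelse(is.na(res$count), 0L, res$count)
}
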