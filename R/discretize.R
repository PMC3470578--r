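#' Discretization configuration
#'
#' Parameters turning per-position enrichment ratios into binary modified
#' regions. Defaults follow the standard recipe: positions with enrichment
#' of at least 3 are joined into a region when consecutive kept positions
#' are closer than 100 nt (less than one nucleosome), and candidate regions
#' shorter than 100 nt are discarded as likely mapping noise.
#'
#' @param enrichment_threshold minimal enrichment ratio (inclusive,
#'   default 3).
#' @param max_join_gap join gap in bp; consecutive kept positions are
#'   joined only if their distance is strictly smaller (default 100).
#' @param min_region_length minimal retained region length in bp (default
#'   100; shorter regions are treated as unmodified).
#' @param wce_zero_policy what to do when the control count is 0 at a
#'   position with modification reads: `"exclude"` (ratio undefined,
#'   conservative default) or `"pseudocount"` (divide by `pseudocount`).
#' @param pseudocount denominator used under the pseudocount policy.
#' @return object of class `discretization_config`.
#' @export
discretization_config <- function(enrichment_threshold = 3,
                                  max_join_gap = 100L,
                                  min_region_length = 100L,
                                  wce_zero_policy = c("exclude", "pseudocount"),
                                  pseudocount = 1) {
  wce_zero_policy <- match.arg(wce_zero_policy)
  if (enrichment_threshold <= 0 || max_join_gap <= 0 ||
      min_region_length <= 0 || pseudocount <= 0)
    stop("discretization_config: all thresholds must be > 0")
  structure(list(enrichment_threshold = enrichment_threshold,
                 max_join_gap = as.integer(max_join_gap),
                 min_region_length = as.integer(min_region_length),
                 wce_zero_policy = wce_zero_policy,
                 pseudocount = pseudocount),
            class = "discretization_config")
}

#' Validate modification counts against an H3 control track
#'
#' Counts of the modified-H3 track are set aside (zeroed) at every position
#' where the H3 control has no mapped reads; positions with H3 evidence are
#' untouched.
#'
#' @param mod,h3 [count_track()]s on the same layout.
#' @return a `count_track` equal to `mod` restricted to positions where
#'   `h3 > 0`.
#' @export
validate_against_h3 <- function(mod, h3) {
  .check_same_layout(attr(mod, "layout"), attr(h3, "layout"))
  keep <- data.table::as.data.table(mod)[
    data.table::as.data.table(h3)[, .(chrom, pos)],
    on = c("chrom", "pos"), nomatch = NULL]
  count_track(keep$chrom, keep$pos, keep$count, attr(mod, "layout"))
}

#' Enrichment track: per-position modification/control ratio
#'
#' Defined only at positions with a positive modification count; where the
#' control count is positive the value is `mod/wce`, otherwise the
#' `wce_zero_policy` of the configuration applies.
#'
#' @param mod,wce [count_track()]s on the same layout.
#' @param cfg a [discretization_config()].
#' @param scale_mod,scale_wce optional per-track scale factors applied to
#'   the counts before the ratio (default 1: raw ratio, no library-size
#'   normalization).
#' @return object of class `enrichment_track`: `data.table(chrom, pos,
#'   ratio)` with a `layout` attribute.
#' @export
compute_enrichment <- function(mod, wce, cfg = discretization_config(),
                               scale_mod = 1, scale_wce = 1) {
  .check_same_layout(attr(mod, "layout"), attr(wce, "layout"))
  m <- data.table::as.data.table(mod)
  w <- data.table::as.data.table(wce)
  j <- w[m, on = c("chrom", "pos")] # all mod positions, wce count or NA
  data.table::setnames(j, c("count", "i.count"), c("count.wce", "count.mod"))
  j[is.na(count.wce), count.wce := 0L]
  j[, ratio := ifelse(count.wce > 0,
                      (scale_mod * count.mod) / (scale_wce * count.wce),
                      NA_real_)]
  if (cfg$wce_zero_policy == "pseudocount")
    j[count.wce == 0L, ratio := (scale_mod * count.mod) / cfg$pseudocount]
  out <- j[!is.na(ratio), .(chrom, pos, ratio)]
  data.table::setkey(out, chrom, pos)
  data.table::setattr(out, "layout", attr(mod, "layout"))
  data.table::setattr(out, "class", c("enrichment_track", class(out)))
  out[]
}

#' Construct an enrichment track directly from positions and ratios
#' @param chrom,pos,ratio vectors (0-based positions, ratio >= 0).
#' @param layout a [genome_layout()].
#' @return class `enrichment_track`.
#' @export
enrichment_track <- function(chrom = character(), pos = integer(),
                             ratio = numeric(), layout) {
  stopifnot(inherits(layout, "genome_layout"))
  dt <- data.table::data.table(chrom = as.character(chrom),
                               pos = as.integer(pos),
                               ratio = as.numeric(ratio))
  if (nrow(dt)) {
    if (any(dt$ratio < 0)) stop("enrichment_track: ratio must be >= 0")
    if (any(dt$pos < 0) || any(dt$pos >= unclass(layout)[dt$chrom]))
      stop("enrichment_track: position outside chromosome bounds")
    if (anyDuplicated(dt, by = c("chrom", "pos")))
      stop("enrichment_track: duplicated positions")
  }
  data.table::setkey(dt, chrom, pos)
  data.table::setattr(dt, "layout", layout)
  data.table::setattr(dt, "class", c("enrichment_track", class(dt)))
  dt[]
}

#' Call modified regions from an enrichment track
#'
#' Positions with enrichment at or above the threshold are scanned in
#' genomic order per chromosome; consecutive kept positions are joined into
#' one region while their distance is strictly smaller than `max_join_gap`.
#' Each region spans `[first_kept, last_kept + 1)`. Regions shorter than
#' `min_region_length` are dropped (treated as unmodified).
#'
#' @param enr an `enrichment_track` (see [compute_enrichment()]).
#' @param cfg a [discretization_config()].
#' @param label optional label for the resulting region set.
#' @return a [region_set()]: the modification state (MS) of the data set.
#' @export
call_modified_regions <- function(enr, cfg = discretization_config(),
                                  label = NULL) {
  layout <- attr(enr, "layout")
  kept <- data.table::as.data.table(enr)[ratio >= cfg$enrichment_threshold]
  if (!nrow(kept))
    return(region_set(layout = layout, label = label))
  data.table::setorder(kept, chrom, pos)
  reg <- kept[, {
    brk <- cumsum(c(1L, as.integer(diff(pos) >= cfg$max_join_gap)))
    list(start = tapply(pos, brk, min), end = tapply(pos, brk, max) + 1L)
  }, by = chrom]
  reg <- reg[end - start >= cfg$min_region_length]
  region_set(reg$chrom, reg$start, reg$end, layout, label)
}

#' Full discretization of one modification data set
#'
#' Convenience wrapper: optional H3 validation, enrichment ratio, region
#' calling.
#'
#' @param mod,wce [count_track()]s.
#' @param h3 optional H3 control [count_track()].
#' @param cfg a [discretization_config()].
#' @param label optional label.
#' @return a [region_set()].
#' @export
discretize_track <- function(mod, wce, h3 = NULL,
                             cfg = discretization_config(), label = NULL) {
  if (!is.null(h3)) mod <- validate_against_h3(mod, h3)
  call_modified_regions(compute_enrichment(mod, wce, cfg), cfg, label)
}
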