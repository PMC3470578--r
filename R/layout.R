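#' Genome layout (chromosome sizes)
#'
#' A named vector of chromosome lengths in bp. Chromosome name matching
#' throughout the package is exact string equality; no "chr" aliasing is
#' performed.
#'
#' @param lengths named numeric/integer vector; names are chromosome names,
#'   values are lengths in bp (positive integers).
#' @return an object of class `genome_layout` (a named integer vector).
#' @examples
#' gl <- genome_layout(c(chr1 = 1000, chr2 = 500))
#' @export
genome_layout <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("genome_layout: chromosome names must be unique and non-empty")
  len <- as.numeric(lengths)
  if (any(!is.finite(len)) || any(len <= 0) || any(len != round(len)))
    stop("genome_layout: lengths must be positive integers")
  structure(setNames(as.integer(len), nm), class = "genome_layout")
}

#' Read a chromosome-sizes TSV (name, length)
#'
#' @param path two-column tab-separated file without header.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  genome_layout(setNames(dt$length, dt$chrom))
}

#' Write a chromosome-sizes TSV
#' @param layout a [genome_layout()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  data.table::fwrite(data.table::data.table(chrom = names(layout),
                                            length = as.integer(layout)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.check_same_layout <- function(a, b, what = "tracks") {
  if (!identical(unclass(a), unclass(b)))
    stop("layout mismatch: ", what, " are not defined on the same genome layout")
  invisible(TRUE)
}
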