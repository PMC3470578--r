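#' Gene models: transcripts grouped by gene
#'
#' A `gene_models` object is a `data.table` with one row per transcript:
#' columns `gene_id`, `transcript_id`, `chrom`, `start`, `end` (0-based
#' half-open transcript span) and `strand` (`+`/`-`). Intervals are clipped
#' to chromosome bounds on read.
#'
#' @param gene_id,transcript_id character vectors.
#' @param chrom,start,end,strand transcript span columns.
#' @param layout a [genome_layout()].
#' @return object of class `gene_models`.
#' @export
gene_models <- function(gene_id, transcript_id, chrom, start, end, strand,
                        layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!all(strand %in% c("+", "-")))
    stop("gene_models: validation error: strand must be '+' or '-'")
  unknown <- setdiff(chrom, names(layout))
  if (length(unknown))
    stop("gene_models: unknown chromosome(s): ", paste(unknown, collapse = ", "))
  dt <- data.table::data.table(gene_id = as.character(gene_id),
                               transcript_id = as.character(transcript_id),
                               chrom = as.character(chrom),
                               start = pmax(0L, as.integer(start)),
                               end = pmin(as.integer(end),
                                          unclass(layout)[as.character(chrom)]),
                               strand = as.character(strand))
  if (any(dt$end <= dt$start))
    stop("gene_models: empty transcript span after clipping")
  data.table::setattr(dt, "layout", layout)
  data.table::setattr(dt, "class", c("gene_models", class(dt)))
  dt[]
}

#' Read gene models from BED12 or GTF
#'
#' The dialect is declared, not sniffed. Only the transcript span is kept
#' (exon structure is not used downstream). For BED12, the `name` column is
#' taken as both gene and transcript id unless it contains
#' `"<gene>|<transcript>"`. For GTF, transcripts are grouped under their
#' `gene_id` attribute; GTF 1-based closed coordinates are converted to
#' 0-based half-open on read.
#'
#' @param path input file.
#' @param layout a [genome_layout()].
#' @param format `"bed12"` or `"gtf"`.
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path, layout, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stop("read_gene_models: validation error: unknown strand symbol")
    nm <- if (!is.null(gr$name)) gr$name else paste0("feature", seq_along(gr))
    has_pipe <- grepl("|", nm, fixed = TRUE)
    gid <- ifelse(has_pipe, sub("\\|.*$", "", nm), nm)
    tid <- ifelse(has_pipe, sub("^.*\\|", "", nm), nm)
    gene_models(gid, tid, as.character(GenomicRanges::seqnames(gr)),
                BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                strand, layout)
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[gr$type %in% c("transcript", "mRNA")]
    if (!length(gr))
      stop("read_gene_models: no transcript records in GTF")
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stop("read_gene_models: validation error: unknown strand symbol")
    tid <- gr$transcript_id
    if (is.null(tid)) tid <- paste0("tx", seq_along(gr))
    gene_models(gr$gene_id, tid, as.character(GenomicRanges::seqnames(gr)),
                BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                strand, layout)
  }
}

#' Extend transcripts upstream of their 5' end (strand-aware)
#'
#' Promoter and enhancer chromatin upstream of the transcription start site
#' matters for expression, so transcripts are extended by `extension` bp at
#' the 5' end before overlapping them with segments: on `+` the start moves
#' left, on `-` the end moves right. Results are clipped to chromosome
#' bounds.
#'
#' @param genes a [gene_models()] table.
#' @param extension bp to add upstream (default 2000).
#' @return a `gene_models` table with extended spans.
#' @export
extend_upstream <- function(genes, extension = 2000L) {
  layout <- attr(genes, "layout")
  dt <- data.table::copy(data.table::as.data.table(genes))
  dt[strand == "+", start := pmax(0L, start - as.integer(extension))]
  dt[strand == "-", end := pmin(unclass(layout)[chrom],
                                end + as.integer(extension))]
  data.table::setattr(dt, "layout", layout)
  data.table::setattr(dt, "class", class(genes))
  dt[]
}

#' Read a present/absent expression table
#'
#' Tab-separated with header: first column `gene_id`, remaining columns one
#' per cell type with entries 0 (absent) or 1 (present).
#'
#' @param path TSV file.
#' @return `data.table` keyed by `gene_id`; class `expression_table`.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  data.table::setnames(dt, 1, "gene_id")
  expression_table(dt)
}

#' Construct an expression table from a data.frame
#' @param df data.frame with `gene_id` column plus one 0/1 column per cell
#'   type.
#' @return class `expression_table`.
#' @export
expression_table <- function(df) {
  dt <- data.table::as.data.table(df)
  if (!"gene_id" %in% names(dt)) stop("expression_table: need gene_id column")
  flags <- as.matrix(dt[, !"gene_id"])
  if (ncol(flags) < 1) stop("expression_table: need at least one cell-type column")
  if (!all(flags %in% c(0, 1)))
    stop("expression_table: flags must be 0 or 1")
  data.table::setkey(dt, gene_id)
  data.table::setattr(dt, "class", c("expression_table", class(dt)))
  dt[]
}

#' Write an expression table as TSV
#' @param expr an [expression_table()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  data.table::fwrite(data.table::as.data.table(expr), path, sep = "\t")
  invisible(path)
}
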