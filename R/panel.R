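#' Panel of modification states
#'
#' Houses the m x n matrix of modification states: one [region_set()] per
#' (mark, cell type) pair, all on the same [genome_layout()]. The
#' declaration order of `marks` and `cell_types` fixes the canonical state
#' order used for CEP bits and coverage columns downstream.
#'
#' @param states named list of [region_set()]s; names must be
#'   `"<mark>:<cell_type>"` for every combination of `marks` and
#'   `cell_types`.
#' @param marks character vector of mark identifiers (e.g. H3K4me3).
#' @param cell_types character vector of cell type identifiers.
#' @return object of class `state_panel`.
#' @examples
#' gl <- genome_layout(c(chr1 = 1000))
#' sts <- setNames(
#'   rep(list(region_set(layout = gl)), 2),
#'   c("H3K4me3:ESC", "H3K4me3:MEF"))
#' state_panel(sts, marks = "H3K4me3", cell_types = c("ESC", "MEF"))
#' @export
state_panel <- function(states, marks, cell_types) {
  expected <- as.vector(t(outer(marks, cell_types, paste, sep = ":")))
  missing <- setdiff(expected, names(states))
  if (length(missing))
    stop("state_panel: missing state(s): ", paste(missing, collapse = ", "))
  states <- states[expected]
  if (!all(vapply(states, inherits, TRUE, "region_set")))
    stop("state_panel: all states must be region_set objects")
  layouts <- lapply(states, attr, "layout")
  for (l in layouts) .check_same_layout(layouts[[1]], l, "panel states")
  structure(list(states = states, marks = marks, cell_types = cell_types,
                 layout = layouts[[1]]),
            class = "state_panel")
}

#' @export
print.state_panel <- function(x, ...) {
  cat(sprintf("state_panel: %d mark(s) x %d cell type(s) on %d chromosome(s)\n",
              length(x$marks), length(x$cell_types), length(x$layout)))
  invisible(x)
}

#' Look up one modification state
#' @param panel a [state_panel()].
#' @param mark,cell_type identifiers.
#' @return the [region_set()] for that state.
#' @export
panel_state <- function(panel, mark, cell_type) {
  key <- paste(mark, cell_type, sep = ":")
  if (!key %in% names(panel$states)) stop("panel_state: no state ", key)
  panel$states[[key]]
}

#' Read a panel from a manifest TSV
#'
#' Three tab-separated columns with header `mark`, `cell_type`, `path`;
#' each path is a BED file of modified regions. Mark and cell-type
#' declaration order follows first appearance in the manifest.
#'
#' @param path manifest TSV.
#' @param layout a [genome_layout()].
#' @param base_dir directory against which relative paths resolve
#'   (default: the manifest's directory).
#' @return a [state_panel()].
#' @export
read_panel <- function(path, layout, base_dir = dirname(path)) {
  man <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot(all(c("mark", "cell_type", "path") %in% names(man)))
  marks <- unique(man$mark)
  cells <- unique(man$cell_type)
  states <- list()
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, man$path[i])
    key <- paste(man$mark[i], man$cell_type[i], sep = ":")
    states[[key]] <- read_regions(p, layout, label = key)
  }
  state_panel(states, marks, cells)
}

#' Write a panel to BED files plus a manifest TSV
#' @param panel a [state_panel()].
#' @param dir output directory (created).
#' @return path of the manifest file.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (key in names(panel$states)) {
    fn <- paste0(gsub(":", "_", key), ".bed")
    write_regions(panel$states[[key]], file.path(dir, fn))
    mk <- sub(":.*$", "", key)
    ct <- sub("^.*:", "", key)
    rows[[key]] <- data.table::data.table(mark = mk, cell_type = ct, path = fn)
  }
  man <- data.table::rbindlist(rows)
  mpath <- file.path(dir, "panel.tsv")
  data.table::fwrite(man, mpath, sep = "\t")
  invisible(mpath)
}
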