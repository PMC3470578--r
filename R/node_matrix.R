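#' Per-node scalar map on the SOM grid
#'
#' One scalar per SOM node plus rendering metadata. Values are stored in
#' node-index order (row-major: node `k` sits at row `(k-1) %/% width + 1`,
#' column `(k-1) %% width + 1`). Masked nodes are `NA`.
#'
#' @param values numeric vector of length `width * height`; `NA` = masked.
#' @param width,height grid shape.
#' @param scale `"linear"` or `"log"` rendering hint.
#' @param inverted logical; reverse the color scale (used for the segment
#'   length map where small values should be warm).
#' @param label legend label.
#' @return object of class `node_map`.
#' @export
node_map <- function(values, width, height, scale = c("linear", "log"),
                     inverted = FALSE, label = "") {
  scale <- match.arg(scale)
  if (length(values) != width * height)
    stop("node_map: validation error: expected ", width * height,
         " values, got ", length(values))
  structure(list(values = as.numeric(values), width = as.integer(width),
                 height = as.integer(height), scale = scale,
                 inverted = isTRUE(inverted), label = label),
            class = "node_map")
}

#' @export
print.node_map <- function(x, ...) {
  cat(sprintf("node_map '%s': %dx%d, scale=%s%s, %d masked\n", x$label,
              x$width, x$height, x$scale, if (x$inverted) " (inverted)" else "",
              sum(is.na(x$values))))
  invisible(x)
}

#' Node map values as a height x width matrix
#' @param map a [node_map()].
#' @return numeric matrix (rows = grid rows).
#' @export
node_map_matrix <- function(map) {
  matrix(map$values, nrow = map$height, ncol = map$width, byrow = TRUE)
}

#' Write a node map as a TSV matrix
#'
#' Header row holds column indices; one row per grid row; masked nodes are
#' written as `NA`. The file round-trips losslessly through
#' [read_node_matrix()].
#'
#' @param map a [node_map()].
#' @param path output path.
#' @param meta_path optional JSON sidecar receiving scale/inverted/label
#'   metadata (default: `paste0(path, ".json")`; `NA` to skip).
#' @export
write_node_matrix <- function(map, path, meta_path = paste0(path, ".json")) {
  m <- node_map_matrix(map)
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, as.character(seq_len(ncol(m))))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  if (!is.na(meta_path)) {
    jsonlite::write_json(list(width = map$width, height = map$height,
                              scale = map$scale, inverted = map$inverted,
                              label = map$label),
                         meta_path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a node map TSV written by [write_node_matrix()]
#' @param path TSV path.
#' @param meta_path optional JSON sidecar path (`NA` or missing file:
#'   defaults used).
#' @return a [node_map()].
#' @export
read_node_matrix <- function(path, meta_path = paste0(path, ".json")) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", na.strings = "NA")
  m <- as.matrix(dt)
  meta <- list(scale = "linear", inverted = FALSE, label = "")
  if (!is.na(meta_path) && file.exists(meta_path))
    meta <- utils::modifyList(meta, jsonlite::read_json(meta_path,
                                                        simplifyVector = TRUE))
  node_map(as.numeric(t(m)), width = ncol(m), height = nrow(m),
           scale = meta$scale, inverted = meta$inverted, label = meta$label)
}
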