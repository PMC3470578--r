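#' Run the full pipeline from a configuration
#'
#' Stages: (optional) discretize per-state count tracks, segment, train the
#' SOM, build all maps, render mosaic images. Every default is echoed into
#' the resolved configuration written to the manifest, so a run is
#' reproducible byte-for-byte from the manifest alone. Any stage failure
#' aborts with the stage name.
#'
#' Configuration (JSON file or R list):
#' \describe{
#'   \item{output}{output directory (required).}
#'   \item{inputs}{`chrom_sizes` (TSV) plus either `panel` (manifest TSV of
#'     region BEDs) or `tracks` (list of `mark`, `cell_type`, `mod`, `wce`,
#'     optional `h3` bedGraph paths for the discretize stage); optional
#'     `genome` FASTA, `genes` (+ `genes_format`), `expression` TSV,
#'     `gene_set` text file.}
#'   \item{synthetic}{alternative to `inputs`: `seed` for the built-in
#'     generator.}
#'   \item{discretize}{`enrichment_threshold` (3), `max_join_gap` (100),
#'     `min_region_length` (100), `wce_zero_policy` ("exclude").}
#'   \item{segmentation}{`mode` ("ES"), `reference`, `min_segment_length`
#'     (200), `coverage_weight` (1).}
#'   \item{som}{`width`/`height` (40), `epochs` (auto: ~200,000
#'     presentations), `alpha` (0.05, 0.005), `sigma` (width/4, 1).}
#'   \item{maps}{`occupancy_threshold` (10), `extension` (2000),
#'     `active_threshold` (1.0).}
#'   \item{render}{logical: write PNG mosaics (default TRUE).}
#' }
#'
#' @param config path to a JSON config file, or an equivalent nested list.
#' @return the output directory, invisibly; outputs: `segments.bed`,
#'   `segments_dropped.bed`, `profiles.tsv`, `som.tsv`, `assignment.tsv`,
#'   `maps/*.tsv` (+ `.json` sidecars), `images/*.png`, `manifest.json`,
#'   `pipeline.log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- .resolve_config(config)
  out <- cfg$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "maps"), showWarnings = FALSE)
  logf <- file.path(out, "pipeline.log")
  cat("", file = logf)
  log_line <- function(stage, msg)
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  # --- inputs / discretize -------------------------------------------------
  panel <- stage("inputs", {
    if (!is.null(cfg$synthetic)) {
      spec <- synthetic_spec(seed = cfg$synthetic$seed)
      make_region_panel(spec)$panel
    } else {
      layout <- read_chrom_sizes(cfg$inputs$chrom_sizes)
      if (!is.null(cfg$inputs$panel)) {
        read_panel(cfg$inputs$panel, layout)
      } else if (!is.null(cfg$inputs$tracks)) {
        dcfg <- discretization_config(cfg$discretize$enrichment_threshold,
                                      cfg$discretize$max_join_gap,
                                      cfg$discretize$min_region_length,
                                      cfg$discretize$wce_zero_policy)
        tracks <- cfg$inputs$tracks
        if (is.data.frame(tracks))
          tracks <- split(tracks, seq_len(nrow(tracks)))
        states <- list()
        marks <- character(); cells <- character()
        for (tr in tracks) {
          mod <- read_count_track(tr$mod, layout)
          wce <- read_count_track(tr$wce, layout)
          h3 <- if (!is.null(tr$h3) && !is.na(tr$h3))
            read_count_track(tr$h3, layout) else NULL
          key <- paste(tr$mark, tr$cell_type, sep = ":")
          states[[key]] <- discretize_track(mod, wce, h3, dcfg, key)
          marks <- union(marks, tr$mark)
          cells <- union(cells, tr$cell_type)
        }
        state_panel(states, marks, cells)
      } else stop("config needs inputs$panel, inputs$tracks or synthetic")
    }
  })
  log_line("inputs", sprintf("%d marks x %d cell types",
                             length(panel$marks), length(panel$cell_types)))

  # --- segmentation --------------------------------------------------------
  segs <- stage("segment", {
    scfg <- segmentation_config(cfg$segmentation$mode,
                                cfg$segmentation$reference,
                                cfg$segmentation$min_segment_length,
                                cfg$segmentation$coverage_weight)
    segment_genome(panel, scfg)
  })
  write_segments(segs, file.path(out, "segments.bed"),
                 file.path(out, "segments_dropped.bed"))
  write_profiles(segs, file.path(out, "profiles.tsv"))
  log_line("segment", sprintf("%d segments, %d dropped",
                              nrow(segs$segments), nrow(segs$dropped)))

  # --- SOM -----------------------------------------------------------------
  trained <- stage("train", {
    w <- cfg$som$width; h <- cfg$som$height
    epochs <- if (is.null(cfg$som$epochs))
      default_epochs(nrow(segs$profiles)) else as.integer(cfg$som$epochs)
    sched <- training_schedule(epochs, cfg$som$alpha[1], cfg$som$alpha[2],
                               cfg$som$sigma[1], cfg$som$sigma[2])
    cfg$som$epochs <- epochs
    grid0 <- linear_initialize(segs$profiles, w, h)
    som_train(segs$profiles, grid0, sched)
  })
  write_som(trained$grid, file.path(out, "som.tsv"))
  data.table::fwrite(data.table::data.table(segment = seq_along(trained$assignment),
                                            node = trained$assignment),
                     file.path(out, "assignment.tsv"), sep = "\t")
  log_line("train", sprintf("QE = %.4f",
                            quantization_error(segs$profiles, trained$grid,
                                               trained$assignment)))

  # --- maps ----------------------------------------------------------------
  maps <- stage("maps", {
    grid <- trained$grid; asg <- trained$assignment
    m <- list(population = population_map(asg, grid),
              segment_length = segment_length_map(asg, segs, grid))
    atlas <- coverage_atlas(asg, segs, grid)
    names(atlas) <- paste0("coverage_", gsub(":", "_", names(atlas)))
    m <- c(m, atlas)
    isl <- island_labeling(asg, segs$cep_labels, grid,
                           cfg$maps$occupancy_threshold)
    aux <- .load_aux_inputs(cfg)
    if (!is.null(aux$genome))
      m$cpg_density <- cpg_density_map(asg, segs, aux$genome, grid)
    if (!is.null(aux$genes) && !is.null(aux$expression))
      m$present_call <- present_call_map(asg, segs, aux$genes,
                                         aux$expression, grid,
                                         cfg$maps$extension,
                                         cfg$maps$active_threshold)
    if (!is.null(aux$genes) && !is.null(aux$gene_set))
      m$gene_set <- gene_set_fraction_map(asg, segs, aux$genes,
                                          aux$gene_set, grid,
                                          cfg$maps$extension)
    for (chr in unique(segs$segments$chrom)) {
      cm <- chromosome_maps(asg, segs, chr, grid)
      m[[paste0("population_", chr)]] <- cm$population
      m[[paste0("enrichment_", chr)]] <- cm$enrichment
    }
    list(maps = m, islands = isl)
  })
  for (nm in names(maps$maps))
    write_node_matrix(maps$maps[[nm]], file.path(out, "maps",
                                                 paste0(nm, ".tsv")))
  data.table::fwrite(maps$islands$islands, file.path(out, "maps",
                                                     "islands.tsv"),
                     sep = "\t")
  log_line("maps", sprintf("%d maps, %d islands", length(maps$maps),
                           nrow(maps$islands$islands)))

  # --- render --------------------------------------------------------------
  if (isTRUE(cfg$render)) {
    stage("render", {
      dir.create(file.path(out, "images"), showWarnings = FALSE)
      for (nm in names(maps$maps))
        render_heatmap(maps$maps[[nm]],
                       path = file.path(out, "images", paste0(nm, ".png")))
    })
    log_line("render", sprintf("%d images", length(maps$maps)))
  }

  # --- manifest ------------------------------------------------------------
  tsvs <- list.files(out, pattern = "\\.(tsv|bed)$", recursive = TRUE,
                     full.names = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("episegsom")),
                   config = cfg,
                   checksums = as.list(tools::md5sum(tsvs)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

.resolve_config <- function(config) {
  def <- list(
    output = NULL, inputs = NULL, synthetic = NULL,
    discretize = list(enrichment_threshold = 3, max_join_gap = 100,
                      min_region_length = 100, wce_zero_policy = "exclude"),
    segmentation = list(mode = "ES", reference = NULL,
                        min_segment_length = 200, coverage_weight = 1),
    som = list(width = 40, height = 40, epochs = NULL,
               alpha = c(0.05, 0.005), sigma = NULL),
    maps = list(occupancy_threshold = 10, extension = 2000,
                active_threshold = 1.0),
    render = TRUE)
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  if (is.null(cfg$output)) stop("config: 'output' is required")
  if (is.null(cfg$segmentation$reference))
    stop("config: segmentation$reference is required")
  if (is.null(cfg$som$sigma)) cfg$som$sigma <- c(cfg$som$width / 4, 1)
  cfg
}

.load_aux_inputs <- function(cfg) {
  aux <- list()
  if (!is.null(cfg$synthetic)) {
    spec <- synthetic_spec(seed = cfg$synthetic$seed)
    ge <- make_genes_and_expression(spec)
    return(list(genome = ge$genome, genes = ge$genes,
                expression = ge$expression, gene_set = ge$gene_set))
  }
  inp <- cfg$inputs
  layout <- read_chrom_sizes(inp$chrom_sizes)
  if (!is.null(inp$genome)) {
    if (!file.exists(inp$genome))
      stop("configuration error: genome FASTA not found: ", inp$genome)
    aux$genome <- Biostrings::readDNAStringSet(inp$genome)
  }
  if (!is.null(inp$genes)) {
    fmt <- if (is.null(inp$genes_format)) "bed12" else inp$genes_format
    aux$genes <- read_gene_models(inp$genes, layout, fmt)
  }
  if (!is.null(inp$expression)) aux$expression <- read_expression(inp$expression)
  if (!is.null(inp$gene_set)) aux$gene_set <- readLines(inp$gene_set)
  aux
}
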