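#' Run the imaging pipeline end to end
#'
#' For each imaging day: read the z-stack, segment foreground objects, crop
#' at the spheroid's widest point, split the spheroid mass from candidate
#' cells, build the smoothed reference surface, fit the periphery ellipse,
#' measure and classify every cell, and assemble the invasion time series.
#' All tabular outputs are written as CSV plus a JSON run summary; every
#' file carries the md5 hash of the resolved configuration, so identical
#' configurations produce identical outputs.
#'
#' Config fields (list or YAML file path): `inputs` (data frame with `day`
#' and `path` columns of TIFF stacks), optional `spacing` override,
#' `method` (`"otsu"`/`"fixed"`) and `threshold`, `min_volume` (um^3),
#' `smoothing_scale` (um), `sphericity_threshold`, `distance_method`,
#' `output_dir`.
#'
#' @param config List or path to a YAML file.
#' @return A list with `cells` (per-cell tibble), `timeseries`
#'   (per-day tibble), `geometry`, `config_hash` and the output paths,
#'   invisibly written under `output_dir`.
#' @export
run_imaging_pipeline <- function(config) {
  cfg <- resolve_config(config, defaults = list(
    spacing = NULL, method = "otsu", threshold = NULL, min_volume = 65,
    smoothing_scale = 10, sphericity_threshold = 0.8,
    distance_method = "surface", output_dir = NULL
  ))
  inputs <- as_tibble(cfg$inputs)
  if (!all(c("day", "path") %in% names(inputs))) {
    abort("`inputs` must have `day` and `path` columns.")
  }
  missing <- inputs$path[!file.exists(inputs$path)]
  if (length(missing)) {
    abort(sprintf("input stack(s) not found: %s", paste(missing, collapse = ", ")))
  }
  hash <- config_hash(cfg[setdiff(names(cfg), "output_dir")])
  inputs <- arrange(inputs, .data$day)
  all_cells <- list()
  geometry <- list()
  for (i in seq_len(nrow(inputs))) {
    day <- inputs$day[i]
    vol <- read_volume_tiff(inputs$path[i], spacing = cfg$spacing)
    mask <- segment_foreground(vol, method = cfg$method,
                               threshold = cfg$threshold,
                               min_volume = cfg$min_volume)
    if (!length(mask$label_ids)) {
      abort(sprintf("day %s: segmentation produced no objects.", day))
    }
    cr <- crop_at_widest(mask)
    parts <- split_spheroid_and_cells(cr$mask)
    ref <- smoothed_reference_surface(parts$spheroid, cfg$smoothing_scale)
    nz <- dim(parts$spheroid$labels)[3]
    slice <- parts$spheroid$labels[, , nz] > 0L
    ell <- fit_periphery_ellipse(slice, vol$spacing[1:2])
    geometry[[i]] <- dplyr::bind_cols(tibble(day = day),
                                      spheroid_geometry(ell$a, ell$b, cr$z_depth))
    cm <- measure_cells(parts$cells, ref)
    cm <- classify_phenotype(cm, cfg$sphericity_threshold)
    cm$day <- day
    all_cells[[i]] <- cm
  }
  cells <- bind_rows(all_cells)
  geometry <- bind_rows(geometry)
  ts <- build_timeseries(geometry, cells)
  out <- list(cells = cells, geometry = geometry, timeseries = ts,
              config_hash = hash)
  if (!is.null(cfg$output_dir)) {
    out$paths <- write_run_outputs(cfg$output_dir, hash, list(
      cells = cells, geometry = geometry, timeseries = ts
    ), summary = list(
      tool = "spheroquant", version = as.character(utils::packageVersion("spheroquant")),
      pipeline = "imaging", config_hash = hash,
      n_days = nrow(geometry), n_cells = nrow(cells)
    ))
  }
  invisible(out)
}

#' Run the counts pipeline end to end
#'
#' Reads a raw count matrix, removes all-zero genes, applies the
#' housekeeping quality filter, normalizes the retained cells
#' (median-of-ratios + log2), clusters them (Ward/Euclidean) and flags
#' dendrogram outliers. Outputs (QC report, normalized matrix, cluster
#' assignments, Newick + JSON dendrogram, JSON summary) are stamped with
#' the config hash.
#'
#' Config fields: `counts` (path, or matrix when called programmatically),
#' `format` (`"csv"`/`"mtx"`), `orientation`, `panel` (character vector or
#' path to a one-gene-per-line file), `min_count`, `max_low_fraction`,
#' `outlier_factor`, `k` (optional cut), `output_dir`.
#'
#' @param config List or path to a YAML file.
#' @return List with `qc`, `normalized`, `clustering`, `outliers`,
#'   `clusters` (when `k` given), `config_hash`, `paths`.
#' @export
run_counts_pipeline <- function(config) {
  cfg <- resolve_config(config, defaults = list(
    format = "csv", orientation = "genes_by_cells", min_count = 10,
    max_low_fraction = 0.30, outlier_factor = 3, k = NULL, output_dir = NULL
  ))
  counts <- cfg$counts
  if (is.character(counts)) {
    if (!file.exists(counts)) abort(sprintf("count file not found: %s", counts))
    counts <- read_count_matrix(counts, format = cfg$format,
                                orientation = cfg$orientation)
  }
  if (!nrow(counts) || !ncol(counts)) abort("count matrix is empty.")
  panel <- cfg$panel
  if (is.character(panel) && length(panel) == 1L && file.exists(panel)) {
    panel <- readLines(panel)
  }
  hash_cfg <- cfg[setdiff(names(cfg), "output_dir")]
  if (is.matrix(hash_cfg$counts)) {
    hash_cfg$counts <- unname(config_hash(list(d = dim(counts),
                                               s = sum(counts))))
  }
  hash <- config_hash(hash_cfg)
  counts <- drop_zero_genes(counts)
  qc <- housekeeping_qc(counts, panel, min_count = cfg$min_count,
                        max_low_fraction = cfg$max_low_fraction)
  kept <- qc$cell_id[!qc$excluded]
  if (length(kept) < 2L) abort("fewer than 2 cells pass the housekeeping filter.")
  norm <- normalize_for_clustering(counts[, kept, drop = FALSE])
  cl <- ward_cluster(norm)
  outliers <- flag_outliers(cl, factor = cfg$outlier_factor)
  clusters <- if (!is.null(cfg$k)) cut_clusters(cl, cfg$k)
  out <- list(qc = qc, normalized = norm, clustering = cl,
              outliers = outliers, clusters = clusters, config_hash = hash)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    norm_df <- dplyr::bind_cols(tibble(gene = rownames(norm)), as_tibble(norm))
    tabs <- list(qc_report = qc, normalized = norm_df)
    if (!is.null(clusters)) tabs$clusters <- clusters
    out$paths <- write_run_outputs(cfg$output_dir, hash, tabs, summary = list(
      tool = "spheroquant", version = as.character(utils::packageVersion("spheroquant")),
      pipeline = "counts", config_hash = hash,
      n_cells_in = ncol(counts), n_cells_kept = length(kept),
      n_excluded = sum(qc$excluded), outliers = outliers
    ))
    nwk <- file.path(cfg$output_dir, "dendrogram.nwk")
    dendrogram_newick(cl, nwk)
    dj <- file.path(cfg$output_dir, "dendrogram.json")
    dendrogram_json(cl, dj)
    out$paths <- c(out$paths, dendrogram_newick = nwk, dendrogram_json = dj)
  }
  invisible(out)
}

resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- list(defaults[[nm]])
  }
  config
}

# Write each tibble as CSV with a `# config: <hash>` comment line, plus a
# JSON summary; returns named paths.
write_run_outputs <- function(dir, hash, tables, summary) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    con <- file(p, "w")
    writeLines(sprintf("# config: %s", hash), con)
    close(con)
    readr::write_csv(tables[[nm]], p, append = TRUE, col_names = TRUE)
    paths[nm] <- p
  }
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA, null = "null")
  paths["summary"] <- sp
  paths
}
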