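#' Write and read imaging volumes as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 32-bit float pages scaled to `[0, 1]`; the
#' scale factor, voxel spacing (um) and channel name go to a JSON sidecar
#' next to the TIFF (`<path>.json`), since plain TIFF carries no trustworthy
#' physical calibration.
#'
#' @param volume A [voxel_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  v <- volume$intensities
  scale <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(spacing_um = volume$spacing, intensity_scale = scale,
         channel_name = volume$channel_name),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param spacing Optional spacing override (um per axis); required when the
#'   sidecar is missing.
#' @export
read_volume_tiff <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  scale <- 1
  channel <- "unknown"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(spacing)) spacing <- meta$spacing_um
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    if (!is.null(meta$channel_name)) channel <- meta$channel_name
  }
  if (is.null(spacing)) {
    abort("no spacing metadata: sidecar JSON missing and no `spacing` override given.")
  }
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  voxel_volume(arr * scale, spacing, channel)
}

#' Write and read a count matrix
#'
#' CSV layout: first column `gene`, remaining columns one per cell. MTX
#' layout: MatrixMarket triplet `counts.mtx` plus `genes.txt` and
#' `cells.txt` line files in the same directory.
#'
#' @param counts Integer genes x cells matrix with dimnames.
#' @param path CSV file path, or the `.mtx` path for `format = "mtx"`.
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, format = c("csv", "mtx")) {
  check_counts(counts)
  format <- match.arg(format)
  if (format == "csv") {
    df <- tibble(gene = rownames(counts))
    df <- dplyr::bind_cols(df, as_tibble(counts))
    readr::write_csv(df, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    base <- dirname(path)
    writeLines(rownames(counts), file.path(base, "genes.txt"))
    writeLines(colnames(counts), file.path(base, "cells.txt"))
  }
  invisible(path)
}

#' @rdname write_count_matrix
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`
#'   (transposed on read).
#' @export
read_count_matrix <- function(path, format = c("csv", "mtx"),
                              orientation = c("genes_by_cells", "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    m <- as.matrix(Matrix::readMM(path))
    base <- dirname(path)
    rownames(m) <- readLines(file.path(base, "genes.txt"))
    colnames(m) <- readLines(file.path(base, "cells.txt"))
  }
  if (orientation == "cells_by_genes") m <- t(m)
  storage.mode(m) <- "integer"
  check_counts(m)
  m
}
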