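#' Classify invading cells into epithelial, escaping and amoeboid
#'
#' The three phenotypes seen around an invading spheroid are defined by
#' attachment and shape: cells in contact with the spheroid periphery and
#' compact (high sphericity) are `epithelial`; attached but elongated cells
#' (sphericity below the threshold) have commenced tumor escape and are
#' `escaping`; detached cells, which in this assay migrate individually with
#' a rounded morphology, are `amoeboid`.
#'
#' The default threshold of 0.8 reflects that detached cells in collagen
#' maintain sphericities of about 0.8-0.9 while actively escaping cells are
#' markedly elongated.
#'
#' @param metrics A [measure_cells()] tibble (needs `psi`, `attached`).
#' @param sphericity_threshold Attached cells below this sphericity are
#'   called escaping.
#' @return The input tibble with a `phenotype` column appended.
#' @export
classify_phenotype <- function(metrics, sphericity_threshold = 0.8) {
  stopifnot(is.data.frame(metrics))
  if (!all(c("psi", "attached") %in% names(metrics))) {
    abort("`metrics` must contain `psi` and `attached` columns.")
  }
  dplyr::mutate(
    metrics,
    phenotype = dplyr::case_when(
      !.data$attached ~ "amoeboid",
      .data$psi < sphericity_threshold ~ "escaping",
      TRUE ~ "epithelial"
    )
  )
}

#' Invasion density: escaped cells per um^2 of imaged surface
#'
#' Normalizes an escaped-cell count to the spherical-cap surface area of the
#' imaged hemispheroid, so invasiveness is comparable across spheroids of
#' different sizes.
#'
#' @param escaped_count Number of escaped (detached) cells.
#' @param SA Cap surface area, um^2 (> 0).
#' @return Cells per um^2 (vectorized).
#' @export
invasion_density <- function(escaped_count, SA) {
  if (any(SA <= 0)) abort("`SA` must be positive.")
  escaped_count / SA
}

#' Build the per-day invasion time series
#'
#' Combines per-day spheroid geometry with per-day cell metrics into the
#' population metrics tracked over a drug assay: estimated volume and volume
#' relative to day 0, cap surface area, newly and cumulatively escaped cell
#' counts (escaped = detached, `d > 0`; attached escaping cells are reported
#' separately), invasion density (cumulative escaped cells per um^2 of cap
#' surface), mean escaped-cell sphericity and distance, and invasion speed
#' (day-to-day change in mean escaped distance; a population-level rate, no
#' cell tracking).
#'
#' @param geometry_by_day Tibble with a `day` column plus the
#'   [spheroid_geometry()] columns for that day.
#' @param cells_by_day Tibble of per-cell metrics with `day`, `d`, `psi`
#'   and `attached` columns (e.g. stacked [classify_phenotype()] outputs).
#' @return A tibble of class `invasion_timeseries`, one row per day.
#' @export
build_timeseries <- function(geometry_by_day, cells_by_day = NULL) {
  stopifnot(is.data.frame(geometry_by_day))
  if (!"day" %in% names(geometry_by_day)) {
    abort("`geometry_by_day` must have a `day` column.")
  }
  geo <- arrange(geometry_by_day, .data$day)
  if (anyDuplicated(geo$day)) abort("duplicate days in `geometry_by_day`.")
  if (!any(geo$day == 0)) {
    warn("day 0 missing: relative volume is undefined and reported as NA.")
    v0 <- NA_real_
  } else {
    v0 <- geo$V[geo$day == 0]
  }
  if (is.null(cells_by_day) || !nrow(cells_by_day)) {
    cells_by_day <- tibble(day = numeric(), d = numeric(), psi = numeric(),
                           attached = logical())
  }
  if (!"phenotype" %in% names(cells_by_day)) {
    cells_by_day$phenotype <- NA_character_
  }
  per_day <- cells_by_day |>
    group_by(.data$day) |>
    summarise(
      escaped_count = sum(!.data$attached),
      attached_escaping = sum(.data$attached & !is.na(.data$phenotype) &
                                .data$phenotype == "escaping"),
      mean_escaped_psi = if (any(!.data$attached)) {
        mean(.data$psi[!.data$attached])
      } else NA_real_,
      mean_escaped_d = if (any(!.data$attached)) {
        mean(.data$d[!.data$attached])
      } else NA_real_,
      .groups = "drop"
    )
  out <- geo |>
    left_join(per_day, by = "day") |>
    mutate(
      escaped_count = dplyr::coalesce(.data$escaped_count, 0L),
      attached_escaping = dplyr::coalesce(.data$attached_escaping, 0L),
      # each image shows every cell escaped so far, so newly escaped cells
      # are the day-over-day increase (no tracking; a shrinking count means
      # no new detections) and the cumulative count is their running sum
      new_escaped = pmax(.data$escaped_count -
                           dplyr::lag(.data$escaped_count, default = 0L), 0L),
      cumulative_escaped = cumsum(.data$new_escaped),
      relative_volume = .data$V / v0,
      invasion_density = invasion_density(.data$cumulative_escaped, .data$SA),
      invasion_speed = c(NA_real_, diff(.data$mean_escaped_d) / diff(.data$day))
    )
  class(out) <- c("invasion_timeseries", class(out))
  out
}
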