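#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_segment facet_wrap labs theme_minimal vars
NULL

#' Plot an invasion time series
#'
#' Line panels of the headline assay metrics over time: relative spheroid
#' volume, cumulative escaped cells per um^2, and mean escaped-cell
#' sphericity per day.
#'
#' @param object An [build_timeseries()] result.
#' @param metrics Character vector of columns to panel.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.invasion_timeseries <- function(object,
                                         metrics = c("relative_volume",
                                                     "invasion_density",
                                                     "mean_escaped_psi"),
                                         ...) {
  long <- object |>
    select(dplyr::all_of(c("day", metrics))) |>
    tidyr::pivot_longer(-"day", names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$day, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(vars(.data$metric), scales = "free_y") +
    labs(x = "day", y = NULL) +
    theme_minimal()
}

#' Plot a housekeeping QC report
#'
#' Per-cell fraction of low housekeeping genes with the exclusion threshold.
#'
#' @param object A [housekeeping_qc()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qc_report <- function(object, ...) {
  thr <- attr(object, "max_low_fraction")
  df <- mutate(object, cell_id = factor(.data$cell_id, levels = .data$cell_id))
  ggplot(df, aes(x = .data$cell_id, y = .data$fraction_low,
                 fill = .data$excluded)) +
    geom_col() +
    geom_hline(yintercept = thr, linetype = "dashed") +
    labs(x = NULL, y = "fraction of housekeeping panel < min_count") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot per-cell morphometrics
#'
#' Sphericity against distance to the reference surface, colored by
#' phenotype when present: the two axes along which invading cells are
#' selected.
#'
#' @param object A [measure_cells()] (optionally classified) tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_metrics <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$d, y = .data$psi))
  if ("phenotype" %in% names(object)) {
    p <- p + geom_point(aes(color = .data$phenotype), size = 2)
  } else {
    p <- p + geom_point(size = 2)
  }
  p + labs(x = "distance to reference surface (um)", y = "sphericity") +
    theme_minimal()
}

#' Plot a Ward clustering dendrogram
#'
#' @param object A [ward_cluster()] result.
#' @param label_size Leaf label text size.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ward_clustering <- function(object, label_size = 2.5, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    ch <- hc$merge[i, ]
    cx <- ifelse(ch < 0, xpos[-ch], node_x[pmax(ch, 1)])
    chh <- ifelse(ch < 0, 0, node_h[pmax(ch, 1)])
    node_x[i] <- mean(cx)
    segs[[i]] <- tibble(
      x = c(cx[1], cx[2], cx[1]), xend = c(cx[1], cx[2], cx[2]),
      y = c(chh[1], chh[2], node_h[i]), yend = c(node_h[i], node_h[i], node_h[i])
    )
  }
  leaves <- tibble(x = xpos, label = hc$labels)
  ggplot(bind_rows(segs)) +
    geom_segment(aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       aes(x = .data$x, y = -0.02 * max(node_h),
                           label = .data$label),
                       angle = 90, hjust = 1, size = label_size) +
    labs(x = NULL, y = "merge height") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
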