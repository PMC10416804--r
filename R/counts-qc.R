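#' Drop genes with zero detected reads across all cells
#'
#' Removes every gene whose row sum is zero; cells are untouched. The first
#' filtering step applied to raw plate-based single-cell counts.
#'
#' @param counts Integer genes x cells matrix with rownames (gene ids) and
#'   colnames (cell ids).
#' @return The filtered count matrix.
#' @export
drop_zero_genes <- function(counts) {
  check_counts(counts)
  counts[rowSums(counts) > 0, , drop = FALSE]
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must be a matrix with gene rownames and cell colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene ids.")
  if (anyDuplicated(colnames(counts))) abort("duplicate cell ids.")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must contain non-negative integers.")
  }
  invisible(counts)
}

#' Housekeeping-gene quality filter
#'
#' Housekeeping genes are expected in every viable cell, so low detection
#' across a housekeeping panel marks a failed library rather than biology.
#' For each cell the filter counts panel genes with raw count strictly below
#' `min_count` and excludes the cell iff more than `max_low_fraction` of the
#' panel is low (both comparisons strict: a count of exactly `min_count`
#' passes, a low fraction of exactly `max_low_fraction` is retained).
#'
#' @param counts Raw integer genes x cells matrix.
#' @param panel Character vector of housekeeping gene ids; every panel gene
#'   must be present in `counts` (missing genes are an error, so the
#'   denominator is always the full panel).
#' @param min_count Raw-count floor; counts below it are "low" (default 10).
#' @param max_low_fraction Exclusion threshold on the low fraction
#'   (default 0.30).
#' @return A tibble of class `qc_report`: per cell `n_housekeeping_low`,
#'   `fraction_low`, `excluded` and `reason`.
#' @export
housekeeping_qc <- function(counts, panel, min_count = 10,
                            max_low_fraction = 0.30) {
  check_counts(counts)
  if (!length(panel)) abort("housekeeping `panel` must not be empty.")
  missing <- setdiff(panel, rownames(counts))
  if (length(missing)) {
    abort(sprintf("panel gene(s) absent from the count matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  sub <- counts[panel, , drop = FALSE]
  n_low <- colSums(sub < min_count)
  frac <- n_low / length(panel)
  excluded <- n_low > max_low_fraction * length(panel)
  out <- tibble(
    cell_id = colnames(counts),
    n_housekeeping_low = as.integer(n_low),
    fraction_low = as.numeric(frac),
    excluded = as.logical(excluded),
    reason = ifelse(excluded,
                    sprintf("%d/%d housekeeping genes below %d raw counts",
                            as.integer(n_low), length(panel), as.integer(min_count)),
                    NA_character_)
  )
  class(out) <- c("qc_report", class(out))
  attr(out, "panel_size") <- length(panel)
  attr(out, "min_count") <- min_count
  attr(out, "max_low_fraction") <- max_low_fraction
  out
}

#' Median-of-ratios size factors
#'
#' Per-cell scaling factor: the median, across genes expressed in every
#' cell, of the ratio between the cell's count and the gene's geometric
#' mean. When no gene is expressed in all cells the factors fall back to
#' relative library sizes, with a warning.
#'
#' @param counts Raw integer genes x cells matrix (>= 2 cells).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  check_counts(counts)
  if (ncol(counts) < 2L) abort("size factors need at least 2 cells.")
  expressed_all <- rowSums(counts > 0) == ncol(counts)
  if (!any(expressed_all)) {
    warn("no gene is expressed in every cell; falling back to library-size factors.")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  sub <- counts[expressed_all, , drop = FALSE]
  log_geo <- rowMeans(log(sub))
  apply(sub, 2, function(cnt) exp(median(log(cnt) - log_geo)))
}

#' Normalize raw counts for clustering
#'
#' A documented stand-in for a variance-stabilizing transformation: counts
#' are divided by median-of-ratios size factors and shifted-log transformed,
#' `log2(count / sf + 1)`. Used only to put cells on a comparable scale
#' before hierarchical clustering; it is not a replacement for model-based
#' VST in differential-expression work.
#'
#' @param counts Raw integer genes x cells matrix.
#' @return Numeric matrix of the same shape, log2 scale.
#' @export
normalize_for_clustering <- function(counts) {
  sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' @rdname housekeeping_qc
#' @param x A `qc_report`.
#' @param ... Unused.
#' @export
glance.qc_report <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_excluded = sum(x$excluded),
    n_retained = sum(!x$excluded),
    panel_size = attr(x, "panel_size"),
    min_count = attr(x, "min_count"),
    max_low_fraction = attr(x, "max_low_fraction")
  )
}
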