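#' Ward/Euclidean hierarchical clustering of cells
#'
#' Agglomerative clustering of cells by expression profile using the Ward
#' variance-minimization criterion on Euclidean distances, with the height
#' convention under which two singletons merge at their Euclidean distance
#' (the convention shared by `hclust(method = "ward.D2")` and scipy's
#' `linkage(method = "ward")`; dendrogram heights differ between Ward
#' variants by constant factors, so the convention is fixed and documented).
#'
#' @param x Normalized genes x cells matrix (cells are clustered), e.g. from
#'   [normalize_for_clustering()]; no missing values.
#' @return Object of class `ward_clustering`: the underlying `hclust`, leaf
#'   labels, and a tidy merge table (`left`, `right`, `height`, `size`).
#' @export
ward_cluster <- function(x) {
  if (!is.matrix(x)) abort("`x` must be a matrix (genes x cells).")
  if (ncol(x) < 2L) abort("clustering needs at least 2 cells.")
  if (is.null(colnames(x))) abort("`x` must carry cell ids as colnames.")
  if (anyDuplicated(colnames(x))) abort("duplicate cell ids.")
  if (anyNA(x)) abort("`x` must not contain missing values.")
  hc <- hclust(dist(t(x), method = "euclidean"), method = "ward.D2")
  merges <- tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height,
    size = cluster_sizes(hc$merge)
  )
  structure(list(hclust = hc, labels = hc$labels, merges = merges),
            class = "ward_clustering")
}

cluster_sizes <- function(merge) {
  n <- nrow(merge)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    l <- merge[i, 1]; r <- merge[i, 2]
    sizes[i] <- (if (l < 0) 1L else sizes[l]) + (if (r < 0) 1L else sizes[r])
  }
  sizes
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d cells, %d merges, max height %.3g\n",
              length(x$labels), nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' @rdname ward_cluster
#' @param x,object A `ward_clustering`.
#' @param ... Unused.
#' @export
tidy.ward_clustering <- function(x, ...) x$merges

#' @rdname ward_cluster
#' @export
glance.ward_clustering <- function(x, ...) {
  tibble(
    n_cells = length(x$labels),
    n_merges = nrow(x$merges),
    max_height = max(x$merges$height),
    median_height = median(x$merges$height),
    heights_monotone = !is.unsorted(x$merges$height)
  )
}

#' Cut a clustering into k groups
#'
#' @param clustering A [ward_cluster()] result.
#' @param k Number of groups.
#' @return Tibble with `cell_id` and `cluster`.
#' @export
cut_clusters <- function(clustering, k) {
  stopifnot(inherits(clustering, "ward_clustering"))
  ct <- cutree(clustering$hclust, k = k)
  tibble(cell_id = names(ct), cluster = unname(ct))
}

#' Flag outlier cells from a dendrogram
#'
#' Default rule: a cell that is still a singleton when it joins the tree,
#' at a height exceeding `factor` times the median merge height, is flagged.
#' This is a surrogate for eyeballing a dendrogram for cells that only merge
#' at the very top; it is a screening rule, not a significance test.
#'
#' @param clustering A [ward_cluster()] result.
#' @param factor Multiple of the median merge height (default 3); `Inf`
#'   flags nothing.
#' @return Character vector of flagged cell ids (possibly empty).
#' @export
flag_outliers <- function(clustering, factor = 3) {
  stopifnot(inherits(clustering, "ward_clustering"))
  hc <- clustering$hclust
  med <- median(hc$height)
  singleton_rows <- which(hc$merge[, 1] < 0 | hc$merge[, 2] < 0)
  flagged <- character(0)
  for (i in singleton_rows) {
    if (hc$height[i] > factor * med) {
      for (side in 1:2) {
        leaf <- hc$merge[i, side]
        if (leaf < 0) flagged <- c(flagged, hc$labels[-leaf])
      }
    }
  }
  sort(unique(flagged))
}

#' Export a dendrogram
#'
#' `dendrogram_newick()` writes the merge tree in Newick format (via ape);
#' `dendrogram_json()` returns/writes a nested-list JSON representation with
#' merge heights.
#'
#' @param clustering A [ward_cluster()] result.
#' @param path Optional file path; when `NULL` the string is returned.
#' @return The Newick/JSON string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "ward_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  s <- ape::write.tree(phy)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname dendrogram_newick
#' @export
dendrogram_json <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "ward_clustering"))
  hc <- clustering$hclust
  node <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    list(height = hc$height[i],
         children = list(node(hc$merge[i, 1]), node(hc$merge[i, 2])))
  }
  tree <- node(nrow(hc$merge))
  s <- jsonlite::toJSON(tree, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
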