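#' Construct a cluster map
#'
#' A cluster map assigns probes to disjoint, non-empty clusters; it is the
#' unit of model input. Cluster sizes range from singletons upward.
#'
#' @param clusters Named list: cluster id -> character vector of probe ids.
#' @return An object of class `cluster_map`.
#' @export
cluster_map <- function(clusters) {
  if (!is.list(clusters) || is.null(names(clusters)) ||
      any(!nzchar(names(clusters)))) {
    abort("`clusters` must be a named list of probe-id vectors.")
  }
  sizes <- lengths(clusters)
  if (any(sizes == 0)) abort("clusters must be non-empty.")
  all_probes <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_probes)) {
    abort(paste0("clusters must be disjoint; probe '",
                 all_probes[duplicated(all_probes)][1], "' appears twice."))
  }
  structure(clusters, class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("<cluster_map> %d clusters over %d probes (sizes %d..%d)\n",
              length(x), sum(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.cluster_map <- function(x) length(unclass(x))

#' Summarise a cluster map as a tibble
#' @param x A [cluster_map()].
#' @param ... Unused.
#' @return Tibble with `cluster_id`, `size`.
#' @export
tidy.cluster_map <- function(x, ...) {
  tibble(cluster_id = names(x), size = unname(lengths(x)))
}

#' Cluster CpG probes by methylation pattern
#'
#' Probes are clustered across the whole cohort by profile similarity:
#' hierarchical agglomerative clustering with distance 1 - Pearson correlation
#' between probe profiles and average linkage, cut so that probes merged at a
#' correlation above `cor_threshold` share a cluster. Singletons are allowed.
#'
#' @param matrix An M-scale [methylation_matrix()] with >= 2 samples.
#' @param cor_threshold Correlation cut height (default 0.7); the dendrogram
#'   is cut at distance `1 - cor_threshold`.
#' @param method Agglomeration method passed to [stats::hclust()].
#' @return A [cluster_map()] whose ids are `"cl0001"`, ... in dendrogram
#'   order.
#' @export
cluster_cpgs <- function(matrix, cor_threshold = 0.7, method = "average") {
  if (value_scale(matrix) != "m") abort("clustering expects an M-scale matrix.")
  if (ncol(matrix) < 2) abort("need >= 2 samples to correlate probe profiles.")
  v <- apply(matrix, 1, var)
  if (any(!is.finite(v)) || any(v == 0)) {
    abort(paste0("zero-variance probe(s) must be filtered before clustering: '",
                 rownames(matrix)[which(!is.finite(v) | v == 0)][1], "'"))
  }
  cmat <- cor(t(unclass(matrix)), use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - cmat)
  hc <- stats::hclust(d, method = method)
  ass <- stats::cutree(hc, h = 1 - cor_threshold)
  ids <- split(rownames(matrix), ass)
  names(ids) <- sprintf("cl%04d", seq_along(ids))
  cluster_map(ids)
}

#' Select the top clusters for model training
#'
#' Clusters are ranked by size (descending), ties broken by mean
#' within-cluster probe variance (descending), then lexicographic cluster id;
#' the top `k` are retained. Larger clusters average away more measurement
#' noise, which is the purpose of training on clusters.
#'
#' @param cmap A [cluster_map()].
#' @param matrix The M-scale matrix the clusters refer to.
#' @param k Number of clusters to keep (default 10000).
#' @return A [cluster_map()] with `k` entries, in rank order.
#' @export
select_top_clusters <- function(cmap, matrix, k = 10000) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) abort("`k` must be a positive integer.")
  if (k > length(cmap)) abort("`k` exceeds the number of clusters.")
  sizes <- lengths(cmap)
  mvar <- vapply(unclass(cmap), function(p) {
    mean(apply(unclass(matrix)[p, , drop = FALSE], 1, var, na.rm = TRUE))
  }, numeric(1))
  ord <- order(-sizes, -mvar, names(cmap))
  cluster_map(unclass(cmap)[ord[seq_len(k)]])
}

#' Average probe M values within clusters
#'
#' Row `c` of the result is the arithmetic mean of the member probes' M
#' values, per sample, ignoring missing entries; a cluster whose members are
#' all missing in a sample yields a missing value.
#'
#' @param matrix An M-scale [methylation_matrix()] containing every probe the
#'   map references.
#' @param cmap A [cluster_map()].
#' @return A `cluster_matrix`: clusters x samples matrix (class also
#'   `methylation_matrix`, M scale).
#' @export
average_clusters <- function(matrix, cmap) {
  if (value_scale(matrix) != "m") abort("cluster averaging operates on M values.")
  probes <- unlist(unclass(cmap), use.names = FALSE)
  absent <- setdiff(probes, rownames(matrix))
  if (length(absent)) {
    abort(paste0("cluster map references probe(s) absent from the matrix: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  v <- unclass(matrix)
  out <- matrix(NA_real_, length(cmap), ncol(v),
                dimnames = list(names(cmap), colnames(v)))
  for (i in seq_along(cmap)) {
    rows <- v[cmap[[i]], , drop = FALSE]
    out[i, ] <- colMeans(rows, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  structure(out, scale = "m",
            class = c("cluster_matrix", "methylation_matrix", "matrix", "array"))
}
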