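#' Hierarchical clustering of fold-change profiles
#'
#' Clusters probes by their log2 fold-change profile across the four disease
#' stages (the heatmap view of the union and intersection collections).
#' Rows are sorted lexicographically by probe id before the distance
#' computation, which fixes the agglomeration order under distance ties and
#' makes the tree invariant to the input row order. Only rows are clustered:
#' the four stage columns form an ordered progression and are left in place.
#'
#' @param log2fc numeric matrix of log2 fold changes with probe ids as row
#'   names (at least 2 rows, all values finite).
#' @param metric distance metric passed to [stats::dist()] (default
#'   euclidean).
#' @param linkage agglomeration method passed to [stats::hclust()] (default
#'   average).
#' @return An object of class `cluster_result`: the `hclust` tree, the leaf
#'   order (probe ids, left to right), and the metric/linkage used.
#' @export
cluster_profiles <- function(log2fc, metric = "euclidean",
                             linkage = "average") {
  x <- as.matrix(log2fc)
  if (nrow(x) < 2L)
    stop("cluster_profiles: need at least 2 profiles", call. = FALSE)
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("row%04d", seq_len(nrow(x)))
  bad <- rownames(x)[!apply(is.finite(x), 1L, all)]
  if (length(bad))
    stop("cluster_profiles: non-finite values in profile(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 metric = metric, linkage = linkage, n = nrow(x)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: %d profiles, %s distance, %s linkage\n",
              x$n, x$metric, x$linkage))
  cat("  leaf order:", paste(utils::head(x$leaf_order, 8L), collapse = " "),
      if (x$n > 8L) "..." else "", "\n")
  invisible(x)
}

#' Export a clustering tree in Newick format
#'
#' @param cluster a [cluster_profiles()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(cluster, path) {
  stopifnot(inherits(cluster, "cluster_result"))
  ape::write.tree(ape::as.phylo(cluster$hclust), file = path)
  invisible(path)
}

#' Export the leaf order of a clustering tree
#'
#' @param cluster a [cluster_profiles()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_leaf_order <- function(cluster, path) {
  stopifnot(inherits(cluster, "cluster_result"))
  utils::write.table(
    data.frame(position = seq_along(cluster$leaf_order),
               probe_id = cluster$leaf_order),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
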