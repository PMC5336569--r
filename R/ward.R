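#' Ward hierarchical clustering of condition score vectors
#'
#' Agglomerative clustering of labeled points (per-condition mean OPLS-DA
#' scores) using Ward's minimum-variance criterion in its Lance-Williams
#' form on squared Euclidean distances ([stats::hclust()] method
#' `"ward.D"` on squared distances; merge heights are therefore twice the
#' within-cluster sum-of-squares increase). Rows are ordered
#' lexicographically by label before clustering so ties break
#' deterministically.
#'
#' @param points Numeric matrix of per-label vectors (rownames are labels
#'   unless `labels` is given).
#' @param labels Optional character labels, one per row, unique.
#' @return A `ward_dendrogram`: merge matrix, merge heights, leaf labels
#'   and the underlying `hclust` object.
#' @export
hca_ward <- function(points, labels = rownames(points)) {
  points <- as.matrix(points)
  if (is.null(labels)) abort("labels are required")
  if (nrow(points) < 2) abort("need at least 2 labeled points")
  if (anyDuplicated(labels)) abort("duplicate labels")
  ord <- order(labels)
  points <- points[ord, , drop = FALSE]
  labels <- labels[ord]
  d2 <- stats::dist(points)^2
  hc <- stats::hclust(d2, method = "ward.D")
  hc$labels <- labels
  structure(list(merge = hc$merge, height = hc$height, labels = labels,
                 hclust = hc),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("<ward_dendrogram> ", length(x$labels), " leaves, max height ",
      sprintf("%.3g", max(x$height)), "\n", sep = "")
  invisible(x)
}

#' Leaf membership of the top-level partition
#'
#' Labels on each side of the final (root) merge.
#'
#' @param dend A `ward_dendrogram`.
#' @return List of two character vectors.
#' @export
top_partition <- function(dend) {
  k2 <- stats::cutree(dend$hclust, k = 2)
  split(names(k2), unname(k2))
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are differences of merge heights, so root-to-leaf path
#' lengths reproduce the merge heights.
#'
#' @param dend A `ward_dendrogram`.
#' @param file Optional path; when given, the tree is written there.
#' @return The Newick string, invisibly when writing to a file.
#' @export
as_newick <- function(dend, file = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
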