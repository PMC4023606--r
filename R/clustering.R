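#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of samples from an RPKM matrix. The default
#' distance is `1 - Pearson correlation` of `log2(rpkm + 1)` profiles with
#' average linkage. Samples are ordered lexicographically before
#' clustering so the result (including leaf order at ties) is
#' deterministic.
#'
#' @param expr RPKM matrix, genes in rows, samples in columns.
#' @param distance `"correlation"` (1 - Pearson r) or `"euclidean"`.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param log_transform Cluster on `log2(rpkm + 1)` (default) or raw
#'   values.
#' @return An [stats::hclust] tree over the samples.
#' @seealso [as_newick()] to serialise the tree.
#' @export
cluster_samples <- function(expr, distance = c("correlation", "euclidean"),
                            linkage = "average", log_transform = TRUE) {
  distance <- match.arg(distance)
  if (ncol(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(expr))) stop("expression must be finite", call. = FALSE)
  expr <- expr[, sort(colnames(expr)), drop = FALSE]
  m <- if (log_transform) log2(expr + 1) else expr
  if (distance == "correlation") {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("zero-variance sample(s) under correlation distance: %s",
                   paste(colnames(m)[sds == 0], collapse = ", ")),
           call. = FALSE)
    }
    d <- as.dist(1 - cor(m))
  } else {
    d <- stats::dist(t(m))
  }
  hclust(d, method = linkage)
}

#' Serialise an hclust tree as a Newick string
#'
#' @param hc An [stats::hclust] object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
as_newick <- function(hc, file = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
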