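#' Pairwise mutual-Q matrix over an ensemble
#'
#' Computes \code{\link{qw}} between every pair of models. The matrix is the
#' input to \code{\link{clusterModels}}: how the independent prediction runs
#' relate to each other tells whether the sampling has converged on one fold
#' or is scattered over several basins.
#'
#' @param models list of \linkS4class{CoarseModel}s on a shared roster, or a
#'   \linkS4class{CoarseEnsemble}.
#' @param minSeqSep passed to \code{\link{qw}}.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
mutualQMatrix <- function(models, minSeqSep = 3L) {
  if (is(models, "CoarseEnsemble")) models <- frames(models)
  m <- length(models)
  if (m < 2L) stop("precondition error: need >= 2 models")
  q <- diag(1, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      q[i, j] <- q[j, i] <- qw(models[[i]], models[[j]], minSeqSep = minSeqSep)
    }
  }
  q
}

#' Cluster an ensemble by mutual Q
#'
#' Agglomerative clustering on the dissimilarity d = 1 - Q, cut at
#' d = 1 - \code{qThreshold}: frames whose mutual Q exceeds the threshold end
#' up together. Average linkage keeps the clustergram deterministic for a
#' fixed input. Cluster ids are renumbered in order of first appearance so
#' the labelling is reproducible.
#'
#' @param q symmetric mutual-Q matrix (unit diagonal), e.g. from
#'   \code{\link{mutualQMatrix}}.
#' @param linkage agglomeration method for \code{stats::hclust}.
#' @param qThreshold Q level at which the tree is cut (default 0.75, between
#'   the ~0.9 intra-cluster similarity of well-converged runs and the ~0.5
#'   inter-cluster value seen for scattered ones).
#' @param dominantFraction passed to the pattern rule (see
#'   \code{\link{classifyPattern}}).
#' @return A \linkS4class{ClusterResult}.
#' @export
clusterModels <- function(q, linkage = "average", qThreshold = 0.75,
                          dominantFraction = 0.5) {
  q <- as.matrix(q)
  if (nrow(q) != ncol(q) || max(abs(q - t(q))) > 1e-8)
    stop("consistency error: Q matrix must be square and symmetric")
  q <- (q + t(q)) / 2
  diag(q) <- 1
  hc <- stats::hclust(stats::as.dist(1 - q), method = linkage)
  raw <- stats::cutree(hc, h = 1 - qThreshold)
  labels <- as.integer(match(raw, unique(raw)))  # renumber by first appearance
  res <- new("ClusterResult", qMatrix = q, labels = labels, linkage = linkage,
             threshold = qThreshold, pattern = "dispersed", dendro = hc)
  res@pattern <- classifyPattern(res, dominantFraction)$pattern
  validObject(res)
  res
}

#' Classify the clustering pattern of a prediction ensemble
#'
#' Encodes the qualitative read-out of a clustergram:
#' \describe{
#'   \item{single_dominant}{one cluster holds at least
#'     \code{dominantFraction} of the frames — the runs converged; such
#'     targets are usually solvable, and more trials are worthwhile.}
#'   \item{multi_cluster}{no dominant cluster, but at least two clusters of
#'     two or more frames that remain mutually similar (mean between-cluster
#'     Q above \code{interSimilarityFloor}) — several distinct but related
#'     folds were sampled; one of the small clusters may be native, so more
#'     trials are advised.}
#'   \item{dispersed}{neither of the above: the frames scatter into
#'     singletons, or the clusters are mutually dissimilar (between-cluster
#'     Q at or below the floor, the regime seen for failed targets) — the
#'     target itself may be too hard for the protocol.}
#' }
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param dominantFraction fraction of frames the largest cluster must reach
#'   to count as dominant (default 0.5).
#' @param interSimilarityFloor mean between-cluster Q at or below which a
#'   multi-cluster layout is called dispersed instead (default 0.5).
#' @return list with \code{pattern} and an \code{advisory} string.
#' @export
classifyPattern <- function(result, dominantFraction = 0.5,
                            interSimilarityFloor = 0.5) {
  stopifnot(is(result, "ClusterResult"))
  sizes <- clusterSizes(result)
  lab <- clusterLabels(result)
  n <- length(lab)
  between <- outer(lab, lab, "!=") & upper.tri(result@qMatrix)
  mean_between_q <- if (any(between)) mean(result@qMatrix[between]) else 1
  pattern <- if (max(sizes) >= dominantFraction * n) {
    "single_dominant"
  } else if (sum(sizes >= 2L) >= 2L && mean_between_q > interSimilarityFloor) {
    "multi_cluster"
  } else {
    "dispersed"
  }
  advisory <- switch(pattern,
    single_dominant = "runs converged on one fold; more trials should be performed",
    multi_cluster = "several distinct folds sampled; more trials should be performed",
    dispersed = "predictions do not cluster; the target itself may be too hard")
  list(pattern = pattern, advisory = advisory)
}

#' Export a clustergram (reordered Q matrix + heatmap image)
#'
#' Writes the mutual-Q matrix, rows and columns permuted into dendrogram
#' order, as TSV, and optionally renders a heatmap with the dendrogram
#' attached. The row order comes from the stored \code{hclust} object, so
#' re-exporting the same result is byte-identical.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param path output TSV path.
#' @param imagePath optional PNG path for the heatmap + dendrogram.
#' @return \code{path}, invisibly.
#' @export
exportClustergram <- function(result, path, imagePath = NULL) {
  stopifnot(is(result, "ClusterResult"))
  ord <- result@dendro$order
  q <- result@qMatrix[ord, ord, drop = FALSE]
  rownames(q) <- colnames(q) <- sprintf("frame_%d", ord)
  ok <- tryCatch({
    utils::write.table(format(q, digits = 10, trim = TRUE), file = path,
                       sep = "\t", quote = FALSE, col.names = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing clustergram TSV: ",
                        conditionMessage(ok))
  if (!is.null(imagePath)) {
    m <- result@qMatrix
    rownames(m) <- colnames(m) <- sprintf("frame_%d", seq_len(nrow(m)))
    pheatmap::pheatmap(m, cluster_rows = result@dendro,
                       cluster_cols = result@dendro,
                       filename = imagePath, silent = TRUE)
  }
  invisible(path)
}
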