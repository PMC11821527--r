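#' Hierarchical clustering of screen conditions
#'
#' Clusters the condition columns of a fold-change matrix: every molecule row
#' is z-scored (mean 0, s.d. 1) first, condition-to-condition Euclidean
#' distances are computed on the z-scored profiles, and conditions are merged
#' agglomeratively (average linkage by default).  Constant rows (zero
#' variance, for which the z-score is undefined) are dropped with a warning.
#'
#' @param fc_matrix molecules x conditions matrix, e.g. from
#'   \code{\link{conditionMeanFC}}; >= 2 condition columns of finite values.
#' @param n_clusters number of flat clusters to cut the tree into.
#' @param linkage linkage method passed to \code{\link[stats]{hclust}}.
#' @return a \linkS4class{ClusterResult}.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(1.1, 2, 3.2), c = c(-1, -2, -3))
#' rownames(m) <- paste0("mol", 1:3)
#' clusterStrains(m, n_clusters = 2)
#' @export
clusterStrains <- function(fc_matrix, n_clusters = 4L, linkage = "average") {
  .check(is.matrix(fc_matrix) && ncol(fc_matrix) >= 2,
         "need a matrix with >= 2 condition columns")
  .check(all(is.finite(fc_matrix)), "fc_matrix must be finite")
  sds <- apply(fc_matrix, 1, sd)
  nDropped <- sum(sds == 0)
  if (nDropped > 0) {
    warning(sprintf("dropped %d constant molecule row(s) before z-scoring",
                    nDropped))
    fc_matrix <- fc_matrix[sds > 0, , drop = FALSE]
  }
  .check(nrow(fc_matrix) >= 1, "no non-constant rows left to cluster on")
  z <- t(scale(t(fc_matrix)))            # z-score each molecule row
  hc <- hclust(dist(t(z), method = "euclidean"), method = linkage)
  labels <- cutree(hc, k = min(n_clusters, ncol(fc_matrix)))
  new("ClusterResult", hclust = hc, labels = as.integer(labels),
      nClusters = as.integer(n_clusters), nDropped = as.integer(nDropped))
}

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@labels), "conditions in",
      object@nClusters, "clusters\n")
  lab <- object@labels
  names(lab) <- object@hclust$labels
  print(lab)
  if (object@nDropped > 0)
    cat("(", object@nDropped, "constant rows dropped )\n")
  invisible(NULL)
})

#' @describeIn clusterStrains flat cluster labels, named by condition
#' @param x a ClusterResult
#' @export
clusterLabels <- function(x) setNames(x@labels, x@hclust$labels)

#' @describeIn clusterStrains the underlying hclust merge tree
#' @export
clusterTree <- function(x) x@hclust
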