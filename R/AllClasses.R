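#' ScreenExperiment: annotated molecules-by-samples abundance matrix
#'
#' A \linkS4class{SummarizedExperiment} subclass holding log2 abundances for a
#' multiomic screen.  Rows are molecules (proteins, lipids, metabolites) and
#' columns are samples, one per (strain, timepoint, replicate) triple.
#'
#' Required \code{rowData} columns:
#' \describe{
#'   \item{layer}{\code{"protein"}, \code{"lipid"} or \code{"metabolite"}.}
#'   \item{is_mito}{logical mitochondrial flag (proteins; \code{NA} elsewhere).}
#'   \item{lipid_class}{lipid class label such as \code{"TAG"} or \code{"CL"}
#'     (\code{NA} for non-lipids).}
#'   \item{acyl_composition}{\code{"carbons:double_bonds"} string for lipids.}
#' }
#' Required \code{colData} columns: \code{strain}, \code{group} (one of WT,
#' WTV, G1, G2, G3, G4), \code{timepoint} (\code{"E"} early or \code{"L"}
#' late) and \code{replicate}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases ScreenExperiment-class
#' @exportClass ScreenExperiment
setClass("ScreenExperiment", contains = "SummarizedExperiment")

.validScreenExperiment <- function(object) {
  msg <- character()
  rd <- rowData(object)
  cd <- colData(object)
  needRow <- c("layer", "is_mito", "lipid_class")
  needCol <- c("strain", "group", "timepoint", "replicate")
  missRow <- setdiff(needRow, colnames(rd))
  missCol <- setdiff(needCol, colnames(cd))
  if (length(missRow))
    msg <- c(msg, paste("missing rowData columns:",
                        paste(missRow, collapse = ", ")))
  if (length(missCol))
    msg <- c(msg, paste("missing colData columns:",
                        paste(missCol, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "molecule ids (rownames) must be present and unique")
  if (!length(missCol)) {
    triple <- paste(cd$strain, cd$timepoint, cd$replicate, sep = "_")
    if (anyDuplicated(triple))
      msg <- c(msg, "duplicated (strain, timepoint, replicate) triples")
    bad <- setdiff(unique(as.character(cd$timepoint)), c("E", "L"))
    if (length(bad))
      msg <- c(msg, paste("invalid timepoint labels:",
                          paste(bad, collapse = ", ")))
  }
  if (!length(missRow)) {
    bad <- setdiff(unique(as.character(rd$layer)),
                   c("protein", "lipid", "metabolite"))
    if (length(bad))
      msg <- c(msg, paste("invalid layer labels:", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("ScreenExperiment", .validScreenExperiment)

#' CorrelationRanking: average-rank Spearman score against a query set
#'
#' Result of \code{\link{averageRankScore}}.  For every query molecule the
#' Spearman correlation against all other molecules' fold-change profiles is
#' computed, molecules are ranked (rank 1 = most positively correlated) and
#' ranks are averaged across queries.
#'
#' @slot ranking data.frame with columns \code{molecule_id}, \code{mean_rho},
#'   \code{average_rank}, \code{position}, ordered by ascending average rank.
#' @slot queryIds character, the query molecule ids.
#' @slot nConditions integer, number of condition columns used per profile.
#' @slot undefinedPairs integer, count of (query, molecule) pairs with
#'   undefined correlation (constant profile) excluded from averaging.
#' @slot dropped character, molecules undefined against every query.
#' @exportClass CorrelationRanking
setClass("CorrelationRanking",
         representation(ranking = "data.frame",
                        queryIds = "character",
                        nConditions = "integer",
                        undefinedPairs = "integer",
                        dropped = "character"))

#' EnrichmentResult: Fisher exact test on a 2x2 classification table
#'
#' @slot contingency 2x2 integer matrix; rows = mitochondrial yes/no, columns
#'   = changed (significant in the requested direction) yes/no.
#' @slot oddsRatio ad/bc cross-product ratio (Inf when bc = 0).
#' @slot pValue two-sided Fisher exact p-value.
#' @slot direction \code{"up"} or \code{"down"}.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
         representation(contingency = "matrix",
                        oddsRatio = "numeric",
                        pValue = "numeric",
                        direction = "character"))

#' ClusterResult: agglomerative clustering of screen conditions
#'
#' @slot hclust the \code{\link[stats]{hclust}} merge tree (average linkage on
#'   Euclidean distances between z-scored fold-change profiles).
#' @slot labels named integer vector of flat cluster labels at the requested
#'   cut.
#' @slot nClusters requested number of flat clusters.
#' @slot nDropped number of constant (zero-variance) molecule rows dropped
#'   before z-scoring.
#' @exportClass ClusterResult
setClass("ClusterResult",
         representation(hclust = "ANY",
                        labels = "integer",
                        nClusters = "integer",
                        nDropped = "integer"))
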