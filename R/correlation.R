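#' Spearman rank correlation coefficient
#'
#' Pearson correlation of the average ranks of the two vectors (ties receive
#' the mean of their rank range).  Constant vectors have undefined rank
#' correlation and return \code{NA}; \code{\link{averageRankScore}} excludes
#' such pairs from averaging with a count.
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @return correlation in [-1, 1], or \code{NA} if either vector is constant.
#' @examples
#' spearmanRho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
spearmanRho <- function(x, y) {
  .check(length(x) == length(y), "x and y must have equal length")
  .check(length(x) >= 3, "need at least 3 paired observations")
  .check(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Average-rank Spearman correlation score against a query molecule set
#'
#' The correlation score used to find proteins co-varying with depleted TAG
#' species: for every query molecule \eqn{q}, the Spearman correlation between
#' \eqn{q}'s condition-wise fold-change profile and every other molecule's
#' profile is computed; molecules are rank-ordered by the coefficient (rank 1
#' = most positively correlated, ties averaged); and each molecule's score is
#' the average of its ranks across all queries.  The output is ordered by
#' ascending average rank, ties broken by descending mean coefficient and
#' then lexically by molecule id.
#'
#' Self-pairs \eqn{\rho(q, q)} are excluded from \eqn{q}'s own ranking (they
#' are always 1 and uninformative); query molecules still appear in the other
#' queries' rankings.  Pairs with undefined correlation (constant profile)
#' are excluded from that query's ranking; molecules undefined against every
#' query are dropped with a warning.
#'
#' @param fc_matrix molecules x conditions matrix of mean log2 fold changes
#'   (see \code{\link{conditionMeanFC}}); >= 4 condition columns.
#' @param query_ids character vector of query molecule ids (subset of
#'   rownames); >= 2 recommended.
#' @param most_positive if \code{TRUE} (default) rank 1 is the most
#'   positively correlated molecule; set \code{FALSE} to rank most-negative
#'   first for exploratory use.
#' @return a \linkS4class{CorrelationRanking}.
#' @examples
#' m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("m", 1:8), NULL))
#' averageRankScore(m, query_ids = c("m1", "m2"))
#' @export
averageRankScore <- function(fc_matrix, query_ids, most_positive = TRUE) {
  .check(is.matrix(fc_matrix) && !is.null(rownames(fc_matrix)),
         "fc_matrix must be a matrix with molecule-id rownames")
  absent <- setdiff(query_ids, rownames(fc_matrix))
  if (length(absent))
    stop("input error: query molecule(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  .check(ncol(fc_matrix) >= 4,
         "statistics error: fewer than 4 usable conditions")
  ids <- rownames(fc_matrix)
  M <- nrow(fc_matrix)
  rankMat <- matrix(NA_real_, M, length(query_ids),
                    dimnames = list(ids, query_ids))
  rhoMat <- matrix(NA_real_, M, length(query_ids),
                   dimnames = list(ids, query_ids))
  ## rank-transform profiles once; Spearman rho = Pearson on row ranks
  rowSd <- apply(fc_matrix, 1, sd)
  ranked <- t(apply(fc_matrix, 1, rank))
  for (q in query_ids) {
    if (rowSd[q] == 0) next                      # query undefined vs everyone
    others <- setdiff(ids, q)
    rho <- suppressWarnings(
      as.vector(cor(t(ranked[others, , drop = FALSE]), ranked[q, ],
                    method = "pearson")))
    rho[rowSd[others] == 0] <- NA_real_
    rhoMat[others, q] <- rho
    keyed <- if (most_positive) -rho else rho
    rk <- rank(keyed, ties.method = "average", na.last = "keep")
    rankMat[others, q] <- rk
  }
  definedN <- rowSums(!is.na(rankMat))
  undefinedPairs <- sum(is.na(rankMat)) - length(query_ids)  # minus self-pairs
  dropped <- ids[definedN == 0]
  if (length(dropped))
    warning(sprintf("%d molecule(s) undefined against every query dropped",
                    length(dropped)))
  keep <- definedN > 0
  avgRank <- rowMeans(rankMat, na.rm = TRUE)[keep]
  meanRho <- rowMeans(rhoMat, na.rm = TRUE)[keep]
  ## tie-break on a rounded mean rho so the order is stable to 1e-10
  ord <- order(avgRank, round(-meanRho, 10), ids[keep])
  ranking <- data.frame(molecule_id = ids[keep][ord],
                        mean_rho = meanRho[ord],
                        average_rank = avgRank[ord],
                        position = seq_along(ord),
                        row.names = NULL)
  new("CorrelationRanking", ranking = ranking,
      queryIds = as.character(query_ids),
      nConditions = ncol(fc_matrix),
      undefinedPairs = as.integer(max(0L, undefinedPairs)),
      dropped = dropped)
}

setMethod("show", "CorrelationRanking", function(object) {
  cat("CorrelationRanking:", nrow(object@ranking), "molecules vs",
      length(object@queryIds), "queries over", object@nConditions,
      "conditions\n")
  print(head(object@ranking, 5))
  if (nrow(object@ranking) > 5) cat("...\n")
  invisible(NULL)
})

#' Top of a correlation ranking
#'
#' @param ranking a \linkS4class{CorrelationRanking}.
#' @param n number of molecules to report (default 50, the screen's top-50
#'   report); must be positive and at most the number of ranked molecules.
#' @return data.frame of the first \code{n} rows of the ranking
#'   (molecule_id, mean_rho, average_rank, position).
#' @export
topCorrelates <- function(ranking, n = 50L) {
  .check(methods::is(ranking, "CorrelationRanking"),
         "'ranking' must be a CorrelationRanking")
  .check(n > 0, "input error: n must be positive")
  .check(n <= nrow(ranking@ranking),
         "input error: n (%d) exceeds ranked molecules (%d)",
         n, nrow(ranking@ranking))
  ranking@ranking[seq_len(n), , drop = FALSE]
}

#' @describeIn topCorrelates the full ranking table
#' @export
rankingTable <- function(ranking) ranking@ranking
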