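#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Computes the two-sided Fisher exact p-value by summing, over all tables
#' with the observed margins, the hypergeometric probabilities that do not
#' exceed the observed table's probability (with a small relative tolerance
#' for ties, as is conventional).
#'
#' @param tab 2x2 non-negative integer matrix.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}
#'   (enrichment in the top-left cell).
#' @return p-value in (0, 1].
#' @keywords internal
.fisherP <- function(tab, alternative = "two.sided") {
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # margin: row 1 total
  n <- sum(tab[2, ])   # row 2 total
  k <- sum(tab[, 1])   # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  if (alternative == "greater")
    return(sum(probs[support >= a]))
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Mitochondrial enrichment among significantly changed molecules
#'
#' Builds the 2x2 table (mitochondrial vs not) x (significant in the requested
#' direction vs not) and tests enrichment with the two-sided Fisher exact
#' test, as used to ask whether significantly decreased proteins are enriched
#' for mitochondrial proteins.
#'
#' @param records classified fold-change records (see
#'   \code{\link{classifySignificant}}) with columns \code{molecule_id},
#'   \code{significant}, \code{direction}.
#' @param mito_ids character vector of mitochondrial molecule ids; must be a
#'   subset of \code{records$molecule_id}.
#' @param direction \code{"up"} or \code{"down"}: the change direction tested.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"} for
#'   the one-sided enrichment p-value.
#' @return an \linkS4class{EnrichmentResult}.
#' @examples
#' rec <- data.frame(molecule_id = paste0("m", 1:8),
#'                   significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
#'                                   FALSE, FALSE),
#'                   direction = c("down", "down", "down", rep("none", 5)))
#' mitoEnrichment(rec, mito_ids = paste0("m", 1:4), direction = "down")
#' @export
mitoEnrichment <- function(records, mito_ids, direction = c("down", "up"),
                           alternative = c("two.sided", "greater")) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  .check(nrow(records) > 0, "input error: empty record list")
  .check(all(mito_ids %in% records$molecule_id),
         "mito_ids must be a subset of the record molecule ids")
  isMitoRec <- records$molecule_id %in% mito_ids
  changed <- records$significant & records$direction == direction
  tab <- matrix(c(sum(isMitoRec & changed),  sum(isMitoRec & !changed),
                  sum(!isMitoRec & changed), sum(!isMitoRec & !changed)),
                nrow = 2, byrow = TRUE,
                dimnames = list(mito = c("mito", "non_mito"),
                                changed = c("changed", "unchanged")))
  bc <- tab[1, 2] * tab[2, 1]
  orat <- if (bc == 0) Inf else (tab[1, 1] * tab[2, 2]) / bc
  new("EnrichmentResult", contingency = tab, oddsRatio = orat,
      pValue = .fisherP(tab, alternative), direction = direction)
}

setMethod("show", "EnrichmentResult", function(object) {
  cat("Fisher exact enrichment (direction:", object@direction, ")\n")
  print(object@contingency)
  cat(sprintf("odds ratio = %.4g, two-sided p = %.4g\n",
              object@oddsRatio, object@pValue))
  invisible(NULL)
})

#' @describeIn mitoEnrichment accessor for the p-value
#' @param x an EnrichmentResult
#' @export
enrichmentPValue <- function(x) x@pValue

#' @describeIn mitoEnrichment accessor for the odds ratio
#' @export
enrichmentOddsRatio <- function(x) x@oddsRatio

#' @describeIn mitoEnrichment accessor for the 2x2 contingency table
#' @export
enrichmentTable <- function(x) x@contingency
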