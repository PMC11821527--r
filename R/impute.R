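#' Impute missing values from a down-shifted normal distribution
#'
#' Per-column (sample-wise) imputation of missing log2 abundances, as used for
#' label-free proteomics: missing entries in a column are drawn from
#' \eqn{N(\mu - d\,\sigma,\ (w\,\sigma)^2)} where \eqn{\mu} and \eqn{\sigma}
#' are the observed mean and s.d. of that column, \eqn{w} = \code{width} and
#' \eqn{d} = \code{downshift}.  Defaults are width 0.3 and down shift 1.8,
#' applied separately for each column.  Observed values are untouched.
#'
#' @param x a \linkS4class{ScreenExperiment} or numeric matrix on the log2
#'   scale; each column must have at least 2 observed values.
#' @param width s.d. multiplier of the imputation distribution.
#' @param downshift mean down shift in units of the column s.d.
#' @param seed integer seed; imputation is deterministic given the seed.
#' @return object of the same class as \code{x} with no missing values.
#' @examples
#' m <- matrix(c(20, 21, NA, 19, NA, 22), 3, 2)
#' imputeMissing(m, seed = 1)
#' @export
imputeMissing <- function(x, width = 0.3, downshift = 1.8, seed = 1L) {
  isSE <- methods::is(x, "SummarizedExperiment")
  vals <- if (isSE) assay(x) else x
  .check(is.matrix(vals) && is.numeric(vals), "input must be numeric")
  nObs <- colSums(!is.na(vals))
  if (any(nObs < 2)) {
    bad <- colnames(vals)[nObs < 2]
    if (is.null(bad)) bad <- which(nObs < 2)
    stop("imputation error: column(s) with fewer than 2 observed values: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  withSeed(seed, {
    for (j in seq_len(ncol(vals))) {
      miss <- is.na(vals[, j])
      if (!any(miss)) next
      mu <- mean(vals[, j], na.rm = TRUE)
      sg <- sd(vals[, j], na.rm = TRUE)
      vals[miss, j] <- rnorm(sum(miss), mu - downshift * sg, width * sg)
    }
  })
  if (isSE) {
    assay(x) <- vals
    x
  } else {
    vals
  }
}
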