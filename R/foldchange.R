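#' Per-molecule log2 fold changes with Student's t-test
#'
#' Computes, for every molecule, the difference of replicate means on the log2
#' scale between a case and a reference sample set, with a two-sided
#' equal-variance (Student's) t-test on the replicate log2 values.
#'
#' Zero within-group variance on both sides with equal means yields
#' \code{log2_fc = 0, p = 1}; with unequal means the p-value is reported as
#' the smallest positive representable double and the record is flagged
#' \code{degenerate}.
#'
#' @param x a \linkS4class{ScreenExperiment} or numeric matrix (molecules x
#'   samples) with no missing values (impute first).
#' @param case,ref logical or integer sample selectors (e.g. from
#'   \code{\link{selectSamples}}), each matching >= 2 columns.
#' @return data.frame with columns \code{molecule_id}, \code{log2_fc},
#'   \code{p_value}, \code{n_case}, \code{n_ref}, \code{degenerate}.
#' @examples
#' m <- matrix(rnorm(60, 20), 10, 6,
#'             dimnames = list(sprintf("m%02d", 1:10), NULL))
#' fc <- log2FoldChanges(m, case = 1:3, ref = 4:6)
#' head(fc)
#' @export
log2FoldChanges <- function(x, case, ref) {
  vals <- if (methods::is(x, "SummarizedExperiment")) assay(x) else x
  if (is.logical(case)) case <- which(case)
  if (is.logical(ref)) ref <- which(ref)
  .check(length(case) >= 2 && length(ref) >= 2,
         "statistics error: fewer than 2 replicates on one side (case %d, ref %d)",
         length(case), length(ref))
  .check(!anyNA(vals[, c(case, ref)]),
         "missing values present; run imputeMissing() first")
  a <- vals[, case, drop = FALSE]
  b <- vals[, ref, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  fc <- m1 - m2
  tstat <- fc / se
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  degenerate <- se == 0
  p[degenerate & fc != 0] <- .Machine$double.xmin
  p[degenerate & fc == 0] <- 1
  ids <- rownames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(vals)))
  data.frame(molecule_id = ids, log2_fc = fc, p_value = p,
             n_case = n1, n_ref = n2, degenerate = degenerate,
             row.names = NULL)
}

#' Classify fold-change records as significantly changed
#'
#' Applies the screen's significance rule: a molecule is significant iff
#' \code{|log2_fc| > fc_threshold} and \code{p_value < p_threshold}, both
#' strict inequalities (boundary values are not significant).  Defaults are
#' the screen's |FC| > 0.7 and P < 0.05.
#'
#' @param records data.frame from \code{\link{log2FoldChanges}} (needs columns
#'   \code{log2_fc} and \code{p_value}).
#' @param fc_threshold absolute log2 fold-change threshold.
#' @param p_threshold p-value threshold.
#' @param fdr if \code{TRUE}, apply Benjamini-Hochberg correction to the
#'   p-values before thresholding (off by default; the screen thresholds raw
#'   P together with the FC cutoff).
#' @return the input with added columns \code{significant} (logical) and
#'   \code{direction} ("up", "down" or "none").
#' @examples
#' classifySignificant(data.frame(log2_fc = c(0.8, 0.7, -0.71),
#'                                p_value = c(0.01, 0.001, 0.049)))
#' @export
classifySignificant <- function(records, fc_threshold = 0.7,
                                p_threshold = 0.05, fdr = FALSE) {
  p <- records$p_value
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  sig <- abs(records$log2_fc) > fc_threshold & p < p_threshold
  records$significant <- sig
  records$direction <- ifelse(!sig, "none",
                              ifelse(records$log2_fc > 0, "up", "down"))
  records
}

#' Condition-wise mean log2 fold changes
#'
#' For every condition (strain x timepoint) computes the mean over replicates
#' minus the mean of the reference replicates, giving the molecules x
#' conditions matrix of average abundance fold changes used for clustering
#' and correlation analysis.
#'
#' @param x a \linkS4class{ScreenExperiment} with no missing values.
#' @param ref logical or integer selector of the reference samples (default:
#'   the WT group at the early timepoint).
#' @return numeric matrix, molecules x conditions, condition columns named
#'   \code{strain_timepoint}.
#' @export
conditionMeanFC <- function(x, ref = selectSamples(x, group = "WT",
                                                   timepoint = "E")) {
  .check(methods::is(x, "SummarizedExperiment"),
         "'x' must be a ScreenExperiment")
  vals <- assay(x)
  .check(!anyNA(vals), "missing values present; run imputeMissing() first")
  if (is.logical(ref)) ref <- which(ref)
  .check(length(ref) >= 2, "statistics error: reference has < 2 replicates")
  cond <- conditionOf(x)
  refMean <- rowMeans(vals[, ref, drop = FALSE])
  condLevels <- unique(cond)
  out <- vapply(condLevels, function(cl) {
    rowMeans(vals[, cond == cl, drop = FALSE]) - refMean
  }, numeric(nrow(vals)))
  dimnames(out) <- list(rownames(vals), condLevels)
  out
}

#' Relative abundance by the delta-delta-Ct method
#'
#' Returns \eqn{2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = (Ct_{target,case} - Ct_{ref,case}) -
#' (Ct_{target,ctrl} - Ct_{ref,ctrl})}, the standard qPCR quantification used
#' e.g. for mtDNA levels normalized to a nuclear reference gene such as actin.
#'
#' @param ct_target_case,ct_ref_case Ct values for the target and reference
#'   amplicons in the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return relative abundance (dimensionless); vectorised over inputs.
#' @examples
#' deltaDeltaCt(20, 10, 18, 10)  # 0.25
#' @export
deltaDeltaCt <- function(ct_target_case, ct_ref_case,
                         ct_target_ctrl, ct_ref_ctrl) {
  .check(all(is.finite(c(ct_target_case, ct_ref_case, ct_target_ctrl,
                         ct_ref_ctrl))), "all Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
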