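#' Construct a ScreenExperiment
#'
#' @param values numeric matrix of log2 abundances (molecules x samples); may
#'   contain \code{NA} for missing measurements.  Rownames are molecule ids,
#'   colnames are \code{strain_timepoint_replicate} sample ids.
#' @param moleculeData data.frame/DataFrame of molecule annotations with
#'   columns \code{layer}, \code{is_mito}, \code{lipid_class} (and optionally
#'   \code{acyl_composition}).
#' @param sampleData data.frame/DataFrame of sample annotations with columns
#'   \code{strain}, \code{group}, \code{timepoint}, \code{replicate}.
#' @param metadata optional named list stored in the object metadata.
#' @return a \linkS4class{ScreenExperiment}.
#' @examples
#' vals <- matrix(rnorm(12, 20), 2, 6,
#'                dimnames = list(c("p1", "p2"), NULL))
#' md <- data.frame(layer = "protein", is_mito = c(TRUE, FALSE),
#'                  lipid_class = NA_character_)
#' sd <- data.frame(strain = rep(c("WT", "g3a"), each = 3),
#'                  group = rep(c("WT", "G3"), each = 3),
#'                  timepoint = "E", replicate = rep(1:3, 2))
#' se <- ScreenExperiment(vals, md, sd)
#' @export
ScreenExperiment <- function(values, moleculeData, sampleData,
                             metadata = list()) {
  .check(is.matrix(values) && is.numeric(values),
         "'values' must be a numeric matrix")
  .check(nrow(values) == nrow(moleculeData),
         "moleculeData rows (%d) != value rows (%d)",
         nrow(moleculeData), nrow(values))
  .check(ncol(values) == nrow(sampleData),
         "sampleData rows (%d) != value columns (%d)",
         nrow(sampleData), ncol(values))
  sampleData <- as.data.frame(sampleData)
  if (is.null(colnames(values)))
    colnames(values) <- paste(sampleData$strain, sampleData$timepoint,
                              sampleData$replicate, sep = "_")
  se <- SummarizedExperiment(
    assays = list(log2abundance = values),
    rowData = S4Vectors::DataFrame(moleculeData),
    colData = S4Vectors::DataFrame(sampleData, row.names = colnames(values)))
  metadata(se) <- metadata
  new("ScreenExperiment", se)
}

#' @describeIn ScreenExperiment molecule ids (rownames)
#' @param x a ScreenExperiment
#' @export
moleculeIds <- function(x) rownames(x)

#' @describeIn ScreenExperiment molecule layer ("protein"/"lipid"/"metabolite")
#' @export
moleculeLayer <- function(x) as.character(rowData(x)$layer)

#' @describeIn ScreenExperiment logical mitochondrial flag per molecule
#' @export
isMito <- function(x) {
  m <- rowData(x)$is_mito
  as.logical(ifelse(is.na(m), FALSE, m))
}

#' @describeIn ScreenExperiment lipid class per molecule (NA for non-lipids)
#' @export
lipidClass <- function(x) as.character(rowData(x)$lipid_class)

#' @describeIn ScreenExperiment condition label (strain_timepoint) per sample
#' @export
conditionOf <- function(x) {
  cd <- colData(x)
  paste(cd$strain, cd$timepoint, sep = "_")
}

#' Select sample columns of a ScreenExperiment
#'
#' Builds a logical sample selector from strain/group/timepoint filters.
#' Selectors are ANDed; \code{NULL} filters match everything, so both the
#' pooled-group style (e.g. all G3 strains at E) and per-strain comparisons
#' are expressible.
#'
#' @param x a \linkS4class{ScreenExperiment}.
#' @param strain,group,timepoint character vectors of levels to keep, or
#'   \code{NULL}.
#' @return logical vector over the samples of \code{x}.
#' @export
selectSamples <- function(x, strain = NULL, group = NULL, timepoint = NULL) {
  cd <- colData(x)
  keep <- rep(TRUE, ncol(x))
  if (!is.null(strain))    keep <- keep & cd$strain %in% strain
  if (!is.null(group))     keep <- keep & cd$group %in% group
  if (!is.null(timepoint)) keep <- keep & cd$timepoint %in% timepoint
  keep
}

setMethod("show", "ScreenExperiment", function(object) {
  lay <- table(moleculeLayer(object))
  cat("ScreenExperiment:", nrow(object), "molecules x", ncol(object),
      "samples\n")
  cat("  layers:", paste(sprintf("%s (%d)", names(lay), lay),
                         collapse = ", "), "\n")
  cat("  conditions:", length(unique(conditionOf(object))),
      "| missing values:",
      sum(is.na(assay(object))), "\n")
  invisible(NULL)
})
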