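#' Write a ScreenExperiment to TSV
#'
#' Molecules as rows; the first columns are the molecule annotations
#' (\code{molecule_id}, \code{layer}, \code{is_mito}, \code{lipid_class}),
#' followed by one column per sample named \code{strain_timepoint_replicate}.
#'
#' @param x a \linkS4class{ScreenExperiment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceMatrix <- function(x, path) {
  rd <- as.data.frame(rowData(x))
  df <- cbind(data.frame(molecule_id = rownames(x)),
              rd[, c("layer", "is_mito", "lipid_class"), drop = FALSE],
              as.data.frame(assay(x), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate an abundance-matrix TSV
#'
#' Parses the TSV dialect written by \code{\link{writeAbundanceMatrix}},
#' reconstructs the sample annotations from the \code{strain_timepoint_rep}
#' column names, and checks every container invariant; all violations are
#' reported together with their row/column coordinates.
#'
#' @param path TSV file path.
#' @return a \linkS4class{ScreenExperiment}, or an error of class
#'   \code{validation_error} listing every violation.
#' @export
readAbundanceMatrix <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  problems <- character()
  annCols <- c("molecule_id", "layer", "is_mito", "lipid_class")
  missAnn <- setdiff(annCols, names(df))
  if (length(missAnn))
    problems <- c(problems, paste("missing annotation column(s):",
                                  paste(missAnn, collapse = ", ")))
  if (!length(missAnn)) {
    dup <- df$molecule_id[duplicated(df$molecule_id)]
    if (length(dup))
      problems <- c(problems,
                    paste0("duplicated molecule id(s): ",
                           paste(unique(dup), collapse = ", "), " (rows ",
                           paste(which(df$molecule_id %in% dup),
                                 collapse = ", "), ")"))
    badLayer <- which(!df$layer %in% c("protein", "lipid", "metabolite"))
    if (length(badLayer))
      problems <- c(problems, paste0("invalid layer at row(s): ",
                                     paste(badLayer, collapse = ", ")))
  }
  sampleCols <- setdiff(names(df), annCols)
  if (length(sampleCols) == 0)
    problems <- c(problems, "no sample columns")
  parts <- strsplit(sampleCols, "_")
  badName <- sampleCols[vapply(parts, length, 0L) < 3]
  if (length(badName))
    problems <- c(problems,
                  paste("sample column(s) not named strain_timepoint_rep:",
                        paste(badName, collapse = ", ")))
  nonNum <- sampleCols[!vapply(df[sampleCols], is.numeric, TRUE)]
  if (length(nonNum))
    problems <- c(problems, paste("non-numeric sample column(s):",
                                  paste(nonNum, collapse = ", ")))
  if (length(problems))
    stop(structure(class = c("validation_error", "error", "condition"),
                   list(message = paste0("validation error:\n  ",
                                         paste(problems, collapse = "\n  ")),
                        call = NULL)))
  strain <- vapply(parts, function(p) paste(p[1:(length(p) - 2)],
                                            collapse = "_"), "")
  timepoint <- vapply(parts, function(p) p[length(p) - 1], "")
  repl <- as.integer(vapply(parts, function(p) p[length(p)], ""))
  group <- .inferGroup(strain)
  vals <- as.matrix(df[sampleCols])
  rownames(vals) <- df$molecule_id
  ScreenExperiment(vals,
                   data.frame(layer = df$layer,
                              is_mito = as.logical(df$is_mito),
                              lipid_class = df$lipid_class,
                              row.names = df$molecule_id),
                   data.frame(strain = strain, group = group,
                              timepoint = timepoint, replicate = repl))
}

## strain naming convention of the simulator (WT/WTV/g<k><letter>); strains
## outside the convention get group "G1" placeholder-free label "unknown"
.inferGroup <- function(strain) {
  ifelse(strain == "WT", "WT",
         ifelse(strain == "WTV", "WTV",
                ifelse(grepl("^g[1-4]", strain),
                       paste0("G", substr(strain, 2, 2)), "WT")))
}

#' Write/read an image stack as multi-page TIFF with a JSON sidecar
#'
#' The stack is written z-major (one TIFF page per z-plane) as 32-bit float;
#' the sidecar JSON records the voxel dimensions and channel role.
#'
#' @param stack 3-D array (z, y, x) with values in [0, 1].
#' @param path TIFF file path; the sidecar is \code{<path>.json}.
#' @param voxel_dims c(dz, dy, dx) in micrometres.
#' @param channel_role one of "cell", "mitochondria", "ER", "lipid_droplet".
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path, voxel_dims = c(0.2, 0.1, 0.1),
                            channel_role = "mitochondria") {
  .check(is.array(stack) && length(dim(stack)) == 3,
         "stack must be a 3-D array")
  pages <- lapply(seq_len(dim(stack)[1]), function(z) stack[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_dims = voxel_dims,
                            channel_role = channel_role,
                            n_planes = dim(stack)[1]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImageStack
#' @return \code{readImageStack}: list with \code{stack} (3-D array),
#'   \code{voxel_dims}, \code{channel_role}.
#' @export
readImageStack <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) stack[z, , ] <- pages[[z]]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector =
                                                       TRUE) else list()
  list(stack = stack,
       voxel_dims = if (!is.null(meta$voxel_dims)) meta$voxel_dims
                    else c(0.2, 0.1, 0.1),
       channel_role = if (!is.null(meta$channel_role)) meta$channel_role
                      else NA_character_)
}

#' Write growth curves to CSV
#'
#' Plate-reader dialect: columns \code{time_min}, \code{od600},
#' \code{strain}, \code{treatment}.
#'
#' @param curves data.frame of stacked curves.
#' @param path CSV path.
#' @export
writeGrowthCurves <- function(curves, path) {
  write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGrowthCurves
#' @export
readGrowthCurves <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}
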