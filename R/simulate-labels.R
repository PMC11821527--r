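#' Simulate a labeled-lipid pulse-chase feature table
#'
#' Emulates a [13C1]oleate pulse-chase: for every target species the fully
#' labeled isotopologue starts at \code{label_fraction} of the light pool at
#' T0 and decays exponentially at the condition's mobilization rate, while
#' the light species stays at its baseline.  Each sample carries an
#' internal-standard area with small multiplicative noise, and every feature
#' row carries peak width, S/N, blank and QC CV columns so the feature
#' filters can be exercised on simulated data.
#'
#' @param targets data.frame of target species with columns \code{species},
#'   \code{class}, \code{mz}, \code{rt_min} (see
#'   \code{\link{exampleTargetList}}).
#' @param label_fraction fraction of the light pool labeled at T0.
#' @param decay_rate_per_h named numeric vector: decay rate (per hour) per
#'   condition.
#' @param timepoints_h chase timepoints in hours (must include 0).
#' @param internal_standard_area nominal internal-standard area per sample.
#' @param n_replicates replicates per condition x timepoint.
#' @param area_noise_sdlog lognormal s.d. of peak-area noise.
#' @param is_noise_sdlog lognormal s.d. of internal-standard noise.
#' @param base_area nominal light-species area.
#' @param seed integer RNG seed; a fixed seed gives an identical table.
#' @return list with \code{features} (one row per species x label state, with
#'   \code{area_<condition>_T<h>_r<rep>} sample columns), \code{samples}
#'   (sample annotation incl. internal-standard areas) and \code{truth}
#'   (planted rates and label fraction).
#' @export
simulateLabeledPeaks <- function(targets = exampleTargetList(),
                                 label_fraction = 0.3,
                                 decay_rate_per_h = c(WT = log(2) / 3,
                                                      PLN1_OE = log(2) / 12),
                                 timepoints_h = c(0, 1, 3, 5),
                                 internal_standard_area = 2e6,
                                 n_replicates = 3L,
                                 area_noise_sdlog = 0.1,
                                 is_noise_sdlog = 0.05,
                                 base_area = 1e7, seed = 1L) {
  .check(0 %in% timepoints_h, "timepoints_h must include 0 (the T0 pulse)")
  .check(!is.null(names(decay_rate_per_h)),
         "decay_rate_per_h must be named by condition")
  withSeed(seed, {
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           timepoint_h = sort(timepoints_h),
                           condition = names(decay_rate_per_h),
                           stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "timepoint_h", "replicate")]
    samples$sample_id <- sprintf("%s_T%g_r%d", samples$condition,
                                 samples$timepoint_h, samples$replicate)
    samples$is_area <- internal_standard_area *
      exp(rnorm(nrow(samples), 0, is_noise_sdlog))

    rows <- list()
    for (i in seq_len(nrow(targets))) {
      sp <- targets[i, ]
      k <- expectedLabelCount(sp$class)
      for (lab in c(0L, k)) {
        mz <- isotopologueMz(sp$mz, lab)
        mean_area <- if (lab == 0L) {
          rep(base_area * (1 - label_fraction), nrow(samples))
        } else {
          rate <- decay_rate_per_h[samples$condition]
          base_area * label_fraction * exp(-rate * samples$timepoint_h)
        }
        areas <- mean_area * exp(rnorm(nrow(samples), 0, area_noise_sdlog))
        row <- data.frame(feature_id = sprintf("%s_k%d", sp$species, lab),
                          species = sp$species, class = sp$class,
                          label_count = lab, mz = mz, rt_min = sp$rt_min,
                          peak_width_min = 0.25, snr = 25,
                          blank_area = base_area / 100, qc_cv_percent = 8)
        row[paste0("area_", samples$sample_id)] <- as.list(areas)
        rows[[length(rows) + 1L]] <- row
      }
    }
    features <- do.call(rbind, rows)
    rownames(features) <- NULL
    list(features = features, samples = samples,
         truth = list(decay_rate_per_h = decay_rate_per_h,
                      label_fraction = label_fraction,
                      internal_standard_area = internal_standard_area,
                      seed = seed))
  })
}

#' Example targeted-compound list
#'
#' A small synthetic targeted list mirroring the shape of a targeted
#' lipidomics compound table (species, class, acyl composition, polarity,
#' m/z, retention time).  The m/z and retention-time values are synthetic
#' placeholders, not measured values.
#'
#' @return data.frame with columns \code{species}, \code{class},
#'   \code{carbons}, \code{double_bonds}, \code{polarity}, \code{mz},
#'   \code{rt_min}.
#' @export
exampleTargetList <- function() {
  data.frame(
    species = c("TAG 54:3 (triolein)", "CL 72:4", "PC 36:2", "PE 36:2"),
    class = c("TAG", "CL", "PC", "PE"),
    carbons = c(54L, 72L, 36L, 36L),
    double_bonds = c(3L, 4L, 2L, 2L),
    polarity = c("+", "-", "+", "+"),
    mz = c(902.82, 1455.98, 786.60, 744.55),
    rt_min = c(19.5, 18.2, 12.4, 12.1))
}

#' Extract per-condition labeled measurements from a simulated feature table
#'
#' Convenience bridge from \code{\link{simulateLabeledPeaks}} output to the
#' long format consumed by \code{\link{mobilizationKinetics}}: selects the
#' fully labeled isotopologue of one species, normalizes each sample's area
#' to its internal standard, and returns one row per sample.
#'
#' @param sim result of \code{\link{simulateLabeledPeaks}}.
#' @param species species name (default: first target).
#' @return data.frame with columns \code{condition}, \code{timepoint_h},
#'   \code{replicate}, \code{normalized_abundance}.
#' @export
labeledMeasurements <- function(sim, species = NULL) {
  feats <- sim$features
  if (is.null(species)) species <- feats$species[1]
  row <- feats[feats$species == species & feats$label_count > 0, ]
  .check(nrow(row) == 1, "no unique labeled feature for species '%s'",
         species)
  areas <- unlist(row[paste0("area_", sim$samples$sample_id)])
  data.frame(condition = sim$samples$condition,
             timepoint_h = sim$samples$timepoint_h,
             replicate = sim$samples$replicate,
             normalized_abundance = normalizeToStandard(
               unname(areas), sim$samples$is_area),
             row.names = NULL)
}
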