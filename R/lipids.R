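#' Lipid species class model
#'
#' Describes a lipid species by class and acyl composition.  The number of
#' acyl chains is class-determined: TAG has 3, cardiolipin (CL) has 4, and
#' diacyl glycerophospholipids (PC, PE, PG, PA, PS, PI) have 2.
#'
#' @param class_label lipid class, e.g. \code{"TAG"}, \code{"CL"},
#'   \code{"PC"}.
#' @param total_carbons total acyl carbons (the "72" in "72:4 CL").
#' @param double_bonds total acyl double bonds.
#' @param base_mz targeted m/z of the unlabeled species.
#' @param polarity \code{"+"} or \code{"-"} ionisation mode.
#' @param expected_rt expected retention time in minutes.
#' @param charge ion charge (singly charged assumed by default; the target
#'   list supplies m/z directly so no adduct chemistry is computed).
#' @return list of class \code{LipidSpecies} with an \code{n_chains} field.
#' @examples
#' lipidSpecies("CL", 72, 4, base_mz = 1455.98, polarity = "-",
#'              expected_rt = 18.2)$n_chains  # 4
#' @export
lipidSpecies <- function(class_label, total_carbons, double_bonds,
                         base_mz = NA_real_, polarity = "+",
                         expected_rt = NA_real_, charge = 1L) {
  nch <- .chainsForClass(class_label)
  .check(total_carbons >= nch * 2,
         "total_carbons (%d) below minimum for %d chains",
         total_carbons, nch)
  .check(is.na(base_mz) || base_mz > 0, "base_mz must be positive")
  structure(list(class_label = class_label,
                 total_carbons = as.integer(total_carbons),
                 double_bonds = as.integer(double_bonds),
                 n_chains = nch, base_mz = base_mz, polarity = polarity,
                 expected_rt = expected_rt, charge = as.integer(charge)),
            class = "LipidSpecies")
}

.diacylClasses <- c("PC", "PE", "PG", "PA", "PS", "PI")

.chainsForClass <- function(class_label) {
  if (class_label == "TAG") return(3L)
  if (class_label == "CL") return(4L)
  if (class_label %in% .diacylClasses) return(2L)
  stop("class-model error: unknown lipid class '", class_label, "'",
       call. = FALSE)
}

#' Expected heavy-label count of the fully labeled isotopologue
#'
#' With a [13C1]oleic acid tracer each incorporated oleoyl chain carries one
#' heavy carbon, so the fully labeled isotopologue of a species carries
#' \code{n_chains * labels_per_chain} labels: 3 for TAG (e.g. [13C3]triolein),
#' 4 for CL (e.g. [13C4]72:4 CL), and 2 for diacyl phospholipids (e.g.
#' [13C2]36:2 PC).
#'
#' @param species a \code{LipidSpecies} or a class label string.
#' @param labels_per_chain heavy atoms per acyl chain (default 1).
#' @return integer label count.
#' @examples
#' expectedLabelCount("TAG")  # 3
#' @export
expectedLabelCount <- function(species, labels_per_chain = 1L) {
  nch <- if (inherits(species, "LipidSpecies")) species$n_chains
         else .chainsForClass(species)
  as.integer(nch * labels_per_chain)
}

#' Exact 13C - 12C mass difference in Da
#' @export
C13_MASS_SHIFT <- 1.0033548

#' m/z of a 13C isotopologue
#'
#' Adds \code{k} times the exact 13C-12C mass difference (1.0033548 Da) to
#' the base m/z; singly charged ions assumed unless the species carries a
#' charge field.
#'
#' @param species a \code{LipidSpecies} (with \code{base_mz}) or a numeric
#'   base m/z.
#' @param k number of 13C labels (>= 0).
#' @return isotopologue m/z, strictly increasing in \code{k}.
#' @examples
#' isotopologueMz(885.55, 3)
#' @export
isotopologueMz <- function(species, k) {
  .check(all(k >= 0), "input error: negative label count")
  if (inherits(species, "LipidSpecies")) {
    base <- species$base_mz
    z <- species$charge
  } else {
    base <- species
    z <- 1L
  }
  .check(all(is.finite(base)) && all(base > 0), "base m/z must be positive")
  base + k * C13_MASS_SHIFT / z
}

#' Quality-filter a lipidomics feature table
#'
#' Applies the numeric feature-level exclusion chain used for untargeted
#' lipidomics: a feature is kept iff its peak intensity is at least
#' \code{min_intensity} (2e6 by default; use 5e4 via
#' \code{preset = "metabolomics"}), its peak width is at most
#' \code{max_width_min} (0.75 min), its signal-to-noise ratio is at least
#' \code{min_snr} (1.5), its intensity is at least \code{min_blank_fold}
#' (3-fold) above the blank, and its QC coefficient of variation is below
#' \code{max_qc_cv} (30 percent).  Removed features carry the name of the
#' first failing rule, checked in that order.
#'
#' @param features data.frame with columns \code{peak_width_min}, \code{snr},
#'   \code{blank_area}, \code{qc_cv_percent} and one or more per-sample area
#'   columns whose names start with \code{area_} (peak intensity is the
#'   maximum per-sample area).  An explicit \code{intensity} column, if
#'   present, takes precedence.
#' @param min_intensity,max_width_min,min_snr,min_blank_fold,max_qc_cv rule
#'   thresholds (all configurable).
#' @param preset \code{"lipidomics"} (default) or \code{"metabolomics"}
#'   (lowers \code{min_intensity} to 5e4).
#' @return list with data.frames \code{kept} and \code{removed}; the latter
#'   has an extra \code{reason} column naming the first failing rule
#'   (\code{"intensity"}, \code{"width"}, \code{"snr"}, \code{"blank"},
#'   \code{"qc_cv"}).
#' @export
filterFeatureTable <- function(features, min_intensity = 2e6,
                               max_width_min = 0.75, min_snr = 1.5,
                               min_blank_fold = 3, max_qc_cv = 30,
                               preset = c("lipidomics", "metabolomics")) {
  preset <- match.arg(preset)
  if (preset == "metabolomics" && missing(min_intensity)) min_intensity <- 5e4
  if (nrow(features) == 0)
    return(list(kept = features,
                removed = cbind(features, reason = character(0))))
  intensity <- if ("intensity" %in% names(features)) {
    features$intensity
  } else {
    areaCols <- grep("^area_", names(features), value = TRUE)
    .check(length(areaCols) > 0,
           "no 'intensity' column and no 'area_*' sample columns")
    do.call(pmax, features[areaCols])
  }
  reason <- rep(NA_character_, nrow(features))
  fail <- function(cond, nm) ifelse(is.na(reason) & cond, nm, reason)
  reason <- fail(intensity < min_intensity, "intensity")
  reason <- fail(features$peak_width_min > max_width_min, "width")
  reason <- fail(features$snr < min_snr, "snr")
  reason <- fail(intensity < min_blank_fold * features$blank_area, "blank")
  reason <- fail(features$qc_cv_percent >= max_qc_cv, "qc_cv")
  keep <- is.na(reason)
  removed <- features[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = features[keep, , drop = FALSE], removed = removed)
}

#' Match observed features to a targeted compound list
#'
#' Assigns features to targets when the mass error is within \code{ppm_tol}
#' parts per million and the retention-time difference is within
#' \code{rt_tol_min} minutes (the 10 ppm / 0.4 min compound-grouping
#' tolerances).  Assignment is one-to-one: candidate pairs are ranked by
#' absolute mass error (ties by retention-time error) and matched greedily,
#' so each target receives at most one feature and vice versa.
#'
#' @param features data.frame with columns \code{feature_id}, \code{mz},
#'   \code{rt_min}.
#' @param targets data.frame with columns \code{species}, \code{mz},
#'   \code{rt_min}.
#' @param ppm_tol mass tolerance in ppm.
#' @param rt_tol_min retention-time tolerance in minutes.
#' @return list with \code{assignments} (feature_id, species, ppm_error,
#'   rt_error_min) and \code{unmatched} (feature ids).  Targets whose m/z
#'   collide within tolerance trigger an ambiguity warning listing them.
#' @export
matchLabeledPeaks <- function(features, targets, ppm_tol = 10,
                              rt_tol_min = 0.4) {
  .check(all(c("mz", "rt_min") %in% names(features)) &&
           all(c("species", "mz", "rt_min") %in% names(targets)),
         "features need mz/rt_min; targets need species/mz/rt_min")
  ## warn about targets indistinguishable by mass
  if (nrow(targets) > 1) {
    tm <- targets$mz
    coll <- which(outer(tm, tm, function(a, b)
      abs(a - b) / pmax(a, b) <= ppm_tol * 1e-6) &
        upper.tri(matrix(TRUE, length(tm), length(tm))), arr.ind = TRUE)
    if (nrow(coll) > 0)
      warning("ambiguous targets within mass tolerance: ",
              paste(sprintf("%s~%s", targets$species[coll[, 1]],
                            targets$species[coll[, 2]]), collapse = ", "))
  }
  cand <- expand.grid(f = seq_len(nrow(features)), t = seq_len(nrow(targets)))
  cand$ppm <- abs(features$mz[cand$f] - targets$mz[cand$t]) /
    targets$mz[cand$t] * 1e6
  cand$drt <- abs(features$rt_min[cand$f] - targets$rt_min[cand$t])
  cand <- cand[cand$ppm <= ppm_tol & cand$drt <= rt_tol_min, , drop = FALSE]
  cand <- cand[order(cand$ppm, cand$drt), , drop = FALSE]
  usedF <- logical(nrow(features)); usedT <- logical(nrow(targets))
  rows <- integer(0)
  for (i in seq_len(nrow(cand))) {
    f <- cand$f[i]; t <- cand$t[i]
    if (!usedF[f] && !usedT[t]) {
      usedF[f] <- TRUE; usedT[t] <- TRUE
      rows <- c(rows, i)
    }
  }
  asg <- cand[rows, , drop = FALSE]
  fid <- if ("feature_id" %in% names(features)) features$feature_id
         else as.character(seq_len(nrow(features)))
  assignments <- data.frame(feature_id = fid[asg$f],
                            species = targets$species[asg$t],
                            ppm_error = asg$ppm, rt_error_min = asg$drt,
                            row.names = NULL)
  list(assignments = assignments, unmatched = fid[!usedF])
}

#' Normalize peak areas to an internal standard
#'
#' Element-wise division of peak areas by the internal-standard area of the
#' same sample (the CoQ8-style run normalization).
#'
#' @param areas numeric vector/matrix of peak areas (>= 0).
#' @param standard_area positive internal-standard area (scalar or one per
#'   sample).
#' @return normalized abundances (dimensionless).
#' @export
normalizeToStandard <- function(areas, standard_area) {
  .check(all(standard_area > 0),
         "normalization error: standard_area must be positive")
  areas / standard_area
}

#' TAG mobilization kinetics from labeled measurements
#'
#' Normalizes labeled-species abundances to the mean of the same condition's
#' T0 samples and fits a per-condition log-linear decay
#' \eqn{\log(y) = a - k t}, giving the mobilization rate \eqn{k} (per hour)
#' with its standard error.  Also provides the percent-difference comparison
#' between two conditions at a timepoint, \eqn{(1 - \bar y_A/\bar y_B)
#' \times 100}.
#'
#' @param measurements data.frame with columns \code{condition},
#'   \code{timepoint_h}, \code{replicate}, \code{normalized_abundance}
#'   (internal-standard normalized areas).  Each condition needs T0
#'   (\code{timepoint_h == 0}) replicates with positive mean.
#' @return list with \code{measurements} (input plus a \code{t0_relative}
#'   column) and \code{rates}, a data.frame of per-condition \code{rate_per_h},
#'   \code{se}, \code{n}.
#' @export
mobilizationKinetics <- function(measurements) {
  need <- c("condition", "timepoint_h", "normalized_abundance")
  .check(all(need %in% names(measurements)),
         "measurements need columns: %s", paste(need, collapse = ", "))
  out <- measurements
  out$t0_relative <- NA_real_
  rates <- list()
  for (cc in unique(out$condition)) {
    sel <- out$condition == cc
    t0 <- out$normalized_abundance[sel & out$timepoint_h == 0]
    .check(length(t0) > 0 && mean(t0) > 0,
           "kinetics error: condition '%s' lacks T0 samples with positive mean",
           cc)
    out$t0_relative[sel] <- out$normalized_abundance[sel] / mean(t0)
    d <- out[sel & out$t0_relative > 0, ]
    fit <- lm(log(t0_relative) ~ timepoint_h, data = d)
    rates[[cc]] <- data.frame(condition = cc,
                              rate_per_h = -coef(fit)[["timepoint_h"]],
                              se = summary(fit)$coefficients["timepoint_h",
                                                             "Std. Error"],
                              n = nrow(d), row.names = NULL)
  }
  list(measurements = out, rates = do.call(rbind, rates))
}

#' Percent difference between two condition means
#'
#' The comparison form "A is x percent lower than B":
#' \eqn{(1 - \bar y_A / \bar y_B) \times 100}.
#'
#' @param mean_a,mean_b condition means (\code{mean_b} > 0).
#' @return percent difference (positive when A is lower than B).
#' @examples
#' percentLower(0.57, 1.0)  # 43
#' @export
percentLower <- function(mean_a, mean_b) {
  .check(all(mean_b > 0), "reference mean must be positive")
  (1 - mean_a / mean_b) * 100
}
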