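#' Configuration for the synthetic multiomic screen
#'
#' The defaults emulate the structure of the yeast screen the package models:
#' two wild-type controls (WT and the vehicle control WTV), strains in four
#' respiratory stress groups, biological triplicates, and an early (E)
#' timepoint for every strain plus a late (L) recovery timepoint for the
#' growth-delayed groups 2 and 3.  Planted log2 effects (mitochondrial protein
#' depletion at E with recovery at L, TAG depletion in recovering groups,
#' cardiolipin overshoot at L, and none of these in the non-recovering group 4)
#' reproduce the qualitative signature of the screen; the magnitudes are
#' configurable and not asserted to be measured values.
#'
#' @param n_proteins,n_lipids,n_metabolites molecule counts per layer.
#' @param frac_mito proportion of proteins flagged mitochondrial.
#' @param n_tag_species number of lipids designated TAG; a further
#'   \code{n_cl_species} are designated cardiolipin (CL).
#' @param n_cl_species number of CL species.
#' @param strains data.frame with columns \code{strain}, \code{group},
#'   \code{has_late}; \code{NULL} for the default 10-strain design.
#' @param effects named list, one entry per group, each a list with
#'   \code{mito_log2fc_E}, \code{mito_log2fc_L}, \code{tag_log2fc_E},
#'   \code{cl_log2fc_L}.  \code{NULL} for defaults.
#' @param strain_severity_sd lognormal s.d. of the per-strain severity
#'   multiplier applied to all of a strain's planted effects (mean 1).
#'   Strains within a group share the group's effect profile but differ in
#'   magnitude, as real point mutants do.
#' @param axis_jitter_sd lognormal s.d. of the per-strain, per-effect-axis
#'   (mitochondrial / TAG / CL) multiplier (mean 1), decoupling the extent of
#'   TAG mobilization from proteome depletion across strains.
#' @param n_replicates biological replicates per condition (>= 2).
#' @param noise_sd replicate noise s.d. on the log2 scale.
#' @param correlate_strength scaling between the planted perilipin-like
#'   protein's condition profile and the mean TAG profile (its profile noise
#'   s.d. is \code{noise_sd * (1 - correlate_strength)}, so the zero-noise
#'   limit is exact).
#' @param missing_rate overall proportion of protein values injected as
#'   missing (abundance-dependent; see Details).
#' @param seed integer RNG seed.
#' @details Missingness is injected only into the protein layer with
#'   probability logistic in the within-sample abundance rank, concentrating
#'   missing values at low abundance as in label-free MS data.
#' @return a list of class \code{screenSimConfig}.
#' @export
screenSimConfig <- function(n_proteins = 400L, n_lipids = 120L,
                            n_metabolites = 60L, frac_mito = 0.25,
                            n_tag_species = 15L, n_cl_species = 4L,
                            strains = NULL, effects = NULL,
                            strain_severity_sd = 0.2, axis_jitter_sd = 0.2,
                            n_replicates = 3L, noise_sd = 0.2,
                            correlate_strength = 0.9, missing_rate = 0.05,
                            seed = 1L) {
  if (is.null(strains)) {
    strains <- data.frame(
      strain = c("WT", "WTV", "g1a", "g1b", "g2a", "g2b", "g3a", "g3b", "g3c",
                 "g4a"),
      group = c("WT", "WTV", "G1", "G1", "G2", "G2", "G3", "G3", "G3", "G4"),
      has_late = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   FALSE))
  }
  if (is.null(effects)) {
    effects <- list(
      WT  = list(mito_log2fc_E = 0,    mito_log2fc_L = 0,
                 tag_log2fc_E = 0,     cl_log2fc_L = 0),
      WTV = list(mito_log2fc_E = 0,    mito_log2fc_L = 0,
                 tag_log2fc_E = 0,     cl_log2fc_L = 0),
      G1  = list(mito_log2fc_E = 0,    mito_log2fc_L = 0,
                 tag_log2fc_E = 0,     cl_log2fc_L = 0),
      G2  = list(mito_log2fc_E = -0.5, mito_log2fc_L = -0.1,
                 tag_log2fc_E = -0.5,  cl_log2fc_L = 0.4),
      G3  = list(mito_log2fc_E = -1.5, mito_log2fc_L = -0.3,
                 tag_log2fc_E = -1.5,  cl_log2fc_L = 1.0),
      G4  = list(mito_log2fc_E = -1.5, mito_log2fc_L = NA,
                 tag_log2fc_E = 0,     cl_log2fc_L = NA))
  }
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_lipids = as.integer(n_lipids),
              n_metabolites = as.integer(n_metabolites),
              frac_mito = frac_mito, n_tag_species = as.integer(n_tag_species),
              n_cl_species = as.integer(n_cl_species), strains = strains,
              effects = effects, strain_severity_sd = strain_severity_sd,
              axis_jitter_sd = axis_jitter_sd,
              n_replicates = as.integer(n_replicates),
              noise_sd = noise_sd, correlate_strength = correlate_strength,
              missing_rate = missing_rate, seed = as.integer(seed))
  .check(all(c(cfg$n_proteins, cfg$n_lipids, cfg$n_metabolites) >= 1L),
         "molecule counts must be >= 1")
  .check(cfg$frac_mito >= 0 && cfg$frac_mito <= 1, "frac_mito must be in [0,1]")
  .check(cfg$missing_rate >= 0 && cfg$missing_rate <= 1,
         "missing_rate must be in [0,1]")
  .check(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  .check(cfg$n_replicates >= 2L,
         "configuration error: n_replicates must be >= 2")
  .check(cfg$n_tag_species + cfg$n_cl_species <= cfg$n_lipids,
         "TAG + CL species exceed n_lipids")
  cfg
}

# planted condition-wise effect for one molecule class within one group
.groupEffect <- function(eff, timepoint, what) {
  switch(what,
         mito = if (timepoint == "E") eff$mito_log2fc_E else eff$mito_log2fc_L,
         tag  = if (timepoint == "E") eff$tag_log2fc_E
                else eff$tag_log2fc_E / 2,   # partial TAG restoration at L
         cl   = if (timepoint == "E") eff$mito_log2fc_E  # CL tracks mito at E
                else eff$cl_log2fc_L,
         0)
}

#' Simulate a multiomic screen with planted ground truth
#'
#' Generates a molecules x samples log2 abundance matrix.  Effects are added
#' per condition (strain x timepoint) on the log2 scale before replicate
#' noise: mitochondrial proteins and CL species carry the group's
#' mitochondrial depletion/recovery signature, TAG species carry the group's
#' TAG depletion, and exactly one designated perilipin-like protein
#' (\code{"prot_pln_like"}) has a condition profile equal to the mean TAG
#' profile scaled by \code{correlate_strength} plus independent noise.
#' Missing values are then injected into the protein layer preferentially at
#' low abundance.
#'
#' @param config a \code{\link{screenSimConfig}}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{ScreenExperiment}) and \code{truth}, a list holding the
#'   planted per-molecule condition effects matrix, the correlate id, the TAG
#'   / CL / mito id sets and the config.
#' @examples
#' sim <- simulateScreen(screenSimConfig(n_proteins = 50, n_lipids = 30,
#'                                       n_metabolites = 10, seed = 7))
#' sim$experiment
#' @export
simulateScreen <- function(config = screenSimConfig()) {
  cfg <- config
  withSeed(cfg$seed, {
    ## molecule annotation
    prot_ids <- sprintf("prot_%03d", seq_len(cfg$n_proteins))
    n_mito <- round(cfg$frac_mito * cfg$n_proteins)
    is_mito <- c(rep(TRUE, n_mito), rep(FALSE, cfg$n_proteins - n_mito))
    ## the planted correlate is a non-mitochondrial protein
    pln_idx <- cfg$n_proteins            # last protein is non-mito by layout
    prot_ids[pln_idx] <- "prot_pln_like"
    is_mito[pln_idx] <- FALSE
    lip_ids <- sprintf("lip_%03d", seq_len(cfg$n_lipids))
    lclass <- rep("PC", cfg$n_lipids)
    lclass[seq_len(cfg$n_tag_species)] <- "TAG"
    lclass[cfg$n_tag_species + seq_len(cfg$n_cl_species)] <- "CL"
    met_ids <- sprintf("met_%03d", seq_len(cfg$n_metabolites))
    ids <- c(prot_ids, lip_ids, met_ids)
    layer <- rep(c("protein", "lipid", "metabolite"),
                 c(cfg$n_proteins, cfg$n_lipids, cfg$n_metabolites))
    rowdat <- data.frame(
      layer = layer,
      is_mito = c(is_mito, rep(NA, cfg$n_lipids + cfg$n_metabolites)),
      lipid_class = c(rep(NA_character_, cfg$n_proteins), lclass,
                      rep(NA_character_, cfg$n_metabolites)),
      row.names = ids)

    ## sample design
    st <- cfg$strains
    conds <- rbind(
      data.frame(strain = st$strain, group = st$group, timepoint = "E"),
      data.frame(strain = st$strain[st$has_late],
                 group = st$group[st$has_late], timepoint = "L"))
    cond_lab <- paste(conds$strain, conds$timepoint, sep = "_")
    samp <- conds[rep(seq_len(nrow(conds)), each = cfg$n_replicates), ]
    samp$replicate <- rep(seq_len(cfg$n_replicates), nrow(conds))
    rownames(samp) <- NULL

    ## planted condition effects (molecules x conditions)
    theta <- matrix(0, length(ids), nrow(conds),
                    dimnames = list(ids, cond_lab))
    tag_ids <- lip_ids[lclass == "TAG"]
    cl_ids <- lip_ids[lclass == "CL"]
    mito_ids <- prot_ids[is_mito]
    ## per-strain severity and per-axis multipliers (mean 1): strains within
    ## a group share the group's profile but differ in magnitude, and the
    ## extent of TAG mobilization decouples from proteome depletion
    lnorm1 <- function(n, sdlog) exp(rnorm(n, -sdlog^2 / 2, sdlog))
    sev <- setNames(lnorm1(nrow(st), cfg$strain_severity_sd), st$strain)
    axisMult <- sapply(c("mito", "tag", "cl"), function(ax)
      setNames(lnorm1(nrow(st), cfg$axis_jitter_sd), st$strain))
    for (j in seq_len(nrow(conds))) {
      eff <- cfg$effects[[conds$group[j]]]
      tp <- conds$timepoint[j]
      sn <- conds$strain[j]
      theta[mito_ids, j] <- .groupEffect(eff, tp, "mito") * sev[sn] *
        axisMult[sn, "mito"]
      theta[tag_ids, j]  <- .groupEffect(eff, tp, "tag") * sev[sn] *
        axisMult[sn, "tag"]
      theta[cl_ids, j]   <- .groupEffect(eff, tp, "cl") * sev[sn] *
        axisMult[sn, "cl"]
    }
    tag_profile <- colMeans(theta[tag_ids, , drop = FALSE])
    theta["prot_pln_like", ] <- cfg$correlate_strength * tag_profile +
      rnorm(nrow(conds), 0, cfg$noise_sd * (1 - cfg$correlate_strength))

    ## baselines + replicate noise
    baseline <- rnorm(length(ids), mean = 20, sd = 2)
    cond_of_sample <- match(paste(samp$strain, samp$timepoint, sep = "_"),
                            cond_lab)
    vals <- baseline + theta[, cond_of_sample, drop = FALSE] +
      matrix(rnorm(length(ids) * nrow(samp), 0, cfg$noise_sd),
             length(ids), nrow(samp))
    dimnames(vals) <- list(ids, paste(samp$strain, samp$timepoint,
                                      samp$replicate, sep = "_"))

    ## abundance-dependent missingness, protein layer only; the designated
    ## correlate is exempt (it is planted as a quantified protein - a
    ## correlate lost to missingness would have no recoverable identity)
    if (cfg$missing_rate > 0) {
      prot_rows <- which(layer == "protein" & ids != "prot_pln_like")
      for (s in seq_len(ncol(vals))) {
        v <- vals[prot_rows, s]
        rk <- rank(v) / length(v)            # low rank = low abundance
        w <- plogis((0.25 - rk) / 0.1)
        p <- pmin(1, cfg$missing_rate * w / mean(w))
        drop <- runif(length(v)) < p
        ## keep >= 2 observed per column (imputation precondition)
        if (sum(!drop) < 2) drop[order(v, decreasing = TRUE)[1:2]] <- FALSE
        vals[prot_rows[drop], s] <- NA
      }
    }

    se <- ScreenExperiment(vals, rowdat, samp,
                           metadata = list(simulated = TRUE, seed = cfg$seed))
    truth <- list(effects = theta, correlate_id = "prot_pln_like",
                  tag_ids = tag_ids, cl_ids = cl_ids, mito_ids = mito_ids,
                  baseline = setNames(baseline, ids), config = cfg)
    list(experiment = se, truth = truth)
  })
}
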