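#' Simulate a diauxic growth curve
#'
#' Builds a two-phase respiratory growth curve sampled every 10 minutes:
#' a first logistic (fermentative) phase rising from \code{od0} to \code{k1},
#' a diauxic dip of depth \code{dip_depth} starting at \code{dip_time_min},
#' and - for survivors - a second logistic (respiratory) phase that leaves
#' the post-dip baseline at \code{lag_min} and grows at \code{max_rate_per_h}
#' towards \code{k2}.  Non-survivors plateau after the dip.  The planted
#' \code{lag_min} is the time at which the phase-2 logistic passes through
#' the post-dip baseline, i.e. the tangent-intercept lag of the respiratory
#' phase.
#'
#' @param lag_min planted respiratory lag in minutes (must exceed the end of
#'   the dip); ignored when \code{single_phase = TRUE} except as the growth
#'   start time.
#' @param max_rate_per_h planted maximum specific growth rate (1/h) of the
#'   respiratory phase.
#' @param k1,k2 carrying capacities (OD600) of phases 1 and 2.
#' @param od0 inoculation OD600.
#' @param r1_per_h phase-1 rate (1/h).
#' @param dip_time_min start of the diauxic dip; \code{NULL} picks the first
#'   sampled time at which phase 1 reaches 99 percent of \code{k1}.
#' @param dip_depth OD drop over the dip.
#' @param dip_duration_min duration of the dip.
#' @param survive_diauxic if \code{FALSE} the curve plateaus after the dip.
#' @param single_phase if \code{TRUE}, a single logistic from \code{od0}
#'   starting at \code{lag_min} with rate \code{max_rate_per_h} towards
#'   \code{k2} (no dip).
#' @param t_max_min,dt_min observation window and sampling interval (10 min).
#' @param noise_sd additive OD noise s.d. (0 = noiseless).
#' @param strain,treatment labels carried through to the output.
#' @param seed RNG seed for the noise.
#' @return data.frame with columns \code{time_min}, \code{od600},
#'   \code{strain}, \code{treatment}; attribute \code{truth} holds the
#'   planted parameters.
#' @export
simulateGrowthCurve <- function(lag_min = 400, max_rate_per_h = 0.35,
                                k1 = 0.2, k2 = 1.2, od0 = 0.02,
                                r1_per_h = 2, dip_time_min = NULL,
                                dip_depth = 0.05, dip_duration_min = 30,
                                survive_diauxic = TRUE, single_phase = FALSE,
                                t_max_min = 2880, dt_min = 10,
                                noise_sd = 0, strain = "strain",
                                treatment = "none", seed = NULL) {
  tt <- seq(0, t_max_min, by = dt_min)
  .check(all(diff(tt) > 0), "input error: non-monotone time vector")
  logistic <- function(t, y0, K, r_h, t0) {
    ## logistic through (t0, y0) with low-density rate r_h, capacity K
    r <- r_h / 60
    y0 * K * exp(r * (t - t0)) / (K + y0 * (exp(r * (t - t0)) - 1))
  }
  if (single_phase) {
    od <- ifelse(tt < lag_min, od0, logistic(tt, od0, k2, max_rate_per_h,
                                             lag_min))
    truth <- list(lag_min = lag_min, max_rate_per_h = max_rate_per_h,
                  survive_diauxic = TRUE, single_phase = TRUE)
  } else {
    ph1 <- logistic(tt, od0, k1, r1_per_h, 0)
    if (is.null(dip_time_min)) {
      hit <- which(ph1 >= 0.99 * k1)
      .check(length(hit) > 0, "phase 1 never saturates; extend t_max_min")
      dip_time_min <- tt[hit[1]]
    }
    dipEnd <- dip_time_min + dip_duration_min
    .check(!survive_diauxic || lag_min > dipEnd,
           "lag_min (%g) must exceed the end of the dip (%g)",
           lag_min, dipEnd)
    b1 <- k1 - dip_depth
    od <- ph1
    inDip <- tt >= dip_time_min & tt < dipEnd
    od[inDip] <- k1 - dip_depth * (tt[inDip] - dip_time_min) /
      dip_duration_min
    od[tt >= dipEnd] <- b1
    if (survive_diauxic) {
      ph2 <- tt >= lag_min
      od[ph2] <- logistic(tt[ph2], b1, k2, max_rate_per_h, lag_min)
    }
    truth <- list(lag_min = lag_min, max_rate_per_h = max_rate_per_h,
                  k1 = k1, k2 = k2, dip_time_min = dip_time_min,
                  dip_depth = dip_depth, survive_diauxic = survive_diauxic,
                  single_phase = FALSE)
  }
  if (noise_sd > 0)
    od <- withSeed(seed, pmax(od + rnorm(length(od), 0, noise_sd), 1e-4))
  out <- data.frame(time_min = tt, od600 = od, strain = strain,
                    treatment = treatment)
  attr(out, "truth") <- truth
  out
}

#' Simulate a set of growth curves from per-group parameters
#'
#' @param group_params data.frame with one row per curve and columns
#'   \code{strain}, \code{lag_min}, \code{max_rate_per_h},
#'   \code{survive_diauxic} plus optionally any other
#'   \code{\link{simulateGrowthCurve}} parameter as a column.
#' @param noise_sd additive OD noise s.d.
#' @param seed base RNG seed; curve \code{i} uses \code{seed + i}.
#' @return list with \code{curves} (one data.frame, rows stacked) and
#'   \code{truth} (the parameter table).
#' @export
simulateGrowthCurves <- function(group_params, noise_sd = 0, seed = 1L) {
  pieces <- lapply(seq_len(nrow(group_params)), function(i) {
    p <- as.list(group_params[i, , drop = FALSE])
    args <- p[intersect(names(p), names(formals(simulateGrowthCurve)))]
    args$noise_sd <- noise_sd
    args$seed <- seed + i
    do.call(simulateGrowthCurve, args)
  })
  list(curves = do.call(rbind, pieces), truth = group_params)
}
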