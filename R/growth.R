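#' Growth metrics from an OD600 curve
#'
#' Estimates the respiratory-phase lag and maximum specific growth rate of a
#' plate-reader growth curve, excluding timepoints before the diauxic shift
#' and during stationary phase:
#' \enumerate{
#'   \item the OD trace is smoothed with a centred moving average (window 5
#'     points = 50 min at 10-min sampling);
#'   \item the diauxic shift is located at the local minimum of the smoothed
#'     OD derivative between the two growth phases (curves with a single
#'     phase are analysed whole);
#'   \item within the post-shift, pre-stationary segment, the slope of
#'     log(OD) is fitted over a sliding window; each window slope is
#'     corrected by the logistic capacity factor \eqn{(1 - OD/\hat K)^{-1}}
#'     (with \eqn{\hat K} the stationary OD) and the maximum corrected slope
#'     is the growth rate - the raw log-slope of a logistic underestimates
#'     the low-density rate once growth resumes from a non-negligible
#'     baseline;
#'   \item the lag is where the tangent at the maximal-slope window crosses
#'     the pre-shift baseline (the post-dip plateau OD, or the initial OD for
#'     single-phase curves).
#' }
#' Stationary phase is the terminal segment whose smoothed log-slope stays
#' below 5 percent of the maximum rate.  All metrics are invariant under
#' uniform OD scaling.
#'
#' @param curve data.frame with columns \code{time_min} (strictly increasing,
#'   >= 10 points) and \code{od600}.
#' @param smooth_window moving-average window (points).
#' @param slope_window sliding-window width (points) for log-OD slopes.
#' @param stationary_frac stationary threshold as a fraction of the maximum
#'   rate.
#' @return list with \code{lag_min}, \code{max_rate_per_h},
#'   \code{diauxic_shift_min} (NA if no shift detected),
#'   \code{diauxic_survived} (NA when no dip was observed), and
#'   \code{no_growth} flag (when TRUE the metrics are NA).
#' @export
growthMetrics <- function(curve, smooth_window = 5L, slope_window = 5L,
                          stationary_frac = 0.05) {
  tt <- curve$time_min
  od <- curve$od600
  .check(length(tt) >= 10, "need >= 10 timepoints")
  .check(all(diff(tt) > 0), "input error: non-monotone time vector")
  .check(all(od >= 0), "negative OD values")
  s <- .movingAverage(od, smooth_window)
  n <- length(s)
  noGrowth <- (max(s) - min(s)) < 0.05 * max(s)
  if (noGrowth)
    return(list(lag_min = NA_real_, max_rate_per_h = NA_real_,
                diauxic_shift_min = NA_real_, diauxic_survived = NA,
                no_growth = TRUE))

  ## derivative of the smoothed trace
  deriv <- c(NA, diff(s) / diff(tt))
  deriv[1] <- deriv[2]

  ## phase-1 peak = first local max of the derivative above 25% of its max
  dmax <- max(deriv, na.rm = TRUE)
  isPeak <- which(deriv > 0.25 * dmax)
  p1 <- isPeak[1]
  ## advance to the local maximum of this excursion
  while (p1 < n && deriv[p1 + 1] >= deriv[p1]) p1 <- p1 + 1

  ## does growth resume after the derivative falls back? look for a second
  ## excursion above 25% of the global max after the first dies down
  after <- which(seq_len(n) > p1 & deriv < 0.1 * dmax)
  shiftIdx <- NA_integer_
  survived <- NA
  segStart <- 1L
  baseline <- mean(od[1:min(3, n)])
  if (length(after) > 0) {
    quiet <- after[1]
    resume <- which(seq_len(n) > quiet & deriv > 0.25 * dmax)
    dipObserved <- any(deriv[quiet:n] < -0.02 * dmax)
    if (length(resume) > 0) {
      ## two-phase curve: shift = argmin of the derivative between phases
      between <- quiet:(resume[1])
      shiftIdx <- between[which.min(deriv[between])]
      survived <- TRUE
      segStart <- shiftIdx
      baseline <- min(s[quiet:resume[1]])
    } else if (dipObserved) {
      ## dip followed by plateau: did not survive the diauxic shift
      survived <- FALSE
      return(list(lag_min = NA_real_, max_rate_per_h = NA_real_,
                  diauxic_shift_min = tt[quiet], diauxic_survived = FALSE,
                  no_growth = FALSE))
    }
    ## else: single-phase saturation, analyse whole curve
  }

  ## stationary phase: terminal run of near-zero smoothed log-slope
  logs <- log(pmax(s, 1e-6))
  lslope <- c(NA, diff(logs) / diff(tt))
  lslope[1] <- lslope[2]
  maxLs <- max(lslope[segStart:n], na.rm = TRUE)
  segEnd <- n
  below <- lslope < stationary_frac * maxLs
  ## find the smallest j >= segStart such that below[j..n] is all TRUE
  run <- rev(cumprod(rev(below[segStart:n])))
  if (any(run == 1)) {
    j <- segStart + which(run == 1)[1] - 1L
    segEnd <- max(j, segStart + slope_window)
  }
  segEnd <- min(segEnd, n)

  ## sliding-window log-OD slopes within the segment
  Khat <- max(s)                          # stationary / carrying capacity
  wins <- list()
  idx <- segStart:segEnd
  if (length(idx) < slope_window)
    idx <- segStart:min(n, segStart + slope_window)
  for (i0 in idx[seq_len(max(1, length(idx) - slope_window + 1))]) {
    w <- i0:(i0 + slope_window - 1L)
    if (max(w) > n) break
    y <- od[w]
    if (any(y <= baseline * 0.5) || any(y <= 0)) next
    fit <- lm(log(y) ~ tt[w])
    tmid <- mean(tt[w])
    wins[[length(wins) + 1L]] <- list(slope = coef(fit)[[2]],  # per minute
                                      a = coef(fit)[[1]], midOd = mean(y),
                                      tmid = tmid,
                                      logmid = coef(fit)[[1]] +
                                        coef(fit)[[2]] * tmid)
  }
  if (length(wins) == 0)
    return(list(lag_min = NA_real_, max_rate_per_h = NA_real_,
                diauxic_shift_min = if (is.na(shiftIdx)) NA_real_
                                    else tt[shiftIdx],
                diauxic_survived = survived, no_growth = TRUE))
  slopes <- vapply(wins, `[[`, 0, "slope")
  midOds <- vapply(wins, `[[`, 0, "midOd")
  tmids <- vapply(wins, `[[`, 0, "tmid")
  logmids <- vapply(wins, `[[`, 0, "logmid")
  ## capacity-corrected per-window rates; the maximum specific rate is
  ## estimated as the median over the exponential core (windows clearly
  ## above the baseline, well below saturation, and within 2x of the best
  ## corrected slope), which is robust to the max-statistic noise bias of a
  ## plain maximal window slope
  corr <- 1 - pmin(midOds / Khat, 0.95)
  rw <- slopes / corr
  valid <- midOds >= 1.3 * baseline & midOds / Khat <= 0.5 & slopes > 0
  if (!any(valid)) valid <- slopes > 0
  if (!any(valid))
    return(list(lag_min = NA_real_, max_rate_per_h = NA_real_,
                diauxic_shift_min = if (is.na(shiftIdx)) NA_real_
                                    else tt[shiftIdx],
                diauxic_survived = survived, no_growth = TRUE))
  core <- valid & rw >= 0.5 * max(rw[valid])
  rate <- median(rw[core])

  ## lag: where the fitted logistic leaves the pre-shift baseline.  Each
  ## window's fitted OD is inverted through the logistic solution
  ## t - lag = (1/r) log[ od (K - B) / (B (K - od)) ], which reduces to the
  ## tangent-baseline intercept in the early-exponential limit; the median
  ## over the exponential-core windows is reported
  lagWins <- which(core)
  odm <- pmin(exp(logmids[lagWins]), 0.95 * Khat)
  lam <- tmids[lagWins] -
    (log(odm) - log(baseline) + log(Khat - baseline) - log(Khat - odm)) /
    rate
  lag <- median(lam)
  list(lag_min = as.numeric(lag),
       max_rate_per_h = as.numeric(rate * 60),
       diauxic_shift_min = if (is.na(shiftIdx)) NA_real_ else tt[shiftIdx],
       diauxic_survived = survived,
       no_growth = FALSE)
}

#' Assign a stress group from growth phenotypes
#'
#' Applies the screen's grouping rules: group 4 if the strain did not survive
#' the diauxic shift; group 1 if its lag is within \code{negligible_lag_min}
#' (20 min) of the wild-type lag; group 2 if the excess lag is at most
#' \code{mild_severe_cutoff_min}; group 3 otherwise.  The boundary between a
#' mild (group 2) and a severe (group 3) lag is a configuration choice with
#' no asserted default provenance.
#'
#' @param phenotype,wt_phenotype lists from \code{\link{growthMetrics}}
#'   (need \code{lag_min} and \code{diauxic_survived}); both phenotypes must
#'   come from the same media and protocol.
#' @param mild_severe_cutoff_min excess-lag boundary between groups 2 and 3.
#' @param negligible_lag_min group-1 boundary (20 min).
#' @return integer group label in 1..4.
#' @export
assignGroup <- function(phenotype, wt_phenotype,
                        mild_severe_cutoff_min = 240,
                        negligible_lag_min = 20) {
  .check(!is.null(wt_phenotype$lag_min) && is.finite(wt_phenotype$lag_min),
         "input error: missing WT reference phenotype")
  if (isFALSE(phenotype$diauxic_survived)) return(4L)
  excess <- phenotype$lag_min - wt_phenotype$lag_min
  if (excess <= negligible_lag_min) return(1L)
  if (excess <= mild_severe_cutoff_min) return(2L)
  3L
}

#' Earliest late-collection time matching the wild-type density
#'
#' The screen's scheduling rule for the late timepoint: growth-delayed
#' strains are collected at the earliest time their OD reaches at least
#' \code{frac} (90 percent) of the average wild-type OD at 24 h.
#'
#' @param curve data.frame with \code{time_min} and \code{od600}.
#' @param wt_od_24h average wild-type OD600 at the 24 h timepoint (> 0).
#' @param frac fraction of the WT OD to reach.
#' @return collection time in hours, or \code{NA} if the threshold is never
#'   reached within the observed window.
#' @export
scheduleLateCollection <- function(curve, wt_od_24h, frac = 0.9) {
  .check(wt_od_24h > 0, "wt_od_24h must be positive")
  hit <- which(curve$od600 >= frac * wt_od_24h)
  if (length(hit) == 0) return(NA_real_)
  curve$time_min[hit[1]] / 60
}
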