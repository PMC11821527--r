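featureRow <- function(id = "f1", intensity = 1e7, width = 0.3, snr = 10,
                       blank = 1e5, qc = 12, mz = 800, rt = 10) {
  data.frame(feature_id = id, mz = mz, rt_min = rt, peak_width_min = width,
             snr = snr, blank_area = blank, qc_cv_percent = qc,
             area_s1 = intensity, area_s2 = intensity * 0.9)
}

test_that("feature filters apply the exclusion chain with first-failure reasons", {
  feats <- rbind(
    featureRow("pass"),
    featureRow("low_int", intensity = 1.5e6),
    featureRow("wide", width = 0.80),
    featureRow("noisy", snr = 1.4),
    featureRow("blank_high", blank = 5e6),
    featureRow("qc_bad", qc = 30))
  out <- filterFeatureTable(feats)
  expect_identical(out$kept$feature_id, "pass")
  expect_identical(out$removed$reason,
                   c("intensity", "width", "snr", "blank", "qc_cv"))
  ## kept + removed partition the input, order-independently
  expect_setequal(c(out$kept$feature_id, out$removed$feature_id),
                  feats$feature_id)
  shuf <- feats[sample(nrow(feats)), ]
  out2 <- filterFeatureTable(shuf)
  expect_setequal(out2$kept$feature_id, out$kept$feature_id)

  ## boundary values: thresholds are inclusive keeps except QC CV
  bnd <- rbind(featureRow("at_int", intensity = 2e6),
               featureRow("at_width", width = 0.75),
               featureRow("at_snr", snr = 1.5),
               featureRow("at_blank", intensity = 6e6, blank = 2e6),
               featureRow("at_qc", qc = 30))
  outB <- filterFeatureTable(bnd)
  expect_setequal(outB$kept$feature_id,
                  c("at_int", "at_width", "at_snr", "at_blank"))
  expect_identical(outB$removed$reason, "qc_cv")

  ## metabolomics preset lowers the intensity floor to 5e4
  met <- featureRow("m", intensity = 1e5, blank = 1e4)
  expect_equal(nrow(filterFeatureTable(met, preset = "metabolomics")$kept), 1)
  expect_equal(nrow(filterFeatureTable(met)$kept), 0)

  ## empty input gives empty output
  empty <- filterFeatureTable(feats[0, ])
  expect_equal(nrow(empty$kept), 0)
})

test_that("label counts follow the class chain model", {
  expect_equal(expectedLabelCount("TAG"), 3)
  expect_equal(expectedLabelCount("CL"), 4)
  expect_equal(expectedLabelCount("PC"), 2)
  expect_equal(expectedLabelCount("PE"), 2)
  expect_equal(expectedLabelCount(lipidSpecies("TAG", 54, 3)), 3)
  expect_equal(expectedLabelCount("CL", labels_per_chain = 2), 8)
  expect_error(expectedLabelCount("XYZ"), "class-model error")
  expect_error(lipidSpecies("TAG", 5, 0), "total_carbons")
})

test_that("isotopologue m/z shifts are exact multiples of the 13C mass difference", {
  base <- 885.55
  expect_equal(isotopologueMz(base, 0), base)
  for (k in 1:4)
    expect_equal(isotopologueMz(base, k) - base, k * 1.0033548,
                 tolerance = 1e-12)
  ## additive: shift(k1+k2) = shift(k1) + shift(k2)
  s <- function(k) isotopologueMz(base, k) - base
  expect_equal(s(5), s(2) + s(3), tolerance = 1e-12)
  ## strictly increasing in k
  expect_true(all(diff(isotopologueMz(base, 0:6)) > 0))
  expect_error(isotopologueMz(base, -1), "input error")
})

test_that("peak-target matching respects ppm and rt tolerances, one-to-one", {
  tg <- data.frame(species = c("A", "B"), mz = c(885.5500, 905.6000),
                   rt_min = c(10, 12))
  feats <- data.frame(feature_id = c("f1", "f2", "f3"),
                      mz = c(885.5560, 885.5600, 905.6000),
                      rt_min = c(10.1, 10.1, 12))
  out <- matchLabeledPeaks(feats, tg)
  ## 6.8 ppm matches, 11.3 ppm does not, exact matches
  expect_identical(out$assignments$feature_id, c("f3", "f1"))
  expect_identical(out$unmatched, "f2")
  expect_equal(out$assignments$ppm_error[out$assignments$feature_id == "f1"],
               6.8, tolerance = 0.05)
  ## rt outside 0.4 min blocks a mass match
  farRt <- data.frame(feature_id = "f4", mz = 885.5500, rt_min = 11)
  expect_equal(nrow(matchLabeledPeaks(farRt, tg)$assignments), 0)
  ## injective onto targets: two candidate features, one target
  two <- data.frame(feature_id = c("g1", "g2"), mz = c(885.5501, 885.5503),
                    rt_min = c(10, 10))
  outT <- matchLabeledPeaks(two, tg[1, ])
  expect_equal(nrow(outT$assignments), 1)
  expect_identical(outT$assignments$feature_id, "g1")
  ## colliding targets raise an ambiguity warning
  dupT <- data.frame(species = c("A", "A2"), mz = c(885.5500, 885.5501),
                     rt_min = c(10, 10))
  expect_warning(matchLabeledPeaks(feats, dupT), "ambiguous")
})

test_that("internal-standard normalization is plain scale-invariant division", {
  expect_equal(normalizeToStandard(1e7, 2e6), 5)
  expect_equal(normalizeToStandard(0, 2e6), 0)
  expect_equal(normalizeToStandard(3 * 1e7, 3 * 2e6),
               normalizeToStandard(1e7, 2e6))
  expect_error(normalizeToStandard(1, 0), "normalization error")
})

test_that("mobilization kinetics recover T0-relative decay", {
  ## all timepoints at the T0 mean: t0_relative 1, rate 0
  flat <- data.frame(condition = "WT",
                     timepoint_h = rep(c(0, 1, 3, 5), each = 2),
                     replicate = rep(1:2, 4), normalized_abundance = 2)
  mk <- mobilizationKinetics(flat)
  expect_true(all(mk$measurements$t0_relative == 1))
  expect_equal(mk$rates$rate_per_h, 0, tolerance = 1e-12)

  ## the percent-lower comparison form
  expect_equal(percentLower(0.57, 1.0), 43)

  ## seeded recovery at n = 3 of a 3-hour half-life
  est <- vapply(1:40, function(s) {
    sm <- simulateLabeledPeaks(seed = s,
                               decay_rate_per_h = c(WT = log(2) / 3))
    mobilizationKinetics(labeledMeasurements(sm))$rates$rate_per_h
  }, numeric(1))
  expect_equal(mean(est), log(2) / 3, tolerance = 0.1)

  expect_error(mobilizationKinetics(
    data.frame(condition = "x", timepoint_h = 1, replicate = 1,
               normalized_abundance = 1)), "kinetics error")
})
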