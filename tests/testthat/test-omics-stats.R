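test_that("imputation draws from the down-shifted normal law per column", {
  ## column without missing values returned unchanged
  m <- matrix(rnorm(40, 20, 2), 20, 2)
  expect_identical(imputeMissing(m, seed = 1), m)

  ## Monte-Carlo check of the Normal(mean - 1.8 sd, (0.3 sd)^2) law
  obs <- rnorm(2000, mean = 20, sd = 2)
  mu <- mean(obs); sg <- sd(obs)
  col <- c(obs, rep(NA_real_, 2e4))
  imp <- imputeMissing(cbind(col), seed = 7)[-seq_along(obs), 1]
  expect_equal(mean(imp), mu - 1.8 * sg, tolerance = 0.02)
  expect_equal(sd(imp), 0.3 * sg, tolerance = 0.02)

  ## deterministic given the seed; observed values untouched
  imp2 <- imputeMissing(cbind(col), seed = 7)
  expect_identical(cbind(col)[seq_along(obs), 1], imp2[seq_along(obs), 1])
  expect_identical(imp, imp2[-seq_along(obs), 1])

  ## entirely-missing column is an error naming the column
  bad <- matrix(c(1, 2, NA, NA), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(imputeMissing(bad, seed = 1), "b")
})

test_that("log2 fold changes match Student's t-test and are antisymmetric", {
  set.seed(11)
  m <- matrix(rnorm(60, 20), 10, 6,
              dimnames = list(sprintf("m%02d", 1:10), NULL))
  fc <- log2FoldChanges(m, case = 1:3, ref = 4:6)
  ## cross-check each molecule against stats::t.test(var.equal = TRUE)
  for (i in 1:10) {
    tt <- t.test(m[i, 1:3], m[i, 4:6], var.equal = TRUE)
    expect_equal(fc$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(fc$log2_fc[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  ## antisymmetry: swapping case/ref negates FC, preserves p
  rev_fc <- log2FoldChanges(m, case = 4:6, ref = 1:3)
  expect_equal(rev_fc$log2_fc, -fc$log2_fc, tolerance = 1e-12)
  expect_equal(rev_fc$p_value, fc$p_value, tolerance = 1e-12)

  ## self-comparison: FC 0, p 1
  self <- log2FoldChanges(m, case = 1:3, ref = 1:3)
  expect_true(all(self$log2_fc == 0))
  expect_true(all(self$p_value == 1))

  ## forced means with zero variance: FC exact, degenerate flag, smallest p
  z <- rbind(a = c(5, 5, 5, 4, 4, 4))
  zz <- log2FoldChanges(z, case = 1:3, ref = 4:6)
  expect_equal(zz$log2_fc, 1)
  expect_true(zz$degenerate)
  expect_equal(zz$p_value, .Machine$double.xmin)

  ## fewer than 2 replicates is a statistics error
  expect_error(log2FoldChanges(m, case = 1, ref = 4:6), "statistics error")
})

test_that("significance rule uses strict |FC| > 0.7 and P < 0.05", {
  rec <- data.frame(log2_fc = c(0.8, 0.7, -0.71, 0.9, 0.1),
                    p_value = c(0.01, 0.001, 0.049, 0.05, 0.001))
  out <- classifySignificant(rec)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$direction, c("up", "none", "down", "none", "none"))
})

test_that("Fisher enrichment p-values are exact", {
  ## 2 mito both changed, 2 non-mito unchanged: one-sided p = 1/6
  rec <- data.frame(molecule_id = c("a", "b", "c", "d"),
                    significant = c(TRUE, TRUE, FALSE, FALSE),
                    direction = c("down", "down", "none", "none"))
  one <- mitoEnrichment(rec, c("a", "b"), "down", alternative = "greater")
  expect_equal(enrichmentPValue(one), 1 / 6, tolerance = 1e-12)
  two <- mitoEnrichment(rec, c("a", "b"), "down")
  expect_equal(enrichmentPValue(two), oracleFisherTwoSided(
    enrichmentTable(two)), tolerance = 1e-12)
  expect_equal(enrichmentOddsRatio(two), Inf)

  ## equal proportions give odds ratio 1
  rec2 <- data.frame(molecule_id = letters[1:8],
                     significant = rep(c(TRUE, FALSE), 4),
                     direction = rep(c("down", "none"), 4))
  eq <- mitoEnrichment(rec2, letters[1:4], "down")
  expect_equal(enrichmentOddsRatio(eq), 1)

  ## random tables agree with stats::fisher.test and the enumeration oracle
  set.seed(2)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 4), 2)
    p <- mitoscreen:::.fisherP(tb)
    expect_equal(p, fisher.test(tb)$p.value, tolerance = 1e-12)
    expect_equal(p, oracleFisherTwoSided(tb), tolerance = 1e-12)
  }

  expect_error(mitoEnrichment(rec[0, ], character(0), "down"),
               "input error")
})

test_that("condition mean FCs are consistent with per-condition records", {
  sim <- makeTinyScreen(seed = 12)
  se <- imputeMissing(sim$experiment, seed = 12)
  ref <- selectSamples(se, group = "WT", timepoint = "E")
  fc <- conditionMeanFC(se, ref)
  expect_equal(unname(fc[, "WT_E"]), rep(0, nrow(se)))
  cond <- conditionOf(se)
  for (cl in c("g3a_E", "g2b_L")) {
    rec <- log2FoldChanges(se, case = cond == cl, ref = ref)
    expect_equal(unname(fc[, cl]), rec$log2_fc, tolerance = 1e-12)
  }
})

test_that("strain clustering recovers planted groups and is permutation invariant", {
  ## low-noise synthetic screen, experimental strains at E: the four planted
  ## stress groups come back exactly (adjusted Rand = 1)
  cfg <- screenSimConfig(noise_sd = 0.01, missing_rate = 0,
                         strain_severity_sd = 0.05, axis_jitter_sd = 0.05,
                         seed = 6)
  sim <- simulateScreen(cfg)
  fc <- conditionMeanFC(sim$experiment)
  eCols <- intersect(colnames(fc),
                     paste0(c("g1a", "g1b", "g2a", "g2b", "g3a", "g3b",
                              "g3c", "g4a"), "_E"))
  cl <- clusterStrains(fc[, eCols], n_clusters = 4)
  planted <- c(1, 1, 2, 2, 3, 3, 3, 4)
  expect_equal(adjustedRand(clusterLabels(cl), planted), 1)

  ## permuting condition columns leaves the flat partition unchanged
  perm <- sample(eCols)
  cl2 <- clusterStrains(fc[, perm], n_clusters = 4)
  expect_equal(adjustedRand(clusterLabels(cl)[eCols],
                            clusterLabels(cl2)[eCols]), 1)

  ## two identical columns merge first at height 0
  m <- cbind(a = rnorm(20), b = rnorm(20))
  m <- cbind(m, c = m[, "a"])
  rownames(m) <- paste0("x", 1:20)
  cl3 <- clusterStrains(m, n_clusters = 2)
  expect_equal(clusterTree(cl3)$height[1], 0)
  expect_equal(clusterLabels(cl3)[["a"]], clusterLabels(cl3)[["c"]])

  ## constant rows dropped with a warning
  m2 <- rbind(m, const = c(1, 1, 1))
  expect_warning(clusterStrains(m2, n_clusters = 2), "constant")
})

test_that("delta-delta-Ct returns 2^-ddCt", {
  expect_equal(deltaDeltaCt(15, 15, 15, 15), 1)
  expect_equal(deltaDeltaCt(14, 10, 15, 10), 2)   # ddCt = -1
  expect_equal(deltaDeltaCt(20, 10, 18, 10), 0.25)
  expect_error(deltaDeltaCt(NA, 1, 1, 1), "finite")
})
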