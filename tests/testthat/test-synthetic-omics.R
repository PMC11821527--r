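test_that("identical seed and config give byte-identical screens", {
  a <- simulateScreen(screenSimConfig(seed = 9))
  b <- simulateScreen(screenSimConfig(seed = 9))
  expect_identical(SummarizedExperiment::assay(a$experiment),
                   SummarizedExperiment::assay(b$experiment))
  expect_identical(a$truth$effects, b$truth$effects)
  c <- simulateScreen(screenSimConfig(seed = 10))
  expect_false(identical(SummarizedExperiment::assay(a$experiment),
                         SummarizedExperiment::assay(c$experiment)))
})

test_that("zero-noise condition means equal the planted effects exactly", {
  cfg <- screenSimConfig(n_proteins = 40, n_lipids = 20, n_metabolites = 8,
                         n_tag_species = 6, n_cl_species = 2,
                         noise_sd = 1e-12, missing_rate = 0, seed = 4)
  sim <- simulateScreen(cfg)
  fc <- conditionMeanFC(sim$experiment)
  ## baselines cancel; condition means minus WT_E reference = planted theta
  expect_equal(unname(fc), unname(sim$truth$effects), tolerance = 1e-6)
})

test_that("planted TAG depletion is recovered within the CLT bound", {
  ## controlled config: severity/axis multipliers off so the planted group
  ## effect is the exact per-strain effect
  cfg <- screenSimConfig(strain_severity_sd = 0, axis_jitter_sd = 0,
                         noise_sd = 0.2, missing_rate = 0, seed = 21)
  sim <- simulateScreen(cfg)
  se <- sim$experiment
  fc <- conditionMeanFC(se)
  tagRows <- sim$truth$tag_ids
  g3e <- intersect(colnames(fc), c("g3a_E", "g3b_E", "g3c_E"))
  mfc <- mean(fc[tagRows, g3e])
  n <- length(tagRows) * length(g3e) * 3
  expect_lt(abs(mfc - (-1.5)), 3 * cfg$noise_sd / sqrt(n) + 0.05)
})

test_that("missingness targets the protein layer at the requested rate, at low abundance", {
  cfg <- screenSimConfig(missing_rate = 0.1, seed = 3)
  sim <- simulateScreen(cfg)
  vals <- SummarizedExperiment::assay(sim$experiment)
  prot <- moleculeLayer(sim$experiment) == "protein"
  expect_lt(abs(mean(is.na(vals[prot, ])) - 0.1), 0.02)
  expect_false(anyNA(vals[!prot, ]))
  ## missing entries sit at low planted baseline abundance
  baseMissing <- sim$truth$baseline[prot][rowSums(is.na(vals[prot, ])) > 0]
  baseFull <- sim$truth$baseline[prot][rowSums(is.na(vals[prot, ])) == 0]
  expect_lt(mean(baseMissing), mean(baseFull))
  ## the planted correlate is always quantified
  expect_false(anyNA(vals["prot_pln_like", ]))
})

test_that("generated matrices pass the validation reader", {
  sim <- makeTinyScreen(seed = 8)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeAbundanceMatrix(sim$experiment, p)
  expect_s4_class(readAbundanceMatrix(p), "ScreenExperiment")
})

test_that("replicate count below 2 is a configuration error", {
  expect_error(screenSimConfig(n_replicates = 1), "n_replicates")
})

test_that("labeled-peak generator obeys its closed-form decay", {
  ## decay 0: T5/T0 ratio is 1 within noise
  s0 <- simulateLabeledPeaks(decay_rate_per_h = c(WT = 0), seed = 5)
  m0 <- labeledMeasurements(s0)
  r0 <- mean(m0$normalized_abundance[m0$timepoint_h == 5]) /
    mean(m0$normalized_abundance[m0$timepoint_h == 0])
  expect_equal(r0, 1, tolerance = 0.15)
  ## half-life 3 h: T3/T0 close to 0.5
  s1 <- simulateLabeledPeaks(decay_rate_per_h = c(WT = log(2) / 3), seed = 5)
  m1 <- labeledMeasurements(s1)
  r1 <- mean(m1$normalized_abundance[m1$timepoint_h == 3]) /
    mean(m1$normalized_abundance[m1$timepoint_h == 0])
  expect_equal(r1, 0.5, tolerance = 0.1)
  ## determinism
  s2 <- simulateLabeledPeaks(decay_rate_per_h = c(WT = log(2) / 3), seed = 5)
  expect_identical(s1$features, s2$features)
})

test_that("image-stack generator plants cells and organelles as stated", {
  sim <- simulateImageStack(n_cells = 2, a_um = 4, b_um = 2.5,
                            organelle_fraction = c(0, 0.04),
                            blob_radius_vox = 6, seed = 2)
  ## fraction 0 cell has no organelle voxels in its half of the stack
  nx <- dim(sim$organelle_truth)[3]
  expect_equal(sum(sim$organelle_truth[, , 1:(nx / 2)]), 0)
  expect_gt(sum(sim$organelle_truth), 0)
  expect_equal(sim$truth$true_fraction[1], 0)
  expect_equal(sim$truth$true_fraction[2], 0.04, tolerance = 0.25)
  ## probability map is a clipped blur of the truth
  expect_true(all(sim$organelle_map >= 0 & sim$organelle_map <= 1))
  ## spherical cell volume in the truth table
  simSph <- simulateImageStack(n_cells = 1, a_um = 3, b_um = 3,
                               organelle_fraction = 0, seed = 1)
  expect_equal(simSph$truth$v_cell_um3, 4 / 3 * pi * 27, tolerance = 1e-10)
})
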