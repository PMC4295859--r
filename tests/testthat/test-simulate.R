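test_that("generators are deterministic given the seed", {
  d <- acuteDesign(n_genes = 60, n_trend_genes = 5, seed = 3,
                   replicates_per_group = 1,
                   hybridizations_per_specimen = 2)
  s1 <- simulateAcute(d); s2 <- simulateAcute(d)
  expect_identical(exprsValues(s1$experiment), exprsValues(s2$experiment))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateAcute(acuteDesign(n_genes = 60, n_trend_genes = 5,
                                  seed = 4, replicates_per_group = 1,
                                  hybridizations_per_specimen = 2))
  expect_false(identical(exprsValues(s1$experiment),
                         exprsValues(s3$experiment)))

  dc <- chronicDesign(n_genes = 40, n_affected_genes = 4, seed = 5)
  expect_identical(exprsValues(simulateChronic(dc)$experiment),
                   exprsValues(simulateChronic(dc)$experiment))

  dp <- plasmaDesign(n_patients = 8, seed = 6)
  expect_identical(panelMeasurements(simulatePlasma(dp)$panel),
                   panelMeasurements(simulatePlasma(dp)$panel))

  expect_identical(geneSets(simulateGeneSets(10, c(3, 6), 50, seed = 7)),
                   geneSets(simulateGeneSets(10, c(3, 6), 50, seed = 7)))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulateAcute(acuteDesign(n_genes = 20, n_trend_genes = 2,
                                      replicates_per_group = 1,
                                      hybridizations_per_specimen = 1,
                                      seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("acute design invariants are enforced", {
  expect_error(acuteDesign(n_genes = 0), "invalid design")
  expect_error(acuteDesign(n_trend_genes = 20, n_genes = 10),
               "invalid design")
  expect_error(acuteDesign(dose_scores = c(2, 1, 3)), "increasing")
  expect_error(acuteDesign(replicates_per_group = 0), "invalid design")
  expect_error(chronicDesign(replicates_per_arm = 1), "invalid design")
  expect_error(simulateGeneSets(5, c(10, 4), 50), "non-empty")
  expect_error(simulateGeneSets(5, c(2, 100), 50), "within")
})

test_that("acute output has the declared design shape and truth table", {
  d <- acuteDesign(n_genes = 50, n_trend_genes = 7, dose_scores = c(1, 2, 3),
                   time_points_h = c(6, 24, 48), replicates_per_group = 2,
                   hybridizations_per_specimen = 4, seed = 11)
  sim <- simulateAcute(d)
  expect_equal(ncol(sim$experiment), 3 * 3 * 2 * 4)
  expect_equal(nrow(sim$truth), 7)
  avg <- averageHybridizations(sim$experiment)
  expect_equal(ncol(avg), 3 * 3 * 2)
  # spiked gene group means rise (or fall) by the effect per dose step
  cd <- designInfo(avg)
  mat <- exprsValues(avg)
  g <- sim$truth$gene[1]
  sgn <- if (sim$truth$direction[1] == "up") 1 else -1
  m <- tapply(mat[g, ], cd$dose_score, mean)
  expect_equal(as.vector(sgn * diff(m) > 0.3), c(TRUE, TRUE))
})

test_that("zero effect leaves spiked genes null-distributed", {
  d <- acuteDesign(n_genes = 400, n_trend_genes = 40, effect_size_log2 = 0,
                   replicates_per_group = 2,
                   hybridizations_per_specimen = 1, seed = 21)
  sim <- simulateAcute(d)
  tab <- trendTable(acuteSigmaZ(sim$experiment))
  spike <- tab$sigma_Z[tab$gene %in% sim$truth$gene]
  # mean of 40 null composites (variance ~ 3) within 3 standard errors
  expect_lt(abs(mean(spike)), 3 * sqrt(3 / 40))
})

test_that("spiked-trend recovery: regression case and monotonicity", {
  recovery <- function(effect, seed) {
    d <- acuteDesign(n_genes = 500, n_trend_genes = 25,
                     effect_size_log2 = effect, noise_sd_log2 = 0.5,
                     replicates_per_group = 2, seed = seed)
    sim <- simulateAcute(d)
    tr <- acuteSigmaZ(averageHybridizations(sim$experiment))
    gl <- geneLists(topKLists(tr, k = 50, setting = "x"))[[1]]
    sum(mapply(function(g, dd) any(gl$gene == g & gl$direction == dd),
               sim$truth$gene, sim$truth$direction))
  }
  expect_gte(recovery(1.0, 7), 22)
  expect_gte(recovery(1.0, 7), recovery(0.25, 7))
})

test_that("chronic generator: empty truth and null p-value uniformity", {
  sim0 <- simulateChronic(chronicDesign(n_genes = 30,
                                        n_affected_genes = 0, seed = 2))
  expect_equal(nrow(sim0$truth), 0)

  simNull <- simulateChronic(chronicDesign(n_genes = 5000,
                                           n_affected_genes = 0,
                                           replicates_per_arm = 4,
                                           effect_size_log2 = 0, seed = 3))
  p <- trendTable(chronicTTest(simNull$experiment))$p_value
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("plasma generator honours missingness, medians and the copula", {
  full <- simulatePlasma(plasmaDesign(n_patients = 10, missing_rate = 0,
                                      seed = 4))$panel
  m <- panelMeasurements(full)
  expect_equal(nrow(m), 10 * 9 * 3)

  # median recovery at large n: per-time-point median ratio near truth
  big <- simulatePlasma(plasmaDesign(n_patients = 400, missing_rate = 0,
                                     seed = 5))
  sm <- summarizeTimecourse(big$panel, "GDF-15")
  truthRatio <- big$truth$course_multipliers["GDF-15", ]
  estRatio <- sm$median / sm$median[sm$timepoint == "c1d1"]
  expect_true(all(abs(estRatio / truthRatio - 1) < 0.15))

  # latent rho 0.9 recovered through Spearman within 0.1
  hi <- simulatePlasma(plasmaDesign(n_patients = 400, missing_rate = 0,
                                    cross_marker_rho = 0.9, seed = 6))$panel
  r <- correlateMarkers(hi, "GDF-15", "vWF", "c1d8")
  expect_lt(abs(r$rho - 0.9), 0.1)

  expect_error(plasmaDesign(markers = c("GDF-15", "mystery")), "unknown")
  expect_error(plasmaDesign(missing_rate = 1), "missing_rate")
  expect_error(plasmaDesign(cross_marker_rho = 1), "cross_marker_rho")
})

test_that("null plasma panel: baseline-change test rejects near 5%", {
  schedule <- plasmaDesign()$timepoint_labels
  d0 <- plasmaDesign(n_patients = 41,
                     course_multipliers = matrix(
                       1, 3, 9, dimnames = list(c("GDF-15", "vWF", "hsCRP"),
                                                schedule)),
                     cross_marker_rho = 0, missing_rate = 0, seed = 0)
  nrep <- 400
  rej <- vapply(seq_len(nrep), function(i) {
    d <- d0; d$seed <- 1000L + i
    panel <- simulatePlasma(d)$panel
    s <- summarizeTimecourse(panel, "GDF-15")
    s$p_vs_baseline[s$timepoint == "c1d8"] <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("gene-set catalog: planted set kept verbatim, sizes respected", {
  planted <- c("G00001", "G00007", "G00010")
  col <- simulateGeneSets(n_sets = 169, size_range = c(5, 20),
                          n_genes = 100, planted_set = planted, seed = 8)
  expect_equal(length(geneSets(col)), 170)
  expect_identical(geneSets(col)$PLANTED, planted)
  sz <- lengths(geneSets(col))[names(geneSets(col)) != "PLANTED"]
  expect_true(all(sz >= 5 & sz <= 20))
})
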