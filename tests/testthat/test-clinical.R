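mkPanel <- function(values, schedule = c("c1d1", "c1d8"),
                    markers = "GDF-15") {
  # values: named list patient -> vector over schedule x markers
  recs <- do.call(rbind, lapply(names(values), function(p) {
    v <- values[[p]]
    grid <- expand.grid(timepoint = schedule, marker = markers,
                        stringsAsFactors = FALSE)
    data.frame(patient_id = p, grid, value = v, unit = "u")
  }))
  recs <- recs[!is.na(recs$value), ]
  new("PlasmaPanel", measurements = S4Vectors::DataFrame(recs),
      patients = S4Vectors::DataFrame(
        data.frame(patient_id = names(values),
                   igcccg_group = rep(c("good", "poor"),
                                      length.out = length(values)))),
      schedule = schedule)
}

test_that("signed-rank test: all-positive worked example and symmetry", {
  res <- pairedSignedRank(rep(1, 6), c(2, 3, 2.5, 4, 2.2, 5))
  expect_equal(res$p.value, 2 / 64)
  expect_equal(res$n_nonzero, 6)

  sym <- pairedSignedRank(c(0, 0, 0, 0, 0, 0), c(1, -1, 2, -2, 3, -3))
  expect_equal(sym$p.value, 1)

  expect_error(pairedSignedRank(c(1, 2), c(1, 2)), "zero")
})

test_that("signed-rank test matches exhaustive sign-flip enumeration", {
  set.seed(26)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    base <- rnorm(n)
    fol <- base + rnorm(n)
    p <- pairedSignedRank(base, fol)$p.value
    expect_equal(p, signedRankExact(fol - base), tolerance = 1e-12)
  }
})

test_that("rank-sum test: worked example and exhaustive enumeration", {
  mw <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 0.1)

  set.seed(27)
  for (i in 1:30) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(wilcoxonRankSum(x, y)$p.value, rankSumExact(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "non-empty")
})

test_that("time-course summary: medians, ranges and baseline tests", {
  set.seed(28)
  vals <- setNames(lapply(1:9, function(i) c(i, i + 10)),
                   paste0("P", 1:9))
  panel <- mkPanel(vals)
  s <- summarizeTimecourse(panel, "GDF-15")
  expect_equal(s$median, c(5, 15))
  expect_equal(s$min, c(1, 11))
  expect_equal(s$max, c(9, 19))
  expect_equal(s$n, c(9, 9))
  expect_true(is.na(s$p_vs_baseline[1]))

  # distinct all-positive differences: exact two-sided p = 2 / 2^9
  vals2 <- setNames(lapply(1:9, function(i) c(i, 11 * i)), paste0("P", 1:9))
  s2 <- summarizeTimecourse(mkPanel(vals2), "GDF-15")
  expect_equal(s2$p_vs_baseline[2], 2 / 2^9)
  expect_true(s2$significant[2])

  # constant values: p = 1 by the zero-difference convention
  const <- mkPanel(setNames(lapply(1:5, function(i) c(3, 3)),
                            paste0("P", 1:5)))
  sc <- summarizeTimecourse(const, "GDF-15")
  expect_equal(sc$p_vs_baseline[2], 1)

  # single patient: test skipped with a warning
  one <- mkPanel(list(P1 = c(1, 2)))
  expect_warning(s1 <- summarizeTimecourse(one, "GDF-15"), "skipped")
  expect_true(is.na(s1$p_vs_baseline[2]))
})

test_that("summaries are invariant to patient order and panel doubling", {
  set.seed(29)
  vals <- setNames(lapply(1:7, function(i) rlnorm(2)), paste0("P", 1:7))
  p1 <- mkPanel(vals)
  p2 <- mkPanel(rev(vals))
  expect_equal(summarizeTimecourse(p1, "GDF-15")$median,
               summarizeTimecourse(p2, "GDF-15")$median)
  doubled <- mkPanel(c(vals, setNames(vals, paste0("Q", 1:7))))
  sD <- summarizeTimecourse(doubled, "GDF-15")
  expect_equal(sD$median, summarizeTimecourse(p1, "GDF-15")$median)
  expect_equal(sD$n, 2 * summarizeTimecourse(p1, "GDF-15")$n)
})

test_that("group comparison uses the metadata split and guards emptiness", {
  vals <- setNames(lapply(c(1, 2, 3, 10, 11, 12), function(v) c(v, v)),
                   paste0("P", 1:6))
  panel <- mkPanel(vals)  # P1,P3,P5 good; P2,P4,P6 poor
  res <- groupCompare(panel, "GDF-15", "c1d1", groupA = "good",
                      groupB = c("intermediate", "poor"))
  expect_equal(res$p.value,
               rankSumExact(c(1, 3, 11), c(2, 10, 12)))
  expect_match(res$summary_a, "n = 3")
  expect_error(groupCompare(panel, "GDF-15", "c1d1",
                            groupA = "intermediate", groupB = "poor"),
               "empty")
  expect_error(groupCompare(panel, "GDF-15", "nope"), "unknown timepoint")
})

test_that("marker correlation: monotone extremes and the pair guard", {
  sched <- "c1d1"
  pts <- paste0("P", 1:6)
  recs <- rbind(
    data.frame(patient_id = pts, timepoint = sched, marker = "A",
               value = 1:6, unit = "u"),
    data.frame(patient_id = pts, timepoint = sched, marker = "B",
               value = exp(1:6), unit = "u"),
    data.frame(patient_id = pts, timepoint = sched, marker = "C",
               value = 7 - (1:6), unit = "u"))
  panel <- new("PlasmaPanel", measurements = S4Vectors::DataFrame(recs),
               patients = S4Vectors::DataFrame(
                 data.frame(patient_id = pts)), schedule = sched)
  expect_equal(correlateMarkers(panel, "A", "B", "c1d1")$rho, 1)
  expect_equal(correlateMarkers(panel, "A", "C", "c1d1")$rho, -1)

  small <- new("PlasmaPanel",
               measurements = S4Vectors::DataFrame(recs[c(1:3, 7:9), ]),
               patients = S4Vectors::DataFrame(
                 data.frame(patient_id = pts)), schedule = sched)
  expect_error(correlateMarkers(small, "A", "B", "c1d1"), "4 complete")
})

test_that("correlation track composes per-time-point correlations", {
  sim <- simulatePlasma(plasmaDesign(n_patients = 60,
                                     cross_marker_rho = 0.6,
                                     missing_rate = 0, seed = 30))
  tr <- correlationTrack(sim$panel, "GDF-15", "vWF")
  expect_equal(nrow(tr), 9)
  expect_equal(tr$n, rep(60, 9))
  one <- correlateMarkers(sim$panel, "GDF-15", "vWF", "c2d1")
  expect_equal(tr$rho[tr$timepoint == "c2d1"], one$rho)
  expect_true(all(tr$rho > 0))
})
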