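test_that("running-sum score: leading single hit and hand enumeration", {
  m <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
  expect_equal(enrichmentScore(m, "a")$ES, 1)

  # set at the bottom two ranks, unweighted: three leading misses drive
  # the running sum to -1 before any hit
  es <- enrichmentScore(m, c("d", "e"), weightP = 0)
  expect_equal(es$ES, -1)
  expect_equal(es$runningSum,
               c(-1 / 3, -2 / 3, -1, -1 / 2, 0))

  expect_error(enrichmentScore(m, c("q", "r")), "no member")
  expect_error(enrichmentScore(m, names(m)), "whole ranking")
})

test_that("score properties: monotone invariance (p=0) and reversal", {
  set.seed(15)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    m <- setNames(rnorm(n), paste0("g", seq_len(n)))
    set <- sample(names(m), sample(2:(n - 2), 1))
    es0 <- enrichmentScore(m, set, weightP = 0)$ES
    # strictly monotone transform leaves ranks, hence ES at p=0, unchanged
    expect_equal(enrichmentScore(setNames(rank(m) / n, names(m)), set,
                                 weightP = 0)$ES, es0)
    # reversing the ranking negates ES (both weightings)
    for (p in c(0, 1)) {
      esf <- enrichmentScore(m, set, weightP = p)$ES
      esr <- enrichmentScore(-m, set, weightP = p)$ES
      expect_equal(esr, -esf, tolerance = 1e-12)
    }
  }
})

test_that("enrichment score agrees with step-by-step enumeration oracle", {
  set.seed(16)
  for (i in 1:50) {
    n <- sample(6:60, 1)
    m <- setNames(rnorm(n), paste0("g", seq_len(n)))
    set <- sample(names(m), sample(1:(n - 1), 1))
    for (p in c(0, 1))
      expect_equal(enrichmentScore(m, set, weightP = p)$ES,
                   esEnum(m, set, weightP = p), tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with the fgsea implementation", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    m <- setNames(sort(rnorm(n), decreasing = TRUE),
                  paste0("g", seq_len(n)))
    set <- sample(names(m), sample(3:10, 1))
    expect_equal(enrichmentScore(m, set, weightP = 1)$ES,
                 fgsea::calcGseaStat(m, which(names(m) %in% set),
                                     gseaParam = 1),
                 tolerance = 1e-9)
  }
})

test_that("tiny permutation test matches exhaustive label enumeration", {
  m <- setNames(c(2.0, 1.2, 0.7, -0.3, -1.1, -2.4), paste0("g", 1:6))
  set <- c("g1", "g2")
  # exact null over all choose(6,2) = 15 label choices
  combos <- combn(names(m), 2, simplify = FALSE)
  nullEs <- vapply(combos, function(s) enrichmentScore(m, s)$ES,
                   numeric(1))
  obs <- enrichmentScore(m, set)$ES
  pexact <- (sum(nullEs[nullEs >= 0] >= obs)) / sum(nullEs >= 0)

  col <- new("GeneSetCollection", sets = list(S = set),
             descriptions = c(S = ""))
  res <- gseaPermutation(m, col, nPerm = 4000, minSize = 2, seed = 18)
  tab <- enrichmentTable(res)
  expect_equal(tab$ES, obs, tolerance = 1e-12)
  expect_lt(abs(tab$p_nominal - pexact), 0.05)
})

test_that("permutation test is deterministic and direction-consistent", {
  set.seed(19)
  m <- setNames(rnorm(300), sprintf("G%05d", 1:300))
  col <- simulateGeneSets(n_sets = 12, size_range = c(5, 25),
                          n_genes = 300, seed = 20)
  r1 <- gseaPermutation(m, col, nPerm = 200, seed = 21)
  r2 <- gseaPermutation(m, col, nPerm = 200, seed = 21)
  expect_identical(enrichmentTable(r1), enrichmentTable(r2))
  tab <- enrichmentTable(r1)
  expect_true(all(abs(tab$ES) <= 1))
  expect_true(all(tab$fdr_q >= 0 & tab$fdr_q <= 1))
  expect_identical(tab$direction[tab$ES > 0],
                   rep("up", sum(tab$ES > 0)))

  expect_error(gseaPermutation(m, col, nPerm = 50, seed = 1), ">= 100")
  expect_error(gseaPermutation(setNames(rep(1, 300), names(m)), col,
                               seed = 1), "degenerate")
})

test_that("a planted top set satisfies the reporting rule", {
  set.seed(22)
  m <- setNames(sort(rnorm(200), decreasing = TRUE),
                sprintf("G%05d", 1:200))
  col <- simulateGeneSets(n_sets = 30, size_range = c(5, 30),
                          n_genes = 200, planted_set = names(m)[1:10],
                          seed = 23)
  res <- gseaPermutation(m, col, nPerm = 1000, seed = 24)
  rep_ <- reportEnriched(res, fdrMax = 0.10, pMax = 0.025)
  expect_true("PLANTED" %in% rep_$gene_set)
  expect_equal(rep_$direction[rep_$gene_set == "PLANTED"], "up")
})

test_that("reporting filter handles '<' bounds and empty input", {
  df <- data.frame(gene_set = c("A", "B", "C"),
                   direction = c("up", "down", "up"),
                   fdr = c("0.05", "<0.01", "0.2"),
                   p_value = c("0.003", "<0.0001", "0.001"))
  out <- reportEnriched(df)
  expect_setequal(out$gene_set, c("A", "B"))
  expect_equal(out$gene_set[1], "B")  # sorted by FDR
  expect_equal(nrow(reportEnriched(df[0, ])), 0)
})
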