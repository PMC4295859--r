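mkTrend <- function(genes, sigma) {
  n <- length(genes)
  tab <- S4Vectors::DataFrame(
    gene = genes, Z_t6 = sigma / 3, Z_t24 = sigma / 3, Z_t48 = sigma / 3,
    sigma_Z = sigma / 3 * 3, p_t6 = 0.5, p_t24 = 0.5, p_t48 = 0.5,
    rank = integer(n), direction = ifelse(sigma > 0, "up", "down"),
    degenerate = FALSE)
  ord <- order(-sigma, genes)
  tab$rank[ord] <- seq_len(n)
  new("TrendResult", table = tab, mode = "acute", scores = 1:3,
      timePoints = c(6, 24, 48))
}

test_that("acute top-k lists split k/2 up and k/2 down deterministically", {
  tr <- mkTrend(c("a", "b", "c"), c(5, -4, 1))
  gl <- geneLists(topKLists(tr, k = 2, setting = "x"))[[1]]
  expect_equal(gl$gene, c("a", "b"))
  expect_equal(gl$direction, c("up", "down"))

  # boundary ties broken lexicographically
  tr2 <- mkTrend(c("d", "b", "c", "a", "e", "f"),
                 c(2, 1, 1, -3, -2, 0.5))
  gl2 <- geneLists(topKLists(tr2, k = 2, setting = "x"))[[1]]
  expect_equal(gl2$gene[1:2], c("d", "a"))
  gl4 <- geneLists(topKLists(tr2, k = 4, setting = "x"))[[1]]
  expect_equal(gl4$gene[2], "b")  # b before c at equal statistic
  # overlapping halves are rejected rather than silently duplicated
  tr3 <- mkTrend(c("d", "b", "c", "a"), c(2, 1, 1, -3))
  expect_error(topKLists(tr3, k = 4, setting = "x"), "overlap")

  expect_error(topKLists(tr, k = 3, setting = "x"), "even")
  expect_error(topKLists(tr, k = 8, setting = "x"), "exceeds")
})

test_that("chronic top-k lists take the k smallest p-values", {
  tab <- S4Vectors::DataFrame(
    gene = c("a", "b", "c", "d"), t_statistic = c(5, -4, 1, 0.2),
    p_value = c(0.001, 0.002, 0.5, 0.9),
    p_bh = rep(1, 4), rank = 1:4,
    direction = c("up", "down", "up", "up"), degenerate = FALSE)
  tr <- new("TrendResult", table = tab, mode = "chronic",
            scores = numeric(0), timePoints = numeric(0))
  gl <- geneLists(topKLists(tr, k = 2, setting = "x"))[[1]]
  expect_equal(gl$gene, c("a", "b"))
  expect_equal(gl$direction, c("up", "down"))
})

test_that("overlap selection agrees with a brute-force set oracle", {
  set.seed(13)
  universe <- sprintf("g%02d", 1:30)
  for (rep in 1:200) {
    nl <- sample(2:5, 1)
    lists <- lapply(seq_len(nl), function(i) {
      g <- sample(universe, sample(3:10, 1))
      data.frame(gene = g,
                 direction = sample(c("up", "down"), length(g),
                                    replace = TRUE))
    })
    names(lists) <- paste0("L", seq_len(nl))
    m <- sample(2:nl, 1)
    rep_ <- overlapSelect(rankedGeneLists(lists), m = m)
    counts <- table(unlist(lapply(lists, function(l) unique(l$gene))))
    expect_setequal(candidateSet(rep_), names(counts)[counts >= m])
    # total membership equals total list length
    expect_equal(sum(membershipTable(rep_)$count),
                 sum(vapply(lists, nrow, 0L)))
    # pairwise sizes against naive intersections
    pw <- pairwiseOverlap(rep_)
    for (i in seq_len(nl)) for (j in seq_len(nl))
      expect_equal(unname(pw[i, j]),
                   length(intersect(lists[[i]]$gene, lists[[j]]$gene)))
  }
})

test_that("candidate sets shrink as the membership threshold grows", {
  set.seed(14)
  lists <- lapply(1:4, function(i)
    data.frame(gene = sample(sprintf("g%02d", 1:15), 8),
               direction = "up"))
  names(lists) <- paste0("L", 1:4)
  rgl <- rankedGeneLists(lists)
  sets <- lapply(2:4, function(m) candidateSet(overlapSelect(rgl, m = m)))
  expect_true(all(sets[[3 - 1]] %in% sets[[2 - 1]]))
  expect_true(all(sets[[4 - 2]] %in% sets[[3 - 2]]))

  same <- rankedGeneLists(list(A = lists[[1]], B = lists[[1]]))
  expect_setequal(candidateSet(overlapSelect(same, m = 2)),
                  lists[[1]]$gene)

  expect_error(overlapSelect(rankedGeneLists(list(A = lists[[1]])), 1),
               "at least 2")
  empty <- rankedGeneLists(list(A = lists[[1]],
                                B = lists[[1]][0, ]))
  expect_error(overlapSelect(empty, m = 2), "empty")
})

test_that("direction concordance: vacuous, concordant and discordant", {
  lists <- list(
    A = data.frame(gene = c("x", "y", "z"), direction = c("up", "up", "up")),
    B = data.frame(gene = c("x", "y"), direction = c("up", "down")))
  rgl <- rankedGeneLists(lists)
  rep_ <- overlapSelect(rgl, m = 2)
  cc <- directionConcordance(rep_, rgl)
  expect_true(cc$concordant[cc$gene == "x"])
  expect_false(cc$concordant[cc$gene == "y"])
  expect_true(cc$concordant[cc$gene == "z"])  # single list: vacuous
})
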