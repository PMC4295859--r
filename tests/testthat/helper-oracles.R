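# Independent brute-force oracles used across the suite. These never call
# package internals: they enumerate the relevant null distributions
# directly.

# all permutations of 1..n as an n! x n matrix (n <= 8)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# exact permutation distribution of T = sum(scores * permuted ranks)
cuzickExact <- function(values, scores) {
  n <- length(values)
  r <- rank(values)
  perms <- allPermutations(n)
  tdist <- as.vector(matrix(r[perms], nrow(perms), n) %*% scores)
  tobs <- sum(scores * r)
  m <- mean(tdist)
  v <- mean((tdist - m)^2)   # population variance over all n! layouts
  list(T = tobs, mean = m, var = v,
       p = mean(abs(tdist - m) >= abs(tobs - m) - 1e-9))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
signedRankExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vdist <- as.vector(signs %*% r)
  ev <- sum(r) / 2
  mean(abs(vdist - ev) >= abs(vobs - ev) - 1e-9)
}

# exact two-sided rank-sum p by enumerating all group assignments
rankSumExact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  wdist <- apply(combos, 2, function(idx) sum(r[idx]))
  ew <- nx * (nx + ny + 1) / 2
  mean(abs(wdist - ew) >= abs(wobs - ew) - 1e-9)
}

# step-by-step running-sum ES, written independently of the package
esEnum <- function(metric, set, weightP = 1) {
  ord <- order(metric, decreasing = TRUE)
  g <- names(metric)[ord]
  hit <- g %in% set
  w <- abs(metric[ord])^weightP
  rs <- 0; best <- 0
  inc <- w / sum(w[hit])
  dec <- 1 / sum(!hit)
  for (i in seq_along(g)) {
    rs <- rs + if (hit[i]) unname(inc[i]) else -dec
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# small gene-level acute experiment built by hand (no simulator)
tinyAcute <- function(values3tp, doses = c(1, 1, 2, 2, 3, 3)) {
  # values3tp: genes x 6 matrix reused at t = 6, 24, 48
  mat <- cbind(values3tp, values3tp, values3tp)
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  design <- data.frame(dose_score = rep(doses, 3),
                       time_h = rep(c(6, 24, 48), each = length(doses)))
  ExposureExperiment(mat, design, level = "gene")
}
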