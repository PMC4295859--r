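#' Cuzick rank test for linear trend across ordered groups
#'
#' Nonparametric test for a monotone trend in a response across ordered
#' exposure groups. Each observation j carries a group score l_j (e.g. dose
#' rank 1, 2, 3 for control, IC50, IC90). With midranks r_j of the pooled
#' values and N observations, the statistic is
#' \deqn{T = \sum_j l_j r_j,}
#' with null moments
#' \deqn{E[T] = \frac{N+1}{2} \sum_j l_j, \quad
#'       Var[T] = \frac{N+1}{12}\left(N \sum_j l_j^2 -
#'                (\sum_j l_j)^2\right) \cdot c,}
#' where \eqn{c = 1 - \sum_g (t_g^3 - t_g)/(N^3 - N)} corrects for tie
#' groups of size \eqn{t_g}. The standardized score \eqn{Z = (T -
#' E[T])/\sqrt{Var[T]}} is referred to the standard normal for a two-sided
#' p-value. Being a rank statistic, Z is invariant under strictly monotone
#' transforms of the response and flips sign when the group scores are
#' reversed.
#'
#' @param values Numeric response, one per observation.
#' @param scores Numeric ordered group score per observation (at least two
#'   distinct values).
#' @param pMethod \code{"normal"} (default) for the standard-normal
#'   two-sided p-value, or \code{"exact"} to enumerate the full
#'   permutation distribution of T (available for N <= 10). The normal
#'   approximation is accurate in the tail but can deviate noticeably
#'   mid-distribution at very small N because T is discrete; see the
#'   package vignette.
#' @return An object of class \code{"htest"} with components
#'   \code{statistic} (T), \code{expected}, \code{variance} (tie-corrected),
#'   \code{z}, \code{p.value} (two-sided), \code{n.per.group} and
#'   \code{scores.used}.
#' @examples
#' cuzickTest(c(1, 2, 3, 4, 5, 6), c(1, 1, 2, 2, 3, 3))  # Z = 8 / sqrt(14)
#' @references Cuzick J. A Wilcoxon-type test for trend.
#'   Statistics in Medicine 1985;4:87-90.
#' @export
cuzickTest <- function(values, scores, pMethod = c("normal", "exact")) {
  pMethod <- match.arg(pMethod)
  if (length(values) != length(scores))
    stop("'values' and 'scores' must have equal length")
  if (length(values) < 3L)
    stop("need at least 3 observations")
  if (any(!is.finite(values)) || any(!is.finite(scores)))
    stop("non-finite values or scores")
  if (length(unique(scores)) < 2L)
    stop("need at least 2 distinct group scores")
  if (length(unique(values)) < 2L)
    stop("degenerate input: all values are tied (zero variance)")
  mom <- .cuzickMoments(values, scores)
  if (mom$variance <= 0)
    stop("degenerate input: null variance of T is zero")
  z <- (mom$T - mom$expected) / sqrt(mom$variance)
  p <- if (pMethod == "exact") {
    n <- length(values)
    if (n > 10L) stop("exact p only available for N <= 10")
    r <- rank(values)
    pm <- .permMatrix(n)
    tdist <- as.vector(matrix(r[pm], nrow(pm), n) %*% scores)
    mean(abs(tdist - mom$expected) >= abs(mom$T - mom$expected) - 1e-9)
  } else {
    2 * stats::pnorm(-abs(z))
  }
  structure(
    list(statistic = c(T = mom$T), expected = mom$expected,
         variance = mom$variance, z = z,
         p.value = p,
         n.per.group = table(scores), scores.used = sort(unique(scores)),
         method = paste0("Cuzick test for linear trend (", pMethod, " p)"),
         alternative = "two.sided",
         data.name = deparse(substitute(values))),
    class = "htest")
}

# all permutations of 1..n, one per row
.permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permMatrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

# exact null moments of T for one response vector
.cuzickMoments <- function(values, scores) {
  n <- length(values)
  r <- rank(values)
  sl <- sum(scores)
  sl2 <- sum(scores^2)
  tt <- table(values)
  tiec <- 1 - sum(tt^3 - tt) / (n^3 - n)
  list(T = sum(scores * r),
       expected = (n + 1) / 2 * sl,
       variance = (n + 1) / 12 * (n * sl2 - sl^2) * tiec)
}

# Vectorized per-row Cuzick Z over a genes x samples matrix.
# Zero-variance rows get Z = 0, p = 1 and a degenerate flag rather than
# aborting a genome-scale run.
.cuzickRows <- function(mat, scores) {
  n <- ncol(mat)
  stopifnot(length(scores) == n, n >= 3L)
  ranks <- t(apply(mat, 1L, rank))
  sl <- sum(scores)
  sl2 <- sum(scores^2)
  tstat <- as.vector(ranks %*% scores)
  expected <- (n + 1) / 2 * sl
  v0 <- (n + 1) / 12 * (n * sl2 - sl^2)
  tiec <- apply(mat, 1L, function(x) {
    tt <- tabulate(match(x, unique(x)))
    1 - sum(tt^3 - tt) / (n^3 - n)
  })
  variance <- v0 * tiec
  degenerate <- variance <= 0
  z <- ifelse(degenerate, 0, (tstat - expected) / sqrt(pmax(variance, 1e-300)))
  p <- ifelse(degenerate, 1, 2 * stats::pnorm(-abs(z)))
  list(z = z, p = p, degenerate = degenerate)
}

#' Largest attainable time-summed trend score for a design
#'
#' Diagnostic bound for the composite trend score: the Cuzick Z of the
#' perfectly dose-ordered arrangement (every observation in a higher-dose
#' group exceeds every observation in a lower-dose group), multiplied by
#' the number of time points being summed. Useful for judging whether a
#' reported composite score is attainable under a given replication level.
#'
#' @param replicatesPerGroup Observations per dose group entering the test.
#' @param scores Ordered group scores (default dose ranks 1, 2, 3).
#' @param nTimePoints Number of time points whose Z are summed (default 3).
#' @return The maximal composite score (numeric scalar).
#' @examples
#' maxSigmaZ(2)  # 3 * 8/sqrt(14) ~ 6.414
#' maxSigmaZ(1)  # 3 * sqrt(2)    ~ 4.243
#' @export
maxSigmaZ <- function(replicatesPerGroup, scores = c(1, 2, 3),
                      nTimePoints = 3L) {
  stopifnot(replicatesPerGroup >= 1, length(scores) >= 2, nTimePoints >= 1)
  obsScores <- rep(sort(scores), each = replicatesPerGroup)
  values <- seq_along(obsScores)   # perfectly ordered, no ties
  mom <- .cuzickMoments(values, obsScores)
  nTimePoints * (mom$T - mom$expected) / sqrt(mom$variance)
}
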