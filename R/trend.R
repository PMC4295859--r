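#' Time-summed Cuzick trend screen for an acute exposure design
#'
#' For every gene, runs the Cuzick trend test over the ordered dose ladder
#' (e.g. control, IC50, IC90) separately at each time point, then sums the
#' standardized scores into the composite
#' \deqn{\Sigma Z = Z_{t_1} + Z_{t_2} + \dots}
#' Genes with a consistent dose trend in the same direction at every time
#' point accumulate a large |composite| score; genes are ranked by the
#' composite, descending. Per-time-point p-values are retained. Genes with
#' zero variance at a time point contribute Z = 0, p = 1 there and are
#' flagged rather than dropped.
#'
#' @param x A gene-level \linkS4class{ExposureExperiment} whose
#'   \code{colData} has \code{dose_score} and \code{time_h} columns.
#' @param doseScores Optional ordered dose scores expected in the design;
#'   defaults to the sorted unique \code{dose_score} values present.
#' @param timePoints Optional time points expected; defaults to the sorted
#'   unique \code{time_h} values present. An error lists any (dose, time)
#'   design cell with no samples.
#' @return A \linkS4class{TrendResult} in acute mode. Its table has one
#'   row per gene: \code{Z_t<h>} and \code{p_t<h>} per time point,
#'   \code{sigma_Z}, \code{rank} (by \code{sigma_Z} descending, ties broken
#'   by gene symbol), \code{direction} and \code{degenerate}.
#' @seealso [cuzickTest()], [chronicTTest()], [topKLists()]
#' @export
acuteSigmaZ <- function(x, doseScores = NULL, timePoints = NULL) {
  stopifnot(is(x, "ExposureExperiment"))
  cd <- colData(x)
  if (!all(c("dose_score", "time_h") %in% colnames(cd)))
    stop("colData must provide 'dose_score' and 'time_h'")
  if (is.null(doseScores)) doseScores <- sort(unique(cd$dose_score))
  if (is.null(timePoints)) timePoints <- sort(unique(cd$time_h))
  if (length(doseScores) < 2L) stop("need at least 2 dose groups")
  cells <- expand.grid(dose_score = doseScores, time_h = timePoints)
  have <- paste(cd$dose_score, cd$time_h)
  missing <- cells[!paste(cells$dose_score, cells$time_h) %in% have, ]
  if (nrow(missing))
    stop("design cells with no samples: ",
         paste(sprintf("(dose %s, t=%s h)", missing$dose_score,
                       missing$time_h), collapse = ", "))

  mat <- exprsValues(x)
  genes <- rownames(mat)
  zs <- ps <- matrix(NA_real_, nrow(mat), length(timePoints))
  degen <- matrix(FALSE, nrow(mat), length(timePoints))
  for (i in seq_along(timePoints)) {
    sel <- cd$time_h == timePoints[i] & cd$dose_score %in% doseScores
    res <- .cuzickRows(mat[, sel, drop = FALSE], cd$dose_score[sel])
    zs[, i] <- res$z
    ps[, i] <- res$p
    degen[, i] <- res$degenerate
  }
  sigma <- rowSums(zs)
  tab <- S4Vectors::DataFrame(gene = genes)
  for (i in seq_along(timePoints)) tab[[paste0("Z_t", timePoints[i])]] <- zs[, i]
  tab$sigma_Z <- sigma
  for (i in seq_along(timePoints)) tab[[paste0("p_t", timePoints[i])]] <- ps[, i]
  ord <- order(-sigma, genes)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  tab$direction <- ifelse(sigma > 0, "up", ifelse(sigma < 0, "down", "none"))
  tab$degenerate <- rowSums(degen) > 0
  new("TrendResult", table = tab, mode = "acute",
      scores = as.numeric(doseScores), timePoints = as.numeric(timePoints))
}

#' Two-sample t ranking for a chronic exposure design
#'
#' Per-gene two-sample t-test of a treated arm (e.g. IC10 at day 30)
#' against the untreated control arm, with genes ranked by ascending
#' p-value. Welch's unequal-variance form is the default; the
#' pooled-variance form is available via \code{pooled = TRUE}. Direction is
#' the sign of (treated mean - control mean). Genes that are constant in
#' both arms get t = 0, p = 1 and a degenerate flag. A Benjamini-Hochberg
#' adjusted column is emitted for reference but plays no role in ranking.
#'
#' @param x A gene-level \linkS4class{ExposureExperiment} whose
#'   \code{colData} has an \code{arm} column with exactly two levels.
#' @param controlArm Label of the control arm (default \code{"control"}).
#' @param pooled Use the pooled-variance t instead of Welch.
#' @return A \linkS4class{TrendResult} in chronic mode; table columns
#'   \code{gene}, \code{t_statistic}, \code{p_value}, \code{p_bh},
#'   \code{rank} (ascending p, ties broken by gene symbol),
#'   \code{direction}, \code{degenerate}.
#' @export
chronicTTest <- function(x, controlArm = "control", pooled = FALSE) {
  stopifnot(is(x, "ExposureExperiment"))
  cd <- colData(x)
  if (!"arm" %in% colnames(cd)) stop("colData must provide 'arm'")
  arms <- unique(cd$arm)
  if (length(arms) != 2L) stop("exactly two arms required, got: ",
                               paste(arms, collapse = ", "))
  if (!controlArm %in% arms) stop("control arm '", controlArm, "' not found")
  treatedArm <- setdiff(arms, controlArm)
  mat <- exprsValues(x)
  a <- mat[, cd$arm == treatedArm, drop = FALSE]
  b <- mat[, cd$arm == controlArm, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each arm needs at least 2 replicate columns")
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(mat))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0 | !is.finite(se)
  tstat <- ifelse(degenerate & ma == mb, 0, (ma - mb) / se)
  tstat[degenerate & ma != mb] <- sign(ma - mb)[degenerate & ma != mb] * Inf
  p <- ifelse(degenerate & ma == mb, 1, 2 * stats::pt(-abs(tstat), df))
  p[degenerate & ma != mb] <- 0
  genes <- rownames(mat)
  ord <- order(p, genes)
  rk <- integer(length(p)); rk[ord] <- seq_along(p)
  tab <- S4Vectors::DataFrame(
    gene = genes, t_statistic = tstat, p_value = p,
    p_bh = stats::p.adjust(p, "BH"), rank = rk,
    direction = ifelse(ma > mb, "up", ifelse(ma < mb, "down", "none")),
    degenerate = degenerate)
  new("TrendResult", table = tab, mode = "chronic",
      scores = numeric(0), timePoints = numeric(0))
}
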