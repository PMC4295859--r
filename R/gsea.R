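# Gene-set enrichment with a gene-label permutation null. This is an
# in-package implementation of the running-sum enrichment statistic:
# walking down the metric-ordered gene list, in-set genes ("hits")
# increment the sum by their normalized |metric|^p weight, out-of-set
# genes decrement it by 1/(N - N_hits); ES is the signed maximum
# deviation from zero. Significance comes from permuting gene labels
# (metric values fixed, set membership randomized).

#' Running-sum enrichment score of one gene set
#'
#' @param metric Named numeric vector: the signed per-gene ranking metric
#'   (e.g. the composite trend score). Genes are ranked by decreasing
#'   metric; ties are kept in input order.
#' @param set Character vector of member gene symbols.
#' @param weightP Weighting exponent on |metric| for hit increments:
#'   1 (default) is the weighted statistic, 0 the classic
#'   Kolmogorov-Smirnov-like form (then ES depends on ranks only).
#' @return A list with \code{ES} (signed maximum deviation, in [-1, 1]),
#'   \code{runningSum} (length-N profile over the ranked genes) and
#'   \code{hits} (logical vector in ranking order).
#' @examples
#' m <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
#' enrichmentScore(m, c("a"))$ES  # 1: the single hit leads the ranking
#' @export
enrichmentScore <- function(metric, set, weightP = 1) {
  if (is.null(names(metric))) stop("'metric' must be named by gene")
  if (anyDuplicated(names(metric))) stop("duplicate gene names in metric")
  n <- length(metric)
  inset <- names(metric) %in% set
  nh <- sum(inset)
  if (nh == 0L) stop("set has no member in the ranking")
  if (nh == n) stop("set covers the whole ranking; ES undefined")
  ord <- order(metric, decreasing = TRUE)
  hits <- inset[ord]
  w <- abs(metric[ord])^weightP
  wh <- sum(w[hits])
  if (wh == 0) stop("all in-set metric weights are zero")
  inc <- ifelse(hits, w / wh, 0)
  dec <- ifelse(hits, 0, 1 / (n - nh))
  rs <- cumsum(inc - dec)
  es <- rs[which.max(abs(rs))]
  list(ES = es, runningSum = rs, hits = hits)
}

# ES from sorted hit positions only (O(k)); w = |metric|^p in ranking
# order. The running-sum maximum occurs at a hit, the minimum just before
# one, so only 2k candidate values need checking.
.esFast <- function(pos, w, n) {
  k <- length(pos)
  wh <- w[pos]
  tot <- sum(wh)
  H <- cumsum(wh) / tot
  miss <- (pos - seq_len(k)) / (n - k)
  up <- max(H - miss)
  dn <- min(c(0, H[-k]) - miss)
  if (up >= -dn) up else dn
}

#' Permutation enrichment test over a gene-set collection
#'
#' For every set (restricted to genes present in the ranking; restricted
#' sizes outside \code{[minSize, maxSize]} are skipped), computes the
#' observed ES and a null distribution of ES from \code{nPerm} random
#' draws of equally sized gene sets (gene-label permutation). The nominal
#' p-value is the add-one-smoothed fraction of same-sign null ES at least
#' as extreme as the observed one; NES divides ES by the mean |same-sign
#' null ES|; the FDR q-value is the standard NES-based ratio estimator
#' (pooled null NES tail fraction over observed NES tail fraction),
#' clipped at 1.
#'
#' @param metric Named signed ranking metric (see [enrichmentScore()]).
#' @param collection A \linkS4class{GeneSetCollection}.
#' @param nPerm Number of label permutations per set (>= 100;
#'   default 1000).
#' @param weightP Hit-weight exponent (see [enrichmentScore()]).
#' @param minSize,maxSize Restricted-size filter (defaults 5 and 500).
#' @param seed Integer seed; results are deterministic given
#'   (seed, inputs).
#' @return An \linkS4class{EnrichmentResult}.
#' @seealso [reportEnriched()]
#' @export
gseaPermutation <- function(metric, collection, nPerm = 1000, weightP = 1,
                            minSize = 5, maxSize = 500, seed = 1L) {
  stopifnot(is(collection, "GeneSetCollection"))
  if (nPerm < 100) stop("nPerm must be >= 100")
  if (length(unique(metric)) < 2L)
    stop("degenerate metric: all values equal")
  if (is.null(names(metric))) stop("'metric' must be named by gene")
  n <- length(metric)
  ord <- order(metric, decreasing = TRUE)
  w <- abs(metric[ord])^weightP
  rankedGenes <- names(metric)[ord]

  sets <- lapply(geneSets(collection), function(s)
    which(rankedGenes %in% s))
  sizes <- lengths(sets)
  keep <- sizes >= minSize & sizes <= maxSize & sizes < n
  if (!any(keep)) stop("no set passes the size filter")
  sets <- sets[keep]
  sizes <- sizes[keep]

  .withSeed(seed, {
    esObs <- numeric(length(sets))
    nes <- numeric(length(sets))
    pNom <- numeric(length(sets))
    nullNesPos <- vector("list", length(sets))
    nullNesNeg <- vector("list", length(sets))
    for (i in seq_along(sets)) {
      k <- sizes[i]
      es <- .esFast(sort.int(sets[[i]]), w, n)
      nullEs <- vapply(seq_len(nPerm), function(j)
        .esFast(sort.int(sample.int(n, k)), w, n), numeric(1))
      pos <- nullEs[nullEs >= 0]
      neg <- nullEs[nullEs < 0]
      mPos <- if (length(pos)) mean(pos) else NA_real_
      mNeg <- if (length(neg)) mean(abs(neg)) else NA_real_
      nullNesPos[[i]] <- if (length(pos)) pos / mPos else numeric(0)
      nullNesNeg[[i]] <- if (length(neg)) neg / mNeg else numeric(0)
      if (es >= 0) {
        pNom[i] <- (1 + sum(pos >= es)) / (1 + length(pos))
        nes[i] <- if (is.na(mPos)) NA_real_ else es / mPos
      } else {
        pNom[i] <- (1 + sum(neg <= es)) / (1 + length(neg))
        nes[i] <- if (is.na(mNeg)) NA_real_ else es / mNeg
      }
      esObs[i] <- es
    }
    poolPos <- unlist(nullNesPos)
    poolNeg <- unlist(nullNesNeg)
    obsPos <- nes[esObs >= 0]
    obsNeg <- nes[esObs < 0]
    fdr <- vapply(seq_along(sets), function(i) {
      if (is.na(nes[i])) return(NA_real_)
      if (esObs[i] >= 0) {
        num <- if (length(poolPos)) mean(poolPos >= nes[i]) else 0
        den <- mean(obsPos >= nes[i])
      } else {
        num <- if (length(poolNeg)) mean(poolNeg <= nes[i]) else 0
        den <- mean(obsNeg <= nes[i])
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
    tab <- S4Vectors::DataFrame(
      gene_set = names(sets), size = as.integer(sizes), ES = esObs,
      NES = nes, p_nominal = pNom, fdr_q = fdr,
      direction = ifelse(esObs > 0, "up",
                         ifelse(esObs < 0, "down", "none")))
    new("EnrichmentResult", table = tab, nPerm = as.integer(nPerm),
        weightP = weightP)
  })
}

# "<0.0001"-style strings from published tables parsed as their upper
# bound; plain numbers pass through.
.parseBound <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(sub("^<\\s*", "", as.character(x)))
}

#' Filter enrichment results by the reporting rule
#'
#' Keeps gene sets meeting both thresholds (by default FDR <= 0.10 and
#' nominal p <= 0.025), sorted by FDR. Accepts either an
#' \linkS4class{EnrichmentResult} or a data.frame with columns
#' \code{fdr}/\code{fdr_q} and \code{p_value}/\code{p_nominal}; values
#' given as strings like \code{"<0.0001"} are read as upper bounds, so
#' published summary tables can be re-filtered directly.
#'
#' @param results \linkS4class{EnrichmentResult} or data.frame.
#' @param fdrMax,pMax Reporting thresholds.
#' @return A data.frame of surviving rows (possibly empty), sorted by
#'   FDR then p.
#' @export
reportEnriched <- function(results, fdrMax = 0.10, pMax = 0.025) {
  tab <- if (is(results, "EnrichmentResult")) {
    df <- enrichmentTable(results)
    df$fdr <- df$fdr_q
    df$p <- df$p_nominal
    df
  } else {
    df <- as.data.frame(results)
    fcol <- intersect(c("fdr", "fdr_q"), colnames(df))[1]
    pcol <- intersect(c("p_value", "p_nominal"), colnames(df))[1]
    if (is.na(fcol) || is.na(pcol))
      stop("need FDR and p-value columns")
    df$fdr <- .parseBound(df[[fcol]])
    df$p <- .parseBound(df[[pcol]])
    df
  }
  out <- tab[!is.na(tab$fdr) & tab$fdr <= fdrMax & tab$p <= pMax, ,
             drop = FALSE]
  out[order(out$fdr, out$p), , drop = FALSE]
}
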