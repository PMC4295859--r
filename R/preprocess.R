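#' Log2-transform raw intensities
#'
#' @param x An \linkS4class{ExposureExperiment} of raw intensities.
#' @param epsilon Floor applied to non-positive intensities before taking
#'   logs when \code{strict = FALSE} (with a warning).
#' @param strict Error (naming the offending probe and sample) instead of
#'   flooring when non-positive values are present.
#' @return The same object with values replaced by their base-2 logarithm;
#'   design labels are untouched.
#' @export
log2Transform <- function(x, epsilon = 1e-3, strict = FALSE) {
  stopifnot(is(x, "ExposureExperiment"), epsilon > 0)
  mat <- exprsValues(x)
  bad <- which(mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    if (strict) {
      stop(sprintf("non-positive intensity at probe '%s', sample '%s'",
                   rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
    }
    warning(sprintf("%d non-positive intensities floored at %g",
                    nrow(bad), epsilon))
    mat[mat <= 0] <- epsilon
  }
  SummarizedExperiment::assay(x, "exprs") <- log2(mat)
  x
}

#' Quantile-normalize sample columns
#'
#' Forces every sample column onto a common value distribution: the
#' vector of row-wise means of the column-sorted values, mapped back by
#' within-column rank. Ties within a column receive the mean of the
#' candidate quantile values. Within-column rank order is preserved and
#' the grand mean is unchanged up to machine tolerance. Implemented via
#' \code{limma::normalizeQuantiles}.
#'
#' @param x An \linkS4class{ExposureExperiment} with at least 2 columns.
#' @return The normalized object (labels unchanged).
#' @examples
#' m <- cbind(s1 = c(1, 3), s2 = c(4, 2))
#' rownames(m) <- c("p1", "p2")
#' ee <- ExposureExperiment(m, data.frame(dose_score = c(1, 2)))
#' exprsValues(quantileNormalize(ee))  # both columns become {1.5, 3.5}
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "ExposureExperiment"))
  mat <- exprsValues(x)
  if (ncol(mat) < 2L)
    stop("quantile normalization is undefined for a single column")
  if (any(!is.finite(mat))) stop("all values must be finite")
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(norm) <- dimnames(mat)
  SummarizedExperiment::assay(x, "exprs") <- norm
  x
}

#' Collapse probe-level rows to gene symbols
#'
#' Averages (arithmetic mean, per sample) all probes mapped to the same
#' gene symbol. Probes with no mapping are dropped; the number dropped is
#' reported via \code{message}.
#'
#' @param x A probe-level \linkS4class{ExposureExperiment}.
#' @param annotation data.frame with columns \code{probe_id} and
#'   \code{symbol} (many probes per symbol allowed; empty/NA symbols count
#'   as unmapped).
#' @return A gene-level \linkS4class{ExposureExperiment}, rows named by
#'   symbol.
#' @export
collapseProbes <- function(x, annotation) {
  stopifnot(is(x, "ExposureExperiment"))
  if (expressionLevel(x) != "probe")
    stop("collapseProbes expects a probe-level object")
  annotation <- as.data.frame(annotation)
  if (!nrow(annotation) ||
      !all(c("probe_id", "symbol") %in% colnames(annotation)))
    stop("empty or malformed annotation (need probe_id, symbol)")
  if (anyDuplicated(annotation$probe_id))
    stop("annotation maps some probe id more than once")
  mat <- exprsValues(x)
  map <- annotation$symbol[match(rownames(mat), annotation$probe_id)]
  mapped <- !is.na(map) & nzchar(map)
  nDropped <- sum(!mapped)
  if (nDropped) message(nDropped, " unmapped probe(s) dropped")
  if (!any(mapped)) stop("no probe maps to a symbol")
  sub <- mat[mapped, , drop = FALSE]
  sym <- map[mapped]
  sums <- rowsum(sub, group = sym)
  counts <- as.vector(table(sym)[rownames(sums)])
  collapsed <- sums / counts
  ExposureExperiment(collapsed, colData(x), level = "gene")
}

#' Average technical hybridizations of the same specimen
#'
#' Collapses the technical-replicate hybridization columns of each
#' specimen into one column of per-gene means, reducing the column count
#' from n_specimens x n_hybridizations to n_specimens.
#'
#' @param x An \linkS4class{ExposureExperiment}.
#' @param groupBy \code{colData} columns that identify a specimen; columns
#'   sharing all these labels are averaged together.
#' @return An \linkS4class{ExposureExperiment} with one column per group.
#' @export
averageHybridizations <- function(x, groupBy = c("drug", "dose_score",
                                                 "time_h", "replicate")) {
  stopifnot(is(x, "ExposureExperiment"))
  cd <- colData(x)
  groupBy <- intersect(groupBy, colnames(cd))
  if (!length(groupBy)) stop("no grouping columns present in colData")
  key <- do.call(paste, c(lapply(groupBy, function(g) cd[[g]]), sep = "|"))
  mat <- exprsValues(x)
  sums <- rowsum(t(mat), group = key)        # groups x genes
  counts <- as.vector(table(key)[rownames(sums)])
  avg <- t(sums / counts)                    # genes x groups
  first <- !duplicated(key)
  newCd <- cd[first, groupBy, drop = FALSE]
  ord <- match(rownames(sums), key[first])
  newCd <- newCd[ord, , drop = FALSE]
  colnames(avg) <- gsub("[|]", "_", rownames(sums))
  ExposureExperiment(avg, newCd, level = expressionLevel(x))
}
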