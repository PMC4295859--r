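#' Construct a QpcrPlate
#'
#' @param wells data.frame with columns \code{gene}, \code{condition},
#'   \code{time_h}, \code{replicate}, \code{ct} (cycle threshold,
#'   cycles).
#' @param housekeeping Housekeeping gene symbol (default \code{"GAPDH"}).
#' @return A \linkS4class{QpcrPlate}.
#' @export
QpcrPlate <- function(wells, housekeeping = "GAPDH") {
  new("QpcrPlate", wells = S4Vectors::DataFrame(wells),
      housekeeping = housekeeping)
}

.cellCt <- function(plate, gene, condition, time_h) {
  w <- plate@wells
  w$ct[w$gene == gene & w$condition == condition & w$time_h == time_h]
}

#' Relative quantity by the CT-ratio rule
#'
#' Relative quantity of a target gene in one condition-by-time cell:
#' the mean cycle threshold of the target divided by the mean cycle
#' threshold of the housekeeping gene in the same cell. Note this
#' CT-ratio convention is direction-inverted relative to transcript
#' abundance (a higher CT means less transcript); the conventional
#' 2^-ddCT quantity is available via [foldChangeDdct()] and both are
#' worth reporting side by side.
#'
#' @param plate A \linkS4class{QpcrPlate}.
#' @param gene Target gene symbol.
#' @param condition Exposure condition label.
#' @param time_h Time point in hours.
#' @return Dimensionless ratio mean(CT_target) / mean(CT_housekeeping).
#' @export
relativeQuantity <- function(plate, gene, condition, time_h) {
  stopifnot(is(plate, "QpcrPlate"))
  target <- .cellCt(plate, gene, condition, time_h)
  ref <- .cellCt(plate, plate@housekeeping, condition, time_h)
  if (!length(target))
    stop(sprintf("no wells for gene '%s' at (%s, t=%s h)", gene,
                 condition, time_h))
  if (!length(ref))
    stop(sprintf("no housekeeping (%s) wells at (%s, t=%s h)",
                 plate@housekeeping, condition, time_h))
  mean(target) / mean(ref)
}

#' Expression difference relative to the baseline time point
#'
#' Ratio of the relative quantity at \code{time_h} to the relative
#' quantity at the baseline time point (default 6 h) within the same
#' condition. Equals 1 at the baseline itself, and stays 1 whenever
#' expression does not change over time (e.g. untreated controls).
#'
#' @inheritParams relativeQuantity
#' @param baseline_time Baseline time point in hours (default 6).
#' @return Dimensionless fold-like ratio.
#' @export
relativeDifference <- function(plate, gene, condition, time_h,
                               baseline_time = 6) {
  relativeQuantity(plate, gene, condition, time_h) /
    relativeQuantity(plate, gene, condition, baseline_time)
}

#' Conventional 2^-ddCT fold change versus baseline
#'
#' The standard comparative-CT quantity: with dCT = CT_target -
#' CT_housekeeping per cell, returns 2^-(dCT(time) - dCT(baseline)).
#' Unlike the CT-ratio rule, larger values mean more transcript.
#'
#' @inheritParams relativeDifference
#' @return Fold change (dimensionless).
#' @export
foldChangeDdct <- function(plate, gene, condition, time_h,
                           baseline_time = 6) {
  dct <- function(t) {
    target <- .cellCt(plate, gene, condition, t)
    ref <- .cellCt(plate, plate@housekeeping, condition, t)
    if (!length(target) || !length(ref))
      stop(sprintf("missing wells at (%s, t=%s h)", condition, t))
    mean(target) - mean(ref)
  }
  2^-(dct(time_h) - dct(baseline_time))
}

#' Compare replicate-level relative quantities between two conditions
#'
#' Two-sample two-sided t-test on per-replicate relative quantities
#' (each replicate's target CT divided by the mean housekeeping CT of
#' its cell) of one gene at one time point.
#'
#' @inheritParams relativeQuantity
#' @param cond_a,cond_b The two condition labels.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A list with \code{t}, \code{p.value}, \code{significant}.
#' @export
compareConditions <- function(plate, gene, time_h, cond_a, cond_b,
                              alpha = 0.05) {
  rq <- function(cond) {
    target <- .cellCt(plate, gene, cond, time_h)
    ref <- .cellCt(plate, plate@housekeeping, cond, time_h)
    if (!length(ref))
      stop(sprintf("no housekeeping wells at (%s, t=%s h)", cond, time_h))
    target / mean(ref)
  }
  a <- rq(cond_a)
  b <- rq(cond_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 replicates per condition")
  ht <- stats::t.test(a, b)
  list(t = unname(ht$statistic), p.value = ht$p.value,
       significant = ht$p.value < alpha)
}
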