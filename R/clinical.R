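# Longitudinal plasma-biomarker statistics: median (range) summaries per
# schedule point, paired signed-rank changes versus baseline,
# Mann-Whitney between-group comparisons and Spearman correlation tracks.
# Tests run pairwise-complete; per the analysis plan no multiple-testing
# adjustment is applied to the flags (a Holm column is emitted for
# reference only).

.markerWide <- function(panel, marker) {
  m <- panel@measurements
  m <- m[m$marker == marker, , drop = FALSE]
  if (!nrow(m)) stop("marker '", marker, "' not present in the panel")
  pts <- sort(unique(panel@measurements$patient_id))
  out <- matrix(NA_real_, length(pts), length(panel@schedule),
                dimnames = list(pts, panel@schedule))
  out[cbind(match(m$patient_id, pts), match(m$timepoint, panel@schedule))] <-
    m$value
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values. Incomplete pairs are
#' dropped first, then zero differences (the usual Wilcoxon convention).
#' The exact distribution is used for up to 25 nonzero differences when
#' there are no tied ranks; otherwise the normal approximation with
#' continuity and tie correction applies.
#'
#' @param x_baseline,x_followup Paired numeric vectors.
#' @return list(W, p.value, n_pairs, n_nonzero).
#' @examples
#' pairedSignedRank(c(1, 1, 1, 1, 1, 1), c(2, 3, 2, 4, 2, 5))$p.value
#' # 2/64 = 0.03125: all six differences positive
#' @export
pairedSignedRank <- function(x_baseline, x_followup) {
  stopifnot(length(x_baseline) == length(x_followup))
  ok <- stats::complete.cases(x_baseline, x_followup)
  d <- x_followup[ok] - x_baseline[ok]
  nz <- d != 0
  if (!any(nz))
    stop("all paired differences are zero (no information)")
  n <- sum(nz)
  ht <- suppressWarnings(
    stats::wilcox.test(x_followup[ok], x_baseline[ok], paired = TRUE,
                       exact = n <= 25, correct = TRUE))
  list(W = unname(ht$statistic), p.value = ht$p.value,
       n_pairs = sum(ok), n_nonzero = n)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided rank-sum comparison of two independent samples, exact for
#' small untied samples and normal-approximated with tie correction
#' otherwise. The reported U counts pairs in which an x-value exceeds a
#' y-value.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return list(U, p.value, n_x, n_y).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(ht$statistic), p.value = ht$p.value,
       n_x = length(x), n_y = length(y))
}

.fmtMedianRange <- function(v, digits = 1) {
  sprintf("%s (%s-%s; n = %d)", round(stats::median(v), digits),
          round(min(v), digits), round(max(v), digits), length(v))
}

#' Median (range) time course of one marker with paired baseline tests
#'
#' Per schedule point: number of patients with a value, median, min, max,
#' and the two-sided paired signed-rank p-value versus the baseline
#' (first schedule label), computed on patients with both values. When
#' every paired difference is zero the change p-value is 1 (no evidence
#' of change); with fewer than 2 complete pairs the test is skipped with
#' a warning. A Holm-adjusted column is emitted for reference but is not
#' used for significance flags.
#'
#' @param panel A \linkS4class{PlasmaPanel}.
#' @param marker Marker name.
#' @param baseline Baseline schedule label (default the first).
#' @return data.frame with one row per schedule point: \code{timepoint},
#'   \code{n}, \code{median}, \code{min}, \code{max},
#'   \code{p_vs_baseline}, \code{p_holm}, \code{significant}.
#' @export
summarizeTimecourse <- function(panel, marker,
                                baseline = panelSchedule(panel)[1]) {
  stopifnot(is(panel, "PlasmaPanel"))
  wide <- .markerWide(panel, marker)
  base <- wide[, baseline]
  rows <- lapply(panel@schedule, function(tp) {
    v <- wide[, tp]
    have <- !is.na(v)
    n <- sum(have)
    med <- if (n) stats::median(v[have]) else NA_real_
    p <- NA_real_
    if (tp != baseline) {
      ok <- have & !is.na(base)
      if (sum(ok) < 2L) {
        warning("fewer than 2 complete pairs at ", tp, "; test skipped")
      } else if (all(v[ok] == base[ok])) {
        p <- 1
      } else {
        p <- pairedSignedRank(base[ok], v[ok])$p.value
      }
    }
    data.frame(timepoint = tp, n = n, median = med,
               min = if (n) min(v[have]) else NA_real_,
               max = if (n) max(v[have]) else NA_real_,
               p_vs_baseline = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_vs_baseline, "holm")
  out$significant <- !is.na(out$p_vs_baseline) & out$p_vs_baseline <= 0.05
  out
}

#' Between-group comparison of one marker at one schedule point
#'
#' Mann-Whitney U comparison of marker values between two patient groups
#' defined by a metadata field (e.g. IGCCCG prognosis group with
#' intermediate and poor merged, mirroring the usual good versus
#' intermediate/poor split).
#'
#' @param panel A \linkS4class{PlasmaPanel}.
#' @param marker Marker name.
#' @param timepoint Schedule label.
#' @param groupingField Column of the patient metadata to split on.
#' @param groupA,groupB Metadata values forming each group.
#' @return list(U, p.value, summary_a, summary_b) where the summaries are
#'   formatted "median (range; n)".
#' @export
groupCompare <- function(panel, marker, timepoint,
                         groupingField = "igcccg_group",
                         groupA = "good",
                         groupB = c("intermediate", "poor")) {
  stopifnot(is(panel, "PlasmaPanel"))
  if (!timepoint %in% panel@schedule) stop("unknown timepoint label")
  pats <- panel@patients
  if (!groupingField %in% colnames(pats))
    stop("no patient metadata field '", groupingField, "'")
  wide <- .markerWide(panel, marker)
  v <- wide[, timepoint]
  grp <- pats[[groupingField]][match(rownames(wide), pats$patient_id)]
  a <- v[grp %in% groupA & !is.na(v)]
  b <- v[grp %in% groupB & !is.na(v)]
  if (!length(a) || !length(b)) stop("empty group")
  mw <- wilcoxonRankSum(a, b)
  list(U = mw$U, p.value = mw$p.value,
       summary_a = .fmtMedianRange(a), summary_b = .fmtMedianRange(b))
}

#' Spearman correlation between two markers at one schedule point
#'
#' Rank correlation on pairwise-complete patient values; at least 4
#' complete pairs are required. The p-value follows
#' \code{stats::cor.test} (exact for small untied samples, otherwise the
#' t-approximation).
#'
#' @param panel A \linkS4class{PlasmaPanel}.
#' @param marker_a,marker_b Marker names.
#' @param timepoint Schedule label.
#' @return list(rho, p.value, n).
#' @export
correlateMarkers <- function(panel, marker_a, marker_b, timepoint) {
  stopifnot(is(panel, "PlasmaPanel"))
  if (!timepoint %in% panel@schedule) stop("unknown timepoint label")
  wa <- .markerWide(panel, marker_a)[, timepoint]
  wb <- .markerWide(panel, marker_b)[, timepoint]
  ok <- !is.na(wa) & !is.na(wb)
  if (sum(ok) < 4L) stop("fewer than 4 complete pairs")
  ht <- suppressWarnings(
    stats::cor.test(wa[ok], wb[ok], method = "spearman"))
  list(rho = unname(ht$estimate), p.value = ht$p.value, n = sum(ok))
}

#' Correlation track of two markers across the whole schedule
#'
#' Applies [correlateMarkers()] at every schedule point; points with
#' fewer than 4 complete pairs yield NA. Raw p-values carry the
#' significance flag (no multiplicity adjustment, matching the analysis
#' plan); a Holm column is provided for reference.
#'
#' @inheritParams correlateMarkers
#' @return data.frame with columns \code{timepoint}, \code{rho},
#'   \code{p.value}, \code{n}, \code{p_holm}, \code{significant}.
#' @export
correlationTrack <- function(panel, marker_a, marker_b) {
  rows <- lapply(panelSchedule(panel), function(tp) {
    res <- tryCatch(correlateMarkers(panel, marker_a, marker_b, tp),
                    error = function(e) list(rho = NA_real_,
                                             p.value = NA_real_, n = 0L))
    data.frame(timepoint = tp, rho = res$rho, p.value = res$p.value,
               n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p.value, "holm")
  out$significant <- !is.na(out$p.value) & out$p.value <= 0.05
  out
}
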