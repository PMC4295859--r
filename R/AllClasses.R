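#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' ExposureExperiment: expression values with exposure-design metadata
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' probe- or gene-level log2 (or raw) intensity matrix together with the
#' per-sample exposure design (drug, ordered dose score, time point,
#' replicate, optional channel and hybridization labels) in \code{colData}.
#'
#' @slot level Either \code{"probe"} or \code{"gene"}; gene-level objects
#'   must have unique row names (HUGO symbols).
#'
#' @seealso [simulateAcute()], [quantileNormalize()], [collapseProbes()]
#' @export
setClass("ExposureExperiment",
  contains = "SummarizedExperiment",
  representation(level = "character"),
  prototype(level = "probe")
)

setValidity("ExposureExperiment", function(object) {
  msg <- NULL
  if (length(object@level) != 1L || !object@level %in% c("probe", "gene"))
    msg <- c(msg, "'level' must be \"probe\" or \"gene\"")
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "column (sample) names must be present and unique")
  if (identical(object@level, "gene") && anyDuplicated(rownames(object)))
    msg <- c(msg, "gene-level objects must have unique row names")
  if (is.null(msg)) TRUE else msg
})

#' TrendResult: per-gene trend-ranking statistics
#'
#' Container for the class-comparison statistics of one exposure setting.
#' In acute mode the table holds one Cuzick Z and p per time point, their
#' sum (the composite trend score), the rank by that sum and a direction
#' flag. In chronic mode it holds the two-sample t statistic, its p-value,
#' the rank by ascending p and the direction of the treated-vs-control
#' difference.
#'
#' @slot table A \linkS4class{DataFrame}, one row per gene.
#' @slot mode \code{"acute"} or \code{"chronic"}.
#' @slot scores Numeric group scores used by the trend test (acute mode).
#' @slot timePoints Numeric time points (hours) the per-time Z refer to.
#' @export
setClass("TrendResult",
  representation(table = "DataFrame", mode = "character",
                 scores = "numeric", timePoints = "numeric")
)

setValidity("TrendResult", function(object) {
  msg <- NULL
  if (!object@mode %in% c("acute", "chronic"))
    msg <- c(msg, "'mode' must be \"acute\" or \"chronic\"")
  if (!"gene" %in% colnames(object@table))
    msg <- c(msg, "table must have a 'gene' column")
  if (object@mode == "acute" && nrow(object@table) > 0) {
    zc <- grep("^Z_t", colnames(object@table), value = TRUE)
    if (!length(zc) || !"sigma_Z" %in% colnames(object@table)) {
      msg <- c(msg, "acute table needs Z_t* columns and sigma_Z")
    } else {
      s <- rowSums(as.matrix(object@table[, zc, drop = FALSE]))
      if (!isTRUE(all.equal(s, object@table$sigma_Z, tolerance = 0)))
        msg <- c(msg, "sigma_Z must equal the sum of the per-time Z columns")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' RankedGeneLists: per-setting ordered candidate lists
#'
#' Named collection of ordered gene lists, one per exposure setting, each a
#' \linkS4class{DataFrame} with columns \code{gene}, \code{direction}
#' (\code{"up"}/\code{"down"}) and \code{statistic}.
#'
#' @slot lists Named list of DataFrames.
#' @slot k Integer list-size cap.
#' @export
setClass("RankedGeneLists",
  representation(lists = "list", k = "integer")
)

setValidity("RankedGeneLists", function(object) {
  msg <- NULL
  if (length(object@lists) && is.null(names(object@lists)))
    msg <- c(msg, "lists must be named by setting")
  for (nm in names(object@lists)) {
    l <- object@lists[[nm]]
    if (!all(c("gene", "direction") %in% colnames(l)))
      msg <- c(msg, sprintf("list '%s' lacks gene/direction columns", nm))
    else if (anyDuplicated(l$gene))
      msg <- c(msg, sprintf("list '%s' has duplicate gene symbols", nm))
    if (nrow(l) > object@k)
      msg <- c(msg, sprintf("list '%s' longer than k = %d", nm, object@k))
  }
  if (is.null(msg)) TRUE else msg
})

#' OverlapReport: multi-setting membership of top-list genes
#'
#' @slot membership DataFrame with one row per gene appearing in at least
#'   one list: logical membership per setting plus the membership count.
#' @slot candidates Genes whose membership count meets the threshold.
#' @slot m Integer minimum-membership threshold.
#' @slot pairwise Symmetric matrix of pairwise intersection sizes.
#' @export
setClass("OverlapReport",
  representation(membership = "DataFrame", candidates = "character",
                 m = "integer", pairwise = "matrix")
)

#' GeneSetCollection: named sets of gene symbols
#'
#' @slot sets Named list of unique-member character vectors.
#' @slot descriptions One description per set (may be empty strings).
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- NULL
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "set names must be present and unique")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0))
      msg <- c(msg, "set members must be unique within a set")
  }
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "need one description per set")
  if (is.null(msg)) TRUE else msg
})

#' EnrichmentResult: per-set enrichment statistics
#'
#' One row per gene set: enrichment score (ES), normalized ES, nominal
#' permutation p-value, FDR q-value, direction and the number of set
#' members present in the ranking.
#'
#' @slot table DataFrame of per-set results.
#' @slot nPerm Number of label permutations used.
#' @slot weightP Weighting exponent applied to the ranking metric.
#' @export
setClass("EnrichmentResult",
  representation(table = "DataFrame", nPerm = "integer", weightP = "numeric")
)

setValidity("EnrichmentResult", function(object) {
  tab <- object@table
  msg <- NULL
  if (nrow(tab)) {
    if (any(abs(tab$ES) > 1 + 1e-12)) msg <- c(msg, "|ES| must be <= 1")
    if (any(tab$fdr_q < 0)) msg <- c(msg, "fdr_q must be >= 0")
    bad <- tab$ES != 0 & tab$direction != ifelse(tab$ES > 0, "up", "down")
    if (any(bad)) msg <- c(msg, "direction must match the sign of ES")
  }
  if (is.null(msg)) TRUE else msg
})

#' QpcrPlate: well-level qRT-PCR cycle-threshold records
#'
#' @slot wells DataFrame with columns gene, condition, time_h, replicate,
#'   ct (cycle threshold, cycles).
#' @slot housekeeping Housekeeping gene symbol (default \code{"GAPDH"}).
#' @export
setClass("QpcrPlate",
  representation(wells = "DataFrame", housekeeping = "character")
)

setValidity("QpcrPlate", function(object) {
  msg <- NULL
  w <- object@wells
  need <- c("gene", "condition", "time_h", "replicate", "ct")
  if (!all(need %in% colnames(w)))
    msg <- c(msg, paste("wells needs columns:", paste(need, collapse = ", ")))
  else if (nrow(w) && (any(!is.finite(w$ct)) || any(w$ct <= 0)))
    msg <- c(msg, "all CT values must be finite and > 0")
  if (length(object@housekeeping) != 1L || !nzchar(object@housekeeping))
    msg <- c(msg, "a single housekeeping gene symbol is required")
  if (is.null(msg)) TRUE else msg
})

#' PlasmaPanel: longitudinal plasma biomarker measurements
#'
#' Long-format patient x time-point x marker values over an ordered
#' sampling schedule (default the three-week BEP course schedule:
#' c1d1, c1d8, c1d15, c2d1, c2d8, c3d1, c3d8, one month post, one year),
#' plus per-patient metadata (age, IGCCCG prognosis group, stage, regimen).
#'
#' @slot measurements DataFrame (patient_id, timepoint, marker, value, unit).
#' @slot patients DataFrame of per-patient metadata keyed by patient_id.
#' @slot schedule Ordered character vector of valid time-point labels.
#' @export
setClass("PlasmaPanel",
  representation(measurements = "DataFrame", patients = "DataFrame",
                 schedule = "character")
)

setValidity("PlasmaPanel", function(object) {
  msg <- NULL
  m <- object@measurements
  need <- c("patient_id", "timepoint", "marker", "value")
  if (!all(need %in% colnames(m)))
    msg <- c(msg, paste("measurements needs columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(m)) {
    if (any(!is.finite(m$value)) || any(m$value <= 0))
      msg <- c(msg, "all values must be finite and > 0")
    if (!all(m$timepoint %in% object@schedule))
      msg <- c(msg, "all timepoint labels must come from the schedule")
    if (anyDuplicated(m[, c("patient_id", "timepoint", "marker")]))
      msg <- c(msg, "at most one record per (patient, timepoint, marker)")
  }
  if (is.null(msg)) TRUE else msg
})
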