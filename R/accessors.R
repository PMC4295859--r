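#' Accessors for doseTrend S4 containers
#'
#' Small accessor layer over the package's S4 classes so downstream code
#' never touches slots directly.
#'
#' @param x An object of the matching class.
#' @return The requested component (see each class's documentation).
#' @name accessors
NULL

#' Construct an ExposureExperiment
#'
#' @param values Numeric matrix (rows = probes or genes, columns = samples).
#' @param design data.frame/DataFrame of per-sample labels, one row per
#'   column of \code{values} (e.g. drug, dose_score, time_h, replicate).
#' @param level \code{"probe"} or \code{"gene"}.
#' @return An \linkS4class{ExposureExperiment}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(dose_score = c(1, 1, 2, 2), time_h = 6)
#' ExposureExperiment(m, d, level = "gene")
#' @export
ExposureExperiment <- function(values, design, level = c("probe", "gene")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  design <- S4Vectors::DataFrame(design)
  if (nrow(design) != ncol(values))
    stop("'design' must have one row per sample column")
  rownames(design) <- colnames(values)
  se <- SummarizedExperiment(assays = list(exprs = values), colData = design)
  new("ExposureExperiment", se, level = level)
}

#' @rdname accessors
#' @export
setMethod("expressionLevel", "ExposureExperiment", function(x) x@level)

#' @rdname accessors
#' @export
setMethod("designInfo", "ExposureExperiment",
          function(x) as.data.frame(colData(x)))

#' Expression values of an ExposureExperiment
#'
#' @param x An \linkS4class{ExposureExperiment}.
#' @return The numeric expression matrix.
#' @export
exprsValues <- function(x) {
  stopifnot(is(x, "ExposureExperiment"))
  assay(x, "exprs")
}

setMethod("show", "ExposureExperiment", function(object) {
  cat(sprintf("ExposureExperiment (%s level): %d features x %d samples\n",
              object@level, nrow(object), ncol(object)))
  labs <- intersect(c("drug", "dose_score", "time_h"),
                    colnames(colData(object)))
  for (l in labs)
    cat(sprintf("  %s: %s\n", l,
                paste(unique(colData(object)[[l]]), collapse = ", ")))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("trendTable", "TrendResult", function(x) as.data.frame(x@table))

setMethod("show", "TrendResult", function(object) {
  cat(sprintf("TrendResult (%s): %d genes\n", object@mode,
              nrow(object@table)))
  if (object@mode == "acute")
    cat(sprintf("  time points (h): %s; group scores: %s\n",
                paste(object@timePoints, collapse = ", "),
                paste(object@scores, collapse = ", ")))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("geneLists", "RankedGeneLists",
          function(x) lapply(x@lists, as.data.frame))

setMethod("show", "RankedGeneLists", function(object) {
  cat(sprintf("RankedGeneLists: %d setting(s), k = %d\n",
              length(object@lists), object@k))
  for (nm in names(object@lists))
    cat(sprintf("  %s: %d genes\n", nm, nrow(object@lists[[nm]])))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("candidateSet", "OverlapReport", function(x) x@candidates)

#' @rdname accessors
#' @export
setMethod("membershipTable", "OverlapReport",
          function(x) as.data.frame(x@membership))

#' @rdname accessors
#' @export
setMethod("pairwiseOverlap", "OverlapReport", function(x) x@pairwise)

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf("OverlapReport: %d genes across %d lists; m = %d\n",
              nrow(object@membership), ncol(object@pairwise), object@m))
  cat(sprintf("  candidates (count >= %d): %s\n", object@m,
              paste(object@candidates, collapse = ", ")))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("GeneSetCollection: %d sets (sizes %s-%s)\n",
              length(object@sets),
              if (length(sz)) min(sz) else 0, if (length(sz)) max(sz) else 0))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("enrichmentTable", "EnrichmentResult",
          function(x) as.data.frame(x@table))

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d sets, %d permutations, weight p = %g\n",
              nrow(object@table), object@nPerm, object@weightP))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("plateWells", "QpcrPlate", function(x) as.data.frame(x@wells))

setMethod("show", "QpcrPlate", function(object) {
  cat(sprintf("QpcrPlate: %d wells, %d gene(s), housekeeping %s\n",
              nrow(object@wells), length(unique(object@wells$gene)),
              object@housekeeping))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("panelMeasurements", "PlasmaPanel",
          function(x) as.data.frame(x@measurements))

#' @rdname accessors
#' @export
setMethod("panelPatients", "PlasmaPanel",
          function(x) as.data.frame(x@patients))

#' @rdname accessors
#' @export
setMethod("panelSchedule", "PlasmaPanel", function(x) x@schedule)

setMethod("show", "PlasmaPanel", function(object) {
  cat(sprintf("PlasmaPanel: %d patients, %d markers, %d records\n",
              nrow(object@patients),
              length(unique(object@measurements$marker)),
              nrow(object@measurements)))
  cat("  schedule:", paste(object@schedule, collapse = " "), "\n")
  invisible(object)
})
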