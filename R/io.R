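# Plain-text readers and writers. All tables are TSV/CSV with header
# rows; gzip-compressed inputs are accepted transparently (base R
# connections decompress .gz).

#' Read an expression matrix TSV
#'
#' First column: probe or gene id; remaining columns: samples. A design
#' sheet (sample, drug, dose_score, time_h, replicate, ...) may be given
#' to populate the per-sample labels; otherwise empty labels are
#' attached.
#'
#' @param path Expression TSV (optionally gzipped).
#' @param designPath Optional design-sheet TSV with a \code{sample}
#'   column matching the matrix column names.
#' @param level \code{"probe"} or \code{"gene"}.
#' @return An \linkS4class{ExposureExperiment}.
#' @export
readExpression <- function(path, designPath = NULL,
                           level = c("probe", "gene")) {
  level <- match.arg(level)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs id + sample columns")
  sampleIds <- colnames(tab)[-1]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  ids <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[-1], is.numeric, TRUE))[1]
    stop("non-numeric values in sample column '",
         colnames(tab)[-1][bad], "'")
  }
  colnames(mat) <- sampleIds
  rownames(mat) <- ids
  design <- if (!is.null(designPath)) {
    d <- utils::read.delim(designPath, stringsAsFactors = FALSE)
    if (!"sample" %in% colnames(d)) stop("design sheet needs 'sample'")
    idx <- match(colnames(mat), d$sample)
    if (anyNA(idx))
      stop("design sheet missing sample(s): ",
           paste(colnames(mat)[is.na(idx)], collapse = ", "))
    d[idx, setdiff(colnames(d), "sample"), drop = FALSE]
  } else {
    data.frame(row.names = colnames(mat))
  }
  ExposureExperiment(mat, design, level = level)
}

#' Write an expression matrix (and design sheet) as TSV
#'
#' @param x An \linkS4class{ExposureExperiment}.
#' @param path Output TSV for the matrix.
#' @param designPath Optional output TSV for the design sheet.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(x, path, designPath = NULL) {
  mat <- exprsValues(x)
  out <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(designPath)) {
    d <- data.frame(sample = colnames(mat), designInfo(x),
                    check.names = FALSE)
    utils::write.table(d, designPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a probe annotation TSV (probe_id, symbol)
#'
#' @param path Annotation TSV.
#' @return data.frame with columns \code{probe_id}, \code{symbol}.
#' @export
readAnnotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "symbol") %in% colnames(tab)))
    stop("annotation needs columns probe_id, symbol")
  tab
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields set name,
#' description, then member symbols. Lines with fewer than 3 fields are
#' parse errors naming the line number.
#'
#' @param path GMT file path.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  new("GeneSetCollection", sets = sets, descriptions = desc)
}

#' Write a GeneSetCollection as GMT
#'
#' @param collection A \linkS4class{GeneSetCollection}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  lines <- vapply(names(collection@sets), function(nm) {
    paste(c(nm, collection@descriptions[[nm]], collection@sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format plasma panel CSV
#'
#' Columns: patient_id, timepoint, marker, value, unit (unit optional).
#' Unknown time-point labels (outside the declared schedule) are
#' reported as errors.
#'
#' @param path Measurements CSV.
#' @param metadataPath Optional patient-metadata CSV keyed by
#'   \code{patient_id}.
#' @param schedule Ordered schedule labels (default the BEP course
#'   schedule).
#' @return A \linkS4class{PlasmaPanel}.
#' @export
readPlasma <- function(path, metadataPath = NULL,
                       schedule = .defaultSchedule) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "marker", "value")
  if (!all(need %in% colnames(m)))
    stop("plasma CSV needs columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(m$timepoint), schedule)
  if (length(unknown))
    stop("unknown timepoint label(s): ", paste(unknown, collapse = ", "))
  if (!"unit" %in% colnames(m)) m$unit <- NA_character_
  pats <- if (!is.null(metadataPath)) {
    utils::read.csv(metadataPath, stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = sort(unique(m$patient_id)),
               stringsAsFactors = FALSE)
  }
  new("PlasmaPanel", measurements = S4Vectors::DataFrame(m),
      patients = S4Vectors::DataFrame(pats), schedule = schedule)
}

#' Write a plasma panel as CSV
#'
#' @param panel A \linkS4class{PlasmaPanel}.
#' @param path Measurements CSV path.
#' @param metadataPath Optional patient-metadata CSV path.
#' @return Invisibly, \code{path}.
#' @export
writePlasma <- function(panel, path, metadataPath = NULL) {
  utils::write.csv(panelMeasurements(panel), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(metadataPath))
    utils::write.csv(panelPatients(panel), metadataPath,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-setting ranked gene lists
#'
#' Each file is a TSV with columns \code{gene}, \code{direction} and
#' optionally \code{statistic}, already ordered; useful for re-analyzing
#' published top-k tables.
#'
#' @param paths Character vector of TSV paths.
#' @param settings Setting labels (default: file names without
#'   extension).
#' @return A \linkS4class{RankedGeneLists}.
#' @export
readGeneLists <- function(paths,
                          settings = sub("\\.[^.]*$", "", basename(paths))) {
  stopifnot(length(paths) == length(settings))
  lists <- lapply(paths, function(p) {
    tab <- utils::read.delim(p, stringsAsFactors = FALSE)
    if (!all(c("gene", "direction") %in% colnames(tab)))
      stop("gene list ", p, " needs columns gene, direction")
    tab
  })
  names(lists) <- settings
  rankedGeneLists(lists)
}

#' Write a TrendResult table as TSV
#'
#' @param trend A \linkS4class{TrendResult}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTrendResult <- function(trend, path) {
  utils::write.table(trendTable(trend), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an OverlapReport (membership TSV + candidate TXT)
#'
#' @param report An \linkS4class{OverlapReport}.
#' @param path Membership TSV path.
#' @param candidatePath Optional plain-text candidate list path.
#' @return Invisibly, \code{path}.
#' @export
writeOverlap <- function(report, path, candidatePath = NULL) {
  utils::write.table(membershipTable(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(candidatePath))
    writeLines(candidateSet(report), candidatePath)
  invisible(path)
}

#' Write an EnrichmentResult table as TSV
#'
#' @param result An \linkS4class{EnrichmentResult}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeEnrichment <- function(result, path) {
  utils::write.table(enrichmentTable(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to a bundled reference table
#'
#' Convenience accessor for the plain-text tables shipped with the
#' package: the four published top-50 gene lists of the HMEC-1
#' bleomycin/cisplatin exposure screens (GEO series GSE62523) and their
#' published KEGG enrichment summary.
#'
#' @param file File name under \code{inst/extdata}; with no argument,
#'   lists the available files.
#' @return A file path (or a vector of available file names).
#' @export
doseTrendData <- function(file = NULL) {
  dir <- system.file("extdata", package = "doseTrend")
  if (is.null(file)) return(list.files(dir))
  fp <- file.path(dir, file)
  if (!file.exists(fp)) stop("no bundled file '", file, "'")
  fp
}
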