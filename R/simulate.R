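# Synthetic-data generators. These emulate the statistical structure the
# downstream screens assume: an acute design with an ordered dose ladder
# (control / IC50 / IC90) sampled at 6, 24 and 48 h with 4 hybridizations
# per specimen, a chronic two-arm (control vs IC10, day 30) design, a
# multi-course plasma biomarker panel, and a random gene-set catalog.
# All generators are pure functions of (design, seed) and restore the
# caller's RNG state.

.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Acute exposure design parameters
#'
#' Parameter bundle for [simulateAcute()]. Defaults mirror the acute study
#' design: an ordered three-step dose ladder scored 1/2/3
#' (control, IC50, IC90), sampling at 6, 24 and 48 hours, two independent
#' biological replicates per dose-by-time cell and four hybridizations per
#' specimen.
#'
#' @param n_genes Number of genes on the array.
#' @param n_trend_genes Number of spiked monotone dose-trend genes.
#' @param dose_scores Strictly increasing group scores for the dose ladder.
#' @param time_points_h Sampling times in hours.
#' @param replicates_per_group Independent specimens per dose-by-time cell.
#' @param hybridizations_per_specimen Technical hybridizations per specimen.
#' @param effect_size_log2 Mean log2 shift per dose step for trend genes.
#' @param noise_sd_log2 Within-condition SD on the log2 scale.
#' @param trend_gene_ids Optional explicit gene ids to spike (overrides
#'   random selection; \code{n_trend_genes} is then their count).
#' @param trend_directions Optional "up"/"down" per spiked gene.
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{"AcuteDesign"}.
#' @export
acuteDesign <- function(n_genes = 15950, n_trend_genes = 50,
                        dose_scores = c(1, 2, 3),
                        time_points_h = c(6, 24, 48),
                        replicates_per_group = 2,
                        hybridizations_per_specimen = 4,
                        effect_size_log2 = 1.0, noise_sd_log2 = 0.5,
                        trend_gene_ids = NULL, trend_directions = NULL,
                        seed = 1L) {
  if (!is.null(trend_gene_ids)) n_trend_genes <- length(trend_gene_ids)
  if (!is.null(trend_directions) &&
      length(trend_directions) != n_trend_genes)
    stop("invalid design: one direction per spiked gene required")
  if (n_genes < 1 || n_trend_genes < 0 || n_trend_genes > n_genes)
    stop("invalid design: need 0 <= n_trend_genes <= n_genes, n_genes >= 1")
  if (any(diff(dose_scores) <= 0) || length(dose_scores) < 2)
    stop("invalid design: dose_scores must be strictly increasing (>= 2)")
  if (replicates_per_group < 1 || hybridizations_per_specimen < 1)
    stop("invalid design: non-positive replication counts")
  if (!is.finite(effect_size_log2) || noise_sd_log2 < 0)
    stop("invalid design: effect size must be finite, noise SD >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_trend_genes = as.integer(n_trend_genes),
                 dose_scores = dose_scores, time_points_h = time_points_h,
                 replicates_per_group = as.integer(replicates_per_group),
                 hybridizations_per_specimen =
                   as.integer(hybridizations_per_specimen),
                 effect_size_log2 = effect_size_log2,
                 noise_sd_log2 = noise_sd_log2,
                 trend_gene_ids = trend_gene_ids,
                 trend_directions = trend_directions,
                 seed = as.integer(seed)),
            class = "AcuteDesign")
}

#' Chronic exposure design parameters
#'
#' Parameter bundle for [simulateChronic()]: a two-arm comparison of
#' low-dose (IC10, twice weekly, collected at day 30) versus untreated
#' control.
#'
#' @param n_genes,n_affected_genes Gene counts (affected <= total).
#' @param arms Two arm labels; the first is the control arm.
#' @param replicates_per_arm Columns per arm (>= 2; the t-test needs
#'   within-arm variance).
#' @param effect_size_log2 Mean log2 arm difference for affected genes.
#' @param noise_sd_log2 Within-arm SD on the log2 scale.
#' @param trend_gene_ids,trend_directions Optional explicit spiked genes
#'   and their "up"/"down" directions (as in [acuteDesign()]).
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{"ChronicDesign"}.
#' @export
chronicDesign <- function(n_genes = 15950, n_affected_genes = 50,
                          arms = c("control", "IC10"),
                          replicates_per_arm = 4,
                          effect_size_log2 = 1.0, noise_sd_log2 = 0.5,
                          trend_gene_ids = NULL, trend_directions = NULL,
                          seed = 1L) {
  if (!is.null(trend_gene_ids)) n_affected_genes <- length(trend_gene_ids)
  if (!is.null(trend_directions) &&
      length(trend_directions) != n_affected_genes)
    stop("invalid design: one direction per spiked gene required")
  if (n_genes < 1 || n_affected_genes < 0 || n_affected_genes > n_genes)
    stop("invalid design: need 0 <= n_affected_genes <= n_genes")
  if (length(arms) != 2L || anyDuplicated(arms))
    stop("invalid design: exactly two distinct arm labels required")
  if (replicates_per_arm < 2)
    stop("invalid design: replicates_per_arm must be >= 2")
  if (!is.finite(effect_size_log2) || noise_sd_log2 < 0)
    stop("invalid design: effect size must be finite, noise SD >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_affected_genes = as.integer(n_affected_genes),
                 arms = arms, replicates_per_arm = as.integer(replicates_per_arm),
                 effect_size_log2 = effect_size_log2,
                 noise_sd_log2 = noise_sd_log2,
                 trend_gene_ids = trend_gene_ids,
                 trend_directions = trend_directions,
                 seed = as.integer(seed)),
            class = "ChronicDesign")
}

.geneIds <- function(n) sprintf("G%05d", seq_len(n))

# spiked gene ids + signed directions, honoring an explicit spike list
.resolveSpikes <- function(design, genes, nSpiked) {
  if (!is.null(design$trend_gene_ids)) {
    if (!all(design$trend_gene_ids %in% genes))
      stop("trend_gene_ids not all present in the gene universe")
    spiked <- design$trend_gene_ids
    dir <- if (is.null(design$trend_directions))
      sample(c(1, -1), length(spiked), replace = TRUE)
    else ifelse(design$trend_directions == "up", 1, -1)
  } else {
    spiked <- sort(sample(genes, nSpiked))
    dir <- sample(c(1, -1), nSpiked, replace = TRUE)
  }
  list(spiked = spiked, dir = dir)
}

#' Simulate an acute dose-by-time expression experiment
#'
#' Draws one sample column per (dose, time, replicate, hybridization).
#' A random subset of \code{n_trend_genes} genes receives a monotone mean
#' shift of \code{effect_size_log2} per dose step, in a per-gene random
#' direction, at every time point; all other genes are dose-independent.
#' Gene baselines are N(8, 1) on the log2 scale and measurement noise is
#' additive Gaussian per column.
#'
#' @param design An [acuteDesign()].
#' @return A list with \code{experiment} (a gene-level
#'   \linkS4class{ExposureExperiment}) and \code{truth} (data.frame of
#'   spiked gene, direction, effect size).
#' @examples
#' sim <- simulateAcute(acuteDesign(n_genes = 100, n_trend_genes = 5,
#'                                  seed = 3))
#' sim$experiment
#' head(sim$truth)
#' @export
simulateAcute <- function(design) {
  stopifnot(inherits(design, "AcuteDesign"))
  .withSeed(design$seed, {
    genes <- .geneIds(design$n_genes)
    sp <- .resolveSpikes(design, genes, design$n_trend_genes)
    spiked <- sp$spiked; dir <- sp$dir
    baseline <- stats::rnorm(design$n_genes, mean = 8, sd = 1)
    names(baseline) <- genes
    shift <- numeric(design$n_genes)
    names(shift) <- genes
    shift[spiked] <- dir * design$effect_size_log2

    grid <- expand.grid(
      hyb = seq_len(design$hybridizations_per_specimen),
      replicate = seq_len(design$replicates_per_group),
      dose_score = design$dose_scores,
      time_h = design$time_points_h)
    doseStep <- match(grid$dose_score, design$dose_scores) - 1L
    mat <- vapply(seq_len(nrow(grid)), function(j) {
      baseline + shift * doseStep[j] +
        stats::rnorm(design$n_genes, 0, design$noise_sd_log2)
    }, numeric(design$n_genes))
    rownames(mat) <- genes
    colnames(mat) <- sprintf("t%g_d%g_r%d_h%d", grid$time_h, grid$dose_score,
                             grid$replicate, grid$hyb)
    cd <- data.frame(drug = "drugA", dose_score = grid$dose_score,
                     time_h = grid$time_h, replicate = grid$replicate,
                     hyb = grid$hyb)
    list(experiment = ExposureExperiment(mat, cd, level = "gene"),
         truth = data.frame(gene = spiked,
                            direction = ifelse(dir > 0, "up", "down"),
                            effect_size_log2 = dir * design$effect_size_log2,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a chronic two-arm expression experiment
#'
#' @param design A [chronicDesign()].
#' @return A list with \code{experiment} (gene-level
#'   \linkS4class{ExposureExperiment}, \code{colData} column \code{arm})
#'   and \code{truth} as in [simulateAcute()].
#' @export
simulateChronic <- function(design) {
  stopifnot(inherits(design, "ChronicDesign"))
  .withSeed(design$seed, {
    genes <- .geneIds(design$n_genes)
    sp <- .resolveSpikes(design, genes, design$n_affected_genes)
    spiked <- sp$spiked; dir <- sp$dir
    baseline <- stats::rnorm(design$n_genes, mean = 8, sd = 1)
    shift <- numeric(design$n_genes)
    names(shift) <- genes
    shift[spiked] <- dir * design$effect_size_log2
    grid <- expand.grid(replicate = seq_len(design$replicates_per_arm),
                        arm = design$arms, stringsAsFactors = FALSE)
    treated <- grid$arm != design$arms[1]
    mat <- vapply(seq_len(nrow(grid)), function(j) {
      baseline + shift * treated[j] +
        stats::rnorm(design$n_genes, 0, design$noise_sd_log2)
    }, numeric(design$n_genes))
    rownames(mat) <- genes
    colnames(mat) <- sprintf("%s_r%d", grid$arm, grid$replicate)
    cd <- data.frame(arm = grid$arm, replicate = grid$replicate,
                     time_h = 30 * 24)
    list(experiment = ExposureExperiment(mat, cd, level = "gene"),
         truth = data.frame(gene = spiked,
                            direction = ifelse(dir > 0, "up", "down"),
                            effect_size_log2 = dir * design$effect_size_log2,
                            stringsAsFactors = FALSE))
  })
}

.defaultSchedule <- c("c1d1", "c1d8", "c1d15", "c2d1", "c2d8", "c3d1",
                      "c3d8", "m1post", "y1")

.defaultMarkerUnits <- c("GDF-15" = "pg/mL", "vWF" = "%", "hsCRP" = "mg/L")

# Per-marker course profiles: published cohort medians at each schedule
# point divided by the baseline median, so simulated medians track the
# observed time courses (GDF-15 pg/mL, vWF %, hsCRP mg/L).
.defaultMultipliers <- function() {
  m <- rbind(
    `GDF-15` = c(383.1, 3473.7, 1587.2, 1145.5, 4898.0, 2067.7, 5542.8,
                 1009.6, 395.2) / 383.1,
    vWF = c(100, 164, 145, 143, 197, 194, 197, 135, 115) / 100,
    hsCRP = c(2.0, 0.6, 4.2, 5.1, 0.6, 3.7, 0.6, 2.2, 1.5) / 2.0)
  colnames(m) <- .defaultSchedule
  m
}

#' Plasma biomarker panel design parameters
#'
#' Parameter bundle for [simulatePlasma()]: a 41-patient panel sampled on
#' the three-week BEP course schedule with three markers (GDF-15 in pg/mL,
#' vWF in %, hsCRP in mg/L). Values are lognormal around
#' baseline-median-times-multiplier targets with a Gaussian copula linking
#' markers within a (patient, time point) draw. Default baseline medians
#' and course multipliers follow the published cohort medians; log-scale
#' SDs are set so the simulated ranges resemble the observed ones.
#'
#' @param n_patients Number of patients.
#' @param timepoint_labels Ordered sampling schedule labels.
#' @param markers Marker names; must have units in \code{marker_units}.
#' @param marker_units Named character vector of units per marker.
#' @param baseline_log_medians Named natural-log baseline medians.
#' @param course_multipliers Marker x time-point matrix of multiplicative
#'   median shifts (all > 0; baseline column should be 1).
#' @param log_sd Named per-marker SD on the natural-log scale.
#' @param cross_marker_rho Pairwise latent Gaussian correlation, |rho| < 1.
#' @param missing_rate Probability a (patient, time point) visit is absent.
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{"PlasmaDesign"}.
#' @export
plasmaDesign <- function(n_patients = 41,
                         timepoint_labels = .defaultSchedule,
                         markers = names(.defaultMarkerUnits),
                         marker_units = .defaultMarkerUnits,
                         baseline_log_medians = NULL,
                         course_multipliers = NULL,
                         log_sd = NULL,
                         cross_marker_rho = 0.35,
                         missing_rate = 0.05, seed = 1L) {
  if (n_patients < 1) stop("invalid design: n_patients must be >= 1")
  unknown <- setdiff(markers, names(marker_units))
  if (length(unknown))
    stop("unknown marker label(s) without units: ",
         paste(unknown, collapse = ", "))
  if (is.null(baseline_log_medians)) {
    baseline_log_medians <- log(c(`GDF-15` = 383.1, vWF = 100, hsCRP = 2.0))
    baseline_log_medians <- baseline_log_medians[markers]
  }
  if (any(is.na(baseline_log_medians[markers])))
    stop("baseline_log_medians required for every marker")
  if (is.null(course_multipliers)) {
    course_multipliers <- .defaultMultipliers()[markers, timepoint_labels,
                                               drop = FALSE]
  }
  if (any(course_multipliers <= 0))
    stop("invalid design: course multipliers must be > 0")
  if (!all(markers %in% rownames(course_multipliers)) ||
      !all(timepoint_labels %in% colnames(course_multipliers)))
    stop("course_multipliers must cover every marker and time point")
  if (is.null(log_sd)) {
    log_sd <- c(`GDF-15` = 0.6, vWF = 0.5, hsCRP = 1.0)[markers]
    log_sd[is.na(log_sd)] <- 0.5
    names(log_sd) <- markers
  }
  if (abs(cross_marker_rho) >= 1)
    stop("invalid design: |cross_marker_rho| must be < 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid design: missing_rate must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 timepoint_labels = timepoint_labels, markers = markers,
                 marker_units = marker_units[markers],
                 baseline_log_medians = baseline_log_medians[markers],
                 course_multipliers =
                   course_multipliers[markers, timepoint_labels, drop = FALSE],
                 log_sd = log_sd[markers],
                 cross_marker_rho = cross_marker_rho,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "PlasmaDesign")
}

#' Simulate a longitudinal plasma biomarker panel
#'
#' For every retained (patient, time point) visit, a latent Gaussian
#' vector with pairwise correlation \code{cross_marker_rho} is drawn and
#' mapped marker-wise to \code{exp(log_median + log(multiplier) +
#' log_sd * z)}, so per-marker per-time-point sample medians converge to
#' baseline-median-times-multiplier and cross-marker dependence follows a
#' Gaussian copula. Visits are dropped completely at random with
#' probability \code{missing_rate}. Patient metadata (age, IGCCCG
#' prognosis group, tumor stage, regimen) are sampled to match the
#' published cohort frequencies.
#'
#' @param design A [plasmaDesign()].
#' @return A list with \code{panel} (a \linkS4class{PlasmaPanel}) and
#'   \code{truth} (the multiplier matrix and latent rho).
#' @export
simulatePlasma <- function(design) {
  stopifnot(inherits(design, "PlasmaDesign"))
  .withSeed(design$seed, {
    nm <- length(design$markers)
    R <- matrix(design$cross_marker_rho, nm, nm)
    diag(R) <- 1
    pts <- sprintf("P%03d", seq_len(design$n_patients))
    visits <- expand.grid(patient_id = pts,
                          timepoint = design$timepoint_labels,
                          stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(visits)) >= design$missing_rate
    visits <- visits[keep, , drop = FALSE]
    z <- MASS::mvrnorm(nrow(visits), mu = rep(0, nm), Sigma = R)
    z <- matrix(z, ncol = nm)
    recs <- do.call(rbind, lapply(seq_along(design$markers), function(k) {
      mk <- design$markers[k]
      data.frame(patient_id = visits$patient_id,
                 timepoint = visits$timepoint, marker = mk,
                 value = exp(design$baseline_log_medians[[mk]] +
                             log(design$course_multipliers[mk,
                                                           visits$timepoint]) +
                             design$log_sd[[mk]] * z[, k]),
                 unit = design$marker_units[[mk]],
                 stringsAsFactors = FALSE)
    }))
    patients <- data.frame(
      patient_id = pts,
      age_years = round(stats::runif(design$n_patients, 18, 46)),
      igcccg_group = sample(c("good", "intermediate", "poor"),
                            design$n_patients, replace = TRUE,
                            prob = c(33, 7, 1) / 41),
      tumor_stage = sample(c("II", "III", "IV"), design$n_patients,
                           replace = TRUE, prob = c(30, 4, 7) / 41),
      regimen = sample(c("3xBEP", "4xBEP", "4xEP"), design$n_patients,
                       replace = TRUE, prob = c(29, 11, 1) / 41),
      stringsAsFactors = FALSE)
    panel <- new("PlasmaPanel",
                 measurements = S4Vectors::DataFrame(recs),
                 patients = S4Vectors::DataFrame(patients),
                 schedule = design$timepoint_labels)
    list(panel = panel,
         truth = list(course_multipliers = design$course_multipliers,
                      cross_marker_rho = design$cross_marker_rho))
  })
}

#' Simulate a gene-set catalog
#'
#' Random sets drawn from a gene universe, optionally with one planted set
#' of supplied member ids (useful for enrichment recovery experiments).
#'
#' @param n_sets Number of random sets (default 169, a KEGG-scale catalog).
#' @param size_range Integer range of set sizes, within \code{[2, n_genes]}.
#' @param n_genes Size of the gene universe (ids as in the simulators).
#' @param planted_set Optional character vector of gene ids inserted
#'   verbatim as an extra set named \code{"PLANTED"}.
#' @param seed Integer RNG seed.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
simulateGeneSets <- function(n_sets = 169, size_range = c(10, 100),
                             n_genes = 15950, planted_set = NULL,
                             seed = 1L) {
  if (length(size_range) != 2L || size_range[1] > size_range[2])
    stop("size_range must be a non-empty (lo, hi) pair")
  if (size_range[1] < 2 || size_range[2] > n_genes)
    stop("size_range must lie within [2, n_genes]")
  .withSeed(seed, {
    universe <- .geneIds(n_genes)
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
    desc <- rep("simulated", n_sets)
    if (!is.null(planted_set)) {
      sets <- c(sets, list(PLANTED = unique(planted_set)))
      desc <- c(desc, "planted")
    }
    names(desc) <- names(sets)
    new("GeneSetCollection", sets = sets, descriptions = desc)
  })
}
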