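#' @include AllClasses.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the biomarker discovery pipeline
#'
#' End-to-end candidate discovery: per-study robust standardization,
#' probe-to-gene collapsing where needed, per-sample quantile
#' discretization at `qDisease` bins, per-disease merging and
#' differential expression, then re-discretization of all studies at
#' `qIntegrated` bins, full integration, integrated differential
#' expression, and cross-disease intersection with top-k ranking.
#' Defaults are Q = 128 within disease and Q = 1028 for the integrated
#' run (1028 is kept verbatim as the conventional value for this
#' pipeline even though a power of two, 1024, may look more natural).
#'
#' Inputs are either a list of [ExpressionStudy] objects (`studies`,
#' with optional per-study probe `maps`) or a simulation design
#' (`design`, as returned by [plantedOverlapDesign()], simulated with
#' `seed`).
#'
#' @param studies Optional list of [ExpressionStudy] objects covering
#'   both diseases.
#' @param maps Optional named list of probe maps for probe-level
#'   studies (names = study ids).
#' @param design Optional simulation design (list with `t2dmParams`,
#'   `cvdParams`, `overlapIds`); used when `studies` is `NULL`.
#' @param qDisease,qIntegrated Bin counts for the within-disease and
#'   integrated runs.
#' @param alpha DEG significance level (primary call: BH q < alpha).
#' @param k Top-k candidate count.
#' @param which DEG call used for the per-disease sets (`"bh"`,
#'   `"bonferroni"`, `"raw"`).
#' @param seed Integer seed for simulation.
#' @param outDir Optional output directory: writes per-stage bin TSVs,
#'   the DEG tables, and a JSON report with per-stage gene counts.
#' @return A list with `candidates` (a [CandidateSet]), `deg` (the
#'   three [DEGTable]s), `truth` (when simulated) and `report` (the
#'   per-stage count summary: per-disease DEG counts and the common
#'   candidate count, the Venn-style triple for these inputs).
#' @export
runDiscovery <- function(studies = NULL, maps = NULL, design = NULL,
                         qDisease = 128L, qIntegrated = 1028L,
                         alpha = 0.05, k = 2L,
                         which = c("bh", "bonferroni", "raw"),
                         seed = 1L, outDir = NULL) {
  which <- match.arg(which)
  truth <- NULL
  if (is.null(studies)) {
    if (is.null(design)) stop("supply either 'studies' or 'design'")
    sim <- .stage("simulate", simulateDiseaseCollection(
      design$t2dmParams, design$cvdParams, design$overlapIds, seed = seed))
    studies <- sim$studies
    truth <- sim$truth
  }
  byDisease <- split(studies, vapply(studies, disease, character(1)))
  if (!all(c("T2DM", "CVD") %in% names(byDisease)))
    stop("need at least one study per disease (T2DM and CVD)")
  prep <- .stage("preprocess", lapply(studies, function(s) {
    s <- standardizeStudy(s)
    if (exprLevel(s) == "probe") {
      pm <- maps[[studyId(s)]]
      if (is.null(pm)) stop("no probe map for study ", studyId(s))
      s <- collapseProbes(s, pm)
    }
    s
  }))
  diseaseOf <- vapply(prep, disease, character(1))
  degDisease <- list()
  mergedDisease <- list()
  for (dz in c("T2DM", "CVD")) {
    dd <- .stage(paste0("discretize-", dz),
                 lapply(prep[diseaseOf == dz], quantileDiscretize,
                        Q = qDisease))
    merged <- if (length(dd) > 1L)
      .stage(paste0("merge-", dz), mergeStudies(dd)) else dd[[1]]
    mergedDisease[[dz]] <- merged
    degDisease[[dz]] <- .stage(paste0("diffexp-", dz),
                               runDifferentialExpression(merged, alpha))
  }
  ddInt <- .stage("discretize-integrated",
                  lapply(prep, quantileDiscretize, Q = qIntegrated))
  mergedInt <- if (length(ddInt) > 1L)
    .stage("merge-integrated", mergeStudies(ddInt)) else ddInt[[1]]
  degInt <- .stage("diffexp-integrated",
                   runDifferentialExpression(mergedInt, alpha))
  candidates <- .stage("intersect", intersectAndRank(
    degDisease$T2DM, degDisease$CVD, degInt, k = k, which = which))
  report <- list(
    schema_version = "1.0",
    seed = seed,
    q_disease = as.integer(qDisease),
    q_integrated = as.integer(qIntegrated),
    alpha = alpha,
    deg_call = which,
    n_studies = length(studies),
    genes_per_study = vapply(studies, nrow, integer(1)),
    n_deg_t2dm = length(degGenes(degDisease$T2DM, which)),
    n_deg_cvd = length(degGenes(degDisease$CVD, which)),
    n_common = length(candidates@commonGenes),
    top_candidates = as.list(topCandidates(candidates)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (dz in names(mergedDisease))
      writeBinsTSV(mergedDisease[[dz]],
                   file.path(outDir, paste0("bins_", tolower(dz), ".tsv")))
    writeBinsTSV(mergedInt, file.path(outDir, "bins_integrated.tsv"))
    for (dz in names(degDisease))
      utils::write.table(as.data.frame(degDisease[[dz]]),
                         file.path(outDir, paste0("deg_", tolower(dz), ".tsv")),
                         sep = "\t", quote = FALSE)
    utils::write.table(as.data.frame(degInt),
                       file.path(outDir, "deg_integrated.tsv"),
                       sep = "\t", quote = FALSE)
    writeReport(c(report,
                  list(ranking = candidateRanking(candidates))),
                file.path(outDir, "discovery_report.json"))
  }
  list(candidates = candidates,
       deg = list(T2DM = degDisease$T2DM, CVD = degDisease$CVD,
                  integrated = degInt),
       truth = truth, report = report)
}

.panelReportAsList <- function(pr) {
  comps <- lapply(pr@composites, function(cs) {
    out <- list(mode = cs@mode, weights = as.list(cs@weights))
    if (!is.na(cs@varianceShare)) out$variance_share <- cs@varianceShare
    out
  })
  rocs <- lapply(pr@roc, function(r) list(
    auc = r@auc, flipped = r@flipped, cutoff = r@cutoff,
    sens_at_cutoff = r@sensAtCutoff, spec_at_cutoff = r@specAtCutoff,
    n_case = r@nCase, n_control = r@nControl, degenerate = r@degenerate))
  list(schema_version = pr@schemaVersion,
       markers = as.list(pr@markers),
       weeks_roc = as.list(pr@weeksRoc),
       readout = pr@readout,
       weekly_tests = pr@weeklyTests,
       composites = comps,
       roc = rocs,
       correlations = pr@correlations)
}

#' Run the panel-evaluation arm
#'
#' Wraps [evaluatePanel()] with simulation or file input and JSON
#' report output. The log records group sizes per week (counts only,
#' never data values).
#'
#' @param panel Optional [BiomarkerPanel]; when `NULL`, the default
#'   serum-panel generator is used with `seed`.
#' @param params [panelSimParams()] used when simulating.
#' @param markers Markers to evaluate (default: all).
#' @param weeksRoc Inclusive ROC week window, default `c(9, 14)`.
#' @param readout Functional readout column.
#' @param seed Integer seed for simulation.
#' @param outDir Optional output directory for `panel_report.json` and
#'   the panel CSV.
#' @return A list with `report` (a [PanelReport]), `truth` (when
#'   simulated) and `panel`.
#' @export
runPanelEvaluation <- function(panel = NULL, params = panelSimParams(),
                               markers = NULL, weeksRoc = c(9L, 14L),
                               readout = "ea_ratio", seed = 1L,
                               outDir = NULL) {
  truth <- NULL
  if (is.null(panel)) {
    sim <- .stage("simulate-panel", simulateSerumPanel(params, seed = seed))
    panel <- sim$panel
    truth <- sim$truth
  }
  if (is.null(markers)) markers <- markerNames(panel)
  d <- panelData(panel)
  tab <- table(d$week, d$group)
  message("panel records per week x group: ",
          paste(apply(tab, 1L, paste, collapse = "/"), collapse = ", "))
  pr <- .stage("evaluate-panel",
               evaluatePanel(panel, markers = markers,
                             weeksRoc = weeksRoc, readout = readout))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePanel(panel, file.path(outDir, "panel.csv"))
    writeReport(c(.panelReportAsList(pr), list(seed = seed)),
                file.path(outDir, "panel_report.json"))
  }
  list(report = pr, truth = truth, panel = panel)
}

#' Run discovery and panel evaluation together
#'
#' Executes [runDiscovery()] followed by [runPanelEvaluation()] and
#' writes a manifest linking the outputs, the seeds and a hash of the
#' configuration, sufficient for an exact re-run.
#'
#' @param config A list with optional elements `design`
#'   ([plantedOverlapDesign()] output), `panelParams`
#'   ([panelSimParams()]), `qDisease`, `qIntegrated`, `alpha`, `k`,
#'   `weeksRoc`.
#' @param seed Integer seed used for both arms.
#' @param outDir Output directory (required).
#' @return A list with `discovery`, `panel`, `manifest`.
#' @export
runAll <- function(config = list(), seed = 1L, outDir) {
  if (missing(outDir)) stop("outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design %||% plantedOverlapDesign()
  disc <- runDiscovery(design = design,
                       qDisease = config$qDisease %||% 128L,
                       qIntegrated = config$qIntegrated %||% 1028L,
                       alpha = config$alpha %||% 0.05,
                       k = config$k %||% 2L, seed = seed,
                       outDir = file.path(outDir, "discovery"))
  pan <- runPanelEvaluation(params = config$panelParams %||%
                              panelSimParams(),
                            weeksRoc = config$weeksRoc %||% c(9L, 14L),
                            seed = seed,
                            outDir = file.path(outDir, "panel"))
  cfgFile <- file.path(outDir, "config.json")
  jsonlite::write_json(.serializeConfig(config), cfgFile,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("dcmScreen")),
    seed = seed,
    config_file = "config.json",
    config_hash = unname(tools::md5sum(cfgFile)),
    outputs = list(discovery = "discovery/discovery_report.json",
                   panel = "panel/panel_report.json"))
  writeReport(manifest, file.path(outDir, "manifest.json"))
  list(discovery = disc, panel = pan, manifest = manifest)
}

# flatten a config (possibly holding parameter objects) to plain lists
.serializeConfig <- function(config) {
  rapply(config, function(x) x, how = "replace")
}
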