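#' @include AllClasses.R
NULL

.geneUniverse <- function(nGenes) sprintf("g%05d", seq_len(nGenes))

#' Simulation parameters for one expression study
#'
#' Describes one synthetic microarray study: a shared gene universe of
#' `nGenes` genes, group sizes, the set of planted differentially
#' expressed (DE) genes with their effect size (a location shift in
#' within-group standard-deviation units, so rank-test power is
#' analytically predictable), and a platform profile (affine scale and
#' offset followed by an optional strictly monotone warp) emulating
#' platform-specific intensity scales. Baseline expression per gene is
#' drawn normal on the log scale to mimic array intensity skew; the
#' warp is applied after the effects, so cross-platform comparability
#' exists only at the rank level — quantile discretization is the
#' load-bearing integration step.
#'
#' @param nGenes Number of genes (>= 1).
#' @param nCase,nControl Group sizes (each >= 2).
#' @param deGenes Character vector of planted DE gene ids (subset of
#'   the universe `sprintf("g%05d", 1:nGenes)`).
#' @param effectSize Non-negative shift in within-group SD units:
#'   either a scalar applied to all `deGenes` or a named vector with
#'   one entry per DE gene.
#' @param platformScale,platformOffset Affine platform transform
#'   applied before the warp (`scale` must be > 0 to keep the
#'   transform strictly increasing).
#' @param warp Monotone platform warp: `"none"`, `"exp"` (exponential)
#'   or `"power"` (signed cube).
#' @param noiseSd Within-group noise SD (> 0).
#' @return A validated parameter list of class `StudySimParams`.
#' @seealso [simulateStudy()]
#' @export
studySimParams <- function(nGenes = 2000, nCase = 10, nControl = 10,
                           deGenes = character(), effectSize = 0,
                           platformScale = 1, platformOffset = 0,
                           warp = c("none", "exp", "power"),
                           noiseSd = 1) {
  warp <- match.arg(warp)
  if (nGenes < 1L) stop("nGenes must be >= 1")
  if (nCase < 2L || nControl < 2L)
    stop("degenerate params: nCase and nControl must each be >= 2")
  if (any(effectSize < 0)) stop("effectSize must be >= 0")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (platformScale <= 0) stop("platformScale must be > 0")
  universe <- .geneUniverse(nGenes)
  deGenes <- as.character(deGenes)
  if (!all(deGenes %in% universe))
    stop("deGenes must be a subset of the gene universe")
  if (length(effectSize) > 1L) {
    if (is.null(names(effectSize)) || !all(names(effectSize) %in% deGenes))
      stop("a vector effectSize must be named by DE gene id")
    eff <- rep(effectSize[[1]], length(deGenes))
    names(eff) <- deGenes
    eff[names(effectSize)] <- effectSize
  } else {
    eff <- rep(as.numeric(effectSize), length(deGenes))
    names(eff) <- deGenes
  }
  structure(list(nGenes = as.integer(nGenes), nCase = as.integer(nCase),
                 nControl = as.integer(nControl), deGenes = deGenes,
                 effectSize = eff, platformScale = platformScale,
                 platformOffset = platformOffset, warp = warp,
                 noiseSd = noiseSd),
            class = "StudySimParams")
}

.applyWarp <- function(x, params) {
  y <- params$platformScale * x + params$platformOffset
  switch(params$warp,
         none = y,
         exp = exp(y),
         power = sign(y) * abs(y)^3)
}

#' Simulate one expression study with planted DE genes
#'
#' Generates `values = baseline(gene) + d * noiseSd * 1[case & DE] +
#' noise`, then applies the platform profile (affine transform followed
#' by the monotone warp). Baselines are drawn once per gene from
#' N(6, 1.5) on the log2-intensity scale. Fully reproducible given
#' `seed`; with `effectSize = 0` the truth set is kept but the study is
#' a global-null dataset.
#'
#' @param params A [studySimParams()] object.
#' @param studyId,disease,platform Study descriptors.
#' @param seed Integer seed.
#' @param baseline Optional numeric vector of per-gene baselines.
#'   A gene's baseline is a property of the gene, so studies meant to
#'   be integrated must share it ([simulateDiseaseCollection()] draws
#'   it once per collection); when `NULL`, a fresh baseline is drawn.
#' @return A list with elements `study` (an [ExpressionStudy], gene
#'   level) and `truth` (list with `deGenes` and `effectSize`).
#' @export
simulateStudy <- function(params, studyId = "sim", disease = "T2DM",
                          platform = NULL, seed = 1L, baseline = NULL) {
  stopifnot(inherits(params, "StudySimParams"))
  set.seed(seed)
  G <- params$nGenes
  n <- params$nCase + params$nControl
  genes <- .geneUniverse(G)
  if (is.null(baseline)) baseline <- stats::rnorm(G, mean = 6, sd = 1.5)
  if (length(baseline) != G) stop("baseline must have one value per gene")
  m <- baseline + matrix(stats::rnorm(G * n, sd = params$noiseSd), G, n)
  cond <- rep(c("case", "control"), c(params$nCase, params$nControl))
  if (length(params$deGenes)) {
    idx <- match(params$deGenes, genes)
    shift <- params$effectSize * params$noiseSd
    m[idx, cond == "case"] <- m[idx, cond == "case"] + shift
  }
  m <- .applyWarp(m, params)
  dimnames(m) <- list(genes, sprintf("%s_s%02d", studyId, seq_len(n)))
  study <- ExpressionStudy(m, cond, studyId = studyId, disease = disease,
                           platform = platform %||%
                             paste0("sim-", params$warp),
                           level = "gene")
  list(study = study,
       truth = list(deGenes = params$deGenes,
                    effectSize = params$effectSize))
}

#' Simulate a two-disease collection with a known DEG overlap
#'
#' Generates several studies per disease on a shared gene universe but
#' heterogeneous platform profiles, with planted DE genes whose
#' cross-disease overlap is known, emulating a T2DM + CVD integration
#' design. `overlapIds` must be planted as DE in at least one study of
#' each disease.
#'
#' @param t2dmParams,cvdParams Lists of [studySimParams()] objects, one
#'   per study; all must share `nGenes`.
#' @param overlapIds Character vector of planted cross-disease overlap
#'   gene ids (may be empty, in which case the downstream intersection
#'   stage must come up empty).
#' @param seed Integer seed; per-study sub-seeds are derived from it.
#' @return A list with `studies` (list of [ExpressionStudy]) and
#'   `truth` (planted DE ids per disease, overlap ids, per-study truth).
#' @export
simulateDiseaseCollection <- function(t2dmParams, cvdParams, overlapIds,
                                      seed = 1L) {
  allParams <- c(t2dmParams, cvdParams)
  if (!all(vapply(allParams, inherits, logical(1), "StudySimParams")))
    stop("params must be StudySimParams objects")
  nG <- unique(vapply(allParams, `[[`, integer(1), "nGenes"))
  if (length(nG) != 1L)
    stop("all studies must share the gene universe (same nGenes)")
  deT2dm <- unique(unlist(lapply(t2dmParams, `[[`, "deGenes")))
  deCvd <- unique(unlist(lapply(cvdParams, `[[`, "deGenes")))
  overlapIds <- as.character(overlapIds)
  if (!all(overlapIds %in% deT2dm) || !all(overlapIds %in% deCvd))
    stop("overlapIds must be planted as DE in at least one study of ",
         "each disease")
  diseases <- rep(c("T2DM", "CVD"), c(length(t2dmParams), length(cvdParams)))
  # per-gene baselines are a property of the gene, shared by every
  # study of the collection; platform heterogeneity enters only through
  # each study's monotone profile
  set.seed(seed)
  baseline <- stats::rnorm(nG, mean = 6, sd = 1.5)
  studies <- vector("list", length(allParams))
  perStudy <- vector("list", length(allParams))
  for (i in seq_along(allParams)) {
    sid <- sprintf("%s%02d", tolower(diseases[i]), i)
    res <- simulateStudy(allParams[[i]], studyId = sid,
                         disease = diseases[i],
                         seed = (seed + 1000L * i) %% .Machine$integer.max,
                         baseline = baseline)
    studies[[i]] <- res$study
    perStudy[[sid]] <- res$truth
  }
  names(studies) <- vapply(studies, studyId, character(1))
  list(studies = studies,
       truth = list(deT2dm = deT2dm, deCvd = deCvd,
                    overlap = overlapIds, perStudy = perStudy))
}

#' Planted-overlap discovery design
#'
#' Convenience design for end-to-end discovery runs: two studies per
#' disease on a 2000-gene universe (15 case vs 15 control each, a
#' typical desk-scale microarray design matched to the spike-in power
#' analysis), 50 cross-disease overlap genes plus 30 disease-specific
#' DE genes per disease at baseline effect `dBase`, with the two
#' designated strongest overlap genes planted at `dStrong` in every
#' study. Platform profiles differ across studies (one raw, one
#' exponentially warped per disease), so integration is only possible
#' at the rank level.
#'
#' @param nGenes Gene universe size.
#' @param nOverlap Number of planted cross-disease overlap genes.
#' @param nSpecific Disease-specific DE genes per disease.
#' @param nCase,nControl Per-study group sizes.
#' @param dStrong,dBase Effect sizes (within-group SD units) for the
#'   two strongest overlap genes and for all other planted genes.
#' @return A list with `t2dmParams`, `cvdParams`, `overlapIds`,
#'   `strongest` (the two top-effect gene ids), suitable for
#'   [simulateDiseaseCollection()] / [runDiscovery()].
#' @export
plantedOverlapDesign <- function(nGenes = 2000, nOverlap = 50,
                                 nSpecific = 30, nCase = 15, nControl = 15,
                                 dStrong = 3, dBase = 1.5) {
  universe <- .geneUniverse(nGenes)
  if (nOverlap + 2L * nSpecific > nGenes)
    stop("gene universe too small for the requested planted sets")
  overlap <- universe[seq_len(nOverlap)]
  strongest <- overlap[seq_len(min(2L, nOverlap))]
  specT <- universe[nOverlap + seq_len(nSpecific)]
  specC <- universe[nOverlap + nSpecific + seq_len(nSpecific)]
  mkEff <- function(de) {
    eff <- rep(dBase, length(de))
    names(eff) <- de
    eff[intersect(strongest, de)] <- dStrong
    eff
  }
  mk <- function(de, warp)
    studySimParams(nGenes = nGenes, nCase = nCase, nControl = nControl,
                   deGenes = de, effectSize = mkEff(de), warp = warp,
                   platformScale = if (warp == "exp") 0.5 else 1)
  list(t2dmParams = list(mk(c(overlap, specT), "none"),
                         mk(c(overlap, specT), "exp")),
       cvdParams = list(mk(c(overlap, specC), "none"),
                        mk(c(overlap, specC), "exp")),
       overlapIds = overlap, strongest = strongest)
}

#' Simulation parameters for a longitudinal serum panel
#'
#' Describes a terminal two-group design (different animals at each
#' week, as in a db/db vs db/+ termination scheme): a week schedule,
#' per-group animal counts, per-marker baseline / SD / case shift
#' trajectory (shifts in baseline-SD units), and an E:A-ratio model
#' with group-by-week means plus per-marker coupling weights that link
#' each marker's within-cell deviation to the E:A deviation.
#'
#' The defaults plant three markers emulating the published serum
#' trajectories: `marker_up` case-elevated from week 9 (LOXL2-like),
#' `marker_down` case-reduced from week 11 (ETFbeta-like), and
#' `marker_null` with no group effect (NT-proBNP-like comparator,
#' unchanged across weeks). E:A declines in cases from week 11 and is
#' coupled negatively to `marker_up` and positively to `marker_down`;
#' the default couplings put the pooled population correlation near
#' |r| = 0.65.
#'
#' @param weeks Strictly increasing integer week schedule.
#' @param nPerGroup Animals per group per week.
#' @param markerSpecs Named list; each element a list with `baseline`,
#'   `sd` (> 0) and `caseShift` (numeric vector along `weeks`, in
#'   baseline-SD units).
#' @param eaModel List with `controlMean` and `caseMean` (numeric along
#'   `weeks`), `sd` (> 0) and `coupling` (named numeric, names must be
#'   markers).
#' @return A validated parameter list of class `PanelSimParams`.
#' @seealso [simulateSerumPanel()]
#' @export
panelSimParams <- function(weeks = c(6L, 9L, 11L, 14L, 16L),
                           nPerGroup = 8L,
                           markerSpecs = list(
                             marker_up = list(baseline = 10, sd = 1,
                               caseShift = c(0.5, 1.5, 2, 1.5, 1.5)),
                             marker_down = list(baseline = 8, sd = 1,
                               caseShift = c(0, -0.5, -2, -2.5, -1.5)),
                             marker_null = list(baseline = 12, sd = 1,
                               caseShift = c(0, 0, 0, 0, 0))),
                           eaModel = list(
                             controlMean = c(1.6, 1.6, 1.6, 1.6, 1.6),
                             caseMean = c(1.6, 1.5, 1.25, 1.15, 1.1),
                             sd = 0.12,
                             coupling = c(marker_up = -0.08,
                                          marker_down = 0.08,
                                          marker_null = 0))) {
  weeks <- as.integer(weeks)
  if (is.unsorted(weeks, strictly = TRUE))
    stop("weeks must be strictly increasing")
  if (nPerGroup < 2L) stop("nPerGroup must be >= 2")
  for (nm in names(markerSpecs)) {
    sp <- markerSpecs[[nm]]
    if (sp$sd <= 0) stop("marker '", nm, "': sd must be > 0")
    if (length(sp$caseShift) != length(weeks))
      stop("marker '", nm, "': caseShift must have one entry per week")
  }
  if (eaModel$sd <= 0) stop("eaModel sd must be > 0")
  if (length(eaModel$controlMean) != length(weeks) ||
      length(eaModel$caseMean) != length(weeks))
    stop("eaModel means must have one entry per week")
  unknown <- setdiff(names(eaModel$coupling), names(markerSpecs))
  if (length(unknown))
    stop("coupling for unknown marker(s): ", paste(unknown, collapse = ", "))
  structure(list(weeks = weeks, nPerGroup = as.integer(nPerGroup),
                 markerSpecs = markerSpecs, eaModel = eaModel),
            class = "PanelSimParams")
}

#' Simulate a longitudinal serum biomarker panel
#'
#' Generates one animal-week record per animal (terminal design). For
#' each marker, `value = baseline + caseShift[week] * sd * 1[case] +
#' N(0, sd)`; the E:A readout is its group-by-week mean plus the
#' coupling-weighted sum of marker deviations plus noise. The truth set
#' records the planted effect sign per marker and the planted
#' marker-vs-E:A correlation signs.
#'
#' @param params A [panelSimParams()] object.
#' @param seed Integer seed.
#' @return A list with `panel` (a [BiomarkerPanel]) and `truth`.
#' @export
simulateSerumPanel <- function(params = panelSimParams(), seed = 1L) {
  stopifnot(inherits(params, "PanelSimParams"))
  set.seed(seed)
  wks <- params$weeks
  npg <- params$nPerGroup
  markers <- names(params$markerSpecs)
  rows <- expand.grid(idx = seq_len(npg), group = c("control", "case"),
                      week = wks, stringsAsFactors = FALSE)
  rows$animal_id <- sprintf("%s_w%02d_%02d",
                            ifelse(rows$group == "case", "db", "wt"),
                            rows$week, rows$idx)
  wpos <- match(rows$week, wks)
  dev <- matrix(0, nrow(rows), length(markers),
                dimnames = list(NULL, markers))
  for (m in markers) {
    sp <- params$markerSpecs[[m]]
    noise <- stats::rnorm(nrow(rows), sd = sp$sd)
    shift <- ifelse(rows$group == "case", sp$caseShift[wpos] * sp$sd, 0)
    rows[[m]] <- sp$baseline + shift + noise
    dev[, m] <- noise
  }
  ea <- params$eaModel
  eaMean <- ifelse(rows$group == "case", ea$caseMean[wpos],
                   ea$controlMean[wpos])
  coup <- ea$coupling[markers]
  coup[is.na(coup)] <- 0
  rows$ea_ratio <- eaMean + as.numeric(dev %*% coup) +
    stats::rnorm(nrow(rows), sd = ea$sd)
  panel <- BiomarkerPanel(
    rows[c("animal_id", "group", "week", markers, "ea_ratio")],
    markers = markers, weeks = wks)
  effSign <- vapply(params$markerSpecs, function(sp) {
    s <- sum(sp$caseShift)
    if (s > 0) 1 else if (s < 0) -1 else 0
  }, numeric(1))
  # pooled marker/E:A correlation sign: residual coupling plus the
  # co-movement of group-by-week means
  corSign <- vapply(markers, function(m) {
    sp <- params$markerSpecs[[m]]
    mMeans <- c(rep(sp$baseline, length(wks)),
                sp$baseline + sp$caseShift * sp$sd)
    aMeans <- c(ea$controlMean, ea$caseMean)
    between <- stats::cov(mMeans, aMeans)
    sign(between + coup[[m]] * sp$sd^2)
  }, numeric(1))
  list(panel = panel,
       truth = list(effectSign = effSign, corSign = corSign))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
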