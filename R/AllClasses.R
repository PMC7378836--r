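#' @include AllGenerics.R
NULL

.DISEASES <- c("T2DM", "CVD")
.LEVELS <- c("gene", "probe")
.CONDITIONS <- c("control", "case")

.checkCondition <- function(cond) {
  if (is.null(cond))
    return("colData must contain a 'condition' column")
  if (!is.factor(cond) || !identical(levels(cond), .CONDITIONS))
    return("'condition' must be a factor with levels 'control', 'case'")
  if (anyNA(cond))
    return("'condition' contains missing values")
  if (sum(cond == "case") < 1L || sum(cond == "control") < 1L)
    return("need at least one case and one control sample")
  NULL
}

# ---------------------------------------------------------------- ExpressionStudy

#' ExpressionStudy: one study's expression matrix with sample conditions
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' microarray study: a feature x sample real-valued matrix (assay
#' `"exprs"`, on whatever scale the platform produced), a per-sample
#' `condition` factor (`control`/`case`) in `colData`, and study
#' descriptors: study id, disease arm (`T2DM` or `CVD`), platform tag,
#' and measurement level (`probe` or `gene`).
#'
#' Validity requires matching dimension names, unique feature and sample
#' ids, finite values, and at least one sample per condition.
#'
#' @param values Numeric feature x sample matrix with row and column
#'   names (all values finite; expression matrices must be complete).
#' @param condition Character or factor giving `"case"`/`"control"` per
#'   sample, either positional or named by sample id.
#' @param studyId Character scalar study identifier.
#' @param disease `"T2DM"` or `"CVD"`.
#' @param platform Free-text platform tag.
#' @param level `"gene"` or `"probe"`.
#' @return An `ExpressionStudy` object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' es <- ExpressionStudy(m, c("case", "case", "control", "control"),
#'                       studyId = "ex1", disease = "T2DM")
#' sampleCondition(es)
#' @aliases ExpressionStudy
#' @export ExpressionStudy
#' @exportClass ExpressionStudy
setClass("ExpressionStudy",
  contains = "SummarizedExperiment",
  slots = c(studyId = "character", disease = "character",
            platformTag = "character", exprLevel = "character"))

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (length(object@studyId) != 1L || !nzchar(object@studyId))
    msg <- c(msg, "'studyId' must be a non-empty character scalar")
  if (length(object@disease) != 1L || !object@disease %in% .DISEASES)
    msg <- c(msg, "'disease' must be one of 'T2DM', 'CVD'")
  if (length(object@exprLevel) != 1L || !object@exprLevel %in% .LEVELS)
    msg <- c(msg, "'exprLevel' must be 'gene' or 'probe'")
  if (!"exprs" %in% assayNames(object)) {
    msg <- c(msg, "assay 'exprs' is required")
  } else {
    v <- assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "'exprs' must be numeric")
    else if (!all(is.finite(v))) msg <- c(msg, "'exprs' contains non-finite values")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cmsg <- .checkCondition(object$condition)
  if (!is.null(cmsg)) msg <- c(msg, cmsg)
  if (length(msg)) msg else TRUE
})

ExpressionStudy <- function(values, condition, studyId = "study",
                            disease = c("T2DM", "CVD"),
                            platform = "unknown",
                            level = c("gene", "probe")) {
  disease <- match.arg(disease)
  level <- match.arg(level)
  values <- as.matrix(values)
  if (!is.null(names(condition)) && !is.null(colnames(values))) {
    miss <- setdiff(colnames(values), names(condition))
    if (length(miss))
      stop("condition missing for sample(s): ", paste(miss, collapse = ", "))
    condition <- condition[colnames(values)]
  }
  cond <- factor(as.character(condition), levels = .CONDITIONS)
  if (anyNA(cond))
    stop("condition labels must be 'case' or 'control'")
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(condition = cond,
                                   row.names = colnames(values)))
  new("ExpressionStudy", se, studyId = studyId, disease = disease,
      platformTag = platform, exprLevel = level)
}

#' @rdname study-accessors
setMethod("studyId", "ExpressionStudy", function(x) x@studyId)
#' @rdname study-accessors
setMethod("disease", "ExpressionStudy", function(x) x@disease)
#' @rdname study-accessors
setMethod("platformTag", "ExpressionStudy", function(x) x@platformTag)
#' @rdname study-accessors
setMethod("exprLevel", "ExpressionStudy", function(x) x@exprLevel)
#' @rdname study-accessors
setMethod("sampleCondition", "ExpressionStudy", function(x) x$condition)

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy '", object@studyId, "' (", object@disease,
      ", platform: ", object@platformTag, ", level: ", object@exprLevel,
      ")\n", sep = "")
  cat("  ", nrow(object), " features x ", ncol(object), " samples (",
      sum(object$condition == "case"), " case / ",
      sum(object$condition == "control"), " control)\n", sep = "")
})

# ------------------------------------------------------------ DiscretizedDataset

#' DiscretizedDataset: quantile-discretized (binned) expression data
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' integer bin matrix produced by per-sample quantile discretization
#' (assay `"bins"`, entries in `1..Q`). `colData` carries the
#' per-sample `condition` factor and, after [mergeStudies()], `study`
#' and `disease` provenance tags so that merged (integrated) datasets
#' use the same container.
#'
#' @seealso [quantileDiscretize()], [mergeStudies()]
#' @aliases DiscretizedDataset
#' @exportClass DiscretizedDataset
setClass("DiscretizedDataset",
  contains = "SummarizedExperiment",
  slots = c(qBins = "integer"))

setValidity("DiscretizedDataset", function(object) {
  msg <- character()
  if (length(object@qBins) != 1L || is.na(object@qBins) || object@qBins < 1L)
    msg <- c(msg, "'qBins' must be a single integer >= 1")
  if (!"bins" %in% assayNames(object)) {
    msg <- c(msg, "assay 'bins' is required")
  } else {
    b <- assay(object, "bins")
    if (anyNA(b) || !all(b == round(b)))
      msg <- c(msg, "'bins' must be whole numbers")
    else if (length(b) && (min(b) < 1L || max(b) > object@qBins))
      msg <- c(msg, "bin values must lie in [1, Q]")
  }
  cmsg <- .checkCondition(object$condition)
  if (!is.null(cmsg)) msg <- c(msg, cmsg)
  if (length(msg)) msg else TRUE
})

.DiscretizedDataset <- function(bins, colData, Q) {
  se <- SummarizedExperiment(assays = list(bins = bins), colData = colData)
  new("DiscretizedDataset", se, qBins = as.integer(Q))
}

#' @rdname study-accessors
setMethod("qBins", "DiscretizedDataset", function(x) x@qBins)
#' @rdname study-accessors
setMethod("binMatrix", "DiscretizedDataset", function(x) assay(x, "bins"))
#' @rdname study-accessors
setMethod("sampleCondition", "DiscretizedDataset", function(x) x$condition)

setMethod("show", "DiscretizedDataset", function(object) {
  cat("DiscretizedDataset: ", nrow(object), " genes x ", ncol(object),
      " samples, Q = ", object@qBins, "\n", sep = "")
  if (!is.null(object$study))
    cat("  merged from studies: ",
        paste(unique(object$study), collapse = ", "), "\n", sep = "")
  cat("  ", sum(object$condition == "case"), " case / ",
      sum(object$condition == "control"), " control\n", sep = "")
})

# --------------------------------------------------------------- BiomarkerPanel

#' BiomarkerPanel: longitudinal two-group serum marker measurements
#'
#' Holds per-animal serum marker measurements from a terminal two-group
#' mouse design (`db/+` controls vs `db/db` cases): one row per
#' (animal, week) record with marker concentrations and the mitral E:A
#' ratio functional readout (missing E:A allowed and flagged).
#'
#' @param data A `data.frame` with columns `animal_id`, `group`
#'   (`"control"`/`"case"`, or raw labels `"db/+"`/`"db/db"`), `week`
#'   (integer), one numeric column per marker, and `ea_ratio` (numeric,
#'   `NA` allowed).
#' @param markers Character vector of marker column names.
#' @param weeks Declared week schedule (defaults to the weeks present).
#' @return A `BiomarkerPanel` object.
#' @examples
#' df <- data.frame(animal_id = c("a1", "a2", "b1", "b2"),
#'                  group = c("control", "control", "case", "case"),
#'                  week = c(9L, 9L, 9L, 9L),
#'                  m1 = c(1.0, 1.2, 2.1, 2.4),
#'                  ea_ratio = c(1.6, 1.5, 1.3, NA))
#' BiomarkerPanel(df, markers = "m1")
#' @aliases BiomarkerPanel
#' @export BiomarkerPanel
#' @exportClass BiomarkerPanel
setClass("BiomarkerPanel",
  slots = c(data = "data.frame", markers = "character",
            weekSchedule = "integer"))

setValidity("BiomarkerPanel", function(object) {
  msg <- character()
  d <- object@data
  need <- c("animal_id", "group", "week", object@markers, "ea_ratio")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("panel data missing column(s):", paste(miss, collapse = ", ")))
  if (!is.factor(d$group) || !identical(levels(d$group), .CONDITIONS))
    msg <- c(msg, "'group' must be a factor with levels 'control', 'case'")
  if (anyNA(d$group)) msg <- c(msg, "'group' contains missing values")
  if (!is.numeric(d$week) || anyNA(d$week) || any(d$week != round(d$week)))
    msg <- c(msg, "'week' must be whole numbers")
  if (!all(d$week %in% object@weekSchedule))
    msg <- c(msg, "rows contain weeks outside the declared schedule")
  if (is.unsorted(object@weekSchedule, strictly = TRUE))
    msg <- c(msg, "week schedule must be strictly increasing")
  if (anyDuplicated(d[c("animal_id", "week")]))
    msg <- c(msg, "duplicate (animal_id, week) records")
  for (m in object@markers)
    if (!is.numeric(d[[m]]))
      msg <- c(msg, paste0("marker '", m, "' must be numeric"))
  if (!is.numeric(d$ea_ratio))
    msg <- c(msg, "'ea_ratio' must be numeric (NA allowed)")
  if (length(msg)) msg else TRUE
})

BiomarkerPanel <- function(data, markers, weeks = sort(unique(data$week))) {
  data <- as.data.frame(data)
  if (!"ea_ratio" %in% names(data)) data$ea_ratio <- NA_real_
  g <- as.character(data$group)
  g[g == "db/db"] <- "case"
  g[g == "db/+"] <- "control"
  bad <- setdiff(unique(g), .CONDITIONS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  data$group <- factor(g, levels = .CONDITIONS)
  data$week <- as.integer(data$week)
  data$animal_id <- as.character(data$animal_id)
  obj <- new("BiomarkerPanel", data = data, markers = as.character(markers),
             weekSchedule = as.integer(weeks))
  nm <- sum(is.na(data$ea_ratio))
  if (nm > 0)
    message(nm, " record(s) with missing ea_ratio (kept; excluded from ",
            "correlation analyses)")
  obj
}

#' @rdname panel-accessors
setMethod("panelData", "BiomarkerPanel", function(x) x@data)
#' @rdname panel-accessors
setMethod("markerNames", "BiomarkerPanel", function(x) x@markers)
#' @rdname panel-accessors
setMethod("weekSchedule", "BiomarkerPanel", function(x) x@weekSchedule)

setMethod("show", "BiomarkerPanel", function(object) {
  d <- object@data
  cat("BiomarkerPanel: ", nrow(d), " animal-week records, markers: ",
      paste(object@markers, collapse = ", "), "\n", sep = "")
  cat("  weeks: ", paste(object@weekSchedule, collapse = ", "),
      "; ", sum(d$group == "case"), " case / ",
      sum(d$group == "control"), " control records\n", sep = "")
  if (anyNA(d$ea_ratio))
    cat("  ", sum(is.na(d$ea_ratio)), " record(s) missing ea_ratio\n", sep = "")
})

# --------------------------------------------------------------------- DEGTable

#' DEGTable: per-gene differential-expression results
#'
#' A [S4Vectors::DataFrame] subclass with one row per gene and columns
#' `W` (rank-sum of the case group), `U` (Mann-Whitney statistic), `z`
#' (standardized W), `p_raw` (two-sided p), `direction`
#' (`up`/`down`/`none`, sign of case-minus-control median bin
#' difference), `p_bonferroni`, `q_bh`, and logical call flags
#' `deg_raw`, `deg_bonf`, `deg_bh`. The significance level alpha and
#' group sizes are stored in `metadata()`.
#'
#' @seealso [runDifferentialExpression()]
#' @aliases DEGTable
#' @exportClass DEGTable
setClass("DEGTable", contains = "DFrame")

setValidity("DEGTable", function(object) {
  need <- c("W", "U", "z", "p_raw", "direction", "p_bonferroni", "q_bh",
            "deg_raw", "deg_bonf", "deg_bh")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(object)) {
    if (any(object$p_raw <= 0 | object$p_raw > 1))
      return("p_raw must lie in (0, 1]")
    if (any(object$p_bonferroni < object$p_raw - 1e-12) ||
        any(object$q_bh < object$p_raw - 1e-12))
      return("adjusted p-values cannot fall below raw p-values")
  }
  TRUE
})

#' @rdname deg-accessors
setMethod("degGenes", "DEGTable",
  function(x, which = c("bh", "bonferroni", "raw")) {
    which <- match.arg(which)
    col <- switch(which, bh = "deg_bh", bonferroni = "deg_bonf",
                  raw = "deg_raw")
    rownames(x)[x[[col]]]
  })

# ------------------------------------------------------------------ CandidateSet

#' CandidateSet: cross-disease candidate genes with integrated ranking
#'
#' The intersection of two disease DEG sets, ranked by the
#' integrated-analysis p-value (ascending; ties broken by |standardized
#' W| descending, then lexicographic gene id), with the top-k selection.
#'
#' @seealso [intersectAndRank()]
#' @aliases CandidateSet
#' @exportClass CandidateSet
setClass("CandidateSet",
  slots = c(commonGenes = "character", ranking = "data.frame",
            topK = "character", k = "integer"))

setValidity("CandidateSet", function(object) {
  msg <- character()
  if (!all(object@ranking$gene %in% object@commonGenes))
    msg <- c(msg, "ranked genes must be a subset of commonGenes")
  if (!all(object@topK %in% object@ranking$gene))
    msg <- c(msg, "topK must come from the ranked list")
  if (nrow(object@ranking) > 1 && is.unsorted(object@ranking$p_integrated))
    msg <- c(msg, "ranking must be sorted by integrated p ascending")
  if (length(msg)) msg else TRUE
})

#' @rdname deg-accessors
setMethod("candidateRanking", "CandidateSet", function(x) x@ranking)
#' @rdname deg-accessors
setMethod("topCandidates", "CandidateSet", function(x) x@topK)

setMethod("show", "CandidateSet", function(object) {
  cat("CandidateSet: ", length(object@commonGenes),
      " common genes, top-", object@k, " selection\n", sep = "")
  if (length(object@topK))
    cat("  top candidates: ", paste(object@topK, collapse = ", "), "\n",
        sep = "")
})

# ---------------------------------------------------------------- CompositeScore

#' CompositeScore: composite biomarker score over panel records
#'
#' Per-record composite scores combining several standardized markers:
#' either the first principal component of the marker correlation
#' matrix (unsupervised; unit-norm weights, sign fixed so the first
#' non-zero weight is positive) or the predicted probability from a
#' logistic regression of group on standardized markers (supervised).
#'
#' @seealso [combineMarkers()]
#' @aliases CompositeScore
#' @exportClass CompositeScore
setClass("CompositeScore",
  slots = c(mode = "character", weights = "numeric", scores = "numeric",
            varianceShare = "numeric", records = "data.frame",
            center = "numeric", scale = "numeric", model = "list"))

setValidity("CompositeScore", function(object) {
  msg <- character()
  if (!object@mode %in% c("unsupervised_pc1", "supervised_logistic"))
    msg <- c(msg, "mode must be 'unsupervised_pc1' or 'supervised_logistic'")
  if (object@mode == "unsupervised_pc1") {
    if (abs(sqrt(sum(object@weights^2)) - 1) > 1e-8)
      msg <- c(msg, "unsupervised weights must have unit norm")
    vs <- object@varianceShare
    if (is.na(vs) || vs < -1e-8 || vs > 1 + 1e-8)
      msg <- c(msg, "varianceShare must lie in [0, 1]")
  }
  if (length(object@scores) != nrow(object@records))
    msg <- c(msg, "one score per record required")
  if (length(msg)) msg else TRUE
})

#' @rdname eval-accessors
setMethod("scoreValues", "CompositeScore", function(x) x@scores)
#' @rdname eval-accessors
setMethod("scoreWeights", "CompositeScore", function(x) x@weights)
#' @rdname eval-accessors
setMethod("varianceShare", "CompositeScore", function(x) x@varianceShare)

setMethod("show", "CompositeScore", function(object) {
  cat("CompositeScore (", object@mode, "), ", length(object@scores),
      " records\n", sep = "")
  cat("  weights:", paste(sprintf("%s=%.3f", names(object@weights),
                                  object@weights), collapse = ", "), "\n")
  if (!is.na(object@varianceShare))
    cat(sprintf("  PC1 variance share: %.3f\n", object@varianceShare))
})

# --------------------------------------------------------------------- RocResult

#' RocResult: ROC curve, AUC and Youden-optimal cutoff
#'
#' Full ROC curve (one point per threshold, thresholds descending so the
#' curve runs from (0,0) to (1,1) in (1-specificity, sensitivity)
#' space), trapezoidal AUC (identically the Mann-Whitney
#' U/(n1*n2) with ties counted 1/2), and the cutoff maximizing Youden's
#' J = sensitivity + specificity - 1 (lowest threshold on ties). If the
#' raw AUC falls below 0.5, `flipped` is set and `aucFlipped = 1 - auc`
#' is reported alongside. Constant scores yield `degenerate = TRUE`,
#' AUC 0.5 and an undefined (NA) cutoff.
#'
#' @seealso [rocAnalysis()]
#' @aliases RocResult
#' @exportClass RocResult
setClass("RocResult",
  slots = c(thresholds = "numeric", sensitivity = "numeric",
            specificity = "numeric", auc = "numeric",
            aucFlipped = "numeric", flipped = "logical",
            cutoff = "numeric", sensAtCutoff = "numeric",
            specAtCutoff = "numeric", nCase = "integer",
            nControl = "integer", degenerate = "logical"))

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    msg <- c(msg, "auc must lie in [0, 1]")
  ln <- length(object@thresholds)
  if (length(object@sensitivity) != ln || length(object@specificity) != ln)
    msg <- c(msg, "curve vectors must have equal length")
  if (ln > 1 && (is.unsorted(object@sensitivity) ||
                 is.unsorted(rev(object@specificity))))
    msg <- c(msg, "sensitivity must be non-decreasing as specificity decreases")
  if (length(msg)) msg else TRUE
})

#' @rdname eval-accessors
setMethod("rocAuc", "RocResult", function(x) x@auc)
#' @rdname eval-accessors
setMethod("rocCutoff", "RocResult", function(x) x@cutoff)

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.3f (%d case vs %d control)\n",
              object@auc, object@nCase, object@nControl))
  if (object@degenerate) {
    cat("  degenerate (constant scores); cutoff undefined\n")
  } else {
    cat(sprintf("  Youden cutoff = %.3f (sens %.3f, spec %.3f)\n",
                object@cutoff, object@sensAtCutoff, object@specAtCutoff))
    if (object@flipped)
      cat(sprintf("  orientation flag: raw AUC < 0.5; flipped AUC = %.3f\n",
                  object@aucFlipped))
  }
})

# ------------------------------------------------------------- CorrelationResult

#' CorrelationResult: marker vs functional-readout correlation
#'
#' Pearson r (on values) and Spearman rho (on ranks) between a serum
#' marker and a functional readout (default the mitral E:A ratio),
#' with p-values and the number of complete pairs.
#'
#' @seealso [correlateFunction()]
#' @aliases CorrelationResult
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(marker = "character", readout = "character",
            pearsonR = "numeric", pearsonP = "numeric",
            spearmanRho = "numeric", spearmanP = "numeric", n = "integer"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (!is.na(object@pearsonR) && abs(object@pearsonR) > 1 + 1e-12)
    msg <- c(msg, "|pearsonR| must be <= 1")
  if (!is.na(object@spearmanRho) && abs(object@spearmanRho) > 1 + 1e-12)
    msg <- c(msg, "|spearmanRho| must be <= 1")
  if (object@n < 3L) msg <- c(msg, "need at least 3 complete pairs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: %s vs %s (n = %d)\n", object@marker,
              object@readout, object@n))
  cat(sprintf("  Pearson r = %.3f (p = %.3g); Spearman rho = %.3f (p = %.3g)\n",
              object@pearsonR, object@pearsonP, object@spearmanRho,
              object@spearmanP))
})

# ------------------------------------------------------------------- PanelReport

#' PanelReport: bundled panel-evaluation results
#'
#' Produced by [evaluatePanel()]: per-week group tests for every marker,
#' composite scores in both modes, ROC results for each single marker
#' and composite (restricted to the configured week window), and
#' marker-vs-readout correlations pooled over all weeks.
#'
#' @aliases PanelReport
#' @exportClass PanelReport
setClass("PanelReport",
  slots = c(weeklyTests = "data.frame", composites = "list", roc = "list",
            correlations = "data.frame", markers = "character",
            weeksRoc = "integer", readout = "character",
            schemaVersion = "character"))

setMethod("show", "PanelReport", function(object) {
  cat("PanelReport (schema ", object@schemaVersion, ")\n", sep = "")
  cat("  markers: ", paste(object@markers, collapse = ", "), "\n", sep = "")
  cat("  ROC week window: ", paste(range(object@weeksRoc), collapse = "-"),
      "\n", sep = "")
  aucs <- vapply(object@roc, rocAuc, numeric(1))
  for (nm in names(aucs))
    cat(sprintf("  AUC[%s] = %.3f\n", nm, aucs[[nm]]))
})
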