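#' Accessors for study containers
#'
#' Retrieve descriptive metadata from an [ExpressionStudy] or
#' [DiscretizedDataset]: the study identifier, the disease arm
#' (`"T2DM"` or `"CVD"`), the platform tag, the measurement level
#' (`"probe"` or `"gene"`), and the per-sample condition factor
#' (`control`/`case`).
#'
#' @param x An `ExpressionStudy` or `DiscretizedDataset`.
#' @return `studyId`, `disease`, `platformTag` and `exprLevel` return a
#'   character scalar; `sampleCondition` returns a factor with levels
#'   `control`, `case`; `qBins` returns the integer bin count Q;
#'   `binMatrix` returns the gene x sample integer bin matrix.
#' @name study-accessors
#' @aliases studyId disease platformTag exprLevel sampleCondition
NULL

#' @rdname study-accessors
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname study-accessors
#' @export
setGeneric("disease", function(x) standardGeneric("disease"))

#' @rdname study-accessors
#' @export
setGeneric("platformTag", function(x) standardGeneric("platformTag"))

#' @rdname study-accessors
#' @export
setGeneric("exprLevel", function(x) standardGeneric("exprLevel"))

#' @rdname study-accessors
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))

#' @rdname study-accessors
#' @export
setGeneric("qBins", function(x) standardGeneric("qBins"))

#' @rdname study-accessors
#' @export
setGeneric("binMatrix", function(x) standardGeneric("binMatrix"))

#' Accessors for biomarker panels
#'
#' @param x A [BiomarkerPanel].
#' @return `panelData` returns the underlying `data.frame` (one row per
#'   animal-week record); `markerNames` the character vector of marker
#'   column names; `weekSchedule` the declared integer week schedule.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("panelData", function(x) standardGeneric("panelData"))

#' @rdname panel-accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname panel-accessors
#' @export
setGeneric("weekSchedule", function(x) standardGeneric("weekSchedule"))

#' Accessors for differential-expression and candidate results
#'
#' @param x A [DEGTable] or [CandidateSet].
#' @param which For `degGenes`, which call to use: `"bh"` (primary,
#'   Benjamini-Hochberg q < alpha), `"bonferroni"`, or `"raw"`.
#' @return `degGenes` returns the character vector of called gene ids;
#'   `candidateRanking` the ranked candidate `data.frame`;
#'   `topCandidates` the character vector of selected top-k gene ids.
#' @name deg-accessors
NULL

#' @rdname deg-accessors
#' @export
setGeneric("degGenes", function(x, which = c("bh", "bonferroni", "raw"))
  standardGeneric("degGenes"))

#' @rdname deg-accessors
#' @export
setGeneric("candidateRanking", function(x) standardGeneric("candidateRanking"))

#' @rdname deg-accessors
#' @export
setGeneric("topCandidates", function(x) standardGeneric("topCandidates"))

#' Accessors for panel-evaluation results
#'
#' @param x A [CompositeScore] or [RocResult].
#' @return `scoreValues` returns the per-record composite scores;
#'   `scoreWeights` the per-marker weights (unit-norm PC1 loadings in
#'   unsupervised mode, standardized logistic coefficients in supervised
#'   mode); `varianceShare` the fraction of total variance on PC1
#'   (`NA` in supervised mode); `rocAuc` the trapezoidal AUC;
#'   `rocCutoff` the Youden-J-optimal threshold on the score scale.
#' @name eval-accessors
NULL

#' @rdname eval-accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname eval-accessors
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))

#' @rdname eval-accessors
#' @export
setGeneric("varianceShare", function(x) standardGeneric("varianceShare"))

#' @rdname eval-accessors
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))

#' @rdname eval-accessors
#' @export
setGeneric("rocCutoff", function(x) standardGeneric("rocCutoff"))
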