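#' @include AllClasses.R
NULL

# Strict TSV matrix reader shared by expression and bin formats.
# Returns a numeric matrix with dimnames; errors locate the offending cell.
.readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "feature_id")
    stop("format error: first header field must be 'feature_id' in ", path)
  samples <- header[-1]
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicated sample column name(s): ", paste(unique(dup), collapse = ", "))
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", na.strings = NULL,
                         quote = "", comment.char = "")
  if (nrow(d) == 0L) stop("no data rows in ", path)
  feats <- d[[1]]
  m <- matrix(NA_real_, nrow(d), length(samples),
              dimnames = list(feats, samples))
  for (j in seq_along(samples)) {
    raw <- d[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad))
      stop("parse error: non-numeric or missing cell at row ", bad[1],
           " (feature '", feats[bad[1]], "'), column '", samples[j], "'")
    m[, j] <- val
  }
  m
}

#' Read and write an expression study TSV
#'
#' The on-disk format is a UTF-8 tab-delimited table whose first column
#' is `feature_id` and whose remaining columns are samples; '.' decimal,
#' no thousands separators. Expression matrices must be complete:
#' missing or non-numeric cells are an error (the downstream rank tests
#' assume complete columns). Sample conditions are not stored in the
#' matrix file; they are supplied through `condition` at read time.
#'
#' @param path File path.
#' @param condition Named (by sample id) or positional character vector
#'   of `"case"`/`"control"` labels, one per sample column.
#' @param studyId,disease,platform,level Study descriptors, see
#'   [ExpressionStudy()].
#' @return `readExpressionStudy` returns an [ExpressionStudy];
#'   `writeExpressionStudy` invisibly returns `path`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' es <- ExpressionStudy(m, c(s1 = "case", s2 = "control"))
#' writeExpressionStudy(es, tf)
#' es2 <- readExpressionStudy(tf, c(s1 = "case", s2 = "control"))
#' stopifnot(identical(assay(es), assay(es2)))
#' @export
readExpressionStudy <- function(path, condition, studyId = "study",
                                disease = c("T2DM", "CVD"),
                                platform = "unknown",
                                level = c("gene", "probe")) {
  m <- .readMatrixTSV(path)
  ExpressionStudy(m, condition, studyId = studyId, disease = disease,
                  platform = platform, level = level)
}

#' @param study An [ExpressionStudy].
#' @rdname readExpressionStudy
#' @export
writeExpressionStudy <- function(study, path) {
  stopifnot(is(study, "ExpressionStudy"))
  .writeMatrixTSV(assay(study, "exprs"), path)
}

.writeMatrixTSV <- function(m, path, digits = 15L) {
  vals <- if (is.integer(m) || all(m == round(m))) {
    format(m, trim = TRUE, scientific = FALSE)
  } else {
    format(m, trim = TRUE, digits = digits)
  }
  d <- cbind(feature_id = rownames(m), as.data.frame(vals))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a discretized dataset as an integer-bin TSV
#'
#' Bins are written as plain integers, so the file round-trips
#' bit-identically.
#'
#' @param dd A [DiscretizedDataset].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
writeBinsTSV <- function(dd, path) {
  stopifnot(is(dd, "DiscretizedDataset"))
  m <- binMatrix(dd)
  storage.mode(m) <- "integer"
  .writeMatrixTSV(m, path)
}

#' Read and write a probe-to-gene map
#'
#' Two-column tab-delimited file with header `probe_id`, `gene_id`;
#' many-to-many mappings are allowed and exact duplicate pairs are
#' dropped on read.
#'
#' @param path File path.
#' @return `readProbeMap` returns a `data.frame` with character columns
#'   `probe_id` and `gene_id`, one row per unique pair.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeProbeMap(data.frame(probe_id = c("p1", "p2"),
#'                          gene_id = c("gA", "gA")), tf)
#' readProbeMap(tf)
#' @export
readProbeMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("empty probe map file: ", path)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", na.strings = NULL,
                         quote = "", comment.char = "")
  if (ncol(d) < 2L)
    stop("parse error: probe map requires two columns (probe_id, gene_id)")
  if (!identical(names(d)[1:2], c("probe_id", "gene_id")))
    stop("format error: header must be 'probe_id<TAB>gene_id'")
  if (nrow(d) == 0L) stop("empty probe map file: ", path)
  pm <- data.frame(probe_id = d[[1]], gene_id = d[[2]],
                   stringsAsFactors = FALSE)
  if (any(!nzchar(pm$probe_id)) || any(!nzchar(pm$gene_id)))
    stop("probe map contains blank probe or gene ids")
  unique(pm)
}

#' @param map A two-column `data.frame` (`probe_id`, `gene_id`).
#' @rdname readProbeMap
#' @export
writeProbeMap <- function(map, path) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(map)))
  utils::write.table(unique(map[c("probe_id", "gene_id")]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write a longitudinal serum-panel CSV
#'
#' Comma-separated with header `animal_id,group,week,<markers...>,
#' ea_ratio`. Group labels `db/db` (leptin-receptor-deficient diabetic)
#' and `db/+` (heterozygous control) are mapped to `case` and `control`
#' respectively; `case`/`control` are also accepted. Missing `ea_ratio`
#' cells are kept and flagged (those records are excluded from
#' correlation analyses only); duplicate (animal, week) records are an
#' error.
#'
#' @param path File path.
#' @param markers Character vector of expected marker column names.
#' @return `readPanel` returns a [BiomarkerPanel].
#' @export
readPanel <- function(path, markers) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "week", markers, "ea_ratio")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("panel file missing column(s): ", paste(miss, collapse = ", "))
  for (m in c(markers, "ea_ratio")) {
    raw <- d[[m]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(trimws(raw)) &
                   toupper(trimws(raw)) != "NA")
    if (length(bad))
      stop("parse error: non-numeric cell at row ", bad[1], ", column '",
           m, "'")
    d[[m]] <- val
  }
  BiomarkerPanel(d, markers = markers)
}

#' @param panel A [BiomarkerPanel].
#' @rdname readPanel
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "BiomarkerPanel"))
  d <- panelData(panel)
  d <- d[c("animal_id", "group", "week", markerNames(panel), "ea_ratio")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write JSON reports
#'
#' All machine-readable reports produced by the pipeline are JSON with a
#' fixed schema carrying a `schema_version` field.
#'
#' @param x A named list (or an object convertible via `as.list`).
#' @param path File path.
#' @return `readReport` returns the parsed list.
#' @export
writeReport <- function(x, path) {
  if (is.null(x$schema_version)) x$schema_version <- "1.0"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
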