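#' @include AllClasses.R
NULL

#' Collapse probe-level values to gene level
#'
#' For each gene, the collapsed value is the arithmetic mean over all
#' probes mapping to it; probes mapping multiple genes contribute to
#' each of their genes, resolving probe redundancy by averaging.
#' Unmapped probes are dropped (their count is reported via
#' `message()`). Output genes are in deterministic lexicographic order.
#'
#' @param study A probe-level [ExpressionStudy].
#' @param map A probe map `data.frame` (`probe_id`, `gene_id`), e.g.
#'   from [readProbeMap()].
#' @return A gene-level [ExpressionStudy].
#' @examples
#' m <- matrix(c(2, 4, 1, 3, 5, 2), 3, 2,
#'             dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' es <- ExpressionStudy(m, c("case", "control"), level = "probe")
#' pm <- data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
#' assay(collapseProbes(es, pm))  # gA = mean(p1, p2)
#' @export
collapseProbes <- function(study, map) {
  stopifnot(is(study, "ExpressionStudy"))
  if (exprLevel(study) != "probe")
    stop("collapseProbes expects a probe-level study")
  map <- unique(as.data.frame(map)[c("probe_id", "gene_id")])
  map <- map[map$probe_id %in% rownames(study), , drop = FALSE]
  if (nrow(map) == 0L)
    stop("probe map covers zero probes of this study")
  nUnmapped <- sum(!rownames(study) %in% map$probe_id)
  if (nUnmapped > 0)
    message(nUnmapped, " unmapped probe(s) dropped")
  v <- assay(study, "exprs")
  idx <- match(map$probe_id, rownames(v))
  sums <- rowsum(v[idx, , drop = FALSE], group = map$gene_id)
  counts <- as.vector(table(map$gene_id)[rownames(sums)])
  collapsed <- sums / counts
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  ExpressionStudy(collapsed, sampleCondition(study),
                  studyId = studyId(study), disease = disease(study),
                  platform = platformTag(study), level = "gene")
}

#' Per-sample quantile discretization (QD binning)
#'
#' Converts each sample independently into `Q` rank-based bins: values
#' are average-ranked (ties share their mean rank) and
#' `bin = ceiling(rank * Q / G)`, clamped to `[1, Q]`, where `G` is the
#' gene count. The binning is monotone in value within a sample and
#' therefore invariant under any strictly increasing per-sample
#' transform — the property that makes arrays from heterogeneous
#' platforms comparable after binning. With no ties and `Q` dividing
#' `G`, every bin holds exactly `G/Q` genes.
#'
#' Typical bin counts are `Q = 128` for within-disease runs and
#' `Q = 1028` for the integrated run (the defaults of
#' [runDiscovery()]).
#'
#' @param study A gene-level [ExpressionStudy].
#' @param Q Bin count (>= 1). A warning is issued when `Q > G`.
#' @return A [DiscretizedDataset]; `colData` carries the condition plus
#'   `study` and `disease` tags.
#' @export
quantileDiscretize <- function(study, Q) {
  stopifnot(is(study, "ExpressionStudy"))
  Q <- as.integer(Q)
  if (is.na(Q) || Q < 1L) stop("Q must be an integer >= 1")
  v <- assay(study, "exprs")
  if (!all(is.finite(v))) stop("non-finite values cannot be discretized")
  G <- nrow(v)
  if (G < Q)
    warning("Q (", Q, ") exceeds the gene count (", G,
            "); bins will be sparse")
  bins <- apply(v, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    pmin(pmax(ceiling(r * Q / G), 1L), Q)
  })
  bins <- matrix(as.integer(bins), nrow = G,
                 dimnames = dimnames(v))
  cd <- S4Vectors::DataFrame(
    condition = sampleCondition(study),
    study = rep(studyId(study), ncol(v)),
    disease = rep(disease(study), ncol(v)),
    row.names = colnames(v))
  .DiscretizedDataset(bins, cd, Q)
}

#' Merge discretized studies on their common genes
#'
#' Restricts every study to the intersection of gene sets (in
#' deterministic lexicographic order) and concatenates samples with
#' study and disease provenance tags. All studies must share the same
#' bin count `Q`. The merged gene set is independent of study order.
#'
#' @param studies A list of >= 2 [DiscretizedDataset] objects.
#' @return A merged [DiscretizedDataset].
#' @export
mergeStudies <- function(studies) {
  if (length(studies) < 2L) stop("need at least two studies to merge")
  if (!all(vapply(studies, is, logical(1), "DiscretizedDataset")))
    stop("all inputs must be DiscretizedDataset objects")
  Qs <- unique(vapply(studies, qBins, integer(1)))
  if (length(Qs) != 1L)
    stop("mismatched Q across studies: ", paste(Qs, collapse = ", "))
  genes <- Reduce(intersect, lapply(studies, rownames))
  if (length(genes) == 0L) stop("empty gene intersection across studies")
  genes <- sort(genes)
  binsList <- lapply(studies, function(s) binMatrix(s)[genes, , drop = FALSE])
  bins <- do.call(cbind, binsList)
  cds <- lapply(seq_along(studies), function(i) {
    s <- studies[[i]]
    tag <- if (!is.null(s$study)) s$study else
      rep(paste0("study", i), ncol(s))
    S4Vectors::DataFrame(
      condition = sampleCondition(s),
      study = tag,
      disease = if (!is.null(s$disease)) s$disease else NA_character_,
      row.names = paste0(tag, ".", colnames(s)))
  })
  cd <- do.call(rbind, cds)
  rownames(cd) <- make.unique(rownames(cd))
  colnames(bins) <- rownames(cd)
  .DiscretizedDataset(bins, cd, Qs)
}

#' Robust per-sample standardization
#'
#' A rank-preserving stand-in for array normalization: per sample,
#' subtract the sample median and divide by the sample median absolute
#' deviation (MAD, consistency-scaled); samples with zero MAD are
#' divided by 1. Because the transform is strictly increasing within
#' each sample, downstream quantile discretization is unchanged by it.
#'
#' @param study An [ExpressionStudy].
#' @return An [ExpressionStudy] with standardized values.
#' @export
standardizeStudy <- function(study) {
  stopifnot(is(study, "ExpressionStudy"))
  v <- assay(study, "exprs")
  med <- apply(v, 2L, stats::median)
  s <- apply(v, 2L, stats::mad)
  s[s == 0] <- 1
  vs <- sweep(sweep(v, 2L, med, "-"), 2L, s, "/")
  ExpressionStudy(vs, sampleCondition(study), studyId = studyId(study),
                  disease = disease(study), platform = platformTag(study),
                  level = exprLevel(study))
}
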