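#' @include AllClasses.R
NULL

# Tie-corrected variance of the Mann-Whitney U statistic.
.uVariance <- function(pooled, n1, n2) {
  n <- n1 + n2
  l <- rle(sort(pooled))$lengths
  (n1 * n2 / 12) * ((n + 1) - sum(l^3 - l) / (n * (n - 1)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test for one gene
#'
#' Two-sided rank-sum test of case values `x` against control values
#' `y`. When the pooled sample size is at most 12 and there are no
#' ties, the p-value is exact (computed from the full null distribution
#' of the U statistic); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used, with
#' two-sided p = min(1, 2 x one-sided). When all values are identical
#' across both groups the result is p = 1 with direction `none`.
#'
#' @param x Case values (length >= 2, finite).
#' @param y Control values (length >= 2, finite).
#' @return A list with `W` (rank-sum of the case group), `U`
#'   (Mann-Whitney statistic, `W - n1(n1+1)/2`), `z` (standardized W,
#'   0 when degenerate), `p` (two-sided), `direction`
#'   (`up`/`down`/`none` from the sign of the case-minus-control median
#'   difference) and `exact` (logical).
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rankSumTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 values per group")
  pooled <- c(x, y)
  if (!all(is.finite(pooled))) stop("values must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  mu <- n1 * n2 / 2
  s2 <- .uVariance(pooled, n1, n2)
  z <- if (s2 > 0) (U - mu) / sqrt(s2) else 0
  if (!ties && n <= 12L) {
    pLo <- stats::pwilcox(U, n1, n2)
    pHi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(pLo, pHi))
    exact <- TRUE
  } else if (s2 <= 0) {
    p <- 1
    exact <- FALSE
  } else {
    zc <- (U - mu - sign(U - mu) * 0.5) / sqrt(s2)
    p <- min(1, 2 * stats::pnorm(-abs(zc)))
    exact <- FALSE
  }
  dmed <- stats::median(x) - stats::median(y)
  direction <- if (s2 <= 0 || dmed == 0) "none" else
    if (dmed > 0) "up" else "down"
  list(W = W, U = U, z = z, p = p, direction = direction, exact = exact)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up q-values
#' (monotone from the largest rank, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param p Vector of raw p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh")  # all 0.04
#' adjustPvalues(c(0.01, 0.5), "bonferroni")       # 0.02, 1.0
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = switch(method, bonferroni = "bonferroni",
                                     bh = "BH"))
}

# Vectorized rank-sum testing over the rows of a bin matrix. Mirrors
# rankSumTest() exactly: per-gene exact path at pooled n <= 12 without
# ties, tie-corrected continuity-corrected normal approximation
# otherwise.
.rankSumRows <- function(bins, isCase) {
  G <- nrow(bins)
  n1 <- sum(isCase); n2 <- sum(!isCase); n <- n1 + n2
  if (n <= 12L) {
    res <- apply(bins, 1L, function(v)
      rankSumTest(v[isCase], v[!isCase]))
    return(data.frame(
      W = vapply(res, `[[`, numeric(1), "W"),
      U = vapply(res, `[[`, numeric(1), "U"),
      z = vapply(res, `[[`, numeric(1), "z"),
      p_raw = vapply(res, `[[`, numeric(1), "p"),
      direction = vapply(res, `[[`, character(1), "direction"),
      row.names = rownames(bins)))
  }
  R <- apply(bins, 1L, rank)                       # n x G
  W <- colSums(R[isCase, , drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  s2 <- apply(bins, 1L, .uVariance, n1 = n1, n2 = n2)
  mu <- n1 * n2 / 2
  z <- ifelse(s2 > 0, (U - mu) / sqrt(s2), 0)
  zc <- ifelse(s2 > 0, (U - mu - sign(U - mu) * 0.5) / sqrt(s2), 0)
  p <- ifelse(s2 > 0, pmin(1, 2 * stats::pnorm(-abs(zc))), 1)
  medCase <- apply(bins[, isCase, drop = FALSE], 1L, stats::median)
  medCtrl <- apply(bins[, !isCase, drop = FALSE], 1L, stats::median)
  dmed <- medCase - medCtrl
  direction <- ifelse(s2 <= 0 | dmed == 0, "none",
                      ifelse(dmed > 0, "up", "down"))
  data.frame(W = W, U = U, z = z, p_raw = p, direction = direction,
             row.names = rownames(bins))
}

#' Per-gene differential expression on discretized data
#'
#' Runs the rank-sum test on the bin values of every gene, attaches
#' Bonferroni and Benjamini-Hochberg adjusted p-values, and calls DEGs.
#' The primary call is `q_bh < alpha`; raw-p and Bonferroni calls are
#' also emitted so that either reading of a "p < alpha" DEG rule is
#' reproducible.
#'
#' @param data A [DiscretizedDataset] (single-study or merged).
#' @param alpha Significance level in (0, 1); `alpha = 0` yields an
#'   empty DEG set.
#' @return A [DEGTable] with `metadata()` fields `alpha`, `nCase`,
#'   `nControl`.
#' @export
runDifferentialExpression <- function(data, alpha = 0.05) {
  stopifnot(is(data, "DiscretizedDataset"))
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  isCase <- sampleCondition(data) == "case"
  if (sum(isCase) < 2L || sum(!isCase) < 2L)
    stop("need at least 2 case and 2 control samples")
  res <- .rankSumRows(binMatrix(data), isCase)
  res$p_bonferroni <- adjustPvalues(res$p_raw, "bonferroni")
  res$q_bh <- adjustPvalues(res$p_raw, "bh")
  res$deg_raw <- res$p_raw < alpha
  res$deg_bonf <- res$p_bonferroni < alpha
  res$deg_bh <- res$q_bh < alpha
  out <- S4Vectors::DataFrame(res)
  S4Vectors::metadata(out) <- list(alpha = alpha, nCase = sum(isCase),
                                   nControl = sum(!isCase))
  new("DEGTable", out)
}

#' Intersect disease DEG sets and rank by the integrated analysis
#'
#' The candidate pool is the intersection of the two disease DEG sets
#' (primary BH call by default). Candidates are ranked by the
#' integrated-analysis p-value ascending — the "Wilcoxon score"
#' selection — with ties broken by |standardized W| descending, then
#' lexicographic gene id; the first `min(k, n)` genes form the top-k
#' selection. An empty intersection yields an empty candidate set with
#' a warning.
#'
#' @param degA,degB [DEGTable]s for the two diseases.
#' @param integrated [DEGTable] from the merged (integrated) analysis;
#'   must cover every gene of the intersection.
#' @param k Number of top candidates to select (default 2).
#' @param which Which DEG call defines the per-disease sets (`"bh"`,
#'   `"bonferroni"` or `"raw"`).
#' @return A [CandidateSet].
#' @export
intersectAndRank <- function(degA, degB, integrated, k = 2L,
                             which = c("bh", "bonferroni", "raw")) {
  which <- match.arg(which)
  stopifnot(is(degA, "DEGTable"), is(degB, "DEGTable"),
            is(integrated, "DEGTable"))
  if (k < 1L) stop("k must be >= 1")
  common <- intersect(degGenes(degA, which), degGenes(degB, which))
  if (length(common) == 0L) {
    warning("empty DEG intersection; candidate set is empty")
    return(new("CandidateSet", commonGenes = character(),
               ranking = data.frame(gene = character(),
                                    p_integrated = numeric(),
                                    z = numeric(), W = numeric(),
                                    U = numeric()),
               topK = character(), k = as.integer(k)))
  }
  missing <- setdiff(common, rownames(integrated))
  if (length(missing))
    stop("integrated table does not cover ", length(missing),
         " intersection gene(s)")
  sub <- integrated[common, ]
  rk <- data.frame(gene = common, p_integrated = sub$p_raw, z = sub$z,
                   W = sub$W, U = sub$U, stringsAsFactors = FALSE)
  ord <- order(rk$p_integrated, -abs(rk$z), rk$gene)
  rk <- rk[ord, , drop = FALSE]
  rownames(rk) <- NULL
  topK <- utils::head(rk$gene, k)
  new("CandidateSet", commonGenes = sort(common), ranking = rk,
      topK = topK, k = as.integer(k))
}
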