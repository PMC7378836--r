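#' @include AllClasses.R
NULL

.filterWeeks <- function(d, weeks) {
  if (is.null(weeks)) return(d)
  d[d$week >= min(weeks) & d$week <= max(weeks), , drop = FALSE]
}

#' Per-week two-group tests for one marker
#'
#' For each week of the schedule, a Gaussian generalized linear model
#' of the marker on the group indicator — algebraically the
#' pooled-variance two-sample t-test. The t statistic is signed as the
#' case mean minus the control mean. Weeks with fewer than two animals
#' in either group are skipped with a warning.
#'
#' @param panel A [BiomarkerPanel].
#' @param marker Marker name.
#' @return A `data.frame` with columns `week`, `marker`, `t_value`,
#'   `p_value`, `n_case`, `n_control` (a Table-2-style per-week
#'   summary).
#' @export
weeklyGroupTests <- function(panel, marker) {
  stopifnot(is(panel, "BiomarkerPanel"))
  if (!marker %in% markerNames(panel))
    stop("unknown marker: ", marker)
  d <- panelData(panel)
  out <- list()
  for (w in weekSchedule(panel)) {
    dw <- d[d$week == w & !is.na(d[[marker]]), , drop = FALSE]
    nc <- sum(dw$group == "case"); nn <- sum(dw$group == "control")
    if (nc < 2L || nn < 2L) {
      warning("week ", w, " skipped: fewer than 2 animals in a group")
      next
    }
    fit <- stats::glm(dw[[marker]] ~ dw$group, family = stats::gaussian())
    sm <- summary(fit)$coefficients
    out[[length(out) + 1L]] <- data.frame(
      week = w, marker = marker,
      t_value = sm["dw$groupcase", "t value"],
      p_value = sm["dw$groupcase", "Pr(>|t|)"],
      n_case = nc, n_control = nn)
  }
  if (length(out) == 0L)
    return(data.frame(week = integer(), marker = character(),
                      t_value = numeric(), p_value = numeric(),
                      n_case = integer(), n_control = integer()))
  do.call(rbind, out)
}

#' Combine markers into a composite score
#'
#' Markers are standardized (mean 0, SD 1 over all used records), then
#' combined either unsupervised — the first principal component of the
#' marker correlation structure, with unit-norm weights whose first
#' non-zero entry is fixed positive, reporting the fraction of total
#' variance on PC1 — or supervised — a logistic regression of group on
#' the standardized markers, scored as the predicted case probability
#' ("groups specified" in ROC terms; the unsupervised score never sees
#' the labels).
#'
#' @param panel A [BiomarkerPanel].
#' @param markers Markers to combine (>= 1).
#' @param mode `"unsupervised_pc1"` or `"supervised_logistic"`.
#' @param weeks Optional inclusive week window `c(lo, hi)`; records
#'   outside it are dropped before scoring.
#' @return A [CompositeScore].
#' @export
combineMarkers <- function(panel, markers,
                           mode = c("unsupervised_pc1",
                                    "supervised_logistic"),
                           weeks = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "BiomarkerPanel"))
  if (length(markers) < 1L) stop("need at least one marker")
  miss <- setdiff(markers, markerNames(panel))
  if (length(miss)) stop("unknown marker(s): ", paste(miss, collapse = ", "))
  d <- .filterWeeks(panelData(panel), weeks)
  keep <- stats::complete.cases(d[markers])
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop("too few complete records to combine markers")
  X <- as.matrix(d[markers])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zero <- names(scl)[scl == 0]
  if (length(zero))
    stop("zero-variance marker(s): ", paste(zero, collapse = ", "))
  Z <- scale(X, center = ctr, scale = scl)
  records <- d[c("animal_id", "group", "week")]
  if (mode == "unsupervised_pc1") {
    C <- stats::cov(Z)  # correlation matrix of the raw markers
    e <- eigen(C, symmetric = TRUE)
    w <- e$vectors[, 1L]
    fnz <- which(abs(w) > 1e-12)[1]
    if (!is.na(fnz) && w[fnz] < 0) w <- -w
    names(w) <- markers
    scores <- as.numeric(Z %*% w)
    vs <- e$values[1L] / sum(e$values)
    new("CompositeScore", mode = mode, weights = w, scores = scores,
        varianceShare = vs, records = records, center = ctr, scale = scl,
        model = list())
  } else {
    y <- d$group == "case"
    if (length(unique(y)) < 2L)
      stop("supervised mode requires both groups among the records")
    df <- data.frame(y = y, Z)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    if (!fit$converged)
      stop("logistic fit did not converge (", fit$iter, " iterations; ",
           "deviance ", format(fit$deviance), ")")
    w <- stats::coef(fit)[-1L]
    names(w) <- markers
    scores <- as.numeric(stats::fitted(fit))
    new("CompositeScore", mode = mode, weights = w, scores = scores,
        varianceShare = NA_real_, records = records, center = ctr,
        scale = scl,
        model = list(intercept = unname(stats::coef(fit)[1L]),
                     deviance = fit$deviance, converged = fit$converged))
  }
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Builds the full ROC curve (thresholds are the unique scores,
#' descending, preceded by +Inf; a record is called positive when its
#' score is >= the threshold, cases being the positive class) and
#' computes the trapezoidal AUC — identically equal to the
#' Mann-Whitney U/(n_case * n_control) with tied case-control pairs
#' counted 1/2. If the raw AUC is below 0.5, the flipped value is
#' reported alongside with a flag. The operating cutoff maximizes
#' Youden's J = sensitivity + specificity - 1, taking the lowest
#' threshold on ties. Constant scores give a degenerate result with
#' AUC 0.5 and an undefined cutoff.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case/control labels: a factor with levels
#'   `control`/`case`, or a logical vector (TRUE = case).
#' @return A [RocResult].
#' @export
rocAnalysis <- function(scores, labels) {
  if (is.logical(labels)) {
    isCase <- labels
  } else {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("case", "control"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    isCase <- labels == "case"
  }
  keep <- !is.na(scores) & !is.na(isCase)
  scores <- scores[keep]; isCase <- isCase[keep]
  n1 <- sum(isCase); n2 <- sum(!isCase)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  if (length(unique(scores)) == 1L) {
    return(new("RocResult", thresholds = c(Inf, scores[1]),
               sensitivity = c(0, 1), specificity = c(1, 0),
               auc = 0.5, aucFlipped = 0.5, flipped = FALSE,
               cutoff = NA_real_, sensAtCutoff = NA_real_,
               specAtCutoff = NA_real_, nCase = as.integer(n1),
               nControl = as.integer(n2), degenerate = TRUE))
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) sum(isCase & scores >= t) / n1, numeric(1))
  spec <- vapply(th, function(t) sum(!isCase & scores < t) / n2, numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  flipped <- auc < 0.5
  j <- sens + spec - 1
  finite <- is.finite(th)
  jf <- j[finite]; thf <- th[finite]
  best <- which(jf == max(jf))
  pick <- best[which.min(thf[best])]
  cutoff <- thf[pick]
  new("RocResult", thresholds = th, sensitivity = sens,
      specificity = spec, auc = auc, aucFlipped = 1 - auc,
      flipped = flipped, cutoff = cutoff,
      sensAtCutoff = sens[finite][pick], specAtCutoff = spec[finite][pick],
      nCase = as.integer(n1), nControl = as.integer(n2),
      degenerate = FALSE)
}

#' Correlate a marker with the functional readout
#'
#' Pearson r on values and Spearman rho on ranks between a serum
#' marker and a functional readout (default the mitral E:A ratio),
#' pooling animal-week records; records with a missing value in either
#' variable are excluded pairwise.
#'
#' @param panel A [BiomarkerPanel].
#' @param marker Marker name.
#' @param readout Readout column name (default `"ea_ratio"`).
#' @param weeks Optional inclusive week window `c(lo, hi)`.
#' @return A [CorrelationResult].
#' @export
correlateFunction <- function(panel, marker, readout = "ea_ratio",
                              weeks = NULL) {
  stopifnot(is(panel, "BiomarkerPanel"))
  d <- .filterWeeks(panelData(panel), weeks)
  if (!marker %in% names(d)) stop("unknown marker: ", marker)
  if (!readout %in% names(d)) stop("unknown readout: ", readout)
  x <- d[[marker]]; y <- d[[readout]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  new("CorrelationResult", marker = marker, readout = readout,
      pearsonR = unname(pe$estimate), pearsonP = pe$p.value,
      spearmanRho = unname(sp$estimate), spearmanP = sp$p.value,
      n = length(x))
}

#' Evaluate a biomarker panel end to end
#'
#' Bundles, for a given marker set: per-week group tests for every
#' marker; composite scores in both modes (supervised logistic =
#' "groups specified", unsupervised PC1 = "groups not specified");
#' ROC analysis for each single marker and each composite, restricted
#' to the configured week window (default weeks 9-14, the window in
#' which both candidate markers differ between groups); and
#' marker-vs-readout correlations pooled over all weeks. Animal-week
#' records are treated as independent observations, matching a
#' terminal design in which different animals are measured each week.
#'
#' @param panel A [BiomarkerPanel].
#' @param markers Markers to evaluate (default: all panel markers).
#' @param weeksRoc Inclusive week window for ROC, default `c(9, 14)`.
#' @param readout Functional readout column, default `"ea_ratio"`.
#' @return A [PanelReport].
#' @export
evaluatePanel <- function(panel, markers = markerNames(panel),
                          weeksRoc = c(9L, 14L), readout = "ea_ratio") {
  stopifnot(is(panel, "BiomarkerPanel"))
  weekly <- do.call(rbind, lapply(markers, function(m)
    weeklyGroupTests(panel, m)))
  composites <- list(
    supervised = combineMarkers(panel, markers, "supervised_logistic",
                                weeks = weeksRoc),
    unsupervised = combineMarkers(panel, markers, "unsupervised_pc1",
                                  weeks = weeksRoc))
  d <- .filterWeeks(panelData(panel), weeksRoc)
  roc <- list()
  for (m in markers)
    roc[[m]] <- rocAnalysis(d[[m]], d$group)
  for (nm in names(composites)) {
    cs <- composites[[nm]]
    roc[[paste0("composite_", nm)]] <-
      rocAnalysis(scoreValues(cs), cs@records$group)
  }
  cors <- do.call(rbind, lapply(markers, function(m) {
    cr <- correlateFunction(panel, m, readout = readout)
    data.frame(marker = m, readout = readout, pearson_r = cr@pearsonR,
               pearson_p = cr@pearsonP, spearman_rho = cr@spearmanRho,
               spearman_p = cr@spearmanP, n = cr@n)
  }))
  new("PanelReport", weeklyTests = weekly, composites = composites,
      roc = roc, correlations = cors, markers = markers,
      weeksRoc = as.integer(weeksRoc), readout = readout,
      schemaVersion = "1.0")
}
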