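# Shared in-code fixtures: tiny studies, panels and independent oracles.

makeStudy <- function(values, condition = NULL, ...) {
  if (is.null(condition))
    condition <- rep(c("case", "control"), length.out = ncol(values))
  ExpressionStudy(values, condition, ...)
}

randomStudy <- function(nGenes = 30, nCase = 4, nControl = 4, seed = 1,
                        level = "gene") {
  set.seed(seed)
  n <- nCase + nControl
  m <- matrix(rnorm(nGenes * n, 6, 1.5), nGenes, n,
              dimnames = list(sprintf("g%05d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(n))))
  makeStudy(m, rep(c("case", "control"), c(nCase, nControl)), level = level)
}

makePanelFrame <- function(up, down, nullm = NULL, ea = NULL, group, week) {
  n <- length(up)
  d <- data.frame(animal_id = sprintf("a%03d", seq_len(n)),
                  group = group, week = as.integer(week),
                  marker_up = up, marker_down = down)
  if (!is.null(nullm)) d$marker_null <- nullm
  d$ea_ratio <- if (is.null(ea)) as.numeric(seq_len(n)) else ea
  d
}

# --- independent oracles -------------------------------------------------

# Exact two-sided rank-sum p by enumerating every case/control rank split.
enumRankSumP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1)
  u <- apply(sets, 2L, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u <= uObs), mean(u >= uObs)))
}

# Brute-force BH step-up q-values.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

bruteBonferroni <- function(p) pmin(1, length(p) * p)

# Rank-then-bin enumeration oracle for per-sample quantile binning.
bruteQD <- function(x, Q) {
  G <- length(x)
  r <- rank(x, ties.method = "average")
  vapply(r, function(ri) min(max(ceiling(ri * Q / G), 1), Q), numeric(1))
}

# O(n^2) concordant/tied pair counting AUC oracle.
bruteAUC <- function(scores, isCase) {
  cs <- scores[isCase]; ct <- scores[!isCase]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# Closed-form pooled-variance two-sample t statistic (case minus control).
poolT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
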