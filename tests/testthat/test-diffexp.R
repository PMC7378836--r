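test_that("rank-sum test is exact for small untied samples", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_identical(r$direction, "down")
  expect_true(r$exact)

  # identical multisets: complete symmetry
  r2 <- rankSumTest(c(2, 4, 7), c(2, 4, 7))
  expect_equal(r2$p, 1)
  expect_identical(r2$direction, "none")

  # all values identical across both groups: p = 1, no error
  r3 <- rankSumTest(rep(3, 4), rep(3, 5))
  expect_equal(r3$p, 1)
  expect_identical(r3$direction, "none")

  expect_error(rankSumTest(1, c(1, 2)), "at least 2")
})

test_that("approximate p with ties tracks a permutation enumeration oracle", {
  # the enumeration oracle covers the tied approximate path: the
  # tie-corrected normal approximation must stay close to the exact
  # permutation p where calls are made (small p), and roughly everywhere
  set.seed(21)
  for (i in 1:8) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(1:6, 8, replace = TRUE)
    r <- rankSumTest(x, y)
    expect_false(r$exact)
    pExact <- enumRankSumP(x, y)
    expect_lt(abs(r$p - pExact), if (pExact <= 0.2) 0.02 else 0.1)
  }
  # and the untied exact path equals the enumeration to machine precision
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(rankSumTest(x, y)$p, enumRankSumP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum statistic obeys group-swap and monotone invariances", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(9)
    a <- rankSumTest(x, y); b <- rankSumTest(y, x)
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p, b$p, tolerance = 1e-12)
    # p is a rank statistic: invariant under strictly increasing maps
    w <- rankSumTest(exp(x), exp(y))
    expect_equal(a$p, w$p, tolerance = 1e-12)
    expect_equal(a$U, w$U)
  }
})

test_that("exact and approximate p-paths agree closely for 6-vs-6 untied data", {
  # deterministic sweep over every achievable U at 6 vs 6: the normal
  # approximation matches the exact p within 0.01 in the decision
  # region (exact p <= 0.2) and within 0.02 everywhere
  s2 <- 36 * 13 / 12
  for (U in 0:36) {
    pExact <- min(1, 2 * min(pwilcox(U, 6, 6),
                             pwilcox(U - 1, 6, 6, lower.tail = FALSE)))
    zc <- (U - 18 - sign(U - 18) * 0.5) / sqrt(s2)
    pApprox <- min(1, 2 * pnorm(-abs(zc)))
    expect_lt(abs(pExact - pApprox), if (pExact <= 0.2) 0.01 else 0.02)
  }
  # the implementation takes the exact path on untied 6v6 input
  expect_true(rankSumTest(rnorm(6), rnorm(6))$exact)
})

test_that("p-value corrections match definitions and ordering", {
  expect_equal(adjustPvalues(0.04, "bonferroni"), 0.04)
  expect_equal(adjustPvalues(0.04, "bh"), 0.04)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjustPvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1.0))
  expect_error(adjustPvalues(numeric(0), "bh"), "empty")
  expect_error(adjustPvalues(c(0.1, 0), "bh"), "0, 1")

  set.seed(30)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    bonf <- adjustPvalues(p, "bonferroni")
    bh <- adjustPvalues(p, "bh")
    expect_equal(bonf, bruteBonferroni(p), tolerance = 1e-12)
    expect_equal(bh, bruteBH(p), tolerance = 1e-12)
    expect_true(all(bonf >= bh - 1e-12) && all(bh >= p - 1e-12))
  }
})

test_that("runDifferentialExpression matches per-gene tests and calls DEGs", {
  set.seed(3)
  es <- randomStudy(nGenes = 40, nCase = 10, nControl = 10, seed = 3)
  dd <- quantileDiscretize(es, Q = 20)
  deg <- runDifferentialExpression(dd, alpha = 0.05)
  expect_s4_class(deg, "DEGTable")
  bins <- binMatrix(dd)
  isCase <- sampleCondition(dd) == "case"
  for (g in sample(rownames(bins), 8)) {
    ref <- rankSumTest(bins[g, isCase], bins[g, !isCase])
    expect_equal(deg[g, "p_raw"], ref$p, tolerance = 1e-12)
    expect_equal(deg[g, "U"], ref$U)
    expect_identical(deg[g, "direction"], ref$direction)
  }
  # and the tied/approximate column agrees with wilcox.test's normal path
  wt <- suppressWarnings(wilcox.test(bins[1, isCase], bins[1, !isCase],
                                     correct = TRUE, exact = FALSE))
  expect_equal(deg[1, "p_raw"], wt$p.value, tolerance = 1e-10)

  # alpha = 0 empties every DEG set
  deg0 <- runDifferentialExpression(dd, alpha = 0)
  expect_length(degGenes(deg0, "raw"), 0)
  expect_length(degGenes(deg0, "bh"), 0)

  expect_error(ExpressionStudy(assay(es), rep("case", 20)), "control")
})

test_that("planted effects separate cleanly from null genes in rank", {
  p <- studySimParams(nGenes = 400, nCase = 15, nControl = 15,
                      deGenes = sprintf("g%05d", 1:20), effectSize = 2)
  sim <- simulateStudy(p, seed = 77)
  dd <- quantileDiscretize(sim$study, Q = 128)
  deg <- runDifferentialExpression(dd)
  planted <- sim$truth$deGenes
  nullP <- deg[setdiff(rownames(deg), planted), "p_raw"]
  worstPlanted <- max(deg[planted, "p_raw"])
  expect_lt(mean(nullP < worstPlanted), 0.05)
})

test_that("intersectAndRank ranks by integrated p with documented tie-breaks", {
  mkDeg <- function(genes, p, deg) {
    d <- S4Vectors::DataFrame(
      W = seq_along(genes), U = seq_along(genes),
      z = rev(seq_along(genes)), p_raw = p, direction = "up",
      p_bonferroni = pmin(1, p * length(p)), q_bh = p,
      deg_raw = deg, deg_bonf = deg, deg_bh = deg,
      row.names = genes)
    new("DEGTable", d)
  }
  genes <- c("gB", "gA", "gC", "gD")
  dA <- mkDeg(genes, c(0.01, 0.01, 0.2, 0.01), c(TRUE, TRUE, FALSE, TRUE))
  dB <- mkDeg(genes, c(0.01, 0.01, 0.01, 0.3), c(TRUE, TRUE, TRUE, FALSE))
  dI <- mkDeg(genes, c(0.02, 0.02, 0.001, 0.5), rep(TRUE, 4))
  cs <- intersectAndRank(dA, dB, dI, k = 2)
  # common = {gA, gB}; tie on p broken by |z| descending: gB has z = 4
  expect_setequal(cs@commonGenes, c("gA", "gB"))
  expect_identical(candidateRanking(cs)$gene, c("gB", "gA"))
  expect_identical(topCandidates(cs), c("gB", "gA"))

  # k beyond the intersection returns everything ranked
  cs2 <- intersectAndRank(dA, dB, dI, k = 10)
  expect_identical(topCandidates(cs2), c("gB", "gA"))

  # disjoint DEG sets yield an empty candidate set with a warning
  dC <- mkDeg(genes, rep(0.01, 4), c(FALSE, FALSE, TRUE, FALSE))
  expect_warning(cs3 <- intersectAndRank(dA, dC, dI, k = 2), "empty")
  expect_length(topCandidates(cs3), 0)

  # integrated table must cover the intersection
  dIshort <- mkDeg("gC", 0.01, TRUE)
  expect_error(intersectAndRank(dA, dB, dIshort, k = 2), "cover")
})
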