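test_that("weekly group tests equal the pooled-variance t statistic", {
  set.seed(1)
  # identical group values: t = 0, p = 1
  d <- makePanelFrame(up = rep(c(1, 2, 3, 4), 2), down = rnorm(8),
                      group = rep(c("control", "case"), each = 4),
                      week = 9)
  names(d)[names(d) == "marker_up"] <- "m"
  names(d)[names(d) == "marker_down"] <- "m2"
  pan <- BiomarkerPanel(d, markers = c("m", "m2"))
  wt <- weeklyGroupTests(pan, "m")
  expect_equal(wt$t_value, 0, tolerance = 1e-12)
  expect_equal(wt$p_value, 1, tolerance = 1e-12)

  # constant positive offset gives t > 0 (case minus control sign)
  d2 <- d
  d2$m <- d$m + ifelse(d$group == "case", 2, 0)
  wt2 <- weeklyGroupTests(BiomarkerPanel(d2, markers = c("m", "m2")), "m")
  expect_gt(wt2$t_value, 0)

  # random 8-vs-8 matches the closed-form pooled-t oracle
  for (i in 1:5) {
    x <- rnorm(8, 1); y <- rnorm(8)
    dr <- makePanelFrame(up = c(y, x), down = rnorm(16),
                         group = rep(c("control", "case"), each = 8),
                         week = 11)
    panr <- BiomarkerPanel(dr, markers = c("marker_up", "marker_down"))
    wtr <- weeklyGroupTests(panr, "marker_up")
    expect_equal(wtr$t_value, poolT(x, y), tolerance = 1e-10)
    expect_equal(wtr$n_case, 8L)
  }

  # a week with a single group is skipped with a warning
  d3 <- makePanelFrame(up = 1:4, down = rnorm(4),
                       group = rep("case", 4), week = 16)
  names(d3)[names(d3) == "marker_up"] <- "m"
  names(d3)[names(d3) == "marker_down"] <- "m2"
  pan3 <- BiomarkerPanel(rbind(d, d3), markers = c("m", "m2"),
                         weeks = c(9L, 16L))
  expect_warning(wt3 <- weeklyGroupTests(pan3, "m"), "skipped")
  expect_identical(wt3$week, 9L)
})

test_that("composite scores behave as specified in both modes", {
  set.seed(2)
  n <- 60
  z <- rnorm(n)
  d <- makePanelFrame(up = z + rnorm(n, sd = 0.5),
                      down = -z + rnorm(n, sd = 0.5),
                      group = rep(c("control", "case"), each = n / 2),
                      week = 11)
  pan <- BiomarkerPanel(d, markers = c("marker_up", "marker_down"))

  # single marker, unsupervised: score is the standardized marker
  cs1 <- combineMarkers(pan, "marker_up", "unsupervised_pc1")
  expect_equal(varianceShare(cs1), 1.0)
  expect_equal(scoreValues(cs1),
               as.numeric(scale(d$marker_up)), tolerance = 1e-10)

  # perfectly correlated pair: rank-1 correlation, share 1
  d2 <- d
  d2$marker_down <- 3 * d$marker_up - 1
  cs2 <- combineMarkers(BiomarkerPanel(d2, markers = c("marker_up",
                                                       "marker_down")),
                        c("marker_up", "marker_down"), "unsupervised_pc1")
  expect_equal(varianceShare(cs2), 1.0, tolerance = 1e-12)
  expect_equal(sqrt(sum(scoreWeights(cs2)^2)), 1, tolerance = 1e-12)

  # PC1 share matches the closed form (1 + |rho|) / 2 for two markers
  vs <- varianceShare(combineMarkers(pan, c("marker_up", "marker_down"),
                                     "unsupervised_pc1"))
  rho <- cor(d$marker_up, d$marker_down)
  expect_equal(vs, (1 + abs(rho)) / 2, tolerance = 1e-10)
  # and equals the top eigenvalue fraction of the correlation matrix
  ev <- eigen(cor(d[c("marker_up", "marker_down")]))$values
  expect_equal(vs, ev[1] / sum(ev), tolerance = 1e-12)

  # supervised single-marker composite is a monotone transform of the
  # marker, so its ROC is identical to the marker's
  d$marker_up <- d$marker_up + ifelse(d$group == "case", 1.5, 0)
  pan <- BiomarkerPanel(d, markers = c("marker_up", "marker_down"))
  csSup <- combineMarkers(pan, "marker_up", "supervised_logistic")
  aucSup <- rocAuc(rocAnalysis(scoreValues(csSup), d$group))
  aucRaw <- rocAuc(rocAnalysis(d$marker_up, d$group))
  expect_equal(aucSup, aucRaw, tolerance = 1e-12)

  # zero-variance marker is refused by name
  d$marker_down <- 1
  expect_error(combineMarkers(BiomarkerPanel(d, markers = c("marker_up",
                                                            "marker_down")),
                              c("marker_up", "marker_down"),
                              "unsupervised_pc1"),
               "marker_down")
})

test_that("ROC analysis matches pair counting, pROC, and handles edge cases", {
  # perfect separation
  r <- rocAnalysis(c(1, 2, 3, 11, 12, 13),
                   c(rep("control", 3), rep("case", 3)))
  expect_equal(rocAuc(r), 1.0)
  expect_equal(r@sensAtCutoff, 1)
  expect_equal(r@specAtCutoff, 1)
  expect_equal(rocCutoff(r), 11)

  # tied scores equal brute-force pair counting exactly
  set.seed(5)
  for (i in 1:20) {
    sc <- sample(1:5, 30, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    r <- rocAnalysis(sc, lb)
    expect_equal(rocAuc(r), bruteAUC(sc, lb), tolerance = 1e-12)
    # curve anchored at (0,0) and (1,1)
    expect_equal(r@sensitivity[1], 0)
    expect_equal(r@specificity[1], 1)
    expect_equal(r@sensitivity[length(r@sensitivity)], 1)
    expect_equal(r@specificity[length(r@specificity)], 0)
  }

  # agreement with pROC on untied data
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- rnorm(40); lb <- rep(c(TRUE, FALSE), 20)
  sc[lb] <- sc[lb] + 1
  expect_equal(rocAuc(rocAnalysis(sc, lb)),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)

  # AUC invariant under strictly increasing score transforms
  expect_equal(rocAuc(rocAnalysis(exp(sc), lb)),
               rocAuc(rocAnalysis(sc, lb)), tolerance = 1e-12)

  # orientation flag when scores run the wrong way
  rFlip <- rocAnalysis(-sc, lb)
  expect_true(rFlip@flipped)
  expect_equal(rFlip@aucFlipped, rocAuc(rocAnalysis(sc, lb)),
               tolerance = 1e-12)

  # constant scores: degenerate, AUC 0.5, undefined cutoff
  rc <- rocAnalysis(rep(2, 10), rep(c(TRUE, FALSE), 5))
  expect_true(rc@degenerate)
  expect_equal(rocAuc(rc), 0.5)
  expect_true(is.na(rocCutoff(rc)))

  expect_error(rocAnalysis(1:4, rep("case", 4)), "both classes")
})

test_that("marker-function correlations match closed forms and exclude missing pairs", {
  set.seed(7)
  n <- 30
  d <- makePanelFrame(up = rnorm(n), down = rnorm(n),
                      ea = rnorm(n),
                      group = rep(c("control", "case"), each = n / 2),
                      week = 16)
  d$ea_ratio <- d$marker_up
  pan <- BiomarkerPanel(d, markers = c("marker_up", "marker_down"))
  cr <- correlateFunction(pan, "marker_up")
  expect_equal(cr@pearsonR, 1, tolerance = 1e-12)
  expect_equal(cr@spearmanRho, 1, tolerance = 1e-12)

  d$ea_ratio <- -d$marker_up
  pan <- BiomarkerPanel(d, markers = c("marker_up", "marker_down"))
  expect_equal(correlateFunction(pan, "marker_up")@pearsonR, -1,
               tolerance = 1e-12)

  # pairwise exclusion of missing readout
  d$ea_ratio <- d$marker_up
  d$ea_ratio[1:3] <- NA
  pan <- suppressMessages(BiomarkerPanel(d, markers = c("marker_up",
                                                        "marker_down")))
  cr2 <- correlateFunction(pan, "marker_up")
  expect_equal(cr2@n, n - 3L)
  expect_equal(unname(cr2@pearsonR),
               unname(cor(d$marker_up[-(1:3)], d$ea_ratio[-(1:3)])),
               tolerance = 1e-12)

  dTiny <- d[1:5, ]
  dTiny$ea_ratio <- c(NA, NA, NA, 1, 2)
  panTiny <- suppressMessages(BiomarkerPanel(dTiny,
                                             markers = c("marker_up",
                                                         "marker_down")))
  expect_error(correlateFunction(panTiny, "marker_up"), "3 complete")
})

test_that("evaluatePanel bundles weekly tests, composites, ROC and correlations", {
  sim <- simulateSerumPanel(seed = 10)
  pr <- suppressWarnings(evaluatePanel(sim$panel))
  expect_s4_class(pr, "PanelReport")
  expect_setequal(unique(pr@weeklyTests$marker),
                  c("marker_up", "marker_down", "marker_null"))
  expect_setequal(names(pr@roc),
                  c("marker_up", "marker_down", "marker_null",
                    "composite_supervised", "composite_unsupervised"))
  # ROC restricted to weeks 9-14: 3 weeks x 8 per group
  expect_equal(pr@roc$marker_up@nCase, 24L)
  # composite modes present with sensible shares
  expect_true(is.na(varianceShare(pr@composites$supervised)))
  expect_gt(varianceShare(pr@composites$unsupervised), 1 / 3)
  # correlations pooled over all weeks
  expect_equal(unique(pr@correlations$n), 80L)
  # supervised in-sample AUC is not systematically below unsupervised
  expect_gte(rocAuc(pr@roc$composite_supervised),
             rocAuc(pr@roc$composite_unsupervised) - 0.02)
})
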