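test_that("collapseProbes averages probes per gene, sharing multi-mapped probes", {
  m <- matrix(c(2, 4, 10, 3, 5, 20), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  es <- makeStudy(m, c("case", "control"), level = "probe")
  pm <- data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
  expect_message(out <- collapseProbes(es, pm), "1 unmapped")
  expect_equal(assay(out)["gA", ], c(s1 = 3, s2 = 4))

  # a probe mapping two genes contributes to both means
  pm2 <- data.frame(probe_id = c("p1", "p1", "p2"),
                    gene_id = c("gA", "gB", "gB"))
  out2 <- suppressMessages(collapseProbes(es, pm2))
  expect_equal(assay(out2)["gA", "s1"], 2)
  expect_equal(assay(out2)["gB", "s1"], mean(c(2, 4)))

  expect_error(collapseProbes(es, data.frame(probe_id = "px",
                                             gene_id = "gZ")),
               "zero probes")
  expect_error(collapseProbes(out2, pm2), "probe-level")
})

test_that("collapseProbes matches a brute-force per-gene mean on a random map", {
  set.seed(42)
  es <- randomStudy(nGenes = 50, seed = 42, level = "probe")
  pm <- data.frame(probe_id = sample(rownames(es), 80, replace = TRUE),
                   gene_id = sample(sprintf("G%02d", 1:10), 80,
                                    replace = TRUE))
  pm <- unique(pm)
  out <- suppressMessages(collapseProbes(es, pm))
  v <- assay(es)
  for (g in rownames(out)) {
    probes <- pm$probe_id[pm$gene_id == g]
    expected <- colMeans(v[probes, , drop = FALSE])
    expect_equal(assay(out)[g, ], expected, tolerance = 1e-12)
  }
})

test_that("quantile discretization follows the rank-then-bin rule", {
  # strictly increasing sample with G = Q: identity binning
  G <- 128
  m <- matrix(seq_len(G) + 0.5, G, 2,
              dimnames = list(sprintf("g%03d", 1:G), c("s1", "s2")))
  dd <- quantileDiscretize(makeStudy(m, c("case", "control")), Q = 128)
  expect_identical(binMatrix(dd)[, 1], setNames(1:128, rownames(m)))

  # Q = 1 collapses everything into one bin
  dd1 <- quantileDiscretize(makeStudy(m, c("case", "control")), Q = 1)
  expect_true(all(binMatrix(dd1) == 1L))

  # random vectors with ties match the brute-force oracle
  for (seed in 1:20) {
    set.seed(seed)
    x <- sample(round(rnorm(40, 6, 2), 1), 40, replace = TRUE)
    mm <- matrix(rep(x, 2), 40, 2,
                 dimnames = list(sprintf("g%02d", 1:40), c("s1", "s2")))
    Q <- sample(c(2, 5, 8, 40), 1)
    dd <- quantileDiscretize(makeStudy(mm, c("case", "control")), Q = Q)
    expect_equal(unname(binMatrix(dd)[, 1]), bruteQD(x, Q))
  }

  expect_warning(quantileDiscretize(makeStudy(m, c("case", "control")),
                                    Q = 200), "exceeds")
})

test_that("binning is invariant under strictly monotone warps", {
  set.seed(9)
  m <- matrix(rnorm(200 * 4, 6, 1.5), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:4)))
  es <- makeStudy(m, rep(c("case", "control"), 2))
  ref <- binMatrix(quantileDiscretize(es, Q = 50))
  for (f in list(exp, function(x) 2 * x + 7, function(x) x^3)) {
    esW <- makeStudy(f(m), rep(c("case", "control"), 2))
    expect_identical(binMatrix(quantileDiscretize(esW, Q = 50)), ref)
  }
})

test_that("bins are exactly uniform when there are no ties and Q divides G", {
  set.seed(13)
  m <- matrix(rnorm(120), 120, 1, dimnames = list(sprintf("g%03d", 1:120),
                                                  "s1"))
  m <- cbind(m, s2 = rnorm(120))
  dd <- quantileDiscretize(makeStudy(m, c("case", "control")), Q = 12)
  for (j in 1:2)
    expect_true(all(table(binMatrix(dd)[, j]) == 10))
})

test_that("mergeStudies intersects genes deterministically and concatenates samples", {
  s1 <- quantileDiscretize(randomStudy(nGenes = 30, seed = 1), Q = 10)
  s2full <- randomStudy(nGenes = 30, nCase = 3, nControl = 4, seed = 2)
  s2 <- quantileDiscretize(s2full[c(5:30, 1:2), ], Q = 10)
  mg <- mergeStudies(list(s1, s2))
  expect_identical(rownames(mg), sort(intersect(rownames(s1), rownames(s2))))
  expect_equal(ncol(mg), ncol(s1) + ncol(s2))
  # order-insensitive gene content
  mg2 <- mergeStudies(list(s2, s1))
  expect_identical(rownames(mg2), rownames(mg))
  # self-merge keeps the gene set and doubles samples
  mgSelf <- mergeStudies(list(s1, s1))
  expect_identical(rownames(mgSelf), sort(rownames(s1)))
  expect_equal(ncol(mgSelf), 2L * ncol(s1))

  sQ <- quantileDiscretize(randomStudy(nGenes = 30, seed = 3), Q = 5)
  expect_error(mergeStudies(list(s1, sQ)), "mismatched Q")
  sDisj <- quantileDiscretize(randomStudy(nGenes = 30, seed = 4), Q = 10)
  rownames(sDisj) <- sprintf("x%05d", 1:30)
  expect_error(mergeStudies(list(s1, sDisj)), "empty gene intersection")
  expect_error(mergeStudies(list(s1)), "at least two")
})

test_that("standardizeStudy is a rank-preserving per-sample transform", {
  # constant sample: MAD guard yields all zeros
  m <- matrix(c(5, 5, 5, 1, 2, 9), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  out <- standardizeStudy(makeStudy(m, c("case", "control")))
  expect_true(all(assay(out)[, "s1"] == 0))
  # idempotent on an already-standardized sample
  out2 <- standardizeStudy(out)
  expect_equal(assay(out2)[, "s2"], assay(out)[, "s2"], tolerance = 1e-12)
  # downstream bins unchanged by standardization
  es <- randomStudy(nGenes = 60, seed = 5)
  expect_identical(binMatrix(quantileDiscretize(es, Q = 12)),
                   binMatrix(quantileDiscretize(standardizeStudy(es),
                                                Q = 12)))
})
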