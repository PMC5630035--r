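test_that("median imputation fills gaps gene by gene", {
  x <- matrix(c(0.2, 0.4, NA, 0.8, 0.6, NA), ncol = 1L,
              dimnames = list(NULL, "f"))
  fm <- featureMatrix(x, labels = c(1, 0, 1, 0, 1, 0),
                      gene = rep(c("g1", "g2"), each = 3L))
  out <- featureScores(imputeMissingScores(fm))
  expect_equal(unname(out[3L, "f"]), 0.3)  # median of 0.2, 0.4
  expect_equal(unname(out[6L, "f"]), 0.7)  # median of 0.8, 0.6
  # no missing values -> identity
  fm2 <- featureMatrix(matrix(runif(10), 5L, dimnames = list(NULL, c("a", "b"))))
  expect_identical(featureScores(imputeMissingScores(fm2)),
                   featureScores(fm2))
  # a feature with no annotated value in a gene is an error
  fmBad <- featureMatrix(matrix(c(NA, NA, 0.5), 3L,
                                dimnames = list(NULL, "f")),
                         gene = c("g1", "g1", "g2"))
  expect_error(imputeMissingScores(fmBad), "no annotated value")
})

test_that("near-zero-variance pruning flags degenerate features", {
  n <- 1000L
  x <- cbind(const = rep(0.5, n),
             lopsided = c(rep(0, 900L), rep(1, 100L)),
             smooth = seq(0, 1, length.out = n))
  fm <- featureMatrix(x)
  kept <- pruneNearZeroVariance(fm)
  expect_false("const" %in% kept)     # ratio infinite, 1 distinct value
  expect_false("lopsided" %in% kept)  # ratio 9 > 4 and 0.2% unique < 5%
  expect_true("smooth" %in% kept)     # all values distinct
})

test_that("correlation pruning removes the worse member of each tight pair", {
  set.seed(3)
  n <- 400L
  a <- runif(n)
  x <- cbind(A = a, B = a, C = runif(n))
  fm <- featureMatrix(x)
  kept <- prunePairwiseCorrelated(fm)
  expect_equal(sum(c("A", "B") %in% kept), 1L)  # exactly one of the pair
  expect_true("C" %in% kept)
  # A ~ B strongly; A also leans on C, so A has the larger mean |r| and goes
  b <- 0.9 * a + 0.1 * runif(n)
  cc <- 0.5 * a + 0.5 * runif(n)
  x2 <- apply(cbind(A = a, B = b, C = cc), 2L, function(v) {
    (rank(v) - 1) / (n - 1)
  })
  fm2 <- featureMatrix(x2)
  cm <- abs(cor(x2))
  expect_gt(cm["A", "B"], 0.75)
  expect_lt(cm["B", "C"], 0.75)
  # mean absolute correlation over all columns (diagonal contributes equally)
  worse <- names(which.max(colMeans(cm[, c("A", "B")])))
  kept2 <- prunePairwiseCorrelated(fm2)
  expect_setequal(kept2, setdiff(c("A", "B", "C"), worse))
  # nothing above threshold -> identity
  x3 <- matrix(runif(3L * n), ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
  expect_setequal(prunePairwiseCorrelated(featureMatrix(x3)),
                  c("x", "y", "z"))
})

test_that("shadow importance finds the planted feature and is reproducible", {
  fm <- simulateFeatureMatrix(150L, 150L, seed = 10L)
  rep1 <- assessFeatureImportance(fm, seed = 2L, runs = 15L, trees = 120L)
  cats <- importanceCategory(rep1)
  expect_equal(as.character(cats[["f1"]]), "informative")
  expect_false(any(as.character(cats[paste0("n", 1:4)]) == "informative"))
  expect_false(any(rep1@highlyInformative[-1L]))
  # bit-for-bit reproducibility under the seed
  rep2 <- assessFeatureImportance(fm, seed = 2L, runs = 15L, trees = 120L)
  expect_identical(rep1@zScores, rep2@zScores)
  expect_identical(rep1@shadowMax, rep2@shadowMax)
  # all-noise input yields no highly informative feature
  fmNull <- simulateFeatureMatrix(
    120L, 120L, featureSpec = data.frame(name = paste0("n", 1:4),
                                         effect = 0),
    seed = 4L)
  repN <- assessFeatureImportance(fmNull, seed = 3L, runs = 15L,
                                  trees = 120L)
  expect_false(any(repN@highlyInformative))
  # degenerate labels are rejected
  fmOne <- featureMatrix(matrix(runif(10), 10L, dimnames = list(NULL, "f")),
                         labels = rep(1L, 10L))
  expect_error(assessFeatureImportance(fmOne), "both classes")
})

test_that("stepwise selection keeps genuine signal and stops on noise", {
  fm <- simulateFeatureMatrix(
    400L, 400L,
    featureSpec = data.frame(name = c("sig", "noise"), effect = c(1.5, 0)),
    seed = 20L)
  model <- selectGeneModel(fm, c("sig", "noise"))
  expect_true("sig" %in% names(model@coefficients))
  expect_false("noise" %in% names(model@coefficients))
  tr <- model@trace
  expect_equal(tr$action[1L], "start")
  expect_lt(tr$aic[tr$feature == "sig"], tr$aic[tr$action == "start"])
  expect_false(tr$accepted[tr$feature == "noise"])
  expect_gt(model@trainingAuc, 0.7)
})

test_that("a duplicated informative candidate enters only once", {
  fm <- simulateFeatureMatrix(
    300L, 300L, featureSpec = data.frame(name = "sig", effect = 2),
    seed = 30L)
  x <- cbind(featureScores(fm), sig2 = featureScores(fm)[, "sig"])
  fm2 <- featureMatrix(x, labels = featureLabels(fm), gene = "g")
  model <- selectGeneModel(fm2, c("sig", "sig2"))
  expect_true("sig" %in% names(model@coefficients))
  expect_false("sig2" %in% names(model@coefficients))
})

test_that("the MTR term seeds the model when requested", {
  fm <- simulateFeatureMatrix(
    200L, 200L, featureSpec = data.frame(name = "sig", effect = 1.5),
    seed = 40L)
  fm@mtr <- ifelse(featureLabels(fm) == 1L, runif(400L, 0, 0.7),
                   runif(400L, 0.3, 1.3))
  model <- selectGeneModel(fm, "sig", includeMtr = TRUE)
  expect_true("MTR" %in% names(model@coefficients))
  expect_lt(unname(model@coefficients[["MTR"]]), 0)  # lower MTR, more risk
  modelNo <- selectGeneModel(fm, "sig", includeMtr = FALSE)
  expect_false("MTR" %in% names(modelNo@coefficients))
})

test_that("perfect separation falls back to the ridge-penalized fit", {
  x <- matrix(c(seq(0, 0.4, length.out = 10L),
                seq(0.6, 1, length.out = 10L)), ncol = 1L,
              dimnames = list(NULL, "f"))
  fm <- featureMatrix(x, labels = rep(c(0L, 1L), each = 10L))
  model <- selectGeneModel(fm, "f")
  expect_true("f" %in% names(model@coefficients))
  expect_true(any(grepl("ridge fallback", model@trace$note)))
  expect_true(all(is.finite(modelCoefficients(model))))
})

test_that("GPP scores are the inverse-logit of the linear predictor", {
  m0 <- new("GeneModel", geneSymbol = "g", intercept = 0,
            coefficients = c(f = 0), trace = data.frame(),
            trainingAuc = NA_real_)
  expect_equal(scoreGpp(m0, data.frame(f = 0.3)), 0.5)
  m1 <- new("GeneModel", geneSymbol = "g", intercept = -2,
            coefficients = c(f = 4), trace = data.frame(),
            trainingAuc = NA_real_)
  expect_equal(scoreGpp(m1, data.frame(f = 0.5)), 0.5)
  xs <- data.frame(f = seq(0, 1, 0.1))
  expect_true(all(diff(scoreGpp(m1, xs)) > 0))
  expect_error(scoreGpp(m1, data.frame(g = 1)), "missing from input")
  expect_error(scoreGpp(m1, data.frame(f = NA_real_)), "missing feature value")
})

test_that("rank AUC counts pairwise wins with half credit for ties", {
  expect_equal(evaluateAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(evaluateAuc(rep(0.5, 6L), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(evaluateAuc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 0.75)
  expect_error(evaluateAuc(1:3, c(1, 1, 1)), "both classes")
  # agrees with the Mann-Whitney statistic on tie-free data
  set.seed(14)
  s <- rnorm(40)
  y <- rep(c(1, 0), 20L)
  u <- unname(wilcox.test(s[y == 1], s[y == 0])$statistic)
  expect_equal(evaluateAuc(s, y), u / (20 * 20))
})

test_that("the pipeline enforces its stage order and supports a global model", {
  fm <- simulateFeatureMatrix(120L, 120L, seed = 50L, missingRate = 0.05)
  cfg <- runConfig(importanceRuns = 12L, importanceTrees = 100L)
  res <- runGppPipeline(fm, config = cfg)
  expect_true("f1" %in% res$retained)
  expect_true("f1" %in% names(res$models[[1L]]@coefficients))
  expect_gt(res$auc[[1L]], 0.7)
  expect_length(res$scores, 240L)
  expect_true(all(res$scores > 0 & res$scores < 1))
  # pooling two genes through the global path yields one shared model
  fm2 <- simulateFeatureMatrix(120L, 120L, seed = 51L)
  fm2@gene <- rep(c("gA", "gB"), 120L)
  resG <- runGppPipeline(fm2, global = TRUE, config = cfg)
  expect_length(resG$models, 1L)
  expect_equal(resG$models[[1L]]@geneSymbol, "global")
  unl <- featureMatrix(featureScores(fm), labels = NA_integer_)
  expect_error(runGppPipeline(unl, config = cfg), "no labels")
})
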