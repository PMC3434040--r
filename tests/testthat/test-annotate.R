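# Builds tiny AnnotationDatasets directly (features are arbitrary here; the
# protocol machinery is what is under test).
mkDataset <- function(Y, X = NULL, terms = NULL) {
  n <- nrow(Y)
  if (is.null(X)) { set.seed(99); X <- matrix(rnorm(n * 3), n, 3) }
  rownames(X) <- rownames(Y) <- sprintf("g%03d", seq_len(n))
  f <- colSums(Y)
  ord <- order(-f, colnames(Y))
  Y <- Y[, ord, drop = FALSE]
  new("AnnotationDataset", X = X, Y = Y, termNames = colnames(Y),
      termFrequencies = as.integer(colSums(Y)))
}

test_that("term selection keeps the most frequent terms and drops empty groups", {
  set.seed(50)
  Y <- cbind(a = rbinom(40, 1, 0.8), b = rbinom(40, 1, 0.5),
             c = rbinom(40, 1, 0.3), d = rbinom(40, 1, 0.2))
  ds <- mkDataset(Y)
  full <- selectTerms(ds, 4)
  expect_identical(termNames(full), termNames(ds))
  expect_equal(nrow(featureMatrix(full)), sum(rowSums(Y) > 0))

  top2 <- selectTerms(ds, 2)
  hand <- names(sort(colSums(Y), decreasing = TRUE))[1:2]
  expect_setequal(termNames(top2), hand)
  # step sequence gives nested term sets
  expect_identical(termNames(selectTerms(ds, 2)),
                   termNames(selectTerms(ds, 3))[1:2])
  expect_identical(termNames(selectTerms(ds, 3)),
                   termNames(selectTerms(ds, 4))[1:3])

  Yrare <- cbind(a = rep(1, 10), b = c(1, rep(0, 9)))
  expect_error(selectTerms(mkDataset(Yrare), 2), "< 2 positive")
})

test_that("partitions are disjoint, exhaustive, and stratified per term", {
  # forced case: 1 term, 2 positives in 4 groups -> 1 positive per side
  Yf <- cbind(a = c(1, 1, 0, 0))
  df <- mkDataset(Yf)
  for (p in makePartitions(df, nPartitions = 10, seed = 1)) {
    expect_equal(sort(c(p$train, p$test)), 1:4)
    expect_equal(sum(Yf[p$train, 1]), 1)
  }

  set.seed(51)
  Y <- cbind(a = rbinom(60, 1, 0.5), b = rbinom(60, 1, 0.4),
             c = rbinom(60, 1, 0.3))
  Y[1:2, ] <- 1                      # ensure no term is empty
  ds <- mkDataset(Y)
  parts <- makePartitions(ds, nPartitions = 30, seed = 7)
  expect_length(parts, 30)
  Ys <- labelMatrix(ds)
  for (p in parts) {
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), seq_len(nrow(Ys)))
    # near-1:1 overall
    expect_lte(abs(length(p$train) - length(p$test)), 1)
    for (t in seq_len(ncol(Ys))) {
      pos <- sum(Ys[, t])
      expect_lte(abs(sum(Ys[p$train, t]) - pos / 2), 1)
    }
  }
})

test_that("oversampling balances positives without touching negatives", {
  set.seed(52)
  X <- matrix(rnorm(24), 12, 2)
  y <- c(1, 1, rep(0, 10))
  os <- oversample(X, y, seed = 3)
  expect_equal(sum(os$y == 1), 10)
  expect_equal(sum(os$y == 0), 10)
  expect_setequal(unique(os$sourceIndex[os$y == 1]), 1:2)
  expect_identical(os$sourceIndex[os$y == 0], 3:12)
  expect_identical(os$X[os$y == 0, ], X[3:12, ])
  expect_identical(oversample(X, y, seed = 3)$sourceIndex, os$sourceIndex)

  balanced <- oversample(X, rep(c(1, 0), 6), seed = 1)
  expect_identical(balanced$X, X)
  expect_error(oversample(X, rep(0, 12)), "zero positives")
})

test_that("one-vs-rest linear SVMs separate separable terms and are deterministic", {
  set.seed(53)
  n <- 40
  X <- rbind(matrix(rnorm(n, mean = 3), n / 2, 2),
             matrix(rnorm(n, mean = -3), n / 2, 2))
  Y <- cbind(sep = rep(c(1, 0), each = n / 2))
  models <- trainOvr(X, Y, classifier = "linear_svm")
  s <- models$sep(X)
  expect_equal(as.numeric(s > 0), Y[, 1])

  # same data, permuted sample order: same predicted labels
  perm <- sample(n)
  models2 <- trainOvr(X[perm, , drop = FALSE], Y[perm, , drop = FALSE])
  expect_equal(as.numeric(models2$sep(X) > 0), Y[, 1])
  # repeat call is bit-identical
  models3 <- trainOvr(X, Y)
  expect_identical(models3$sep(X), s)

  Ybad <- cbind(allpos = rep(1, n))
  expect_error(trainOvr(X, Ybad), "allpos")
})

test_that("logistic and ridge classifiers with CV also learn the separable term", {
  set.seed(54)
  n <- 40
  X <- rbind(matrix(rnorm(n, mean = 2), n / 2, 2),
             matrix(rnorm(n, mean = -2), n / 2, 2))
  Y <- cbind(sep = rep(c(1, 0), each = n / 2))
  for (clf in c("logistic", "ridge")) {
    models <- trainOvr(X, Y, classifier = clf, cv = TRUE, seed = 2)
    expect_gt(rankAuc(models$sep(X), Y[, 1]), 0.95)
  }
})

test_that("rank AUC matches its definition and is monotone-invariant", {
  y <- c(1, 1, 1, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.1, 0.7, 0.3, 0.2, 0.05)
  # direct Mann-Whitney count: pairs (pos, neg) with s_pos > s_neg (+0.5 ties)
  pairs <- outer(s[y == 1], s[y == 0], function(a, b)
    (a > b) + 0.5 * (a == b))
  expect_equal(rankAuc(s, y), mean(pairs))
  expect_equal(rankAuc(log(s + 1), y), rankAuc(s, y))
  expect_equal(rankAuc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # ties get midrank credit
  expect_equal(rankAuc(c(1, 1, 1, 1), c(1, 1, 0, 0)), 0.5)
  skip_if_not_installed("pROC")
  set.seed(55)
  sc <- rnorm(50); lb <- rbinom(50, 1, 0.5)
  expect_equal(rankAuc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("evaluation reproduces hand-computed contingency metrics", {
  # target table: TP=3 FP=1 FN=1 TN=5
  y <- c(rep(1, 4), rep(0, 6))
  s <- c(1, 1, 1, -1, 1, rep(-1, 5))
  models <- structure(list(t1 = function(X) s), class = "ovrModels")
  ev <- evaluateOvr(models, matrix(0, 10, 1), cbind(t1 = y))
  expect_equal(ev$perTerm$sensitivity, 0.75)
  expect_equal(ev$perTerm$specificity, 5 / 6)
  expect_equal(ev$perTerm$f1, 0.75)

  # perfect scores: AUC and F1 both 1
  models2 <- structure(list(t1 = function(X) y - 0.5), class = "ovrModels")
  ev2 <- evaluateOvr(models2, matrix(0, 10, 1), cbind(t1 = y))
  expect_equal(ev2$perTerm$auc, 1)
  expect_equal(ev2$perTerm$f1, 1)

  # random scores on balanced labels: AUC near 1/2
  set.seed(56)
  n <- 1000
  yr <- rep(c(0, 1), n / 2)
  expect_lt(abs(rankAuc(rnorm(n), yr) - 0.5), 0.05)

  # macro F1 equals the mean of independently recomputed per-term F1
  set.seed(57)
  Y2 <- cbind(a = rbinom(30, 1, 0.5), b = rbinom(30, 1, 0.5))
  S2 <- matrix(rnorm(60), 30, 2)
  models3 <- structure(list(a = function(X) S2[, 1],
                            b = function(X) S2[, 2]), class = "ovrModels")
  ev3 <- evaluateOvr(models3, matrix(0, 30, 2), Y2)
  f1hand <- vapply(1:2, function(t) {
    pred <- as.numeric(S2[, t] > 0)
    tp <- sum(pred & Y2[, t]); fp <- sum(pred & !Y2[, t])
    fn <- sum(!pred & Y2[, t])
    2 * tp / (2 * tp + fp + fn)
  }, 1)
  expect_equal(unname(ev3$macro["f1"]), mean(f1hand))

  # a term with one test class is flagged and excluded from the macro
  Y3 <- cbind(a = rep(1, 5), b = c(1, 1, 0, 0, 0))
  models4 <- structure(list(a = function(X) rnorm(5),
                            b = function(X) c(1, 1, -1, -1, -1)),
                       class = "ovrModels")
  expect_warning(ev4 <- evaluateOvr(models4, matrix(0, 5, 2), Y3),
                 "one class")
  expect_true(is.na(ev4$perTerm$auc[1]))
  expect_equal(unname(ev4$macro["f1"]), 1)
})

test_that("oversampling does not hurt recall on an imbalanced toy problem", {
  set.seed(58)
  X <- rbind(matrix(rnorm(4, mean = 2.5), 2, 2),
             matrix(rnorm(36, mean = -1), 18, 2))
  Y <- cbind(rare = c(1, 1, rep(0, 18)))
  base <- trainOvr(X, Y, seed = 1)
  over <- trainOvr(X, Y, oversamplePositives = TRUE, seed = 1)
  recall <- function(m) {
    pred <- as.numeric(m$rare(X) > 0)
    sum(pred & Y[, 1]) / sum(Y[, 1])
  }
  expect_gte(recall(over), recall(base))
})

test_that("the full experiment produces one row per term count, mode and metric", {
  spec <- syntheticSpec(noiseSd = 6)
  gs <- generateGroupSet(spec, nGroups = 24, imagesPerGroup = 1,
                         termCatalog = c("anterior_spot", "posterior_spot"),
                         prevalence = 0.5, seed = 10)
  cfg <- list(codebookSize = 12L, sampleFraction = 0.5, kmeansRestarts = 2L,
              partitions = 2L, seed = 3L,
              modes = c("spatial-sparse", "global-hard"))
  res <- runAnnotationExperiment(gs, cfg)
  expect_equal(nrow(res), 2 * 4)      # 2 modes x 4 metrics, single term count
  expect_setequal(unique(res$mode), cfg$modes)
  expect_true(all(res$metric %in% c("auc", "f1", "sensitivity", "specificity")))
  expect_true(all(res$mean >= 0 & res$mean <= 1))
  expect_true(all(res$sd >= 0))

  # identical config + seed: identical tables
  res2 <- runAnnotationExperiment(gs, cfg)
  expect_identical(res, res2)

  path <- file.path(withr::local_tempdir(), "ann.csv")
  writeAnnotationCsv(res, path)
  tab <- read.csv(path)
  expect_identical(colnames(tab), c("stage_or_dataset", "n_terms", "mode",
                                    "metric", "mean", "sd"))
  expect_equal(nrow(tab), nrow(res))
})
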