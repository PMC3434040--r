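# Multi-label annotation protocol: term selection by frequency, repeated
# stratified 1:1 splits, one-vs-rest linear classifiers (libsvm linear kernel
# with C = 1 by default), optional positive over-sampling, and rank-based
# AUC / macro-F1 / sensitivity / specificity.

#' Retain the most frequent terms
#'
#' Keeps the `topN` most frequent terms (term columns are already ordered by
#' descending frequency, so term sets grown in steps are nested) and drops
#' groups carrying none of the retained terms. Errors if a retained term ends
#' up with fewer than 2 positive or 2 negative groups, since a stratified 1:1
#' split is then impossible.
#'
#' @param dataset an [AnnotationDataset-class].
#' @param topN number of terms to retain.
#' @return The reduced [AnnotationDataset-class].
#' @export
selectTerms <- function(dataset, topN) {
  terms <- termNames(dataset)
  if (topN > length(terms)) stop("topN exceeds the number of available terms")
  keep <- seq_len(topN)
  Y <- labelMatrix(dataset)[, keep, drop = FALSE]
  rows <- rowSums(Y) > 0
  Y <- Y[rows, , drop = FALSE]
  pos <- colSums(Y)
  if (any(pos < 2))
    stop(sprintf("term(s) with < 2 positive groups: %s",
                 paste(terms[keep][pos < 2], collapse = ", ")))
  if (any(nrow(Y) - pos < 2))
    stop(sprintf("term(s) with < 2 negative groups: %s",
                 paste(terms[keep][nrow(Y) - pos < 2], collapse = ", ")))
  new("AnnotationDataset", X = featureMatrix(dataset)[rows, , drop = FALSE],
      Y = Y, termNames = terms[keep],
      termFrequencies = as.integer(pos))
}

#' Repeated stratified 1:1 train/test partitions
#'
#' Each partition splits the groups into disjoint train and test halves with
#' per-term stratification, processed greedily one term at a time: each
#' term's not-yet-assigned positive groups are placed so the term's positives
#' end up as balanced as parity allows. Terms are processed from rarest to
#' most frequent -- a rare term's few positives are the hardest to balance
#' after the fact, while a frequent term processed late still has plenty of
#' unassigned positives left to correct any imbalance (overlapping labels
#' make exact simultaneous stratification infeasible in general, so later
#' terms are best-effort). Groups left unassigned at the end are used to
#' balance the overall 1:1 ratio. Default 30 partitions.
#'
#' @param dataset an [AnnotationDataset-class].
#' @param nPartitions number of random partitions (default 30).
#' @param seed integer seed.
#' @return List of `nPartitions` lists with integer index vectors `train`
#'   and `test`.
#' @export
makePartitions <- function(dataset, nPartitions = 30L, seed = 1L) {
  Y <- labelMatrix(dataset)
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 groups to partition")
  lapply(seq_len(nPartitions), function(p) withSeed(deriveSeed(seed, p), {
    side <- rep(NA, n)                 # TRUE = train, FALSE = test
    for (t in rev(seq_len(ncol(Y)))) { # rarest term first
      pos <- which(Y[, t] == 1)
      a <- sum(side[pos] %in% TRUE)    # positives already in train
      b <- sum(side[pos] %in% FALSE)
      un <- pos[is.na(side[pos])]
      if (length(un)) un <- un[sample.int(length(un))]
      for (g in un) {
        put <- if (a < b) TRUE else if (b < a) FALSE else sample(c(TRUE, FALSE), 1L)
        side[g] <- put
        if (put) a <- a + 1L else b <- b + 1L
      }
      if (a == 0L || b == 0L)
        stop(sprintf("term '%s' has all positives on one side",
                     termNames(dataset)[t]))
    }
    rest <- which(is.na(side))
    if (length(rest)) rest <- rest[sample.int(length(rest))]
    for (g in rest) {
      nT <- sum(side %in% TRUE); nF <- sum(side %in% FALSE)
      side[g] <- if (nT < nF) TRUE else if (nF < nT) FALSE
                 else sample(c(TRUE, FALSE), 1L)
    }
    list(train = which(side), test = which(!side))
  }))
}

#' Over-sample the positive class
#'
#' Randomly resamples the positive training examples with replacement until
#' their count equals the negative count; negatives are untouched. A no-op if
#' positives already match or outnumber negatives.
#'
#' @param trainX training feature matrix.
#' @param trainY binary label vector for one term.
#' @param seed integer seed.
#' @return List with balanced `X`, `y`, and `sourceIndex`, the row of
#'   `trainX` each returned row came from.
#' @export
oversample <- function(trainX, trainY, seed = 1L) {
  pos <- which(trainY == 1)
  neg <- which(trainY == 0)
  if (length(pos) == 0L) stop("cannot oversample a term with zero positives")
  if (length(neg) == 0L) stop("cannot oversample a term with zero negatives")
  if (length(pos) >= length(neg))
    return(list(X = trainX, y = trainY, sourceIndex = seq_along(trainY)))
  draw <- withSeed(seed, sample(pos, length(neg), replace = TRUE))
  idx <- c(neg, draw)
  list(X = trainX[idx, , drop = FALSE],
       y = trainY[idx], sourceIndex = idx)
}

binaryF1 <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic with
#' midranks for tied scores; invariant to any strictly monotone transform of
#' the scores.
#'
#' @param scores real-valued decision scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
rankAuc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

fitBinary <- function(X, y, classifier, params, cvSeed) {
  if (classifier == "linear_svm") {
    fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                      cost = params$cost, scale = FALSE)
    score <- function(newX) {
      p <- stats::predict(fit, newX, decision.values = TRUE)
      as.numeric(attr(p, "decision.values")[, 1])
    }
    # libsvm's decision-value sign depends on label order; orient so
    # positives score higher on the training data
    s <- score(X)
    sgn <- if (mean(s[y == 1]) >= mean(s[y == 0])) 1 else -1
    function(newX) sgn * score(newX)
  } else if (classifier == "logistic") {
    path <- sort(unique(c(params$lambda, c(100, 10, 1, 0.1, 0.01))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = path, standardize = FALSE)
    function(newX)
      as.numeric(stats::predict(fit, newX, s = params$lambda, type = "link"))
  } else if (classifier == "ridge") {
    path <- sort(unique(c(params$lambda, c(100, 10, 1, 0.1, 0.01))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(X, 2 * y - 1, family = "gaussian", alpha = 0,
                          lambda = path, standardize = FALSE)
    function(newX)
      as.numeric(stats::predict(fit, newX, s = params$lambda))
  } else stop(sprintf("unknown classifier '%s'", classifier))
}

# 4-fold cross-validation over a decade grid of the regularization
# parameter, selecting by mean validation F1 at threshold 0.
selectRegularization <- function(X, y, classifier, grid, seed) {
  folds <- withSeed(seed, {
    f <- rep(NA_integer_, length(y))
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      f[idx] <- rep_len(1:4, length(idx))[sample.int(length(idx))]
    }
    f
  })
  scoreOf <- function(value) {
    params <- if (classifier == "linear_svm") list(cost = value)
              else list(lambda = value)
    mean(vapply(1:4, function(k) {
      tr <- folds != k; va <- !tr
      if (length(unique(y[tr])) < 2L || !any(va)) return(NA_real_)
      mdl <- fitBinary(X[tr, , drop = FALSE], y[tr], classifier, params, seed)
      binaryF1(y[va], as.numeric(mdl(X[va, , drop = FALSE]) > 0))
    }, 1), na.rm = TRUE)
  }
  f1s <- vapply(grid, scoreOf, 1)
  grid[which.max(f1s)]
}

#' Train one-vs-rest binary classifiers
#'
#' One binary linear model per term, each producing real-valued decision
#' scores oriented so larger means more likely positive. The default is a
#' linear-kernel SVM with regularization parameter C = 1; with `cv = TRUE`
#' the regularization value is instead chosen per term by 4-fold
#' cross-validation over `{0.01, 0.1, 1, 10, 100}` maximizing validation F1
#' (the protocol used when comparing classifiers). `"logistic"` and
#' `"ridge"` are L2-regularized logistic / least-squares linear models.
#'
#' @param trainX training feature matrix (groups x features).
#' @param trainY binary label matrix (groups x terms), with column names.
#' @param classifier `"linear_svm"`, `"logistic"` or `"ridge"`.
#' @param params list of fixed parameters: `cost` for the SVM (default 1),
#'   `lambda` for the glmnet models (default 1).
#' @param cv choose the regularization per term by 4-fold CV?
#' @param oversamplePositives balance each term's training set by
#'   [oversample()] before fitting?
#' @param seed integer seed (drives oversampling and CV fold draws).
#' @return List of per-term scoring functions (class `ovrModels`), each
#'   mapping a feature matrix to decision scores.
#' @export
trainOvr <- function(trainX, trainY, classifier = c("linear_svm", "logistic",
                                                    "ridge"),
                     params = list(), cv = FALSE, oversamplePositives = FALSE,
                     seed = 1L) {
  classifier <- match.arg(classifier)
  defaults <- list(cost = 1, lambda = 1)
  params <- utils::modifyList(defaults, params)
  terms <- colnames(trainY)
  if (is.null(terms)) terms <- paste0("term", seq_len(ncol(trainY)))
  # L1-normalized bag vectors have magnitude ~ 1/length; linear models with a
  # fixed regularization level are scale-sensitive, so rescale features to
  # unit mean L2 norm (label-free, deterministic; same factor applied at
  # prediction time)
  rowNorm <- mean(sqrt(rowSums(trainX^2)))
  featScale <- if (rowNorm > 0) 1 / rowNorm else 1
  trainX <- trainX * featScale
  models <- lapply(seq_len(ncol(trainY)), function(t) {
    y <- trainY[, t]
    if (length(unique(y)) < 2L)
      stop(sprintf("term '%s' has a single class in the training set",
                   terms[t]))
    X <- trainX
    if (oversamplePositives) {
      os <- oversample(X, y, seed = deriveSeed(seed, t))
      X <- os$X; y <- os$y
    }
    p <- params
    if (cv) {
      chosen <- selectRegularization(X, y, classifier,
                                     grid = c(0.01, 0.1, 1, 10, 100),
                                     seed = deriveSeed(seed, 1000L + t))
      if (classifier == "linear_svm") p$cost <- chosen else p$lambda <- chosen
    }
    fit <- fitBinary(X, y, classifier, p, deriveSeed(seed, 2000L + t))
    function(newX) fit(newX * featScale)
  })
  names(models) <- terms
  structure(models, class = "ovrModels")
}

#' Evaluate one-vs-rest models on a test set
#'
#' Per-term AUC from the decision scores ([rankAuc()]); binary predictions at
#' decision threshold 0 give F1, sensitivity = TP/(TP+FN) and specificity =
#' TN/(TN+FP). Macro values are unweighted means over the terms; a term
#' missing one class in the test set gets `NA` metrics and is excluded from
#' the macro means with a warning.
#'
#' @param models result of [trainOvr()].
#' @param testX,testY test features and binary labels.
#' @return List with `perTerm` (data.frame: term, auc, f1, sensitivity,
#'   specificity) and `macro` (named numeric vector of the four macro
#'   metrics).
#' @export
evaluateOvr <- function(models, testX, testY) {
  terms <- names(models)
  perTerm <- do.call(rbind, lapply(seq_along(models), function(t) {
    y <- testY[, t]
    if (length(unique(y)) < 2L) {
      warning(sprintf("term '%s' has one class in the test set; metrics undefined",
                      terms[t]))
      return(data.frame(term = terms[t], auc = NA_real_, f1 = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_))
    }
    s <- as.numeric(models[[t]](testX))
    pred <- as.numeric(s > 0)
    tp <- sum(y == 1 & pred == 1); fn <- sum(y == 1 & pred == 0)
    tn <- sum(y == 0 & pred == 0); fp <- sum(y == 0 & pred == 1)
    data.frame(term = terms[t], auc = rankAuc(s, y),
               f1 = binaryF1(y, pred),
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp))
  }))
  macro <- colMeans(perTerm[, c("auc", "f1", "sensitivity", "specificity")],
                    na.rm = TRUE)
  list(perTerm = perTerm, macro = macro)
}

#' Run the split/train/evaluate protocol for one dataset
#'
#' For each partition: fit one-vs-rest models on the training half, evaluate
#' on the test half, collect macro metrics; report mean and SD across
#' partitions.
#'
#' @param dataset an [AnnotationDataset-class] (already term-selected).
#' @param partitions list of train/test splits from [makePartitions()].
#' @param classifier,params,cv,oversamplePositives,seed passed to
#'   [trainOvr()].
#' @return List with `summary` (data.frame: metric, mean, sd), `perPartition`
#'   (partitions x metrics matrix) and `perTerm` (mean per-term metrics).
#' @export
runProtocol <- function(dataset, partitions, classifier = "linear_svm",
                        params = list(), cv = FALSE,
                        oversamplePositives = FALSE, seed = 1L) {
  X <- featureMatrix(dataset); Y <- labelMatrix(dataset)
  res <- lapply(seq_along(partitions), function(p) {
    pt <- partitions[[p]]
    models <- trainOvr(X[pt$train, , drop = FALSE],
                       Y[pt$train, , drop = FALSE],
                       classifier = classifier, params = params, cv = cv,
                       oversamplePositives = oversamplePositives,
                       seed = deriveSeed(seed, p))
    evaluateOvr(models, X[pt$test, , drop = FALSE],
                Y[pt$test, , drop = FALSE])
  })
  M <- do.call(rbind, lapply(res, function(r) r$macro))
  perTermMean <- Reduce(`+`, lapply(res, function(r)
    as.matrix(r$perTerm[, -1]))) / length(res)
  summary <- data.frame(metric = colnames(M),
                        mean = colMeans(M),
                        sd = apply(M, 2, stats::sd),
                        row.names = NULL)
  list(summary = summary, perPartition = M,
       perTerm = data.frame(term = termNames(dataset), perTermMean))
}

#' Run the full annotation experiment
#'
#' End-to-end comparison of representation modes on a labeled group set:
#' build a codebook from sampled descriptors, compute group features for each
#' requested mode, and for each term-count step run the repeated stratified
#' 1:1 split protocol with one-vs-rest classifiers. Partitions are shared
#' across modes so the comparison is paired.
#'
#' @param groupSet a [LabeledGroupSet-class].
#' @param config configuration list; see [defaultConfig()]. Recognized
#'   entries: `radius`, `stride`, `codebookSize`, `sampleFraction`, `lambda`,
#'   `grid`, `modes`, `termCounts` (`NULL` = all terms at once), `partitions`,
#'   `classifier`, `cost`, `cv`, `oversample`, `seed`.
#' @param codebook optional pre-built [VisualCodebook-class]; skips codebook
#'   training.
#' @param verbose print progress messages?
#' @return Data frame with columns `n_terms`, `mode`, `metric`, `mean`, `sd`
#'   (one row per combination), plus attribute `perTerm`.
#' @export
runAnnotationExperiment <- function(groupSet, config = list(),
                                    codebook = NULL, verbose = FALSE) {
  cfg <- utils::modifyList(defaultConfig(), config)
  canvas <- groupSet@canvas
  layout <- makeLayout(canvas[1], canvas[2], cfg$radius, cfg$stride)
  if (is.null(codebook)) {
    if (verbose) message("sampling descriptors and building codebook ...")
    smp <- sampleDescriptors(groupSet, layout, fraction = cfg$sampleFraction,
                             seed = deriveSeed(cfg$seed, 11L))
    codebook <- buildCodebook(smp, c = cfg$codebookSize,
                              seed = deriveSeed(cfg$seed, 12L),
                              nRestarts = cfg$kmeansRestarts)
  }
  if (verbose) message("computing group features ...")
  feats <- groupFeatureMatrices(groupSet, codebook, modes = cfg$modes,
                                grid = cfg$grid, lambda = cfg$lambda,
                                radius = cfg$radius, stride = cfg$stride,
                                verbose = verbose)
  nTermsAvail <- length(termFrequencies(groupSet))
  termCounts <- if (is.null(cfg$termCounts)) nTermsAvail else cfg$termCounts
  rows <- list(); perTerm <- list()
  for (tc in termCounts) {
    base <- selectTerms(makeAnnotationDataset(groupSet, feats[[1]]), tc)
    parts <- makePartitions(base, nPartitions = cfg$partitions,
                            seed = deriveSeed(cfg$seed, 13L + tc))
    for (m in cfg$modes) {
      if (verbose) message(sprintf("protocol: %d terms, mode %s", tc, m))
      ds <- selectTerms(makeAnnotationDataset(groupSet, feats[[m]]), tc)
      pr <- runProtocol(ds, parts, classifier = cfg$classifier,
                        params = list(cost = cfg$cost), cv = cfg$cv,
                        oversamplePositives = cfg$oversample,
                        seed = deriveSeed(cfg$seed, 17L))
      rows[[length(rows) + 1L]] <-
        data.frame(n_terms = tc, mode = m, pr$summary)
      perTerm[[paste(tc, m)]] <- pr$perTerm
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "perTerm") <- perTerm
  out
}

#' Write annotation experiment results as CSV
#'
#' Long-format table with columns
#' `stage_or_dataset,n_terms,mode,metric,mean,sd`.
#'
#' @param results data frame from [runAnnotationExperiment()].
#' @param path output CSV path.
#' @param dataset label for the `stage_or_dataset` column.
#' @return `path`, invisibly.
#' @export
writeAnnotationCsv <- function(results, path, dataset = "synthetic") {
  df <- data.frame(stage_or_dataset = dataset,
                   results[, c("n_terms", "mode", "metric", "mean", "sd")])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
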