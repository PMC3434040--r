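test_that("hard assignment picks the nearest word with low-index ties", {
  cb <- new("VisualCodebook", D = cbind(c(0, 0), c(1, 1)),
            trainingMeta = list())
  expect_equal(hardAssign(c(0.9, 0.9), cb)$index, 2L)
  expect_equal(hardAssign(c(0.9, 0.9), cb)$x, c(0, 1))
  # exactly equidistant -> lowest index
  expect_equal(hardAssign(c(0.5, 0.5), cb)$index, 1L)

  set.seed(30)
  for (i in 1:50) {
    c <- sample(3:12, 1); d <- sample(2:10, 1)
    cb <- randomCodebook(d, c, seed = 100 + i)
    y <- rnorm(d)
    brute <- which.min(vapply(seq_len(c), function(j)
      sum((codebookMatrix(cb)[, j] - y)^2), 1))
    expect_identical(hardAssign(y, cb)$index, brute)
  }
})

test_that("sparse codes hit the analytic limits", {
  # identity dictionary, lambda = 0: exact non-negative reconstruction
  cb <- new("VisualCodebook", D = diag(4) * 1.0, trainingMeta = list())
  y <- c(0.3, 0, 1.2, 0.05)
  fit <- sparseEncode(y, cb, lambda = 0)
  expect_equal(fit$x, y, tolerance = 1e-8)

  # lambda at or above max(D'y) kills every coordinate (KKT threshold)
  set.seed(31)
  for (i in 1:10) {
    cb <- randomCodebook(6, 4, seed = 200 + i)
    y <- rnorm(6)
    lmax <- max(crossprod(codebookMatrix(cb), y))
    fit <- sparseEncode(y, cb, lambda = max(lmax, 0) + 1e-9)
    expect_equal(fit$x, rep(0, 4))
  }
})

test_that("solver objective matches the support-enumeration oracle", {
  set.seed(32)
  worst <- 0
  for (i in 1:100) {
    D <- matrix(rnorm(8 * 5), 8, 5)
    y <- rnorm(8)
    cb <- new("VisualCodebook", D = D, trainingMeta = list())
    for (lam in c(0, 0.01, 0.1)) {
      fit <- sparseEncode(y, cb, lambda = lam)
      ref <- nnlassoOracle(D, y, lam)
      worst <- max(worst, abs(fit$objective - ref))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the L1 norm of the solution is non-increasing along the lambda path", {
  set.seed(33)
  grid <- 10^seq(-4, 1, length.out = 10)
  for (i in 1:20) {
    cb <- randomCodebook(8, 6, seed = 300 + i)
    y <- rnorm(8)
    l1 <- vapply(grid, function(lam) sum(sparseEncode(y, cb, lam)$x), 1)
    expect_true(all(diff(l1) <= 1e-7))
  }
})

test_that("sparse and hard agree on the dominant word for orthonormal dictionaries", {
  set.seed(34)
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
    cb <- new("VisualCodebook", D = Q, trainingMeta = list())
    y <- rnorm(6)
    hard <- hardAssign(y, cb)$index
    xs <- sparseEncode(y, cb, lambda = 1e-6)$x
    if (max(xs) > 0) expect_identical(which.max(xs), hard)
  }
})

test_that("encodeImage carries flags, centers, and beats hard assignment in objective", {
  set.seed(35)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  img[1:33, 1:33] <- 50                       # one flat patch at center (16,16)
  lay <- makeLayout(64, 64)
  ds <- describeImage(img, lay)
  expect_true(zeroFlags(ds)[1])
  cb <- buildCodebook(descriptorMatrix(ds)[!zeroFlags(ds), ], c = 5, seed = 1,
                      nRestarts = 2)

  hard <- encodeImage(ds, cb, mode = "hard")
  live <- !zeroFlags(hard)
  expect_equal(rowSums(codeMatrix(hard))[live], rep(1, sum(live)))
  expect_equal(rowSums(codeMatrix(hard))[!live], rep(0, sum(!live)))
  expect_identical(patchCenters(hard), patchCenters(lay))

  sp <- encodeImage(ds, cb, mode = "sparse", lambda = 0.01)
  support <- rowSums(codeMatrix(sp)[live, , drop = FALSE] > 1e-10)
  expect_gt(mean(support), 1)
  expect_lt(mean(support), numWords(cb))
  # per patch: sparse objective <= hard objective + lambda penalty of the one-hot
  hardPenalized <- hard@objectives[live] + 0.01 * 1
  expect_true(all(sp@objectives[live] <= hardPenalized + 1e-9))

  expect_error(encodeImage(ds, randomCodebook(16, 4), "sparse"),
               "does not match")
})
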