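test_that("cell assignment follows half-open rectangle arithmetic", {
  ctr <- rbind(c(16, 16), c(176, 80), c(32, 0), c(95, 95))
  expect_identical(assignCells(ctr, 192, 96, c(1, 1)), rep(0L, 4))
  # 192x96 with a 3x6 grid: 32x32 cells
  expect_identical(assignCells(rbind(c(16, 16)), 192, 96, c(3, 6)), 0L)
  expect_identical(assignCells(rbind(c(176, 80)), 192, 96, c(3, 6)), 17L)
  # a center exactly on an interior boundary goes to the higher-index cell
  expect_identical(assignCells(rbind(c(32, 0)), 192, 96, c(3, 6)), 1L)
  expect_identical(assignCells(rbind(c(0, 32)), 192, 96, c(3, 6)), 6L)
  expect_error(assignCells(rbind(c(192, 0)), 192, 96, c(3, 6)), "bounds")
})

test_that("remainder pixels are absorbed by the last row and column", {
  # 100x50 on a 3x6 grid: cells 16 px wide, 16 px tall; x in [80,100) is col 5
  expect_identical(assignCells(rbind(c(99, 49)), 100, 50, c(3, 6)), 17L)
  expect_identical(assignCells(rbind(c(96, 48)), 100, 50, c(3, 6)), 17L)
})

test_that("spatial pooling conserves the global bag and patch counts", {
  set.seed(40)
  lay <- makeLayout(192, 96)
  ctr <- patchCenters(lay)
  for (i in 1:5) {
    codes <- matrix(rexp(nrow(ctr) * 7), nrow(ctr), 7)
    pc <- manualCodes(codes, ctr, 192, 96)
    spat <- poolImage(pc, c(3, 6))
    glob <- poolImage(pc, c(1, 1))
    expect_equal(length(bagValues(spat)), 18 * 7)
    blocks <- matrix(bagValues(spat), ncol = 7, byrow = TRUE)
    expect_lt(max(abs(colSums(blocks) - bagValues(glob))), 1e-9)
    # brute-force block check
    cells <- assignCells(ctr, 192, 96, c(3, 6))
    for (b in c(0, 5, 17)) {
      expected <- colSums(codes[cells == b, , drop = FALSE])
      expect_equal(blocks[b + 1, ], expected)
    }
  }
  # hard counts: global bag sums to the number of non-flagged patches (exact)
  onehots <- diag(7)[sample(1:7, nrow(ctr), replace = TRUE), ]
  pch <- manualCodes(onehots, ctr, 192, 96, mode = "hard")
  expect_identical(sum(bagValues(poolImage(pch, c(1, 1)))), as.numeric(nrow(ctr)))
})

test_that("bag vectors are invariant to patch order", {
  set.seed(41)
  lay <- makeLayout(96, 96)
  ctr <- patchCenters(lay)
  codes <- matrix(rexp(nrow(ctr) * 5), nrow(ctr), 5)
  pc <- manualCodes(codes, ctr, 96, 96)
  perm <- sample(nrow(ctr))
  ppc <- new("PatchCodes", codes = codes[perm, ], centers = ctr[perm, ],
             mode = "sparse", lambda = 0.01,
             objectives = numeric(nrow(ctr)),
             zeroFlag = rep(FALSE, nrow(ctr)),
             imageWidth = 96L, imageHeight = 96L)
  expect_equal(bagValues(poolImage(pc, c(3, 6))),
               bagValues(poolImage(ppc, c(3, 6))))
})

test_that("group pooling sums, normalizes and rejects mixed grids", {
  mkbag <- function(v, grid = c(1L, 2L))
    new("BagVector", values = v, grid = grid, J = 3L, level = "image")
  b1 <- mkbag(c(1, 2, 3, 4, 5, 6))
  b2 <- mkbag(c(6, 5, 4, 3, 2, 1))

  single <- poolGroup(list(b1), normalize = FALSE)
  expect_equal(bagValues(single), bagValues(b1))
  expect_identical(single@level, "group")

  # two identical images, normalized: same as one image normalized
  expect_equal(bagValues(poolGroup(list(b1, b1))),
               bagValues(poolGroup(list(b1))))

  expect_equal(bagValues(poolGroup(list(b1, b2), normalize = FALSE)),
               c(7, 7, 7, 7, 7, 7))
  expect_equal(sum(bagValues(poolGroup(list(b1, b2)))), 1)

  b3 <- new("BagVector", values = rep(1, 6), grid = c(2L, 1L), J = 3L,
            level = "image")
  expect_error(poolGroup(list(b1, b3)), "mixed")
  # all-zero group vector is left unnormalized
  z <- mkbag(rep(0, 6))
  expect_equal(bagValues(poolGroup(list(z, z))), rep(0, 6))
})
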