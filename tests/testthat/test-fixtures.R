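test_that("empty term set and zero noise give the bare embryo mask", {
  spec <- syntheticSpec(noiseSd = 0)
  img <- generateImage(spec, character(0))
  expect_setequal(unique(as.numeric(img)), c(0, 60))
  # mask is an ellipse: nonzero pixels bounded by the axis-aligned bounding box
  nz <- which(img > 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 2] - 1 - (192 - 1) / 2) <= 88))
  expect_true(all(abs(nz[, 1] - 1 - (96 - 1) / 2) <= 40))
})

test_that("a 3-stripe pattern yields exactly 3 column-profile maxima", {
  spec <- syntheticSpec(noiseSd = 0)
  img <- generateImage(spec, "stripe_triplet")
  profile <- colSums(img)
  expect_identical(countLocalMaxima(profile), 3L)
})

test_that("noise changes pixels but not the thresholded pattern mask", {
  spec <- syntheticSpec(noiseSd = 8)
  img1 <- generateImage(spec, "dorsal_band", noiseSeed = 11L)
  img2 <- generateImage(spec, "dorsal_band", noiseSeed = 22L)
  expect_false(identical(img1, img2))
  thr <- 60 + 140 / 2
  expect_identical(img1 > thr, img2 > thr)
  # background stays exactly zero outside the mask
  clean <- generateImage(syntheticSpec(noiseSd = 0), "dorsal_band")
  expect_true(all(img1[clean == 0] == 0))
})

test_that("unknown terms are rejected by name", {
  expect_error(generateImage(syntheticSpec(), "no_such_term"), "no_such_term")
})

test_that("group set generation honors prevalence, size and determinism", {
  spec <- syntheticSpec(canvasWidth = 32L, canvasHeight = 32L,
                        embryoAxes = c(14, 14),
                        patterns = list(a = list(kind = "band", center = 0.5,
                                                 width = 0.6)),
                        noiseSd = 0)
  expect_error(generateGroupSet(spec, nGroups = 1), "at least 2 groups")

  gs1 <- generateGroupSet(spec, nGroups = 5, imagesPerGroup = 3,
                          prevalence = 1.0, seed = 2)
  expect_true(all(vapply(groupLabels(gs1), function(l) "a" %in% l, TRUE)))
  expect_true(all(vapply(groupIds(gs1), function(id)
    length(groupImages(gs1, id)), 1L) == 3L))

  gs2 <- generateGroupSet(spec, nGroups = 5, imagesPerGroup = 3,
                          prevalence = 1.0, seed = 2)
  expect_identical(gs1@groups, gs2@groups)
  expect_identical(groupLabels(gs1), groupLabels(gs2))

  # prevalence 0.5 at n = 1000: frequency within 3 binomial SDs of 500
  gs3 <- generateGroupSet(spec, nGroups = 1000, imagesPerGroup = 1,
                          prevalence = 0.5, seed = 3)
  f <- termFrequencies(gs3)[["a"]]
  expect_lt(abs(f - 500), 3 * sqrt(1000 * 0.25))
})

test_that("term frequencies are recountable from the labels", {
  gs <- tinyGroupSet(nGroups = 12, seed = 9)
  f <- termFrequencies(gs)
  recount <- sum(vapply(groupLabels(gs), function(l) "left_half" %in% l, TRUE))
  if (length(f)) expect_identical(unname(f[["left_half"]]), recount)
})

test_that("group sets round-trip through PNG + CSV on disk", {
  gs <- tinyGroupSet(nGroups = 3, imagesPerGroup = 2, seed = 4)
  dir <- withr::local_tempdir()
  writeGroupSet(gs, dir)
  back <- readGroupSet(dir)
  expect_identical(groupIds(back), groupIds(gs))
  expect_identical(groupLabels(back), groupLabels(gs))
  # 8-bit quantization: pixel error at most half a gray level
  for (id in groupIds(gs))
    for (i in seq_along(groupImages(gs, id)))
      expect_lt(max(abs(groupImages(back, id)[[i]] -
                          groupImages(gs, id)[[i]])), 0.5 + 1e-9)
})

test_that("JPEG input is declined with a clear message", {
  tmp <- withr::local_tempfile(fileext = ".jpg")
  writeLines("x", tmp)
  expect_error(flybow:::readImageFile(tmp), "JPEG")
})
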