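test_that("width-averaged sampling reproduces known fields", {
  # constant field is invariant under width averaging
  const <- imageChannel(matrix(7, 20, 20))
  tr <- axisTrace(rbind(c(10, 3), c(10, 16)), widthPx = 5)
  expect_equal(sampleProfile(const, tr), rep(7, 14))

  # single bright pixel picked up only at the position above it
  img <- matrix(0, 12, 12); img[6, 6] <- 10  # (row 5, col 5) 0-based
  ch <- imageChannel(img)
  tr1 <- axisTrace(rbind(c(5, 1), c(5, 10)), widthPx = 1)
  prof <- sampleProfile(ch, tr1)
  expect_equal(prof[5], 10)           # position over column 5
  expect_equal(prof[-5], rep(0, 9))

  # row-gradient field: 5 perpendicular samples at rows 8..12 average to 10
  grad <- imageChannel(matrix(0:19, 20, 20)[, rep(1, 20)])
  trw <- axisTrace(rbind(c(10, 4), c(10, 15)), widthPx = 5)
  expect_equal(sampleProfile(grad, trw), rep(10, 12))
})

test_that("width-1 sampling on a grid-aligned trace equals pixel lookup", {
  set.seed(11)
  img <- matrix(runif(30 * 25, 0, 100), 30, 25)
  ch <- imageChannel(img)
  tr <- axisTrace(rbind(c(7, 2), c(7, 20)), widthPx = 1)
  expect_equal(sampleProfile(ch, tr), img[8, 3:21], tolerance = 1e-12)
})

test_that("sampling is linear in the image", {
  set.seed(12)
  X <- matrix(runif(400, 0, 10), 20, 20)
  Y <- matrix(runif(400, 0, 10), 20, 20)
  tr <- axisTrace(rbind(c(4.3, 3.1), c(9.7, 12.2), c(15.2, 16.8)),
                  widthPx = 3)
  pX <- sampleProfile(imageChannel(X), tr)
  pY <- sampleProfile(imageChannel(Y), tr)
  pMix <- sampleProfile(imageChannel(2.5 * X + 0.5 * Y), tr)
  expect_equal(pMix, 2.5 * pX + 0.5 * pY, tolerance = 1e-12)
})

test_that("rotating image and trace together preserves the profile", {
  set.seed(13)
  img <- matrix(runif(400, 0, 50), 20, 20)
  tr <- axisTrace(rbind(c(8, 3), c(8, 16)), widthPx = 5)
  p1 <- sampleProfile(imageChannel(img), tr)
  # 90-degree rotation: (r, c) -> (c, nrow-1-r)
  rot <- t(img)[, nrow(img):1]
  n <- nrow(img)
  vrot <- cbind(tr@vertices[, 2], n - 1 - tr@vertices[, 1])
  p2 <- sampleProfile(imageChannel(rot), axisTrace(vrot, widthPx = 5))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("invalid traces are rejected", {
  ch <- imageChannel(matrix(1, 10, 10))
  expect_error(axisTrace(rbind(c(5, 1), c(5, 8)), widthPx = 4), "odd")
  near_edge <- axisTrace(rbind(c(1, 2), c(1, 8)), widthPx = 5)
  expect_error(sampleProfile(ch, near_edge), "leaves")
  outside <- axisTrace(rbind(c(5, -3), c(5, 8)), widthPx = 1)
  expect_error(sampleProfile(ch, outside), "leaves")
  expect_error(axisTrace(rbind(c(5, 1), c(5, 1)), widthPx = 1), "distinct")
})

test_that("background is the mean over the union of region pixels", {
  const <- imageChannel(matrix(3, 10, 10))
  m1 <- matrix(FALSE, 10, 10); m1[2:3, 2:3] <- TRUE
  expect_equal(measureBackground(const, list(m1)), 3)

  # two disjoint 2x2 regions of values 1 and 3 average to 2
  img <- matrix(0, 10, 10); img[2:3, 2:3] <- 1; img[6:7, 6:7] <- 3
  m2 <- matrix(FALSE, 10, 10); m2[6:7, 6:7] <- TRUE
  expect_equal(measureBackground(imageChannel(img), list(m1, m2)), 2)

  # overlapping regions: union semantics, no double counting
  img2 <- matrix(0, 10, 10); img2[2:3, 2:3] <- 5
  expect_equal(measureBackground(imageChannel(img2), list(m1, m1)), 5)

  expect_error(backgroundSet(list()), "at least one")
})

test_that("polygon regions rasterize at pixel centers", {
  img <- matrix(0, 12, 12); img[3:6, 3:6] <- 8
  # polygon around the pixel-center block rows/cols 2..5 (0-based)
  poly <- rbind(c(1.5, 1.5), c(1.5, 5.5), c(5.5, 5.5), c(5.5, 1.5))
  expect_equal(measureBackground(imageChannel(img), list(poly)), 8)
  expect_error(
    measureBackground(imageChannel(img),
                      list(rbind(c(-5, -5), c(-5, 20), c(20, 20)))),
    "outside")
})

test_that("background subtraction is elementwise and keeps negatives", {
  expect_equal(subtractBackground(c(5, 6, 7), 5), c(0, 1, 2))
  expect_equal(subtractBackground(c(1, 1), 2), c(-1, -1))
  v <- rnorm(10)
  expect_equal(subtractBackground(v, 0), v)
  expect_error(subtractBackground(c(1, 2), NaN), "finite")
})

test_that("extractProfiles samples all channels on identical geometry", {
  chans <- list(a = imageChannel(matrix(4, 15, 15), "a"),
                b = imageChannel(matrix(9, 15, 15), "b"))
  tr <- axisTrace(rbind(c(7, 3), c(7, 11)), widthPx = 3)
  prof <- extractProfiles(chans, tr, backgrounds = c(a = 4, b = 9))[[1]]
  expect_equal(unname(intensityMatrix(prof)),
               matrix(0, fragmentLength(prof), 2))
  expect_identical(channelNames(prof), c("a", "b"))

  # two traces: results independent of ordering
  tr2 <- axisTrace(rbind(c(3, 3), c(3, 11)), widthPx = 3,
                   fragmentId = "other")
  p12 <- extractProfiles(chans, list(tr, tr2))
  p21 <- extractProfiles(chans, list(tr2, tr))
  expect_equal(intensityMatrix(p12[[1]]), intensityMatrix(p21[[2]]))
  expect_equal(intensityMatrix(p12[[2]]), intensityMatrix(p21[[1]]))
})

test_that("TIFF channels round-trip through the sidecar scale", {
  set.seed(14)
  chans <- list(platform = imageChannel(matrix(runif(100, 0, 800), 10, 10),
                                        "platform"),
                focus = imageChannel(matrix(runif(100, 0, 300), 10, 10),
                                     "focus"))
  path <- tempfile(fileext = ".tif")
  writeImageChannels(chans, path)
  back <- readImageChannels(path)
  expect_identical(names(back), c("platform", "focus"))
  expect_equal(back$platform@pixels, chans$platform@pixels,
               tolerance = 1e-6)
  expect_equal(back$focus@pixels, chans$focus@pixels, tolerance = 1e-6)
})
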