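test_that("channel merge is the per-pixel arithmetic mean", {
  a <- matrix(30, 4, 4); b <- matrix(60, 4, 4); c3 <- matrix(90, 4, 4)
  img <- array(c(a, b, c3), dim = c(4, 4, 3))
  expect_equal(mergeChannels(img), matrix(60, 4, 4))
  same <- array(rep(a, 3), dim = c(4, 4, 3))
  expect_equal(mergeChannels(same), a)
  expect_error(mergeChannels(array(0, dim = c(4, 4, 2))), "3-channel")
  # a cell bright in one channel exceeds background by amplitude / 3
  solo <- array(10, dim = c(4, 4, 3)); solo[2, 2, 1] <- 10 + 90
  expect_equal(mergeChannels(solo)[2, 2] - 10, 30)
})

test_that("Li threshold equals the exhaustive cross-entropy minimizer", {
  # two-point histogram: threshold strictly between the masses, classes pure
  h2 <- integer(256); h2[10 + 1] <- 40; h2[200 + 1] <- 40
  t2 <- liThreshold(h2)
  expect_gt(t2, 10)
  expect_lt(t2, 200)
  expect_identical(t2, liOracle(h2))

  set.seed(421)
  for (i in 1:50) {
    h <- randomHistogram()
    expect_identical(liThreshold(h), liOracle(h))
  }

  # bimodal intensity data: same pixel partition as the oracle threshold
  set.seed(17)
  x <- matrix(pmin(255, pmax(0, round(c(rnorm(4000, 30, 10), rnorm(800, 150, 25))))),
              60, 80)
  t_ex <- liThreshold(x)
  expect_identical(t_ex, liOracle(plangrad:::hist256(x)))
  t_it <- liThreshold(x, method = "iterative")
  expect_identical(x > t_it, x > t_ex)   # both land on the same flat plateau

  expect_error(liThreshold(matrix(5, 3, 3)), "fewer than two")
})

test_that("threshold separates planted cells from background", {
  geom <- testGeometry()
  mask <- makeWormMask(geom, seed = 11)
  cells <- thinNonTouching(sampleCells(mask, 1200, c(3, 5), 1, seed = 11), 1)
  cells[paste0("expr_", c("ndl3", "ptk7", "wntP2"))] <- 100
  fish <- renderFishImage(cells, mask, 1, background_level = 20,
                          blur_sigma_px = 0)
  merged <- mergeChannels(intensityData(fish))
  thr <- liThreshold(merged)
  truth <- merged > 20                       # true cell pixels
  found <- merged > thr
  expect_gte(sum(found & truth) / sum(truth), 0.95)
  expect_lte(sum(found & !truth) / sum(!truth), 0.05)
})

test_that("particle filter keeps in-range disks and drops specks and blobs", {
  img <- matrix(FALSE, 200, 200)
  paint <- function(img, r0, c0, rad) {
    for (r in (r0 - ceiling(rad)):(r0 + ceiling(rad)))
      for (cc in (c0 - ceiling(rad)):(c0 + ceiling(rad)))
        if ((r - r0)^2 + (cc - c0)^2 <= rad^2) img[r, cc] <- TRUE
    img
  }
  img <- paint(img, 50, 50, 11.3)    # ~401 px = ~100 um2 at 0.5 um/px
  img <- paint(img, 50, 150, 3.6)    # ~40 px = ~10 um2, below min
  img <- paint(img, 150, 50, 16)     # ~804 px = ~201 um2, above max
  seg <- segmentParticles(img, SegmentationParams(pixel_size_um = 0.5))
  expect_equal(nrow(seg$particles), 1)
  expect_equal(seg$particles$row, 50, tolerance = 0.001)
  expect_equal(seg$particles$col, 50, tolerance = 0.001)
  expect_lt(abs(seg$particles$area_um2 - 100), 5)
  expect_gt(seg$particles$circularity, 0.85)   # near-perfect disk
  expect_equal(sum(seg$n_discarded), 2)

  # no retained region ever violates the bounds (hard assertion)
  set.seed(99)
  noise <- matrix(runif(200 * 200) < 0.35, 200, 200)
  p <- SegmentationParams(min_area_um2 = 24, max_area_um2 = 166,
                          circularity_range = c(0.3, 1), pixel_size_um = 0.5)
  segn <- segmentParticles(noise, p)
  if (nrow(segn$particles)) {
    expect_true(all(segn$particles$area_um2 >= 24 &
                      segn$particles$area_um2 <= 166))
    expect_true(all(segn$particles$circularity >= 0.3 &
                      segn$particles$circularity <= 1))
  }
})

test_that("connectivity 8 joins diagonal neighbors, connectivity 4 does not", {
  img <- matrix(FALSE, 30, 30)
  img[5:9, 5:9] <- TRUE
  img[10:14, 10:14] <- TRUE                   # touches only diagonally
  p8 <- SegmentationParams(min_area_um2 = 2, max_area_um2 = 500,
                           connectivity = 8L, pixel_size_um = 1)
  p4 <- SegmentationParams(min_area_um2 = 2, max_area_um2 = 500,
                           connectivity = 4L, pixel_size_um = 1)
  expect_equal(nrow(segmentParticles(img, p8)$particles), 1)
  expect_equal(nrow(segmentParticles(img, p4)$particles), 2)
})

test_that("holes are filled before area measurement", {
  img <- matrix(FALSE, 40, 40)
  img[10:20, 10:20] <- TRUE
  img[14:16, 14:16] <- FALSE                 # dim cell center
  p <- SegmentationParams(min_area_um2 = 50, max_area_um2 = 200,
                          pixel_size_um = 1)
  seg <- segmentParticles(img, p)
  expect_equal(seg$particles$area_um2, 121)  # 11 x 11, hole filled
})

test_that("physical scale converts area but leaves circularity alone", {
  img <- matrix(FALSE, 60, 60)
  img[20:40, 20:40] <- TRUE
  p1 <- SegmentationParams(min_area_um2 = 1, max_area_um2 = 1e4,
                           pixel_size_um = 0.5)
  p2 <- SegmentationParams(min_area_um2 = 1, max_area_um2 = 1e4,
                           pixel_size_um = 1)
  s1 <- segmentParticles(img, p1)$particles
  s2 <- segmentParticles(img, p2)$particles
  expect_equal(s2$area_um2, 4 * s1$area_um2)
  expect_equal(s2$circularity, s1$circularity)
})

test_that("cell measurement recovers planted channel means exactly when unblurred", {
  mask <- matrix(TRUE, 80, 80)
  one <- data.frame(cell_id = 1L, row = 40, col = 40, radius_um = 5, u = 0.5,
                    expr_ndl3 = 100, expr_ptk7 = 50, expr_wntP2 = 0)
  fish <- renderFishImage(one, mask, 1, background_level = 0, blur_sigma_px = 0)
  seg <- segmentParticles(mergeChannels(intensityData(fish)) > 10,
                          SegmentationParams(pixel_size_um = 1))
  cells <- measureCells(seg, fish)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$mean_ndl3, 100)
  expect_equal(cells$mean_ptk7, 50)
  expect_equal(cells$mean_wntP2, 0)
  expect_equal(cells$row, 40, tolerance = 0.01)
})

test_that("measured means track planted expression on a default render", {
  geom <- testGeometry()
  w <- suppressMessages(simulateWorm(geom, density = 3000, seed = 31,
                                     wish_genes = character(0)))
  meas <- segmentWorm(w$fish)
  truth <- attr(w$fish, "ground_truth")
  expect_gt(nrow(meas), 20)
  d <- outer(meas$row, truth$row, "-")^2 + outer(meas$col, truth$col, "-")^2
  nn <- apply(d, 1, which.min)
  for (g in c("ndl3", "ptk7", "wntP2"))
    expect_gt(cor(meas[[paste0("mean_", g)]], truth[[paste0("expr_", g)]][nn]),
              0.9)
  # u comes from the body mask's axial extent
  expect_true(all(meas$u >= 0 & meas$u <= 1))
})
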