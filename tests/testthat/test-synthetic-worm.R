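test_that("worm mask is a connected, elongated, seeded ellipse-like shape", {
  geom <- testGeometry()
  m1 <- makeWormMask(geom, seed = 3)
  m2 <- makeWormMask(geom, seed = 3)
  expect_identical(m1, m2)
  expect_false(identical(m1, makeWormMask(geom, seed = 4)))

  lab <- EBImage::bwlabel(EBImage::Image(m1 * 1))
  expect_equal(max(lab), 1)                      # single component
  rows <- which(rowSums(m1) > 0)
  expect_gte(diff(range(rows)) + 1, 0.95 * 300)  # spans nearly all rows

  ellipse <- pi * (300 / 2) * (80 / 2)
  expect_lt(abs(sum(m1) - ellipse) / ellipse, 0.2)

  expect_error(makeWormMask(WormGeometry(2L, 1L, 1)), "degenerate|length")
})

test_that("cell sampling is Poisson-consistent and respects mask and spacing", {
  geom <- testGeometry()
  mask <- makeWormMask(geom, seed = 1)

  expect_equal(nrow(sampleCells(mask, density = 0, seed = 1)), 0)

  density <- 1500
  area_mm2 <- sum(mask) * (1 / 1000)^2
  counts <- vapply(1:100, function(s)
    nrow(sampleCells(mask, density, c(3, 5), 1, seed = s)), numeric(1))
  lambda <- density * area_mm2
  se <- sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), 3 * se)

  cells <- sampleCells(mask, 2000, c(3, 5), 1, seed = 7)
  dist_px <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))))
  centers <- cbind(round(cells$row), round(cells$col))
  expect_true(all(mask[centers]))
  expect_true(all(dist_px[centers] >= cells$radius_um - 1))  # disks inside
  d <- as.matrix(dist(cbind(cells$row, cells$col)))
  diag(d) <- Inf
  expect_gte(min(d), mean(c(3, 5)) - 1e-9)                   # min spacing

  expect_true(all(cells$u >= 0 & cells$u <= 1))
  expect_error(sampleCells(mask, 1e6, c(3, 5), 1, seed = 1, max_tries = 2L),
               "could not place")
})

test_that("rendered single-cell areas follow the disk area formula", {
  mask <- matrix(TRUE, 120, 120)
  cells <- data.frame(cell_id = 1:2, row = c(30, 90), col = c(30, 90),
                      radius_um = c(3, 4), u = c(0.25, 0.75),
                      expr_ndl3 = 100, expr_ptk7 = 100, expr_wntP2 = 100)
  fish <- renderFishImage(cells, mask, pixel_size_um = 0.5,
                          background_level = 0, blur_sigma_px = 0)
  img <- intensityData(fish)[, , 1]
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image((img > 0) * 1))))
  areas_um2 <- sort(tabulate(lab[lab > 0])) * 0.5^2
  expect_equal(length(areas_um2), 2)
  expect_lt(abs(areas_um2[1] - pi * 9) / (pi * 9), 0.15)
  expect_lt(abs(areas_um2[2] - pi * 16) / (pi * 16), 0.15)
})

test_that("expression assignment recovers the model in the noise-free limit", {
  model0 <- GradientModel(sigma_noise = 0)
  cells <- data.frame(u = seq(0, 1, length.out = 21))
  cells <- assignExpression(cells, model0, seed = 1)
  for (g in c("ndl3", "ptk7", "wntP2"))
    expect_equal(cells[[paste0("expr_", g)]], gradientMean(model0, g, cells$u))
  # anterior cells express more ndl3 than posterior cells under defaults
  noisy <- assignExpression(data.frame(u = runif(400)), GradientModel(), seed = 2)
  expect_gt(mean(noisy$expr_ndl3[noisy$u <= 0.1]),
            mean(noisy$expr_ndl3[noisy$u >= 0.9]))
})

test_that("lognormal noise has the right mean and distribution", {
  model <- GradientModel(sigma_noise = 0.3)
  u0 <- 0.5
  n <- 1e4
  cells <- assignExpression(data.frame(u = rep(u0, n)), model, seed = 5)
  for (g in c("ndl3", "ptk7", "wntP2")) {
    mu <- gradientMean(model, g, u0)
    s <- model@sigma_noise
    expected <- mu * exp(s^2 / 2)
    sd_ln <- mu * sqrt((exp(s^2) - 1) * exp(s^2))
    expect_lt(abs(mean(cells[[paste0("expr_", g)]]) - expected),
              3 * sd_ln / sqrt(n))
  }
  # KS on log residuals at fixed u, n = 1e3
  x <- cells$expr_ndl3[1:1000]
  resid <- log(x) - log(gradientMean(model, "ndl3", u0))
  expect_gt(stats::ks.test(resid, "pnorm", 0, 0.3)$p.value, 0.01)
})

test_that("FISH render: background, exact disks, blur-invariant channel sums", {
  mask <- matrix(TRUE, 120, 120)
  none <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                     radius_um = numeric(0), u = numeric(0),
                     expr_ndl3 = numeric(0), expr_ptk7 = numeric(0),
                     expr_wntP2 = numeric(0))
  empty <- renderFishImage(none, mask, 0.5, background_level = 17,
                           blur_sigma_px = 0)
  expect_true(all(intensityData(empty) == 17))

  one <- data.frame(cell_id = 1L, row = 60, col = 60, radius_um = 4, u = 0.5,
                    expr_ndl3 = 100, expr_ptk7 = 50, expr_wntP2 = 0)
  sharp <- renderFishImage(one, mask, 0.5, background_level = 0,
                           blur_sigma_px = 0)
  img <- intensityData(sharp)
  expect_true(all(img[, , 1][img[, , 1] > 0] == 100))
  expect_true(all(img[, , 2][img[, , 2] > 0] == 50))
  expect_true(all(img[, , 3] == 0))
  # ground-truth round trip: mean inside the true disk equals the planted value
  disk <- img[, , 1] > 0
  expect_equal(mean(img[, , 1][disk]), 100)

  blurred <- renderFishImage(one, mask, 0.5, background_level = 10,
                             blur_sigma_px = 2)
  for (k in 1:2)
    expect_lt(abs(sum(intensityData(blurred)[, , k]) -
                    sum(intensityData(renderFishImage(one, mask, 0.5, 10, 0))[, , k])) /
                sum(intensityData(blurred)[, , k]), 0.01)
})

test_that("WISH render is light without expression and darkest where the gradient peaks", {
  geom <- testGeometry()
  mask <- makeWormMask(geom, seed = 2)
  cells <- sampleCells(mask, 6000, c(3, 5), 1, seed = 2)
  zero <- cells
  zero$expr_wntP2 <- 0
  flat <- renderWishImage(zero, mask, "wntP2", 1)
  expect_true(all(intensityData(flat) == 235))

  cells <- assignExpression(cells, GradientModel(), seed = 2)
  wish <- renderWishImage(cells, mask, "wntP2", 1)
  img <- intensityData(wish)
  rows <- which(rowSums(mask) > 0)
  q <- quantile(rows, c(0.25, 0.75))
  ant <- mean(img[rows[rows <= q[1]], ][mask[rows[rows <= q[1]], ]])
  post <- mean(img[rows[rows >= q[2]], ][mask[rows[rows >= q[2]], ]])
  expect_lt(post, ant)          # posterior staining darker
  # inversion flips the ordering: posterior brightest after inversion
  inv <- intensityData(invertImage(wish))
  expect_gt(mean(inv[rows[rows >= q[2]], ]), mean(inv[rows[rows <= q[1]], ]))
})

test_that("simulation is bit-identical under a fixed seed", {
  geom <- testGeometry()
  w1 <- suppressMessages(simulateWorm(geom, seed = 9, wish_genes = "ndl3"))
  w2 <- suppressMessages(simulateWorm(geom, seed = 9, wish_genes = "ndl3"))
  expect_identical(w1$mask, w2$mask)
  expect_identical(w1$cells, w2$cells)
  expect_identical(intensityData(w1$fish), intensityData(w2$fish))
  expect_identical(intensityData(w1$wish$ndl3), intensityData(w2$wish$ndl3))
})
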