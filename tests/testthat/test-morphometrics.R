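test_that("domain length is the normalized axial extent", {
  mask <- matrix(TRUE, 1000, 20)
  dom <- matrix(FALSE, 1000, 20); dom[100:300, ] <- TRUE
  expect_equal(domainLength(mask, dom), 0.2, tolerance = 0.005)
  expect_equal(domainLength(mask, mask), 1)
  expect_warning(z <- domainLength(mask, matrix(FALSE, 1000, 20)), "empty")
  expect_equal(z, 0)
})

test_that("organ position measures from the posterior tip with selectable anchor", {
  mask <- matrix(TRUE, 1000, 20)
  dom <- matrix(FALSE, 1000, 20); dom[740:760, ] <- TRUE   # centroid at row 750
  expect_equal(organPosition(mask, dom, "centroid"), 0.25, tolerance = 0.005)
  expect_equal(organPosition(mask, dom, "anterior_edge"),
               (999 - 739) / 999, tolerance = 0.005)
  expect_gt(organPosition(mask, dom, "anterior_edge"),
            organPosition(mask, dom, "posterior_edge"))

  tip <- matrix(FALSE, 1000, 20); tip[995:1000, ] <- TRUE
  expect_lt(organPosition(mask, tip), 0.01)
  head <- matrix(FALSE, 1000, 20); head[1:6, ] <- TRUE
  expect_gt(organPosition(mask, head), 0.99)
  expect_error(organPosition(mask, matrix(FALSE, 1000, 20)), "empty")
})

test_that("measurements are invariant to translation, scaling and rotation", {
  geom <- testGeometry()
  mask <- makeWormMask(geom, seed = 21)
  dom <- matrix(FALSE, nrow(mask), ncol(mask))
  dom[200:230, 30:50] <- TRUE
  dom <- dom & mask
  len0 <- domainLength(mask, dom)
  pos0 <- organPosition(mask, dom)

  # translation: embed both in a larger canvas with an offset
  big <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m) + 100, ncol(m) + 100)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  expect_equal(domainLength(big(mask, 37, 21), big(dom, 37, 21)), len0,
               tolerance = 1e-9)
  expect_equal(organPosition(big(mask, 37, 21), big(dom, 37, 21)), pos0,
               tolerance = 1e-9)

  # uniform scaling of mask and domain together
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  expect_equal(domainLength(up(mask), up(dom)), len0, tolerance = 0.03)
  expect_equal(organPosition(up(mask), up(dom)), pos0, tolerance = 0.03)

  # the principal axis follows a sideways animal (axis along columns)
  expect_equal(domainLength(t(mask), t(dom)), len0, tolerance = 1e-9)
})

test_that("cell density normalizes count to area", {
  expect_equal(countDensity(50, 2), 25)
  expect_equal(countDensity(0, 3), 0)
  expect_equal(countDensity(100, 4), countDensity(50, 2))
  expect_error(countDensity(10, 0), "positive")
})

test_that("delta-delta-Ct fold changes follow the efficiency-2 model", {
  mk <- function(ct_t, ct_r, group) data.frame(
    sample_id = seq_along(ct_t), group = group,
    ct_target = ct_t, ct_reference = ct_r)
  # treated dCt = calibrator dCt -> fold 1
  rec <- rbind(mk(c(20, 20.2, 19.8), 15, "control"),
               mk(c(22, 22.2, 21.8), 17, "treated"))
  res <- qpcrRelativeAbundance(rec, "control")
  expect_equal(res$fold[res$group == "treated"], 1)
  expect_equal(res$fold[res$group == "control"], 1)   # calibrator == 1 always

  # treated dCt one cycle higher -> fold 0.5
  rec2 <- rbind(mk(c(20, 20.1, 19.9), 15, "control"),
                mk(c(21, 21.1, 20.9), 15, "treated"))
  res2 <- qpcrRelativeAbundance(rec2, "control")
  expect_equal(res2$fold[res2$group == "treated"], 0.5)
  expect_lt(res2$p_value[res2$group == "treated"], 0.05)

  # fold strictly decreasing in the treated mean dCt
  folds <- vapply(c(0, 0.5, 1, 2), function(shift) {
    r <- rbind(mk(c(20, 20.1, 19.9), 15, "control"),
               mk(c(20, 20.1, 19.9) + shift, 15, "treated"))
    q <- qpcrRelativeAbundance(r, "control")
    q$fold[q$group == "treated"]
  }, numeric(1))
  expect_true(all(diff(folds) < 0))

  # identical replicates: degenerate test skipped with a warning
  rec3 <- rbind(mk(rep(20, 3), 15, "control"), mk(rep(20, 3), 15, "treated"))
  expect_warning(res3 <- qpcrRelativeAbundance(rec3, "control"), "zero variance")
  expect_equal(res3$fold[res3$group == "treated"], 1)
  expect_true(is.na(res3$p_value[res3$group == "treated"]))

  # samples missing a reference Ct are excluded
  rec4 <- rbind(mk(c(20, 20.1, 19.9), 15, "control"),
                mk(c(21, 21.1, NA), c(15, 15, NA), "treated"))
  expect_message(res4 <- qpcrRelativeAbundance(rec4, "control"), "excluded 1")
  expect_equal(res4$n[res4$group == "treated"], 2)
})

test_that("a planted posterior domain is recovered at its true position", {
  geom <- WormGeometry(600, 120, 0.5)
  mask <- makeWormMask(geom, seed = 30)
  ar <- range(which(rowSums(mask) > 0))
  # plant a compact domain with centroid a quarter of the way from the tail
  target_row <- ar[2] - 0.25 * diff(ar)
  dom <- matrix(FALSE, nrow(mask), ncol(mask))
  dom[round(target_row) + (-12:12), ] <- TRUE
  dom <- dom & mask
  # round-trip through a label image on disk, as in a real measurement
  tf <- tempfile(fileext = ".png")
  writeWormImage(dom * 255, tf)
  dom2 <- readMask(tf)
  expect_equal(organPosition(mask, dom2, "centroid"), 0.25, tolerance = 0.02)
})
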