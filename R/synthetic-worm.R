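# Synthetic worm generator: seeded worm-shaped masks, subepidermal cell
# fields with graded expression, and WISH-/FISH-like renders with per-cell
# ground truth. Everything downstream of this module is testable against the
# planted truth without any external data.

#' Mean expression of a gradient gene at a normalized axial position
#'
#' @param object a \code{\linkS4class{GradientModel}}.
#' @param gene one of \code{"ndl3"}, \code{"ptk7"}, \code{"wntP2"}.
#' @param u numeric vector of normalized axial positions in \code{[0, 1]}.
#' @return Numeric vector of mean intensities (8-bit scale).
#' @examples
#' gradientMean(GradientModel(), "ndl3", c(0, 0.5, 1))
#' @rdname plangrad-generics
#' @export
setMethod("gradientMean", "GradientModel", function(object, gene, u) {
  gene <- match.arg(gene, c("ndl3", "ptk7", "wntP2"))
  stopifnot(all(u >= 0 & u <= 1))
  b <- object@baseline[gene]; a <- object@amplitude[gene]
  switch(gene,
    ndl3  = b + a * exp(-u / object@lambda_a),
    ptk7  = b + a * exp(-(u - object@u_peak)^2 / (2 * object@sigma_p^2)),
    wntP2 = b + a * exp(-(1 - u) / object@lambda_p))
})

#' Generate a worm-shaped body mask
#'
#' Builds an elongated, tip-tapered body mask: a superellipse-like
#' half-width profile along the axial (row) direction with a small, seeded
#' smooth modulation of the outline so that repeated animals differ the way
#' real specimens do. The default taper exponent (0.35) gives the blunt
#' head and tail tips of a planarian rather than the sharp points of a pure
#' ellipse (exponent 0.5); the enclosed area stays within a few percent of
#' the ellipse of the same axes. The mask is a single connected component.
#'
#' @param geometry a \code{\linkS4class{WormGeometry}}.
#' @param seed integer seed; the same seed yields a bit-identical mask.
#' @param wobble relative amplitude of the smooth outline modulation
#'   (default 0.05; 0 gives the unperturbed outline).
#' @param taper_exponent exponent of the half-width profile
#'   \code{(4 v (1 - v))^p}; smaller is blunter (default 0.35).
#' @return Logical matrix \code{length_px x width_px}, TRUE inside the body.
#' @examples
#' m <- makeWormMask(WormGeometry(300, 80, 1), seed = 1)
#' sum(m) / (pi * 150 * 40)  # close to the ellipse area
#' @export
makeWormMask <- function(geometry, seed = 1L, wobble = 0.05,
                         taper_exponent = 0.35) {
  stopifnot(is(geometry, "WormGeometry"))
  validObject(geometry)
  L <- geometry@length_px; W <- geometry@width_px
  if (L <= 2L) stop("degenerate geometry: length_px must exceed 2 px")
  withSeed(deriveSeed(seed, 1L), {
    v <- (seq_len(L) - 0.5) / L                 # axial position in (0, 1)
    half <- (W / 2 - 1) * pmax(0, 4 * v * (1 - v))^taper_exponent
    if (wobble > 0) {
      ph <- runif(3, 0, 2 * pi); am <- runif(3, 0, wobble)
      mod <- 1 + am[1] * sin(2 * pi * v + ph[1]) +
        am[2] * sin(4 * pi * v + ph[2]) + am[3] * sin(6 * pi * v + ph[3])
      half <- half * mod
    }
    half <- pmax(half, ifelse(v > 1.5 / L & v < 1 - 1.5 / L, 1, 0))
    center <- (W + 1) / 2
    cols <- matrix(seq_len(W), nrow = L, ncol = W, byrow = TRUE)
    mask <- abs(cols - center) <= half
    mask
  })
}

#' Sample a field of subepidermal cells inside a body mask
#'
#' Cell count is Poisson with mean \code{density} times the mask area in
#' square millimeters. Radii are uniform over \code{radius_range_um}.
#' Centers are rejection-sampled so every disk lies fully inside the mask
#' and centers keep a minimum spacing of one mean radius; overlap of disks
#' is otherwise permitted. Each cell receives its normalized axial position
#' \code{u} from the mask's axial bounding box.
#'
#' @param mask logical body mask.
#' @param density cells per square millimeter (>= 0).
#' @param radius_range_um numeric length 2, cell radius interval in microns.
#' @param pixel_size_um microns per pixel.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per requested cell (default
#'   200); exceeding it aborts with an error (density unachievable under the
#'   spacing constraint).
#' @return A \code{data.frame} (the cell field) with columns \code{cell_id},
#'   \code{row}, \code{col} (continuous pixel coordinates), \code{radius_um},
#'   \code{u}.
#' @examples
#' m <- makeWormMask(WormGeometry(300, 80, 1), seed = 1)
#' cells <- sampleCells(m, density = 2000, radius_range_um = c(3, 5),
#'                      pixel_size_um = 1, seed = 2)
#' head(cells)
#' @export
sampleCells <- function(mask, density, radius_range_um = c(3, 5),
                        pixel_size_um = 0.5, seed = 1L, max_tries = 200L) {
  stopifnot(density >= 0, length(radius_range_um) == 2L,
            radius_range_um[1] > 0, diff(radius_range_um) >= 0)
  empty <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                      radius_um = numeric(0), u = numeric(0))
  if (density == 0 || !any(mask)) return(empty)
  area_mm2 <- sum(mask) * (pixel_size_um / 1000)^2
  # distance (px) from every in-mask pixel to the nearest background pixel
  dist_px <- EBImage::distmap(EBImage::Image(mask * 1))
  dist_px <- as.matrix(EBImage::imageData(dist_px))
  idx_in <- which(mask)
  nr <- nrow(mask)
  withSeed(deriveSeed(seed, 2L), {
    n <- rpois(1L, density * area_mm2)
    if (n == 0L) return(empty)
    min_space_px <- mean(radius_range_um) / pixel_size_um
    rows <- cols <- rad <- numeric(n)
    accepted <- 0L
    tries <- 0L
    budget <- max_tries * n
    while (accepted < n) {
      tries <- tries + 1L
      if (tries > budget)
        stop("sampleCells: could not place ", n, " cells after ", budget,
             " tries; density too high for the spacing constraint")
      r_um <- runif(1L, radius_range_um[1], radius_range_um[2])
      r_px <- r_um / pixel_size_um
      pix <- idx_in[sample.int(length(idx_in), 1L)]
      prow <- ((pix - 1L) %% nr) + 1L
      pcol <- ((pix - 1L) %/% nr) + 1L
      crow <- prow + runif(1L, -0.5, 0.5)
      ccol <- pcol + runif(1L, -0.5, 0.5)
      if (dist_px[prow, pcol] < r_px + 1) next     # disk would leave the mask
      if (accepted > 0L) {
        d2 <- (rows[seq_len(accepted)] - crow)^2 + (cols[seq_len(accepted)] - ccol)^2
        if (min(d2) < min_space_px^2) next
      }
      accepted <- accepted + 1L
      rows[accepted] <- crow; cols[accepted] <- ccol; rad[accepted] <- r_um
    }
    data.frame(cell_id = seq_len(n), row = rows, col = cols, radius_um = rad,
               u = rowToU(rows, mask))
  })
}

#' Assign graded expression to a cell field
#'
#' Per cell and gene, true expression is the model mean at the cell's axial
#' position times an independent multiplicative lognormal noise factor:
#' \code{mu_g(u) * exp(N(0, sigma_noise))}.
#'
#' @param cells cell field from \code{\link{sampleCells}} (needs \code{u}).
#' @param model a \code{\linkS4class{GradientModel}}.
#' @param seed integer seed.
#' @return The cell field with columns \code{expr_ndl3}, \code{expr_ptk7},
#'   \code{expr_wntP2} appended.
#' @export
assignExpression <- function(cells, model = GradientModel(), seed = 1L) {
  stopifnot(is(model, "GradientModel"), "u" %in% names(cells))
  n <- nrow(cells)
  withSeed(deriveSeed(seed, 3L), {
    for (g in c("ndl3", "ptk7", "wntP2")) {
      mu <- gradientMean(model, g, cells$u)
      noise <- if (model@sigma_noise > 0)
        rlnorm(n, meanlog = 0, sdlog = model@sigma_noise) else rep(1, n)
      cells[[paste0("expr_", g)]] <- mu * noise
    }
  })
  cells
}

# Paint additive disks onto a zero canvas; returns the canvas.
paintDisks <- function(nr, nc, rows, cols, radii_px, values) {
  canvas <- matrix(0, nr, nc)
  for (i in seq_along(rows)) {
    r <- radii_px[i]
    r0 <- max(1L, floor(rows[i] - r)); r1 <- min(nr, ceiling(rows[i] + r))
    c0 <- max(1L, floor(cols[i] - r)); c1 <- min(nc, ceiling(cols[i] + r))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - rows[i])^2, (cc - cols[i])^2, "+")
    disk <- d2 <= r^2
    canvas[rr, cc] <- canvas[rr, cc] + disk * values[i]
  }
  canvas
}

#' Render a triple-FISH-like three-channel image
#'
#' Each cell is painted as a disk of its per-gene expression intensity added
#' over a uniform background, then each channel is Gaussian-blurred.
#' Intensities above 255 are clipped (count reported via the
#' \code{n_clipped} attribute and a message). The returned ground-truth
#' table carries every cell with its planted expression and its true
#' eight-state class under the stated cutoff.
#'
#' @param cells cell field with expression columns
#'   (\code{\link{assignExpression}}).
#' @param mask logical body mask.
#' @param pixel_size_um microns per pixel.
#' @param background_level uniform background intensity (default 20).
#' @param blur_sigma_px Gaussian blur sigma in pixels (default 1; 0 skips).
#' @param cutoff hi/lo cutoff used for the truth table's class labels
#'   (default 55).
#' @return A \code{\linkS4class{WormImage}} (channels ndl3, ptk7, wntP2)
#'   with attribute \code{ground_truth} (the cell table incl. true class)
#'   and \code{n_clipped}.
#' @export
renderFishImage <- function(cells, mask, pixel_size_um = 0.5,
                            background_level = 20, blur_sigma_px = 1,
                            cutoff = 55) {
  nr <- nrow(mask); nc <- ncol(mask)
  genes <- c("ndl3", "ptk7", "wntP2")
  img <- array(background_level, dim = c(nr, nc, 3L))
  if (nrow(cells)) {
    rad_px <- cells$radius_um / pixel_size_um
    for (k in seq_along(genes)) {
      ch <- paintDisks(nr, nc, cells$row, cells$col, rad_px,
                       cells[[paste0("expr_", genes[k])]])
      img[, , k] <- img[, , k] + ch
    }
  }
  n_clipped <- sum(img > 255)
  if (n_clipped > 0)
    message("renderFishImage: clipped ", n_clipped, " pixel values to 255")
  img <- clip8(img)
  if (blur_sigma_px > 0)
    for (k in 1:3)
      img[, , k] <- gaussianBlur(img[, , k], blur_sigma_px)
  truth <- cells
  if (nrow(cells)) {
    tc <- cells
    names(tc)[names(tc) == "expr_ndl3"] <- "mean_ndl3"
    names(tc)[names(tc) == "expr_ptk7"] <- "mean_ptk7"
    names(tc)[names(tc) == "expr_wntP2"] <- "mean_wntP2"
    truth$true_class <- classifyCells(tc, ClassificationParams(cutoff = cutoff))$class
  } else truth$true_class <- integer(0)
  wi <- WormImage(img, mask, pixel_size_um, genes)
  attr(wi, "ground_truth") <- truth
  attr(wi, "n_clipped") <- n_clipped
  wi
}

#' Render a colorimetric WISH-like grayscale image
#'
#' Emulates NBT/BCIP staining viewed on a light background: staining
#' darkness is proportional to local expression of one gene, so that
#' downstream inversion yields intensity proportional to expression. The
#' stain of each cell spreads somewhat beyond the cell body
#' (\code{stain_scale} times the cell radius) and the darkness field is
#' Gaussian-blurred, reproducing the diffuse look of colorimetric stains at
#' dissecting-scope magnification.
#'
#' @param cells cell field with expression columns.
#' @param mask logical body mask.
#' @param gene gene to stain for.
#' @param pixel_size_um microns per pixel.
#' @param darkness_gain darkness per expression unit (default 0.7, chosen
#'   so peak staining uses most of the 8-bit range without saturating).
#' @param background_level light background intensity (default 235).
#' @param blur_sigma_px blur sigma of the darkness field in pixels
#'   (default 20).
#' @param stain_scale stain radius as a multiple of cell radius (default 2).
#' @return A grayscale \code{\linkS4class{WormImage}} (raw render: dark =
#'   high expression).
#' @export
renderWishImage <- function(cells, mask, gene, pixel_size_um = 0.5,
                            darkness_gain = 0.7, background_level = 235,
                            blur_sigma_px = 20, stain_scale = 2) {
  gene <- match.arg(gene, c("ndl3", "ptk7", "wntP2"))
  nr <- nrow(mask); nc <- ncol(mask)
  dark <- matrix(0, nr, nc)
  if (nrow(cells)) {
    rad_px <- cells$radius_um * stain_scale / pixel_size_um
    dark <- paintDisks(nr, nc, cells$row, cells$col, rad_px,
                       darkness_gain * cells[[paste0("expr_", gene)]])
  }
  if (blur_sigma_px > 0 && any(dark > 0))
    dark <- gaussianBlur(dark, blur_sigma_px)
  img <- clip8(background_level - dark)
  WormImage(img, mask, pixel_size_um, "gray")
}

#' Thin a cell field to pairwise non-touching disks
#'
#' Greedily keeps cells (in sampling order) whose disks stay at least
#' \code{margin_px} pixels away from every previously kept disk. Used to
#' build segmentation stress fixtures in which every rendered cell is an
#' isolated particle; the default sampler deliberately allows touching and
#' overlapping disks.
#'
#' @param cells cell field from \code{\link{sampleCells}}.
#' @param pixel_size_um microns per pixel.
#' @param margin_px minimum gap between disk boundaries, pixels (default 2).
#' @return The subset of \code{cells} that is pairwise non-touching.
#' @export
thinNonTouching <- function(cells, pixel_size_um = 0.5, margin_px = 2) {
  n <- nrow(cells)
  if (n < 2L) return(cells)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (any(keep)) {
      j <- which(keep)
      d <- sqrt((cells$row[j] - cells$row[i])^2 + (cells$col[j] - cells$col[i])^2)
      ok <- all(d > (cells$radius_um[j] + cells$radius_um[i]) / pixel_size_um +
                  margin_px)
    }
    keep[i] <- ok
  }
  cells[keep, , drop = FALSE]
}

#' One-call synthetic animal
#'
#' Convenience wrapper: mask, cell field, expression, FISH render and (per
#' gene) WISH renders for one seeded animal under the stated conditions.
#'
#' @param geometry a \code{\linkS4class{WormGeometry}}.
#' @param model a \code{\linkS4class{GradientModel}}.
#' @param density cells per square millimeter (default 10000: with the
#'   default 28-79 um2 cell cross-sections this covers about half the
#'   projected body area, the confluent look of a subepidermal layer in a
#'   maximum projection).
#' @param radius_range_um cell radius interval in microns (default 3-5 um,
#'   cross-sections 28-79 um2).
#' @param seed integer seed.
#' @param wish_genes genes to render as WISH images (default all three).
#' @param ... further arguments to \code{\link{renderFishImage}}.
#' @return A list with elements \code{mask}, \code{cells}, \code{fish}
#'   (WormImage + ground truth), \code{wish} (named list of WormImages).
#' @export
simulateWorm <- function(geometry = WormGeometry(), model = GradientModel(),
                         density = 10000, radius_range_um = c(3, 5),
                         seed = 1L, wish_genes = c("ndl3", "ptk7", "wntP2"),
                         ...) {
  px <- pixelSize(geometry)
  mask <- makeWormMask(geometry, seed = seed)
  cells <- sampleCells(mask, density, radius_range_um, px, seed = seed)
  cells <- assignExpression(cells, model, seed = seed)
  fish <- renderFishImage(cells, mask, px, ...)
  wish <- lapply(setNames(wish_genes, wish_genes), function(g)
    renderWishImage(cells, mask, g, px))
  list(mask = mask, cells = cells, fish = fish, wish = wish)
}
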