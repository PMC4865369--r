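# Triple-FISH cell identification: channel merge, minimum cross-entropy
# (Li) auto-thresholding, connected-component particle filtering on physical
# area and circularity, and per-cell multichannel intensity measurement.

#' Merge three FISH channels into one grayscale image
#'
#' Per-pixel arithmetic mean of the three channels; keeps the result in the
#' original dynamic range and treats the genes symmetrically. The merged
#' image defines one set of candidate cell regions for all channels.
#'
#' @param image row x col x 3 numeric array or 3-channel
#'   \code{\linkS4class{WormImage}}.
#' @return Numeric matrix (or grayscale \code{WormImage} if one was given).
#' @export
mergeChannels <- function(image) {
  if (is(image, "WormImage")) {
    out <- mergeChannels(intensityData(image))
    return(WormImage(out, bodyMask(image), pixelSize(image), "gray"))
  }
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("mergeChannels: a 3-channel image is required")
  (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
}

# Li cross-entropy criterion for every candidate threshold t = 0..254
# (classes g <= t vs g > t), computed via cumulative sums. Candidates that
# leave either class empty score Inf.
liCriterion <- function(h) {
  stopifnot(length(h) == 256L)
  g <- 0:255
  hg <- h * g
  n0 <- cumsum(h)[1:255]; s0 <- cumsum(hg)[1:255]
  n1 <- sum(h) - n0; s1 <- sum(hg) - s0
  m0 <- ifelse(n0 > 0, s0 / n0, 0)
  m1 <- ifelse(n1 > 0, s1 / n1, 0)
  e <- ifelse(s0 > 0, -s0 * log(m0), 0) + ifelse(s1 > 0, -s1 * log(m1), 0)
  e[n0 == 0 | n1 == 0] <- Inf
  e
}

# Pinned tie rule: the criterion is flat across unoccupied grey levels, so
# the minimum usually sits on a plateau; return the midpoint (floor) of the
# contiguous plateau (relative tolerance rtol) containing the argmin.
liPlateauMid <- function(e, rtol = 1e-12) {
  t_star <- which.min(e)
  tol <- rtol * max(1, abs(e[t_star]))
  lo <- t_star
  while (lo > 1L && is.finite(e[lo - 1L]) && abs(e[lo - 1L] - e[t_star]) <= tol)
    lo <- lo - 1L
  hi <- t_star
  while (hi < length(e) && is.finite(e[hi + 1L]) &&
         abs(e[hi + 1L] - e[t_star]) <= tol)
    hi <- hi + 1L
  as.integer(floor((lo + hi) / 2)) - 1L     # back to grey-level coordinates
}

#' Minimum cross-entropy (Li) automatic threshold
#'
#' Chooses the threshold minimizing Li & Lee's cross-entropy criterion
#' \deqn{\eta(t) = -\sum_{g \le t} h(g)\, g \ln \mu_0(t)
#'               -\sum_{g > t} h(g)\, g \ln \mu_1(t)}
#' where \eqn{\mu_0, \mu_1} are the below-/above-threshold mean intensities.
#' Pixels with intensity strictly above the returned threshold are
#' foreground.
#'
#' The default method evaluates the criterion exactly at every candidate
#' threshold (cumulative-sum formulation, O(256)) and returns the global
#' minimizer. The criterion is flat across unoccupied grey levels, so the
#' minimum generally sits on a plateau; the pinned tie rule returns the
#' midpoint of the contiguous tied plateau around the argmin (for a
#' two-point histogram this lands strictly between the two masses, with
#' both classes pure). \code{method = "iterative"} runs the classical
#' Li-Tam fixed-point iteration \eqn{t \gets (\mu_0 - \mu_1) /
#' (\ln\mu_0 - \ln\mu_1)} from the image mean and snaps to the best nearby
#' candidate; it is faster on deep-bit-depth data but can stall in a local
#' minimum of the discrete criterion, so the exact search is the default.
#'
#' @param x numeric image (matrix/array, 8-bit scale) or a length-256
#'   histogram of counts for grey levels 0..255.
#' @param method \code{"exact"} (default) or \code{"iterative"}.
#' @return Integer threshold in \code{0..254}.
#' @examples
#' h <- integer(256); h[11] <- 50; h[201] <- 50   # masses at 10 and 200
#' liThreshold(h)
#' @export
liThreshold <- function(x, method = c("exact", "iterative")) {
  method <- match.arg(method)
  h <- if (length(x) == 256L && is.null(dim(x)) && all(x >= 0) &&
           all(x == round(x))) as.numeric(x) else hist256(x)
  occ <- which(h > 0) - 1L
  if (length(occ) < 2L)
    stop("liThreshold: histogram has fewer than two occupied grey levels; ",
         "no threshold separates anything")
  e <- liCriterion(h)
  if (method == "exact") {
    return(liPlateauMid(e))
  }
  cand <- occ[-length(occ)]            # occupied levels with nonempty upper class
  g <- 0:255
  t <- sum(h * g) / sum(h)
  for (i in 1:256) {
    lo <- g <= t
    n0 <- sum(h[lo]); n1 <- sum(h[!lo])
    if (n0 == 0 || n1 == 0) break
    m0 <- sum(h[lo] * g[lo]) / n0
    m1 <- sum(h[!lo] * g[!lo]) / n1
    if (m0 <= 0 || m1 <= 0) break
    tn <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(tn - t) < 1e-6) { t <- tn; break }
    t <- tn
  }
  near <- cand[order(abs(cand - t))][1:min(3L, length(cand))]
  near[which.min(e[near + 1L])]
}

#' Segment particles from a binary mask
#'
#' Connected components (8-connectivity by default) of the binary
#' foreground, holes filled before measurement, then filtered to the
#' physical area window and circularity range of the parameters. Circularity
#' is \code{4 * pi * A / P^2} with the weighted-boundary perimeter
#' estimator, clipped to \code{[0, 1]}.
#'
#' @param binary logical or 0/1 matrix of foreground pixels.
#' @param params a \code{\linkS4class{SegmentationParams}}.
#' @return A list: \code{labels} (integer matrix, surviving particles
#'   renumbered 1..k), \code{particles} (data.frame with \code{label},
#'   \code{area_um2}, \code{circularity}, \code{row}, \code{col}), and
#'   \code{n_discarded} (named counts of regions removed by each filter).
#' @export
segmentParticles <- function(binary, params = SegmentationParams()) {
  stopifnot(is(params, "SegmentationParams"))
  validObject(params)
  bin <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  labels <- EBImage::bwlabel(EBImage::Image(bin))
  labels <- as.matrix(EBImage::imageData(labels))
  storage.mode(labels) <- "integer"
  if (params@connectivity == 8L) labels <- merge8Connectivity(labels)
  labels <- as.matrix(EBImage::imageData(
    EBImage::fillHull(EBImage::Image(labels))))
  storage.mode(labels) <- "integer"
  k <- max(labels)
  if (k == 0L)
    return(list(labels = labels,
                particles = data.frame(label = integer(0), area_um2 = numeric(0),
                                       circularity = numeric(0), row = numeric(0),
                                       col = numeric(0)),
                n_discarded = c(area = 0L, circularity = 0L)))
  px2 <- params@pixel_size_um^2
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  area_px <- tabulate(lab, k)
  crow <- as.numeric(rowsum(rows, lab)) / area_px
  ccol <- as.numeric(rowsum(cols, lab)) / area_px
  perim <- vapply(seq_len(k), function(l) {
    sel <- lab == l
    r <- range(rows[sel]); c <- range(cols[sel])
    sub <- matrix(0L, r[2] - r[1] + 1L, c[2] - c[1] + 1L)
    sub[cbind(rows[sel] - r[1] + 1L, cols[sel] - c[1] + 1L)] <- 1L
    regionPerimeter(sub)
  }, numeric(1))
  circ <- pmin(1, pmax(0, 4 * pi * area_px / pmax(perim, 1e-12)^2))
  area_um2 <- area_px * px2
  ok_area <- area_um2 >= params@min_area_um2 & area_um2 <= params@max_area_um2
  ok_circ <- circ >= params@circularity_range[1] &
    circ <= params@circularity_range[2]
  keep <- which(ok_area & ok_circ)
  n_discarded <- c(area = sum(!ok_area),
                   circularity = sum(ok_area & !ok_circ))
  list(labels = compactLabels(labels, keep),
       particles = data.frame(label = seq_along(keep),
                              area_um2 = area_um2[keep],
                              circularity = circ[keep],
                              row = crow[keep], col = ccol[keep]),
       n_discarded = n_discarded)
}

#' Measure per-cell channel intensities
#'
#' For each surviving particle, the mean intensity of every channel over the
#' particle's member pixels, the centroid, and the normalized axial position
#' \code{u} of the centroid from the body mask's axial bounding box.
#' Particles whose centroid falls outside the body mask are excluded (count
#' reported in the \code{n_outside_mask} attribute).
#'
#' @param seg result of \code{\link{segmentParticles}}.
#' @param image 3-channel array or \code{\linkS4class{WormImage}} (the
#'   unblurred or blurred FISH render being quantified).
#' @param mask logical body mask (taken from the image if a
#'   \code{WormImage}).
#' @return \code{data.frame} of segmented cells: \code{cell_id}, \code{row},
#'   \code{col}, \code{u}, \code{area_um2}, \code{circularity},
#'   \code{mean_ndl3}, \code{mean_ptk7}, \code{mean_wntP2}.
#' @export
measureCells <- function(seg, image, mask = NULL) {
  if (is(image, "WormImage")) {
    if (is.null(mask)) mask <- bodyMask(image)
    image <- intensityData(image)
  }
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  labels <- seg$labels
  part <- seg$particles
  genes <- c("ndl3", "ptk7", "wntP2")
  if (!nrow(part)) {
    out <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                      u = numeric(0), area_um2 = numeric(0),
                      circularity = numeric(0))
    for (g in genes) out[[paste0("mean_", g)]] <- numeric(0)
    attr(out, "n_outside_mask") <- 0L
    return(out)
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  k <- nrow(part)
  npx <- tabulate(lab, k)
  means <- vapply(1:3, function(ch) {
    v <- image[, , ch][idx]
    as.numeric(rowsum(v, lab)) / npx
  }, numeric(k))
  means <- matrix(means, nrow = k, ncol = 3L)
  inside <- if (is.null(mask)) rep(TRUE, k) else
    mask[cbind(pmin(nrow(mask), pmax(1L, round(part$row))),
               pmin(ncol(mask), pmax(1L, round(part$col))))]
  n_out <- sum(!inside)
  if (n_out > 0)
    message("measureCells: excluded ", n_out,
            " particle(s) with centroid outside the body mask")
  u <- if (is.null(mask)) rep(NA_real_, k) else rowToU(part$row, mask)
  out <- data.frame(cell_id = seq_len(sum(inside)),
                    row = part$row[inside], col = part$col[inside],
                    u = u[inside], area_um2 = part$area_um2[inside],
                    circularity = part$circularity[inside])
  for (ch in 1:3) out[[paste0("mean_", genes[ch])]] <- means[inside, ch]
  attr(out, "n_outside_mask") <- n_out
  out
}

#' Segment and measure a FISH image in one call
#'
#' Merge channels, Li-threshold the merge, segment particles under the
#' parameter filters, and measure per-cell channel means.
#'
#' @param image 3-channel \code{\linkS4class{WormImage}}.
#' @param params a \code{\linkS4class{SegmentationParams}}; its pixel size
#'   defaults to the image's.
#' @return The cell table of \code{\link{measureCells}}, with the threshold
#'   used in attribute \code{threshold}.
#' @export
segmentWorm <- function(image, params = NULL) {
  stopifnot(is(image, "WormImage"))
  if (is.null(params)) params <- SegmentationParams(pixel_size_um = pixelSize(image))
  merged <- mergeChannels(intensityData(image))
  thr <- liThreshold(merged)
  seg <- segmentParticles(merged > thr, params)
  cells <- measureCells(seg, image)
  attr(cells, "threshold") <- thr
  attr(cells, "n_discarded") <- seg$n_discarded
  cells
}
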