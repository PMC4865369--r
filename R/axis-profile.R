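# Colorimetric gradient quantification: inverted-image lateral intensity
# profiles, normalized in position and intensity, binned into 100 axial bins
# and aggregated across animals.

#' Invert an image within its dynamic range
#'
#' \code{out = range_max - in}, pixelwise. Colorimetric stains are dark
#' where expression is high; inversion makes intensity proportional to
#' expression before profiling.
#'
#' @param image numeric matrix/array or a \code{\linkS4class{WormImage}}.
#' @param range_max top of the dynamic range (default 255).
#' @return Same type as the input.
#' @examples
#' invertImage(matrix(0, 2, 2))[1, 1]  # 255
#' @export
invertImage <- function(image, range_max = 255) {
  if (is(image, "WormImage")) {
    out <- image
    out@img <- range_max - image@img
    return(out)
  }
  range_max - image
}

#' Default lateral profile path for a synthetic worm
#'
#' The hand-drawn lateral line of the bench procedure is replaced by a
#' deterministic surrogate: the mask midline offset laterally by a quarter
#' of the local body width, sampled every \code{step} rows over the mask's
#' axial extent. The strip width defaults to one sixth of the maximal body
#' width.
#'
#' @param mask logical body mask.
#' @param offset_frac lateral offset as a fraction of local width
#'   (default 0.25).
#' @param step row step between polyline vertices (default 5).
#' @param strip_width_px strip width in pixels; default
#'   \code{round(max body width / 6)}.
#' @param side \code{"left"} or \code{"right"} of the midline (equivalent by
#'   symmetry; default right).
#' @return A list of class fields: \code{points} (n x 2 matrix of row, col)
#'   and \code{strip_width_px}.
#' @export
lateralPath <- function(mask, offset_frac = 0.25, step = 5L,
                        strip_width_px = NULL, side = c("right", "left")) {
  side <- match.arg(side)
  rows <- which(rowSums(mask) > 0)
  widths <- rowSums(mask)
  if (is.null(strip_width_px))
    strip_width_px <- max(1L, round(max(widths) / 6))
  use <- rows[seq(1L, length(rows), by = step)]
  if (use[length(use)] != rows[length(rows)]) use <- c(use, rows[length(rows)])
  pts <- t(vapply(use, function(r) {
    cc <- which(mask[r, ])
    mid <- mean(range(cc))
    off <- offset_frac * length(cc) * (if (side == "right") 1 else -1)
    col <- mid + off
    col <- min(max(col, min(cc) + 0.5), max(cc) - 0.5)
    c(r, col)
  }, numeric(2)))
  list(points = pts, strip_width_px = as.integer(strip_width_px))
}

#' Extract a raw intensity profile along a polyline
#'
#' Walks the polyline in unit arc-length steps; at each step the profile
#' value is the mean intensity over a perpendicular strip of
#' \code{strip_width_px} pixels (nearest-pixel sampling, no interpolation).
#' Arc positions are normalized to \code{[0, 1]} by the total path length.
#' Strip pixels falling outside the image, or outside the body mask when one
#' is given, are excluded (with a one-time warning for masked exclusions).
#'
#' @param image numeric matrix or grayscale \code{\linkS4class{WormImage}}.
#' @param path a path as returned by \code{\link{lateralPath}}, or an n x 2
#'   matrix of (row, col) vertices.
#' @param strip_width_px strip width, overriding the path's own (optional).
#' @param mask optional logical mask restricting sampling.
#' @return \code{data.frame} with columns \code{position} (normalized arc
#'   position) and \code{intensity}.
#' @export
extractRawProfile <- function(image, path, strip_width_px = NULL, mask = NULL) {
  if (is(image, "WormImage")) {
    if (is.null(mask)) mask <- bodyMask(image)
    image <- intensityData(image)
  }
  if (length(dim(image)) == 3L) stop("profile extraction needs a grayscale image")
  image <- as.matrix(image)
  if (is.matrix(path)) path <- list(points = path, strip_width_px = 1L)
  pts <- path$points
  if (is.null(strip_width_px)) strip_width_px <- path$strip_width_px
  stopifnot(nrow(pts) >= 2L, strip_width_px >= 1L)
  # resample polyline at unit arc steps
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  cum <- c(0, cumsum(seg_len))
  s <- seq(0, total, by = 1)
  rowf <- approx(cum, pts[, 1], xout = s, rule = 2)$y
  colf <- approx(cum, pts[, 2], xout = s, rule = 2)$y
  # per-step tangent (central differences), perpendicular unit vector
  dr <- c(diff(rowf)[1], diff(rowf))
  dc <- c(diff(colf)[1], diff(colf))
  nrm <- pmax(sqrt(dr^2 + dc^2), 1e-12)
  pr <- -dc / nrm; pc <- dr / nrm
  offs <- seq_len(strip_width_px) - (strip_width_px + 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  masked_out <- FALSE
  vals <- vapply(seq_along(s), function(i) {
    rr <- round(rowf[i] + offs * pr[i])
    cc <- round(colf[i] + offs * pc[i])
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    if (!is.null(mask) && length(rr)) {
      inm <- mask[cbind(rr, cc)]
      if (any(!inm)) masked_out <<- TRUE
      rr <- rr[inm]; cc <- cc[inm]
    }
    if (!length(rr)) return(NA_real_)
    mean(image[cbind(rr, cc)])
  }, numeric(1))
  if (masked_out)
    warning("extractRawProfile: strip pixels outside the body mask were excluded")
  data.frame(position = s / total, intensity = vals)
}

#' Normalize and bin a raw profile
#'
#' The per-animal background — the minimum intensity along the profile — is
#' subtracted first; the result is then divided by its maximum, so the
#' normalized profile spans exactly \code{[0, 1]}. Values are resampled into
#' \code{n_bins} equal position bins (half-open \code{[k/n, (k+1)/n)}, last
#' bin closed) by averaging the samples in each bin; empty bins are filled
#' by linear interpolation from their neighbors. A constant profile has no
#' contrast to normalize and yields all zeros with a warning.
#'
#' @param raw \code{data.frame} from \code{\link{extractRawProfile}}.
#' @param n_bins number of position bins (default 100).
#' @return An \code{\linkS4class{IntensityProfile}}.
#' @examples
#' raw <- data.frame(position = c(0, 1/3, 2/3, 1), intensity = c(2, 4, 6, 8))
#' profileBins(normalizeProfile(raw, n_bins = 4))
#' @export
normalizeProfile <- function(raw, n_bins = 100L) {
  stopifnot(nrow(raw) >= 1L, all(c("position", "intensity") %in% names(raw)))
  v <- raw$intensity
  pos <- raw$position
  keep <- is.finite(v)
  v <- v[keep]; pos <- pos[keep]
  if (!length(v)) stop("normalizeProfile: no finite samples")
  v <- v - min(v)
  mx <- max(v)
  if (mx == 0) {
    warning("normalizeProfile: constant profile, returning all zeros")
    return(new("IntensityProfile", bins = rep(0, n_bins),
               n_bins = as.integer(n_bins), normalized = TRUE))
  }
  v <- v / mx
  bin <- pmin(floor(pos * n_bins) + 1L, n_bins)
  sums <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
  bins <- as.numeric(sums)
  if (anyNA(bins)) {
    filled <- which(!is.na(bins))
    bins <- approx(filled, bins[filled], xout = seq_len(n_bins), rule = 2)$y
  }
  new("IntensityProfile", bins = bins, n_bins = as.integer(n_bins),
      normalized = TRUE)
}

#' Aggregate normalized profiles across animals
#'
#' Per-bin sample mean and standard deviation (n - 1 denominator) across
#' animals, as used to summarize 4-6 stained animals per probe.
#'
#' @param profiles list of \code{\linkS4class{IntensityProfile}} objects
#'   with matching bin counts.
#' @return An \code{\linkS4class{AggregateProfile}}.
#' @export
aggregateProfiles <- function(profiles) {
  if (!length(profiles)) stop("aggregateProfiles: empty profile list")
  stopifnot(all(vapply(profiles, is, logical(1), "IntensityProfile")))
  nb <- vapply(profiles, function(p) p@n_bins, integer(1))
  if (length(unique(nb)) != 1L)
    stop("aggregateProfiles: profiles must share the bin count")
  m <- do.call(rbind, lapply(profiles, profileBins))
  mu <- colMeans(m)
  s <- if (nrow(m) > 1L) apply(m, 2, sd) else rep(0, ncol(m))
  new("AggregateProfile", mean = mu, sd = s, n_animals = nrow(m))
}

#' Full colorimetric profile pipeline for one rendered animal
#'
#' Convenience composition of the bench procedure on a raw WISH render:
#' invert, extract the lateral strip profile, normalize and bin.
#'
#' @param wish a grayscale \code{\linkS4class{WormImage}} (raw render, dark
#'   = high expression).
#' @param n_bins number of axial bins (default 100).
#' @param ... passed to \code{\link{lateralPath}}.
#' @return An \code{\linkS4class{IntensityProfile}}.
#' @export
profileWorm <- function(wish, n_bins = 100L, ...) {
  stopifnot(is(wish, "WormImage"))
  inv <- invertImage(wish)
  path <- lateralPath(bodyMask(wish), ...)
  raw <- extractRawProfile(inv, path)
  normalizeProfile(raw, n_bins = n_bins)
}
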