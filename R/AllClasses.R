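#' Worm image geometry
#'
#' Describes the raster geometry of a synthetic worm: image extent in pixels
#' and the physical pixel size. The anteroposterior axis runs along image
#' rows, anterior at row 1.
#'
#' @slot length_px integer, axial extent in pixels (image rows).
#' @slot width_px integer, mediolateral extent in pixels (image columns).
#' @slot pixel_size_um positive numeric, microns per pixel.
#'
#' @examples
#' g <- WormGeometry(length_px = 600, width_px = 120, pixel_size_um = 0.5)
#' g
#' @name WormGeometry-class
#' @aliases WormGeometry-class
#' @exportClass WormGeometry
setClass("WormGeometry",
  representation(length_px = "integer", width_px = "integer",
                 pixel_size_um = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@length_px) != 1L || length(object@width_px) != 1L ||
        length(object@pixel_size_um) != 1L)
      msg <- c(msg, "all slots must be scalars")
    else {
      if (!(object@length_px > object@width_px && object@width_px > 0L))
        msg <- c(msg, "need length_px > width_px > 0")
      if (!(object@pixel_size_um > 0)) msg <- c(msg, "pixel_size_um must be > 0")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @param length_px,width_px image extent in pixels (rows, columns).
#' @param pixel_size_um microns per pixel.
#' @return A \code{WormGeometry} object.
#' @rdname WormGeometry-class
#' @export
WormGeometry <- function(length_px = 1000L, width_px = 200L,
                         pixel_size_um = 0.5) {
  new("WormGeometry", length_px = as.integer(length_px),
      width_px = as.integer(width_px), pixel_size_um = as.numeric(pixel_size_um))
}

#' Parametric anteroposterior expression gradients
#'
#' Mean expression per gene as a function of normalized axial position
#' \code{u} in \code{[0, 1]} (0 = anterior tip, 1 = posterior tip):
#' \describe{
#'   \item{ndl3}{\code{baseline + amplitude * exp(-u / lambda_a)} — graded
#'     from the anterior.}
#'   \item{ptk7}{\code{baseline + amplitude * exp(-(u - u_peak)^2 /
#'     (2 * sigma_p^2))} — unimodal, peaked in the trunk.}
#'   \item{wntP2}{\code{baseline + amplitude * exp(-(1 - u) / lambda_p)} —
#'     graded from the posterior.}
#' }
#' Per-cell noise is multiplicative lognormal with log-scale standard
#' deviation \code{sigma_noise}.
#'
#' @slot baseline,amplitude named numeric vectors (ndl3, ptk7, wntP2), in
#'   8-bit intensity units.
#' @slot lambda_a,lambda_p decay lengths of the anterior/posterior
#'   exponentials, in units of normalized position.
#' @slot u_peak,sigma_p center and width of the ptk7 Gaussian.
#' @slot sigma_noise lognormal log-scale sd of the per-cell noise.
#'
#' @examples
#' m <- GradientModel()
#' gradientMean(m, "ptk7", c(0, 0.45, 1))
#' @name GradientModel-class
#' @exportClass GradientModel
setClass("GradientModel",
  representation(baseline = "numeric", amplitude = "numeric",
                 lambda_a = "numeric", u_peak = "numeric", sigma_p = "numeric",
                 lambda_p = "numeric", sigma_noise = "numeric"),
  validity = function(object) {
    msg <- NULL
    gn <- c("ndl3", "ptk7", "wntP2")
    if (!identical(names(object@baseline), gn) ||
        !identical(names(object@amplitude), gn))
      msg <- c(msg, "baseline and amplitude must be named ndl3, ptk7, wntP2")
    if (any(object@baseline < 0) || any(object@amplitude < 0))
      msg <- c(msg, "baseline and amplitude must be nonnegative")
    if (object@lambda_a <= 0 || object@lambda_p <= 0 || object@sigma_p <= 0)
      msg <- c(msg, "decay lengths and sigma_p must be positive")
    if (object@u_peak <= 0 || object@u_peak >= 1)
      msg <- c(msg, "u_peak must lie strictly inside (0, 1)")
    if (object@sigma_noise < 0) msg <- c(msg, "sigma_noise must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param baseline,amplitude numeric, recycled to the three genes or named
#'   vectors (ndl3, ptk7, wntP2).
#' @param lambda_a,u_peak,sigma_p,lambda_p,sigma_noise shape parameters, see
#'   slots.
#' @return A \code{GradientModel} object.
#' @rdname GradientModel-class
#' @export
GradientModel <- function(baseline = 20, amplitude = 120, lambda_a = 0.25,
                          u_peak = 0.45, sigma_p = 0.18, lambda_p = 0.25,
                          sigma_noise = 0.3) {
  gn <- c("ndl3", "ptk7", "wntP2")
  bl <- rep_len(as.numeric(baseline), 3L); names(bl) <- gn
  am <- rep_len(as.numeric(amplitude), 3L); names(am) <- gn
  if (!is.null(names(baseline))) bl[names(baseline)] <- baseline
  if (!is.null(names(amplitude))) am[names(amplitude)] <- amplitude
  new("GradientModel", baseline = bl, amplitude = am,
      lambda_a = lambda_a, u_peak = u_peak, sigma_p = sigma_p,
      lambda_p = lambda_p, sigma_noise = sigma_noise)
}

#' A worm raster image with body mask and physical scale
#'
#' The unit of all image operations: a single- or three-channel 8-bit scale
#' intensity array, a logical body mask of the same spatial extent, and the
#' pixel size in microns. Channels, when present, are named after the genes
#' they report (ndl3, ptk7, wntP2).
#'
#' @slot img numeric matrix (rows x cols) or array (rows x cols x 3) on the
#'   \code{[0, 255]} scale.
#' @slot mask logical matrix, TRUE inside the animal.
#' @slot pixel_size_um positive numeric, microns per pixel.
#' @slot channels character, per-channel gene names (or "gray").
#'
#' @name WormImage-class
#' @exportClass WormImage
setClass("WormImage",
  representation(img = "array", mask = "matrix", pixel_size_um = "numeric",
                 channels = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@img)
    if (!length(d) %in% c(2L, 3L)) msg <- c(msg, "img must be 2-D or 3-D")
    if (!identical(d[1:2], dim(object@mask)))
      msg <- c(msg, "mask extent must match img")
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    nc <- if (length(d) == 3L) d[3L] else 1L
    if (length(object@channels) != nc)
      msg <- c(msg, "one channel name per image channel")
    if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param img,mask,pixel_size_um,channels see slots.
#' @return A \code{WormImage} object.
#' @rdname WormImage-class
#' @export
WormImage <- function(img, mask, pixel_size_um, channels = NULL) {
  img <- as.array(img)
  if (is.null(channels))
    channels <- if (length(dim(img)) == 3L) c("ndl3", "ptk7", "wntP2") else "gray"
  new("WormImage", img = img, mask = mask,
      pixel_size_um = as.numeric(pixel_size_um), channels = channels)
}

#' Per-animal normalized axial intensity profile
#'
#' Intensity resampled into 100 equal bins of normalized axial position.
#' When \code{normalized} is TRUE the per-animal minimum was subtracted and
#' the result divided by its maximum, so the bin values span \code{[0, 1]}
#' (all zero for a degenerate constant profile).
#'
#' @slot bins numeric vector of length \code{n_bins}.
#' @slot n_bins integer, number of axial bins (100).
#' @slot normalized logical.
#'
#' @name IntensityProfile-class
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(bins = "numeric", n_bins = "integer", normalized = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@bins) != object@n_bins)
      msg <- c(msg, "bins length must equal n_bins")
    if (object@normalized && length(object@bins)) {
      b <- object@bins
      if (any(!is.finite(b))) msg <- c(msg, "bins must be finite")
      else if (!(all(b >= -1e-9) && (max(b) <= 1 + 1e-9)))
        msg <- c(msg, "normalized bins must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Cross-animal aggregate of normalized profiles
#'
#' Per-bin sample mean and standard deviation (n - 1 denominator) of
#' normalized intensity profiles across animals.
#'
#' @slot mean,sd numeric vectors, one value per axial bin.
#' @slot n_animals integer, number of profiles aggregated.
#'
#' @name AggregateProfile-class
#' @exportClass AggregateProfile
setClass("AggregateProfile",
  representation(mean = "numeric", sd = "numeric", n_animals = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@mean) != length(object@sd))
      msg <- c(msg, "mean and sd must have equal length")
    if (object@n_animals < 1L) msg <- c(msg, "n_animals must be >= 1")
    if (object@n_animals == 1L && any(object@sd != 0))
      msg <- c(msg, "sd must be 0 when n_animals == 1")
    if (is.null(msg)) TRUE else msg
  })

#' Particle-segmentation parameters
#'
#' Filters applied to connected components of the thresholded merged image:
#' physical area window (default 24-166 square microns, the subepidermal
#' cell cross-section range) and circularity window (default the permissive
#' \code{[0, 1]}).
#'
#' @slot min_area_um2,max_area_um2 area window in square microns.
#' @slot circularity_range numeric length 2, within \code{[0, 1]}.
#' @slot connectivity integer, 4 or 8 (default 8).
#' @slot pixel_size_um microns per pixel.
#'
#' @name SegmentationParams-class
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(min_area_um2 = "numeric", max_area_um2 = "numeric",
                 circularity_range = "numeric", connectivity = "integer",
                 pixel_size_um = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@min_area_um2 > 0 && object@min_area_um2 < object@max_area_um2))
      msg <- c(msg, "need 0 < min_area_um2 < max_area_um2")
    cr <- object@circularity_range
    if (length(cr) != 2L || cr[1] > cr[2] || cr[1] < 0 || cr[2] > 1)
      msg <- c(msg, "circularity_range must be an interval inside [0, 1]")
    if (!object@connectivity %in% c(4L, 8L))
      msg <- c(msg, "connectivity must be 4 or 8")
    if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param min_area_um2,max_area_um2,circularity_range,connectivity,pixel_size_um
#'   see slots.
#' @return A \code{SegmentationParams} object.
#' @rdname SegmentationParams-class
#' @export
SegmentationParams <- function(min_area_um2 = 24, max_area_um2 = 166,
                               circularity_range = c(0, 1),
                               connectivity = 8L, pixel_size_um = 0.5) {
  new("SegmentationParams", min_area_um2 = min_area_um2,
      max_area_um2 = max_area_um2, circularity_range = circularity_range,
      connectivity = as.integer(connectivity),
      pixel_size_um = as.numeric(pixel_size_um))
}

#' High/low classification parameters
#'
#' A single intensity cutoff (default 55, in 8-bit arbitrary units) applied
#' to all three channel means, a cutoff sweep range (default 30-75, 10
#' steps) for robustness checks, and the number of axial regions (default
#' 8). A cell is "hi" for a gene iff its mean intensity is >= the cutoff.
#'
#' @slot cutoff numeric intensity cutoff.
#' @slot sweep_range numeric length 2.
#' @slot sweep_count integer, number of sweep cutoffs (>= 2).
#' @slot n_regions integer, number of axial regions.
#'
#' @name ClassificationParams-class
#' @exportClass ClassificationParams
setClass("ClassificationParams",
  representation(cutoff = "numeric", sweep_range = "numeric",
                 sweep_count = "integer", n_regions = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@cutoff < 0 || object@cutoff > 255)
      msg <- c(msg, "cutoff must lie in the 8-bit dynamic range")
    if (length(object@sweep_range) != 2L ||
        object@sweep_range[1] > object@sweep_range[2])
      msg <- c(msg, "sweep_range must be an increasing interval")
    if (object@sweep_count < 2L) msg <- c(msg, "sweep_count must be >= 2")
    if (object@n_regions < 1L) msg <- c(msg, "n_regions must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @param cutoff,sweep_range,sweep_count,n_regions see slots.
#' @return A \code{ClassificationParams} object.
#' @rdname ClassificationParams-class
#' @export
ClassificationParams <- function(cutoff = 55, sweep_range = c(30, 75),
                                 sweep_count = 10L, n_regions = 8L) {
  new("ClassificationParams", cutoff = as.numeric(cutoff),
      sweep_range = as.numeric(sweep_range),
      sweep_count = as.integer(sweep_count), n_regions = as.integer(n_regions))
}
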