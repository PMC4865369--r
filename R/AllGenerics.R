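#' @name plangrad-generics
#' @title Accessor generics
#' @description Accessors for the plangrad S4 classes. Slot access via
#'   \code{@} is discouraged; use these instead.
#' @param object a plangrad S4 object.
#' @param gene one of \code{"ndl3"}, \code{"ptk7"}, \code{"wntP2"}.
#' @param u numeric vector of normalized axial positions in \code{[0, 1]}.
#' @return \code{gradientMean}: numeric vector of mean intensities;
#'   \code{intensityData}: the raw intensity array; \code{bodyMask}: logical
#'   matrix; \code{pixelSize}: microns per pixel; \code{channelNames}:
#'   character vector; \code{profileBins}: numeric vector of bin values.
NULL

#' @rdname plangrad-generics
#' @export
setGeneric("gradientMean", function(object, gene, u)
  standardGeneric("gradientMean"))

#' @rdname plangrad-generics
#' @export
setGeneric("intensityData", function(object) standardGeneric("intensityData"))

#' @rdname plangrad-generics
#' @export
setGeneric("bodyMask", function(object) standardGeneric("bodyMask"))

#' @rdname plangrad-generics
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname plangrad-generics
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname plangrad-generics
#' @export
setGeneric("profileBins", function(object) standardGeneric("profileBins"))

#' @rdname plangrad-generics
#' @export
setMethod("intensityData", "WormImage", function(object) object@img)

#' @rdname plangrad-generics
#' @export
setMethod("bodyMask", "WormImage", function(object) object@mask)

#' @rdname plangrad-generics
#' @export
setMethod("pixelSize", "WormImage", function(object) object@pixel_size_um)

#' @rdname plangrad-generics
#' @export
setMethod("pixelSize", "WormGeometry", function(object) object@pixel_size_um)

#' @rdname plangrad-generics
#' @export
setMethod("channelNames", "WormImage", function(object) object@channels)

#' @rdname plangrad-generics
#' @export
setMethod("profileBins", "IntensityProfile", function(object) object@bins)

#' @rdname plangrad-generics
#' @export
setMethod("profileBins", "AggregateProfile", function(object) object@mean)

setMethod("show", "WormGeometry", function(object) {
  cat("WormGeometry:", object@length_px, "x", object@width_px, "px,",
      object@pixel_size_um, "um/px (axis along rows, anterior at row 1)\n")
})

setMethod("show", "GradientModel", function(object) {
  cat("GradientModel (mean intensity over normalized axis u):\n")
  cat(sprintf("  ndl3 : %g + %g * exp(-u / %g)            [anterior-decaying]\n",
              object@baseline["ndl3"], object@amplitude["ndl3"], object@lambda_a))
  cat(sprintf("  ptk7 : %g + %g * exp(-(u - %g)^2 / (2 * %g^2)) [trunk-peaked]\n",
              object@baseline["ptk7"], object@amplitude["ptk7"],
              object@u_peak, object@sigma_p))
  cat(sprintf("  wntP2: %g + %g * exp(-(1 - u) / %g)        [posterior-rising]\n",
              object@baseline["wntP2"], object@amplitude["wntP2"], object@lambda_p))
  cat(sprintf("  multiplicative lognormal noise, sdlog = %g\n", object@sigma_noise))
})

setMethod("show", "WormImage", function(object) {
  d <- dim(object@img)
  nc <- if (length(d) == 3L) d[3L] else 1L
  cat(sprintf("WormImage: %d x %d px, %d channel(s) [%s], %g um/px, %d mask px\n",
              d[1L], d[2L], nc, paste(object@channels, collapse = ", "),
              object@pixel_size_um, sum(object@mask)))
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d bins, %snormalized, range [%.3g, %.3g]\n",
              object@n_bins, if (object@normalized) "" else "not ",
              min(object@bins), max(object@bins)))
})

setMethod("show", "AggregateProfile", function(object) {
  cat(sprintf("AggregateProfile: %d bins, n = %d animals, argmax bin %d\n",
              length(object@mean), object@n_animals, which.max(object@mean)))
})

#' Plot an aggregate axial profile
#'
#' Mean normalized intensity per axial bin with a +/- 1 SD ribbon.
#'
#' @param x an \code{\linkS4class{AggregateProfile}}.
#' @param y ignored.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
setMethod("plot", signature(x = "AggregateProfile", y = "missing"),
  function(x, y, ...) {
    nb <- length(x@mean)
    pos <- (seq_len(nb) - 0.5) / nb
    graphics::plot(pos, x@mean, type = "n", ylim = c(0, 1.05),
                   xlab = "normalized axial position (anterior -> posterior)",
                   ylab = "normalized intensity", ...)
    graphics::polygon(c(pos, rev(pos)),
                      c(pmin(1, x@mean + x@sd), rev(pmax(0, x@mean - x@sd))),
                      col = "grey85", border = NA)
    graphics::lines(pos, x@mean, lwd = 2)
    invisible(x)
  })
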