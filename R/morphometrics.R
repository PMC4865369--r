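# Organ-position and domain-size measurements on body masks with labeled
# expression domains, plus the delta-delta-Ct qPCR computation.

# Axial coordinates of mask (and optionally domain) pixels: projection onto
# the mask's principal axis, sign-aligned with increasing image row so the
# anterior (row 1) end maps to the low end. Synthetic worms are axis-aligned
# and reduce to the row coordinate.
axialProjection <- function(mask, domain = NULL) {
  idx <- which(mask)
  if (!length(idx)) stop("empty body mask")
  nr <- nrow(mask)
  pr <- ((idx - 1L) %% nr) + 1L
  pc <- ((idx - 1L) %/% nr) + 1L
  ctr <- c(mean(pr), mean(pc))
  xy <- cbind(pr - ctr[1], pc - ctr[2])
  cv <- crossprod(xy) / nrow(xy)
  ev <- eigen(cv, symmetric = TRUE)
  ax <- ev$vectors[, 1]
  if (ax[1] < 0) ax <- -ax          # anterior (low rows) -> low projection
  proj_mask <- xy %*% ax
  out <- list(mask = as.numeric(proj_mask),
              anterior = min(proj_mask), posterior = max(proj_mask))
  if (!is.null(domain)) {
    di <- which(domain)
    if (length(di)) {
      dr <- ((di - 1L) %% nr) + 1L
      dc <- ((di - 1L) %/% nr) + 1L
      out$domain <- as.numeric(cbind(dr - ctr[1], dc - ctr[2]) %*% ax)
    } else out$domain <- numeric(0)
  }
  out
}

#' Normalized axial length of an expression domain
#'
#' Axial extent (posterior edge minus anterior edge, along the animal's
#' principal axis) of the domain, divided by the animal's axial length.
#' Invariant to translation and to uniform scaling of mask and domain
#' together.
#'
#' @param mask logical body mask.
#' @param domain logical matrix of domain pixels (same extent as
#'   \code{mask}).
#' @return Normalized length in \code{[0, 1]}; an empty domain returns 0
#'   with a warning.
#' @examples
#' m <- matrix(TRUE, 1000, 20)
#' d <- matrix(FALSE, 1000, 20); d[100:300, ] <- TRUE
#' domainLength(m, d)  # ~0.2
#' @export
domainLength <- function(mask, domain) {
  stopifnot(identical(dim(mask), dim(domain)))
  ax <- axialProjection(mask, domain)
  if (!length(ax$domain)) {
    warning("domainLength: empty domain")
    return(0)
  }
  L <- ax$posterior - ax$anterior
  if (L <= 0) stop("degenerate mask: zero axial extent")
  (max(ax$domain) - min(ax$domain)) / L
}

#' Normalized organ position from the posterior tip
#'
#' Axial distance from the posterior tip of the animal to the chosen domain
#' anchor (centroid or anterior/posterior edge), divided by the animal's
#' axial length: 0 = at the posterior tip, 1 = at the anterior tip.
#'
#' @param mask logical body mask.
#' @param domain logical matrix of domain pixels.
#' @param anchor \code{"centroid"} (default, used for pharynx position),
#'   \code{"anterior_edge"} or \code{"posterior_edge"} (used for expression
#'   domain boundary measurements).
#' @return Normalized position in \code{[0, 1]}.
#' @export
organPosition <- function(mask, domain,
                          anchor = c("centroid", "anterior_edge",
                                     "posterior_edge")) {
  anchor <- match.arg(anchor)
  stopifnot(identical(dim(mask), dim(domain)))
  ax <- axialProjection(mask, domain)
  if (!length(ax$domain)) stop("organPosition: empty domain")
  L <- ax$posterior - ax$anterior
  if (L <= 0) stop("degenerate mask: zero axial extent")
  pos <- switch(anchor,
                centroid = mean(ax$domain),
                anterior_edge = min(ax$domain),
                posterior_edge = max(ax$domain))
  min(1, max(0, (ax$posterior - pos) / L))
}

#' Cell density normalized to animal area
#'
#' @param n_cells nonnegative cell count.
#' @param animal_area area in square millimeters (> 0).
#' @return Cells per square millimeter.
#' @examples
#' countDensity(50, 2)  # 25
#' @export
countDensity <- function(n_cells, animal_area) {
  stopifnot(n_cells >= 0)
  if (any(animal_area <= 0)) stop("countDensity: area must be positive")
  n_cells / animal_area
}

#' Relative RNA abundance by the delta-delta-Ct method
#'
#' Per sample, \code{dCt = ct_target - ct_reference}; per group,
#' \code{ddCt = mean dCt(group) - mean dCt(calibrator)} and fold change
#' \code{2^(-ddCt)} (amplification efficiency 2, assumed verified). Groups
#' are compared to the calibrator by a two-tailed t-test on the per-sample
#' dCt values; degenerate zero-variance comparisons are skipped with a
#' warning. Samples lacking either Ct value are excluded with a message.
#'
#' @param records \code{data.frame} with columns \code{sample_id},
#'   \code{group}, \code{ct_target}, \code{ct_reference}.
#' @param calibrator_group group name used as calibrator (fold = 1 by
#'   construction).
#' @return \code{data.frame}: per group \code{n}, \code{mean_dct},
#'   \code{sd_dct}, \code{ddct}, \code{fold}, \code{p_value} (NA for the
#'   calibrator or skipped tests).
#' @examples
#' rec <- data.frame(sample_id = 1:6,
#'                   group = rep(c("control", "treated"), each = 3),
#'                   ct_target = c(20, 20.1, 19.9, 21, 21.1, 20.9),
#'                   ct_reference = rep(15, 6))
#' qpcrRelativeAbundance(rec, "control")  # treated fold ~ 0.5
#' @export
qpcrRelativeAbundance <- function(records, calibrator_group) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(records)))
  drop <- !is.finite(records$ct_target) | !is.finite(records$ct_reference)
  if (any(drop)) {
    message("qpcrRelativeAbundance: excluded ", sum(drop),
            " sample(s) with missing Ct values")
    records <- records[!drop, ]
  }
  if (any(records$ct_target <= 0) || any(records$ct_reference <= 0))
    stop("qpcrRelativeAbundance: Ct values must be positive")
  if (!calibrator_group %in% records$group)
    stop("qpcrRelativeAbundance: calibrator group not present")
  records$dct <- records$ct_target - records$ct_reference
  groups <- unique(records$group)
  cal <- records$dct[records$group == calibrator_group]
  res <- lapply(groups, function(g) {
    x <- records$dct[records$group == g]
    ddct <- mean(x) - mean(cal)
    p <- NA_real_
    if (g != calibrator_group) {
      if (sd(x) == 0 && sd(cal) == 0) {
        warning("qpcrRelativeAbundance: zero variance in both groups; ",
                "t-test skipped for group '", g, "'")
      } else {
        p <- t.test(x, cal, var.equal = FALSE)$p.value
      }
    }
    data.frame(group = g, n = length(x), mean_dct = mean(x),
               sd_dct = if (length(x) > 1) sd(x) else 0,
               ddct = ddct, fold = 2^(-ddct), p_value = p)
  })
  do.call(rbind, res)
}
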