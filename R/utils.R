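# Shared internal helpers: seeded streams, mask axial coordinates, the
# weighted-boundary perimeter estimator and 8-connectivity label merging.

# Derive a per-stage seed from the top-level seed; stays inside 32-bit range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Axial bounding rows of a body mask: u = 0 at the first mask row (anterior),
# u = 1 at the last.
maskAxialRange <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  if (!length(rows)) stop("empty body mask")
  c(min(rows), max(rows))
}

# Normalized axial position of row coordinates over the mask's axial extent.
rowToU <- function(row, mask) {
  ar <- maskAxialRange(mask)
  if (ar[2] == ar[1]) return(rep(0, length(row)))
  pmin(1, pmax(0, (row - ar[1]) / (ar[2] - ar[1])))
}

# Pad a logical/integer matrix with a zero border.
padZero <- function(m) {
  out <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out
}

# Weighted-boundary perimeter of a single binary region. Border pixels
# (foreground pixels 4-adjacent to background) are weighted by their local
# border configuration: isolated steps count 1, diagonal steps sqrt(2),
# corner pixels (1 + sqrt(2)) / 2. Matches the standard weighted estimator
# used by particle-analysis tools; unbiased enough that a rasterized disk
# scores circularity near 1.
regionPerimeter <- function(bin) {
  b <- padZero(bin != 0)
  n <- nrow(b); p <- ncol(b)
  core <- b[2:(n - 1L), 2:(p - 1L), drop = FALSE]
  up <- b[1:(n - 2L), 2:(p - 1L), drop = FALSE]
  dn <- b[3:n, 2:(p - 1L), drop = FALSE]
  lf <- b[2:(n - 1L), 1:(p - 2L), drop = FALSE]
  rt <- b[2:(n - 1L), 3:p, drop = FALSE]
  border <- core & !(up & dn & lf & rt)
  bb <- padZero(border)
  bup <- bb[1:(n - 2L), 2:(p - 1L), drop = FALSE]
  bdn <- bb[3:n, 2:(p - 1L), drop = FALSE]
  blf <- bb[2:(n - 1L), 1:(p - 2L), drop = FALSE]
  brt <- bb[2:(n - 1L), 3:p, drop = FALSE]
  bul <- bb[1:(n - 2L), 1:(p - 2L), drop = FALSE]
  bur <- bb[1:(n - 2L), 3:p, drop = FALSE]
  bdl <- bb[3:n, 1:(p - 2L), drop = FALSE]
  bdr <- bb[3:n, 3:p, drop = FALSE]
  orth <- bup + bdn + blf + brt
  diag <- bul + bur + bdl + bdr
  code <- 1L + 2L * orth + 10L * diag
  w <- numeric(length(code))
  w[code %in% c(5L, 7L, 15L, 17L, 25L, 27L)] <- 1
  w[code %in% c(21L, 33L)] <- sqrt(2)
  w[code %in% c(13L, 23L)] <- (1 + sqrt(2)) / 2
  sum(w[border])
}

# Merge 4-connected labels that touch diagonally, yielding 8-connectivity.
# Labels are renumbered 1..k in first-appearance order.
merge8Connectivity <- function(labels) {
  mx <- max(labels)
  if (mx < 2L) return(labels)
  n <- nrow(labels); p <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-n, -p]), as.vector(labels[-1, -1])),
    cbind(as.vector(labels[-n, -1]), as.vector(labels[-1, -p])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(mx)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(mx), find, integer(1))
  newid <- match(root, sort(unique(root)))
  out <- labels
  out[labels > 0] <- newid[labels[labels > 0]]
  out
}

# Relabel a label matrix so labels run 1..k without gaps.
compactLabels <- function(labels, keep) {
  out <- labels
  out[!(labels %in% keep)] <- 0L
  out[out > 0L] <- match(out[out > 0L], keep)
  storage.mode(out) <- "integer"
  out
}

clip8 <- function(x) { x[x < 0] <- 0; x[x > 255] <- 255; x }

# Gaussian blur that also works when the brush would exceed the image:
# small images are zero-padded before filtering and cropped back (outside
# the canvas there is no stain, so zero padding is the right boundary).
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  brush <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  if (min(dim(m)) >= brush) {
    return(as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(m), sigma = sigma))))
  }
  pad <- brush
  big <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  out <- as.matrix(EBImage::imageData(
    EBImage::gblur(EBImage::Image(big), sigma = sigma)))
  out[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}

# 8-bit histogram (counts of grey levels 0..255) from intensities.
hist256 <- function(x) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  tabulate(pmin(255L, pmax(0L, as.integer(round(x)))) + 1L, nbins = 256L)
}
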