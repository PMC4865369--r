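# Independent oracles and fixture helpers shared across the suite. The
# oracles are deliberately naive re-implementations (loops, enumeration)
# kept apart from the package's own code paths.

# Naive minimum cross-entropy threshold: explicit per-candidate loops over
# the criterion, then the pinned plateau-midpoint tie rule.
liOracle <- function(h) {
  g <- 0:255
  eta <- rep(Inf, 255)
  for (t in 0:254) {
    lo <- g <= t
    n0 <- sum(h[lo]); n1 <- sum(h[!lo])
    if (n0 == 0 || n1 == 0) next
    s0 <- sum(h[lo] * g[lo]); s1 <- sum(h[!lo] * g[!lo])
    e <- 0
    if (s0 > 0) e <- e - s0 * log(s0 / n0)
    if (s1 > 0) e <- e - s1 * log(s1 / n1)
    eta[t + 1] <- e
  }
  t_star <- which.min(eta)
  tol <- 1e-12 * max(1, abs(eta[t_star]))
  lo <- t_star
  while (lo > 1 && is.finite(eta[lo - 1]) && abs(eta[lo - 1] - eta[t_star]) <= tol)
    lo <- lo - 1
  hi <- t_star
  while (hi < 255 && is.finite(eta[hi + 1]) && abs(eta[hi + 1] - eta[t_star]) <= tol)
    hi <- hi + 1
  as.integer(floor((lo + hi) / 2)) - 1L
}

# Brute-force Benjamini-Hochberg step-up: sort, walk ranks, running minimum.
bhOracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- 1
  for (j in m:1) {
    run <- min(run, ps[j] * (m / j))
    adj[j] <- run
  }
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Greedy one-to-one matching of measured cells to planted cells: a measured
# cell matches the nearest unused planted cell if their centroids are within
# one planted radius. Returns the number of matches.
matchOneToOne <- function(measured, planted, pixel_size_um) {
  used <- rep(FALSE, nrow(planted))
  matched <- 0L
  for (i in seq_len(nrow(measured))) {
    d <- sqrt((planted$row - measured$row[i])^2 +
                (planted$col - measured$col[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= planted$radius_um[j] / pixel_size_um) {
      matched <- matched + 1L
      used[j] <- TRUE
    }
  }
  matched
}

# Small geometry used across tests to keep renders fast.
testGeometry <- function() WormGeometry(length_px = 300L, width_px = 80L,
                                        pixel_size_um = 1)

# Random 8-bit histogram with irregular occupancy.
randomHistogram <- function() {
  h <- integer(256)
  k <- sample(5:80, 1)
  lev <- sample(0:255, k)
  h[lev + 1] <- rpois(k, lambda = runif(k, 1, 60))
  if (sum(h > 0) < 2) h[c(40, 200) + 1] <- c(5, 7)
  h
}
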