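# Test helpers: small trajectory constructors independent of the
# package's simulator, used as oracles for the analysis path.

# Pure Brownian tracks built directly from Gaussian increments.
brownianTS <- function(n, len, D, dt = 0.05, sigmaLoc = 0, drift = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- cumsum(c(0, stats::rnorm(len - 1, drift, sqrt(2 * D * dt))))
    y <- cumsum(c(0, stats::rnorm(len - 1, 0, sqrt(2 * D * dt))))
    data.frame(trajectory_id = sprintf("t%05d", i), frame = 0:(len - 1),
               x = x + 50 + stats::rnorm(len, 0, sigmaLoc),
               y = y + 50 + stats::rnorm(len, 0, sigmaLoc))
  }))
  trajectorySet(df, frameInterval = dt)
}

# Reflecting-disc confined tracks (radial reflection at radius R).
confinedTS <- function(n, len, D, R, dt = 0.05, sigmaLoc = 0.02,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    xs <- matrix(0, len, 2)
    th <- stats::runif(1, 0, 2 * pi)
    p <- R * sqrt(stats::runif(1)) * c(cos(th), sin(th))
    xs[1, ] <- p
    for (t in 2:len) {
      cand <- p + stats::rnorm(2, 0, sqrt(2 * D * dt))
      d <- sqrt(sum(cand^2))
      if (d > R) cand <- cand * (max(2 * R - d, 0) / d)
      p <- cand
      xs[t, ] <- p
    }
    data.frame(trajectory_id = sprintf("t%05d", i), frame = 0:(len - 1),
               x = xs[, 1] + 50 + stats::rnorm(len, 0, sigmaLoc),
               y = xs[, 2] + 50 + stats::rnorm(len, 0, sigmaLoc))
  }))
  trajectorySet(df, frameInterval = dt)
}

# A single trajectory from an explicit coordinate matrix.
pathTS <- function(xy, dt = 0.05, id = "p1") {
  trajectorySet(data.frame(trajectory_id = id,
                           frame = seq_len(nrow(xy)) - 1L,
                           x = xy[, 1], y = xy[, 2]),
                frameInterval = dt)
}

# Closed-form mean jump length: per-axis variance 2 D dt + 2 sigma^2,
# so r is Rayleigh and E[r] = sqrt(pi (D dt + sigma^2)).
expectedMeanJump <- function(D, dt, sigmaLoc) {
  sqrt(pi * (D * dt + sigmaLoc^2))
}

# Synthetic disc image for locus detection (pixel-centre convention).
discImage <- function(nrow, ncol, pixelSize, cx, cy, radius,
                      value = 1, noise = 0, seed = 1) {
  set.seed(seed)
  xs <- (seq_len(ncol) - 0.5) * pixelSize
  ys <- (seq_len(nrow) - 0.5) * pixelSize
  img <- outer(ys, xs, function(y, x)
    ifelse((x - cx)^2 + (y - cy)^2 <= radius^2, value, 0))
  img + matrix(stats::rnorm(nrow * ncol, 0, noise), nrow)
}
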