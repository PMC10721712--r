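#' Detect candidate spots in one frame
#'
#' Local maxima above background + \code{thresholdSd} background standard
#' deviations, non-maximum suppressed within a 3-pixel radius. Background
#' statistics are taken as the image median and the MAD.
#'
#' @param frame numeric matrix (rows = y, cols = x) of counts.
#' @param thresholdSd detection threshold in background sds (default 5).
#' @return data.frame of candidate pixel positions \code{px}, \code{py}
#'   (1-based) and \code{value}; zero rows when nothing exceeds the
#'   threshold.
#' @export
detectSpots <- function(frame, thresholdSd = 5) {
  bg <- stats::median(frame)
  s <- stats::mad(frame)
  if (s == 0) s <- sqrt(max(bg, 1))       # Poisson floor for flat frames
  thr <- bg + thresholdSd * s
  cand <- which(frame > thr, arr.ind = TRUE)
  if (nrow(cand)) {
    # keep only 8-neighbourhood local maxima (PSF shoulders sit on a
    # slope and are rejected here before non-maximum suppression)
    nr <- nrow(frame); nc <- ncol(frame)
    ismax <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1L]; cc <- cand[i, 2L]
      nb <- frame[max(1L, r - 1L):min(nr, r + 1L),
                  max(1L, cc - 1L):min(nc, cc + 1L)]
      frame[r, cc] >= max(nb)
    }, logical(1))
    cand <- cand[ismax, , drop = FALSE]
  }
  if (!nrow(cand)) return(data.frame(px = integer(0), py = integer(0),
                                     value = numeric(0)))
  vals <- frame[cand]
  o <- order(vals, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]; vals <- vals[o]
  keep <- logical(length(vals))
  taken <- matrix(numeric(0), 0L, 2L)
  for (i in seq_along(vals)) {
    if (nrow(taken)) {
      d2 <- (taken[, 1L] - cand[i, 1L])^2 + (taken[, 2L] - cand[i, 2L])^2
      if (any(d2 <= 9)) next                # suppressed within 3 px
    }
    keep[i] <- TRUE
    taken <- rbind(taken, cand[i, ])
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(px = as.integer(cand[, 2L]), py = as.integer(cand[, 1L]),
             value = vals[keep])
}

#' Fit a symmetric 2D Gaussian to a spot candidate
#'
#' Nonlinear least squares (Levenberg-Marquardt) of amplitude, centre,
#' width and constant background over a square window around the
#' candidate pixel. Returns the sub-pixel position in um. Candidates too
#' close to the image border, or fits that fail to converge, are
#' discarded (NULL).
#'
#' @param frame numeric matrix of counts.
#' @param candidate one row of [detectSpots()] output.
#' @param window window edge in pixels (odd, default 7).
#' @param pixelSize um per pixel.
#' @return list (\code{x}, \code{y} um; \code{sigma} um; \code{amplitude},
#'   \code{background}; \code{fitError} um, the estimated positional sd)
#'   or NULL when discarded.
#' @export
fitGaussianSpot <- function(frame, candidate, window = 7L,
                            pixelSize = 0.110) {
  half <- (window - 1L) %/% 2L
  px <- candidate$px; py <- candidate$py
  if (px - half < 1L || px + half > ncol(frame) ||
      py - half < 1L || py + half > nrow(frame))
    return(NULL)                            # border candidate
  xs <- (px - half):(px + half)
  ys <- (py - half):(py + half)
  z <- frame[ys, xs]
  # flatten row-wise: x cycles fastest, matching as.numeric(t(z))
  d <- data.frame(x = rep(xs, times = window), y = rep(ys, each = window),
                  z = as.numeric(t(z)))
  st <- list(A = max(d$z) - stats::median(d$z), x0 = px, y0 = py,
             s = 1, b = stats::median(d$z))
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2))
                        + b,
                      data = d, start = st,
                      lower = c(0, px - half, py - half, 0.3, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[c("x0", "y0")],
                 error = function(e) c(NA_real_, NA_real_))
  list(x = (cf[["x0"]] - 0.5) * pixelSize,
       y = (cf[["y0"]] - 0.5) * pixelSize,
       sigma = abs(cf[["s"]]) * pixelSize,
       amplitude = cf[["A"]], background = cf[["b"]],
       fitError = max(mean(se) * pixelSize, 1e-4, na.rm = TRUE))
}

#' Localize all spots in an image stack
#'
#' Runs [detectSpots()] and [fitGaussianSpot()] on every frame.
#'
#' @param stack numeric array (ny, nx, nFrames).
#' @param thresholdSd detection threshold.
#' @param pixelSize um per pixel.
#' @param window fit window (px).
#' @return data.frame: \code{frame} (0-based), \code{x}, \code{y},
#'   \code{sigma}, \code{precision} (um).
#' @export
localizeStack <- function(stack, thresholdSd = 5, pixelSize = 0.110,
                          window = 7L) {
  out <- vector("list", dim(stack)[3L])
  for (f in seq_len(dim(stack)[3L])) {
    cands <- detectSpots(stack[, , f], thresholdSd)
    fits <- lapply(seq_len(nrow(cands)), function(i)
      fitGaussianSpot(stack[, , f], cands[i, ], window = window,
                      pixelSize = pixelSize))
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits))
      out[[f]] <- data.frame(frame = f - 1L,
                             x = vapply(fits, `[[`, numeric(1), "x"),
                             y = vapply(fits, `[[`, numeric(1), "y"),
                             sigma = vapply(fits, `[[`, numeric(1), "sigma"),
                             precision = vapply(fits, `[[`, numeric(1),
                                                "fitError"))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Link localizations into gap-free trajectories
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames
#' under a maximum displacement: a link is made when two localizations
#' are each other's nearest neighbour and closer than \code{maxDisp}.
#' Unlinked localizations start or end tracks; no gaps are allowed, and
#' the minimum-length filter applies. Equidistant ties (within 1 nm) are
#' broken deterministically toward the lower point index and counted.
#'
#' @param locs data.frame with \code{frame}, \code{x}, \code{y} and
#'   optionally \code{precision}.
#' @param maxDisp maximum per-frame displacement (um).
#' @param frameInterval seconds.
#' @param nucleusId movie label.
#' @return A \linkS4class{TrajectorySet}; the number of tie-breaks is
#'   attached as attribute \code{"ties"}.
#' @export
linkTrajectories <- function(locs, maxDisp, frameInterval,
                             nucleusId = "linked") {
  stopifnot(all(c("frame", "x", "y") %in% names(locs)))
  locs <- locs[order(locs$frame), , drop = FALSE]
  if (is.null(locs$precision)) locs$precision <- 0.020
  locs$.traj <- NA_integer_
  nextId <- 0L
  ties <- 0L
  frames <- sort(unique(locs$frame))
  idxByFrame <- split(seq_len(nrow(locs)), locs$frame)
  for (fi in seq_along(frames)) {
    cur <- idxByFrame[[as.character(frames[fi])]]
    unass <- cur[is.na(locs$.traj[cur])]
    if (length(unass)) {
      locs$.traj[unass] <- nextId + seq_along(unass)
      nextId <- nextId + length(unass)
    }
    if (fi == length(frames) || frames[fi + 1L] != frames[fi] + 1L)
      next                                   # frame gap: all tracks end
    nxt <- idxByFrame[[as.character(frames[fi + 1L])]]
    if (!length(nxt)) next
    dmat <- sqrt(outer(locs$x[cur], locs$x[nxt], "-")^2 +
                   outer(locs$y[cur], locs$y[nxt], "-")^2)
    # mutual nearest neighbours under maxDisp; 1 nm ties -> lower index
    for (a in seq_along(cur)) {
      row <- dmat[a, ]
      j <- which.min(row)    # which.min takes the lower index on ties
      if (any(abs(row - row[j]) < 1e-3 & seq_along(row) != j))
        ties <- ties + 1L
      if (row[j] > maxDisp) next
      if (which.min(dmat[, j]) != a) next
      locs$.traj[nxt[j]] <- locs$.traj[cur[a]]
    }
  }
  df <- data.frame(trajectory_id = sprintf("t%06d", locs$.traj),
                   frame = locs$frame, x = locs$x, y = locs$y,
                   precision = locs$precision)
  ts <- trajectorySet(df, frameInterval = frameInterval,
                      nucleusId = nucleusId)
  attr(ts, "ties") <- ties
  ts
}
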