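#' Compute jump and turning-angle tables
#'
#' One row per jump (displacement between consecutive localizations) and
#' one per turning angle (between successive jump vectors). The angle is
#' signed via the 2D cross product and mapped to [0, 360): 0 = straight
#' continuation, 180 = reversal, 90 vs 270 distinguishes left from right
#' turns. Each angle carries the mean of its two adjacent jump lengths as
#' its displacement abscissa, and the decoded states of both jumps when a
#' \linkS4class{StateAssignment} is supplied.
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param assignment optional \linkS4class{StateAssignment}; per-jump
#'   states are joined onto the tables (NA otherwise).
#' @return A \linkS4class{JumpTable}.
#' @export
computeJumpTable <- function(ts, assignment = NULL) {
  df <- orderLocs(localizations(ts))
  id <- df$trajectory_id
  first <- !duplicated(id)
  dx <- c(NA, diff(df$x)); dx[first] <- NA
  dy <- c(NA, diff(df$y)); dy[first] <- NA
  jid <- id[!first]
  jdx <- dx[!first]; jdy <- dy[!first]
  jindex <- stats::ave(rep(1L, length(jid)), jid, FUN = seq_along)
  jumps <- data.frame(trajectory_id = jid, jump_index = jindex,
                      dx = jdx, dy = jdy, r = sqrt(jdx^2 + jdy^2),
                      state = NA_integer_)
  if (!is.null(assignment)) {
    key <- paste(jumps$trajectory_id, jumps$jump_index)
    akey <- paste(assignment@jumps$trajectory_id,
                  assignment@jumps$jump_index)
    jumps$state <- assignment@jumps$state[match(key, akey)]
  }
  # angles: successive jump pairs within a trajectory
  nj <- length(jid)
  same <- jumps$trajectory_id[-1L] == jumps$trajectory_id[-nj]
  i1 <- which(same)          # first jump of the pair
  v1x <- jumps$dx[i1]; v1y <- jumps$dy[i1]
  v2x <- jumps$dx[i1 + 1L]; v2y <- jumps$dy[i1 + 1L]
  cross <- v1x * v2y - v1y * v2x
  dot <- v1x * v2x + v1y * v2y
  theta <- atan2(cross, dot) * 180 / pi
  theta <- theta %% 360
  angles <- data.frame(trajectory_id = jumps$trajectory_id[i1],
                       angle_index = jumps$jump_index[i1],
                       theta = theta,
                       mean_disp = (jumps$r[i1] + jumps$r[i1 + 1L]) / 2,
                       state1 = jumps$state[i1],
                       state2 = jumps$state[i1 + 1L])
  new("JumpTable", jumps = jumps, angles = angles)
}

#' Circular summary of turning angles
#'
#' Resultant vector length R = ||mean of unit vectors|| and mean
#' direction. R near 0 indicates an isotropic (uniform) angle
#' distribution, R near 1 strong accumulation around the mean direction;
#' an excess of angles near 180 degrees (backwards anisotropy) shows up as
#' a mean direction near 180 with appreciable R.
#'
#' @param angles numeric vector of angles in degrees.
#' @return list with \code{meanDirection} (degrees in [0, 360)) and
#'   \code{R}.
#' @export
circularSummary <- function(angles) {
  if (!length(angles)) stop("no angles supplied")
  a <- angles * pi / 180
  mx <- mean(cos(a)); my <- mean(sin(a))
  list(meanDirection = (atan2(my, mx) * 180 / pi) %% 360,
       R = sqrt(mx^2 + my^2))
}

#' Fold anisotropy f(180/0)
#'
#' How many-fold more likely a step backwards is than a step forwards:
#' the ratio of angle counts within 180 +/- window to counts within
#' 0 +/- window. Equals 1 for isotropic motion; values above 1 indicate
#' backwards anisotropy (trapping / rebinding).
#'
#' @param angles numeric vector of turning angles in degrees ([0, 360)).
#' @param window half-width of the windows in degrees (default 30).
#' @return the ratio; \code{Inf} (with a warning) when the forward window
#'   is empty.
#' @export
foldAnisotropy <- function(angles, window = 30) {
  a <- angles %% 360
  backward <- sum(a >= 180 - window & a <= 180 + window)
  forward <- sum(a <= window | a >= 360 - window)
  if (forward == 0L) {
    warning("no angles in the forward window; returning Inf")
    return(Inf)
  }
  backward / forward
}

#' Flag anisotropic jumps
#'
#' A jump (of a diffusive-state trajectory) is anisotropic when the angle
#' it forms with its successive jump lies within 180 +/- window degrees.
#'
#' @inheritParams foldAnisotropy
#' @return logical vector, one per angle.
#' @export
flagAnisotropicJumps <- function(angles, window = 30) {
  a <- angles %% 360
  a >= 180 - window & a <= 180 + window
}

#' Anisotropy against displacement with bootstrap errors
#'
#' Bins turning angles by their mean pair displacement and computes
#' f(180/0) per bin, restricted to angles whose two defining jumps both
#' belong to the fastest diffusive states (guaranteeing displacements well
#' above the localization error). Per-bin spread is the sd over bootstrap
#' subsamples drawing \code{bootFrac} of the bin's angles with
#' replacement. Bins with fewer than \code{minAngles} angles are masked.
#'
#' @param jt a \linkS4class{JumpTable}.
#' @param states integer vector of state labels to keep (both jumps of an
#'   angle must match); NULL keeps all angles.
#' @param dispRange c(lo, hi) displacement bounds in um.
#' @param binWidth bin width in um (default 0.050).
#' @param window angular half-width in degrees.
#' @param nBoot bootstrap repeats (default 50).
#' @param bootFrac subsample fraction (default 0.5).
#' @param minAngles minimum angles per reported bin (default 30).
#' @param seed integer seed for the bootstrap.
#' @return An \linkS4class{AnisotropyProfile}.
#' @export
anisotropyVsDisplacement <- function(jt, states = NULL,
                                     dispRange = c(0.050, 0.350),
                                     binWidth = 0.050, window = 30,
                                     nBoot = 50L, bootFrac = 0.5,
                                     minAngles = 30L, seed = NULL) {
  ang <- jt@angles
  if (!is.null(states))
    ang <- ang[!is.na(ang$state1) & !is.na(ang$state2) &
                 ang$state1 %in% states & ang$state2 %in% states, ,
               drop = FALSE]
  edges <- seq(dispRange[1L], dispRange[2L], by = binWidth)
  if (length(edges) < 2L) stop("dispRange narrower than one bin")
  ang <- ang[ang$mean_disp >= dispRange[1L] &
               ang$mean_disp < dispRange[2L], , drop = FALSE]
  if (!nrow(ang)) stop("no angles within the displacement range")
  bin <- findInterval(ang$mean_disp, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1L
  f <- sdv <- rep(NA_real_, nb)
  nn <- integer(nb)
  withLocalSeed(seed, {
    for (b in seq_len(nb)) {
      th <- ang$theta[bin == b]
      nn[b] <- length(th)
      if (nn[b] < minAngles) next
      f[b] <- suppressWarnings(foldAnisotropy(th, window))
      m <- max(1L, round(bootFrac * nn[b]))
      boots <- vapply(seq_len(nBoot), function(i)
        suppressWarnings(foldAnisotropy(th[sample.int(nn[b], m,
                                                      replace = TRUE)],
                                        window)),
        numeric(1))
      sdv[b] <- stats::sd(boots[is.finite(boots)])
    }
  })
  bins <- data.frame(lo = edges[-length(edges)], hi = edges[-1L],
                     mid = (edges[-length(edges)] + edges[-1L]) / 2,
                     f = f, sd = sdv, n = nn,
                     masked = nn < minAngles)
  new("AnisotropyProfile", bins = bins, window = window,
      nBoot = as.integer(nBoot))
}

#' Plot an anisotropy profile
#'
#' f(180/0) against displacement with bootstrap error bars; the dashed
#' line marks the isotropic value 1.
#'
#' @param profile an \linkS4class{AnisotropyProfile}.
#' @param ... passed to \code{plot}.
#' @export
plotAnisotropyProfile <- function(profile, ...) {
  b <- profile@bins[!profile@bins$masked, , drop = FALSE]
  graphics::plot(b$mid * 1000, b$f, type = "b", pch = 16,
                 xlab = "displacement (nm)", ylab = "f(180/0)", ...)
  graphics::arrows(b$mid * 1000, b$f - b$sd, b$mid * 1000, b$f + b$sd,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 2)
}
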