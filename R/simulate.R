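#' Simulation configuration
#'
#' Describes a ground-truthed synthetic tracking experiment: a set of
#' diffusive states (Brownian diffusion coefficients in um^2/s), a
#' per-frame state transition matrix with a stationary occupancy, frame
#' interval, localization error, track-length law and nucleus geometry,
#' plus optional axial defocalization and trap zones.
#'
#' Track lengths are geometric with mean \code{meanTrackLength}
#' localizations (the tracker yields many short tracks and few long ones);
#' tracks shorter than four localizations are discarded and counted, as in
#' the analysis pipeline.
#'
#' @param D numeric vector of state diffusion coefficients (um^2/s).
#' @param occupancy stationary state fractions (sums to 1).
#' @param stickiness per-frame probability mass kept on the current state
#'   when building the default transition matrix (see
#'   [stickyTransitionMatrix()]).
#' @param A optional explicit transition matrix; overrides
#'   \code{stickiness}.
#' @param frameInterval seconds per frame.
#' @param sigmaLoc localization error sigma (um) per axis.
#' @param nTrajectories number of simulated molecules.
#' @param meanTrackLength mean localizations per track.
#' @param nucleus c(width, height) um of the rectangular nuclear region.
#' @param defocalDepth axial detection slab thickness (um); 0 disables
#'   defocalization.
#' @param traps list of trap zones, each
#'   \code{list(centre = c(x, y), radius, escapeProb)}; used by
#'   [simulateTrappedMotion()].
#' @param trapFraction fraction of trappable molecules starting inside a
#'   trap.
#' @param trapDmax only molecules whose state diffusion coefficient is at
#'   most this value interact with traps (default Inf: all molecules);
#'   fast freely-diffusing molecules cross trap zones unaffected.
#' @return list with class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(D = c(0.006, 0.020, 0.078, 0.512),
                             occupancy = c(0.057, 0.187, 0.275, 0.481),
                             stickiness = 0.9, A = NULL,
                             frameInterval = 0.050, sigmaLoc = 0.020,
                             nTrajectories = 1000L, meanTrackLength = 9,
                             nucleus = c(20, 20), defocalDepth = 0,
                             traps = list(), trapFraction = 0,
                             trapDmax = Inf) {
  if (length(D) != length(occupancy))
    stop("D and occupancy must have the same length")
  if (any(D < 0)) stop("diffusion coefficients must be >= 0")
  occupancy <- occupancy / sum(occupancy)
  if (is.null(A)) A <- stickyTransitionMatrix(occupancy, stickiness)
  if (!all(dim(A) == length(D)) || any(abs(rowSums(A) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1 and match length(D)")
  if (frameInterval <= 0 || sigmaLoc <= 0) stop("frameInterval and sigmaLoc must be > 0")
  for (tr in traps) {
    if (tr$radius <= 0) stop("trap radius must be > 0")
    if (tr$radius < sigmaLoc)
      warning("trap radius below sigmaLoc: anisotropy unresolvable")
  }
  structure(list(D = D, occupancy = occupancy, A = A,
                 frameInterval = frameInterval, sigmaLoc = sigmaLoc,
                 nTrajectories = as.integer(nTrajectories),
                 meanTrackLength = meanTrackLength, nucleus = nucleus,
                 defocalDepth = defocalDepth, traps = traps,
                 trapFraction = trapFraction, trapDmax = trapDmax),
            class = "SimulationConfig")
}

#' Sticky transition matrix with exact stationary distribution
#'
#' \code{A = a I + (1 - a) 1 pi'}: with probability \code{a} the state is
#' kept, otherwise it is redrawn from the stationary occupancy \code{pi}.
#' Rows sum to 1 and \code{pi} is exactly stationary, so long-run per-jump
#' state fractions equal the configured occupancies.
#'
#' @param occupancy stationary distribution.
#' @param stickiness a in [0, 1); self-transition probability is
#'   \code{a + (1 - a) pi_i}.
#' @return K x K matrix.
#' @export
stickyTransitionMatrix <- function(occupancy, stickiness = 0.9) {
  occupancy <- occupancy / sum(occupancy)
  K <- length(occupancy)
  stickiness * diag(K) + (1 - stickiness) *
    matrix(occupancy, K, K, byrow = TRUE)
}

#' Condition presets for the tracked transcription-factor system
#'
#' Four-state presets matching the published CSL nuclear dynamics: state
#' diffusion coefficients 0.006, 0.020, 0.078 and 0.512 um^2/s (Bound1,
#' Bound2, Exploratory, Free), 50 ms frames, 20 nm localization error.
#' \code{"notch_off"} uses occupancies 5.7/18.7/27.5/48.1\%;
#' \code{"notch_on"} sets the free-state occupancy to 32\% and
#' redistributes the remainder proportionally among the slower states.
#'
#' @param condition \code{"notch_off"} or \code{"notch_on"}.
#' @param nTrajectories number of molecules.
#' @param ... further overrides passed to [simulationConfig()].
#' @return A \code{SimulationConfig}.
#' @export
presetConfig <- function(condition = c("notch_off", "notch_on"),
                         nTrajectories = 5000L, ...) {
  condition <- match.arg(condition)
  occ <- c(0.057, 0.187, 0.275, 0.481)
  if (condition == "notch_on") {
    free <- 0.32
    occ <- c(occ[1:3] / sum(occ[1:3]) * (1 - free), free)
  }
  simulationConfig(D = c(0.006, 0.020, 0.078, 0.512), occupancy = occ,
                   nTrajectories = nTrajectories, ...)
}

# Draw geometric track lengths (in localizations) with the given mean,
# capped to keep matrices bounded.
drawTrackLengths <- function(n, meanLen, cap = 200L) {
  L <- stats::rgeom(n, prob = 1 / meanLen) + 1L
  pmin(L, cap)
}

# Sample a Markov state sequence matrix (n x Tmax) given lengths in jumps.
sampleStateMatrix <- function(n, Tmax, nJumps, pi0, A) {
  K <- length(pi0)
  S <- matrix(NA_integer_, n, Tmax)
  S[, 1L] <- sample.int(K, n, replace = TRUE, prob = pi0)
  if (Tmax >= 2L) {
    Acum <- t(apply(A, 1L, cumsum))
    for (t in 2:Tmax) {
      act <- which(nJumps >= t)
      if (!length(act)) break
      u <- stats::runif(length(act))
      cum <- Acum[S[act, t - 1L], , drop = FALSE]
      S[act, t] <- 1L + rowSums(cum < u)
    }
  }
  S
}

# Assemble a long-format localization frame + aligned truth from per-point
# vectors; renumbers ids and applies the >= 4 point filter while keeping
# truth aligned.
assembleObserved <- function(id, frame, xobs, yobs, jumpState, precision,
                             frameInterval, nucleusId) {
  keeptab <- table(id)
  keep <- names(keeptab)[keeptab >= 4L]
  dropped <- length(keeptab) - length(keep)
  sel <- id %in% keep
  id <- id[sel]; frame <- frame[sel]
  xobs <- xobs[sel]; yobs <- yobs[sel]; jumpState <- jumpState[sel]
  locs <- data.frame(trajectory_id = id, frame = frame, x = xobs, y = yobs,
                     precision = precision)
  ts <- new("TrajectorySet", locs = orderLocs(locs),
            frameInterval = frameInterval, nucleusId = nucleusId,
            dropped = as.integer(dropped))
  # jumpState[i] = latent state of the jump ENDING at point i (NA at track
  # starts); build the per-jump truth table in the same canonical order
  o <- order(id, frame)
  id <- id[o]; jumpState <- jumpState[o]
  first <- !duplicated(id)
  jt <- data.frame(trajectory_id = id[!first],
                   jump_index = stats::ave(rep(1L, sum(!first)), id[!first],
                                           FUN = seq_along),
                   state = jumpState[!first], in_trap = FALSE)
  modes <- vapply(split(jt$state, jt$trajectory_id), modeStateOf, integer(1))
  truth <- new("GroundTruth", jumps = jt,
               trajectories = data.frame(trajectory_id = names(modes),
                                         mode_state = as.integer(modes)))
  list(trajectories = ts, truth = truth)
}

# Most frequent label; ties broken toward the smaller (slower) state.
modeStateOf <- function(s) {
  tb <- table(s)
  as.integer(names(tb)[which.max(tb)])
}

#' Simulate switching Brownian diffusion with localization noise
#'
#' Each molecule carries a Markov chain over diffusive states; given state
#' s, the 2D increment over one frame is isotropic Gaussian with per-axis
#' variance 2 D_s dt. Independent Gaussian localization noise (sd
#' \code{sigmaLoc} per axis) corrupts every observed position. With
#' \code{defocalDepth > 0} a hidden axial Brownian coordinate (same D_s)
#' restricts observation to |z| <= depth/2: observed tracks are split at
#' the frames the molecule spends out of the slab, reproducing the loss of
#' fast molecules from the focal plane. Tracks shorter than four observed
#' localizations are discarded and counted.
#'
#' @param config a \code{SimulationConfig}.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param nucleusId label for the simulated movie.
#' @return list with \code{trajectories} (\linkS4class{TrajectorySet}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' cfg <- simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 50)
#' sim <- simulateSwitchingDiffusion(cfg, seed = 1)
#' sim$trajectories
#' @export
simulateSwitchingDiffusion <- function(config, seed = NULL,
                                       nucleusId = "sim") {
  stopifnot(inherits(config, "SimulationConfig"))
  withLocalSeed(seed, {
    n <- config$nTrajectories
    dt <- config$frameInterval
    L <- drawTrackLengths(n, config$meanTrackLength)
    J <- L - 1L
    Tmax <- max(J, 1L)
    S <- sampleStateMatrix(n, Tmax, J, config$occupancy, config$A)
    sdstep <- sqrt(2 * config$D * dt)
    DX <- matrix(stats::rnorm(n * Tmax), n, Tmax) * sdstep[S]
    DY <- matrix(stats::rnorm(n * Tmax), n, Tmax) * sdstep[S]
    x0 <- stats::runif(n, 0, config$nucleus[1L])
    y0 <- stats::runif(n, 0, config$nucleus[2L])

    idx <- rep(seq_len(n), L)
    pt <- sequence(L)                     # 1..L_i within trajectory
    inc <- cbind(0, DX)[cbind(idx, pt)]   # increment arriving at each point
    incy <- cbind(0, DY)[cbind(idx, pt)]
    xtrue <- x0[idx] + stats::ave(inc, idx, FUN = cumsum)
    ytrue <- y0[idx] + stats::ave(incy, idx, FUN = cumsum)
    jumpState <- cbind(NA_integer_, S)[cbind(idx, pt)]
    frame <- pt - 1L
    id <- sprintf("t%05d", idx)

    if (config$defocalDepth > 0 && is.finite(config$defocalDepth)) {
      depth <- config$defocalDepth
      DZ <- matrix(stats::rnorm(n * Tmax), n, Tmax) * sdstep[S]
      z0 <- stats::runif(n, -depth / 2, depth / 2)
      ztrue <- z0[idx] + stats::ave(cbind(0, DZ)[cbind(idx, pt)], idx,
                                    FUN = cumsum)
      vis <- abs(ztrue) <= depth / 2
      # split observed tracks at invisible frames: a new observed run
      # starts at a trajectory change or right after an out-of-slab frame
      newrun <- c(TRUE, idx[-1L] != idx[-length(idx)]) |
        c(TRUE, !vis[-length(vis)])
      run <- cumsum(newrun)
      jumpState[newrun] <- NA_integer_
      keep <- vis
      id <- sprintf("r%06d", run[keep])
      frame <- frame[keep]
      xtrue <- xtrue[keep]; ytrue <- ytrue[keep]
      jumpState <- jumpState[keep]
    }

    xobs <- xtrue + stats::rnorm(length(xtrue), 0, config$sigmaLoc)
    yobs <- ytrue + stats::rnorm(length(ytrue), 0, config$sigmaLoc)
    assembleObserved(id, frame, xobs, yobs, jumpState, config$sigmaLoc,
                     dt, nucleusId)
  })
}

#' Simulate diffusion with reflecting trap zones
#'
#' Molecules diffuse with a fixed diffusive state drawn from the
#' configured occupancy (no switching, so trap effects are not confounded
#' with state changes). Inside a trap disc, increments that would exit the
#' radius are reflected at the boundary; each frame the molecule escapes
#' with the configured probability and reverts to free diffusion. Free
#' molecules entering a disc become trapped. Reflection produces the
#' backwards-anisotropy signature whose displacement scale matches the
#' trap size.
#'
#' @inheritParams simulateSwitchingDiffusion
#' @return list with \code{trajectories} and \code{truth}; the truth jump
#'   table flags trap membership per jump.
#' @export
simulateTrappedMotion <- function(config, seed = NULL, nucleusId = "sim") {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!length(config$traps)) stop("config$traps must be non-empty")
  withLocalSeed(seed, {
    n <- config$nTrajectories
    dt <- config$frameInterval
    L <- drawTrackLengths(n, config$meanTrackLength)
    st <- sample.int(length(config$D), n, replace = TRUE,
                     prob = config$occupancy)
    sdstep <- sqrt(2 * config$D * dt)
    ntr <- length(config$traps)
    centres <- t(vapply(config$traps, function(tr) tr$centre, numeric(2)))
    radii <- vapply(config$traps, function(tr) tr$radius, numeric(1))
    esc <- vapply(config$traps, function(tr) tr$escapeProb, numeric(1))

    rows <- vector("list", n)
    trappable <- config$D[st] <= config$trapDmax
    startTrapped <- trappable & stats::runif(n) < config$trapFraction
    for (i in seq_len(n)) {
      Li <- L[i]
      sdi <- sdstep[st[i]]
      pos <- matrix(NA_real_, Li, 2L)
      intrap <- logical(Li)
      if (startTrapped[i]) {
        w <- sample.int(ntr, 1L)
        th <- stats::runif(1, 0, 2 * pi)
        rr <- radii[w] * sqrt(stats::runif(1))
        pos[1L, ] <- centres[w, ] + rr * c(cos(th), sin(th))
        cur <- w
      } else {
        pos[1L, ] <- stats::runif(2) * config$nucleus
        cur <- 0L
        if (trappable[i]) {
          d2 <- colSums((t(centres) - pos[1L, ])^2)
          if (any(d2 <= radii^2)) cur <- which.min(d2)
        }
      }
      intrap[1L] <- cur > 0L
      if (Li >= 2L) for (t in 2:Li) {
        step <- stats::rnorm(2, 0, sdi)
        if (cur > 0L) {
          if (stats::runif(1) < esc[cur]) {        # escape: free step out
            pos[t, ] <- pos[t - 1L, ] + step
            cur <- 0L
          } else {
            cand <- pos[t - 1L, ] + step
            v <- cand - centres[cur, ]
            d <- sqrt(sum(v * v))
            if (d > radii[cur]) {                  # radial reflection
              dref <- max(2 * radii[cur] - d, 0)
              cand <- centres[cur, ] + v * (dref / d)
            }
            pos[t, ] <- cand
          }
        } else {
          pos[t, ] <- pos[t - 1L, ] + step
        }
        if (cur == 0L && trappable[i]) {
          d2 <- colSums((t(centres) - pos[t, ])^2)
          if (any(d2 <= radii^2)) cur <- which.min(d2)
        }
        intrap[t] <- cur > 0L
      }
      rows[[i]] <- list(pos = pos, intrap = intrap)
    }

    id <- sprintf("t%05d", rep(seq_len(n), L))
    frame <- sequence(L) - 1L
    xt <- unlist(lapply(rows, function(r) r$pos[, 1L]))
    yt <- unlist(lapply(rows, function(r) r$pos[, 2L]))
    # jump is "in trap" if either endpoint is trapped
    trapFlag <- unlist(lapply(rows, function(r) {
      k <- length(r$intrap)
      c(NA, r$intrap[-1L] | r$intrap[-k])
    }))
    jumpState <- rep(st, L)
    jumpState[sequence(L) == 1L] <- NA_integer_
    xobs <- xt + stats::rnorm(length(xt), 0, config$sigmaLoc)
    yobs <- yt + stats::rnorm(length(yt), 0, config$sigmaLoc)
    out <- assembleObserved(id, frame, xobs, yobs, jumpState,
                            config$sigmaLoc, dt, nucleusId)
    # attach trap flags aligned with the truth jump table
    o <- order(id, frame)
    first <- !duplicated(id[o])
    tf <- trapFlag[o][!first]
    kept <- id[o][!first] %in% out$truth@jumps$trajectory_id
    out$truth@jumps$in_trap <- tf[kept]
    out
  })
}

#' Simulate a clustered bound-molecule point pattern
#'
#' Superposition of two spatial Poisson processes: a fraction
#' \code{pClustered} of the points is placed uniformly inside
#' \code{nClusters} discs (high local intensity lambda1), the remainder
#' uniformly over the window (clutter intensity lambda2). Disc centres are
#' uniform over the window inset by the disc radius so every disc fits.
#'
#' @param pClustered fraction of clustered points, in [0, 1].
#' @param nClusters number of cluster discs.
#' @param clusterRadius disc radius (um).
#' @param window c(width, height) um of the observation window.
#' @param nPoints total number of points.
#' @param seed integer seed.
#' @return list with \code{points} (n x 2 matrix), \code{clustered}
#'   (logical truth flags), \code{centres} (cluster disc centres) and the
#'   implied intensities \code{lambda1}, \code{lambda2}.
#' @export
simulateBoundPattern <- function(pClustered, nClusters, clusterRadius,
                                 window = c(20, 20), nPoints = 1000L,
                                 seed = NULL) {
  if (pClustered < 0 || pClustered > 1) stop("pClustered must be in [0, 1]")
  if (nClusters > 0 && (2 * clusterRadius >= min(window)))
    stop("cluster discs do not fit the window")
  withLocalSeed(seed, {
    nc <- round(pClustered * nPoints)
    nu <- nPoints - nc
    pts <- matrix(numeric(0), 0L, 2L)
    centres <- matrix(numeric(0), 0L, 2L)
    if (nc > 0L) {
      if (nClusters < 1L) stop("pClustered > 0 requires nClusters >= 1")
      centres <- cbind(stats::runif(nClusters, clusterRadius,
                                    window[1L] - clusterRadius),
                       stats::runif(nClusters, clusterRadius,
                                    window[2L] - clusterRadius))
      memb <- sample.int(nClusters, nc, replace = TRUE)
      th <- stats::runif(nc, 0, 2 * pi)
      rr <- clusterRadius * sqrt(stats::runif(nc))
      pts <- centres[memb, , drop = FALSE] + rr * cbind(cos(th), sin(th))
    }
    if (nu > 0L)
      pts <- rbind(pts, cbind(stats::runif(nu, 0, window[1L]),
                              stats::runif(nu, 0, window[2L])))
    clustered <- rep(c(TRUE, FALSE), c(nc, nu))
    lambda1 <- if (nc > 0L)
      nc / (nClusters * pi * clusterRadius^2) else NA_real_
    lambda2 <- nu / prod(window)
    list(points = pts, clustered = clustered, centres = centres,
         lambda1 = lambda1, lambda2 = lambda2)
  })
}

#' Render camera frames from a TrajectorySet
#'
#' Draws every localization as an integrated symmetric 2D Gaussian on a
#' pixel grid and adds Poisson shot noise, producing a synthetic movie for
#' the localization/linking front end.
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param psfSigma PSF sigma in um (should be at least half the pixel
#'   size for the rendering to be resolvable).
#' @param intensity expected photons per molecule per frame.
#' @param background expected background photons per pixel.
#' @param pixelSize um per pixel (default 0.110).
#' @param imgDim c(nx, ny) pixels; defaults to covering all localizations.
#' @param poissonNoise add shot noise (default TRUE).
#' @param seed integer seed.
#' @return numeric array (ny, nx, nFrames) of photon counts; frames are
#'   indexed from the minimum frame present in \code{ts}.
#' @export
renderFrames <- function(ts, psfSigma = 0.110, intensity = 500,
                         background = 5, pixelSize = 0.110, imgDim = NULL,
                         poissonNoise = TRUE, seed = NULL) {
  df <- localizations(ts)
  if (psfSigma < pixelSize / 2)
    warning("psfSigma below half the pixel size; rendering undersampled")
  if (is.null(imgDim))
    imgDim <- c(ceiling(max(df$x) / pixelSize) + 4L,
                ceiling(max(df$y) / pixelSize) + 4L)
  f0 <- min(df$frame)
  nf <- max(df$frame) - f0 + 1L
  out <- array(background, dim = c(imgDim[2L], imgDim[1L], nf))
  sp <- psfSigma / pixelSize                  # PSF sigma in pixels
  half <- max(3L, ceiling(4 * sp))
  withLocalSeed(seed, {
    for (i in seq_len(nrow(df))) {
      cx <- df$x[i] / pixelSize               # 0-based pixel coordinates
      cy <- df$y[i] / pixelSize
      px <- floor(cx)
      py <- floor(cy)
      xs <- max(0L, px - half):min(imgDim[1L] - 1L, px + half)
      ys <- max(0L, py - half):min(imgDim[2L] - 1L, py + half)
      # integrate the Gaussian over pixel [j, j+1)
      gx <- stats::pnorm(xs + 1, cx, sp) - stats::pnorm(xs, cx, sp)
      gy <- stats::pnorm(ys + 1, cy, sp) - stats::pnorm(ys, cy, sp)
      fr <- df$frame[i] - f0 + 1L
      out[ys + 1L, xs + 1L, fr] <- out[ys + 1L, xs + 1L, fr] +
        intensity * outer(gy, gx)
    }
    if (poissonNoise) {
      out[] <- stats::rpois(length(out), out)
    }
    out
  })
}

#' Trap-zone experiment preset
#'
#' The reference configuration for trap-induced backwards anisotropy: a
#' slow exploratory population (D = 0.1 um^2/s) that interacts with
#' reflecting trap zones of 125 nm radius, and a fast free population
#' (D = 0.512 um^2/s) that crosses them unaffected. With these settings
#' the anisotropy-vs-displacement profile of the pooled jumps peaks at
#' displacements matching the trap size (the 100-150 nm bin).
#'
#' @param nTrajectories number of molecules.
#' @param nTraps number of trap zones, placed uniformly (inset by 1 um)
#'   in a 10 x 10 um nucleus.
#' @param trapRadius trap radius in um (default 0.125).
#' @param escapeProb per-frame escape probability (default 0.01).
#' @param trapFraction fraction of trappable molecules starting trapped.
#' @param seed integer seed for the trap-centre placement.
#' @return A \code{SimulationConfig} for [simulateTrappedMotion()].
#' @export
trapPreset <- function(nTrajectories = 3000L, nTraps = 40L,
                       trapRadius = 0.125, escapeProb = 0.01,
                       trapFraction = 0.8, seed = NULL) {
  traps <- withLocalSeed(seed, lapply(seq_len(nTraps), function(i)
    list(centre = stats::runif(2, 1, 9), radius = trapRadius,
         escapeProb = escapeProb)))
  simulationConfig(D = c(0.1, 0.512), occupancy = c(0.5, 0.5),
                   nTrajectories = nTrajectories, meanTrackLength = 12,
                   nucleus = c(10, 10), traps = traps,
                   trapFraction = trapFraction, trapDmax = 0.2)
}
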