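# Pack the squared jump lengths of a TrajectorySet into an (n x Tmax)
# NA-padded matrix, trajectories in canonical id order.
jumpMatrix <- function(ts) {
  df <- orderLocs(localizations(ts))
  id <- df$trajectory_id
  first <- !duplicated(id)
  dx <- c(NA, diff(df$x)); dy <- c(NA, diff(df$y))
  dx[first] <- NA; dy[first] <- NA
  r2 <- dx * dx + dy * dy
  ids <- unique(id)
  nJ <- as.integer(table(factor(id, levels = ids))) - 1L
  n <- length(ids)
  Tmax <- max(nJ, 1L)
  R2 <- matrix(NA_real_, n, Tmax)
  row <- match(id, ids)[!first]
  col <- unlist(lapply(nJ, seq_len), use.names = FALSE)
  R2[cbind(row, col)] <- r2[!first]
  list(R2 = R2, nJumps = nJ, ids = ids, Tmax = Tmax)
}

# log emission density of a squared jump length r2 in a state with
# per-axis variance v: (dx, dy) isotropic bivariate normal.
logEmission <- function(r2, v) {
  -log(2 * pi * v) - r2 / (2 * v)
}

# One full E step (scaled forward-backward) + sufficient statistics.
# Returns logLik, gamma sums, xi sums, gamma at t = 1 and the full
# posterior array. Vectorized across trajectories: all recursions run on
# (n x K) matrices per time step.
hmmEStep <- function(R2, nJumps, D, A, pi0, sigmaLoc, dt,
                     keepGamma = FALSE) {
  n <- nrow(R2); Tmax <- ncol(R2); K <- length(D)
  v <- 2 * D * dt + 2 * sigmaLoc^2
  pad <- is.na(R2)
  R2z <- R2
  R2z[pad] <- 0
  # scaled emissions per state as full (n x Tmax) matrices; padded steps
  # (beyond a trajectory's last jump) get neutral emissions
  LB <- vector("list", K)
  for (s in seq_len(K))
    LB[[s]] <- -log(2 * pi * v[s]) - R2z / (2 * v[s])
  M <- LB[[1L]]
  if (K >= 2L) for (s in 2:K) M <- pmax(M, LB[[s]])
  B <- vector("list", K)
  for (s in seq_len(K)) {
    bs <- exp(LB[[s]] - M)
    bs[pad] <- 1
    B[[s]] <- bs
  }
  M[pad] <- 0
  Bt <- function(t) {                # (n x K) emission slice at time t
    out <- matrix(1, n, K)
    for (s in seq_len(K)) out[, s] <- B[[s]][, t]
    out
  }

  Alpha <- vector("list", Tmax)      # scaled forward variables
  Cs <- matrix(1, n, Tmax)
  a1 <- Bt(1L) * rep(pi0, each = n)
  c1 <- rowSums(a1)
  Alpha[[1L]] <- a1 / c1
  Cs[, 1L] <- c1
  if (Tmax >= 2L) for (t in 2:Tmax) {
    ap <- (Alpha[[t - 1L]] %*% A) * Bt(t)
    ct <- rowSums(ap)
    ok <- ct > 0
    ap[ok, ] <- ap[ok, , drop = FALSE] / ct[ok]
    ap[!ok, ] <- 0
    Alpha[[t]] <- ap
    Cs[ok & !pad[, t], t] <- ct[ok & !pad[, t]]
  }
  logLik <- sum(log(Cs[!pad])) + sum(M[!pad])

  Beta <- matrix(1, n, K)            # scaled beta at the current t
  gammaSum <- numeric(K)
  vNum <- numeric(K)
  xiSum <- matrix(0, K, K)
  gammaAll <- if (keepGamma) array(0, c(n, K, Tmax)) else NULL
  gamma1 <- NULL
  for (t in Tmax:1) {
    act <- !pad[, t]
    g <- Alpha[[t]] * Beta
    g <- g / pmax(rowSums(g), .Machine$double.xmin)
    g[!act, ] <- 0
    if (keepGamma) gammaAll[, , t] <- g
    vNum <- vNum + colSums(g * R2z[, t])
    gammaSum <- gammaSum + colSums(g)
    if (t == 1L) gamma1 <- g
    if (t >= 2L) {
      bb <- (Bt(t) * Beta) / Cs[, t]
      xiSum <- xiSum +
        A * (crossprod(Alpha[[t - 1L]][act, , drop = FALSE],
                       bb[act, , drop = FALSE]))
      Beta <- bb %*% t(A)
      Beta[!act, ] <- 1   # trajectories already finished stay neutral
    }
  }
  list(logLik = logLik, gammaSum = gammaSum, vNum = vNum,
       xiSum = xiSum, gamma1 = gamma1, gamma = gammaAll)
}

runEM <- function(R2, nJumps, D, A, pi0, sigmaLoc, dt, tol, maxIter) {
  ll <- -Inf
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    es <- hmmEStep(R2, nJumps, D, A, pi0, sigmaLoc, dt)
    trace <- c(trace, es$logLik)
    if (is.finite(ll) && es$logLik - ll < tol) {
      converged <- TRUE
      ll <- es$logLik
      break
    }
    ll <- es$logLik
    iter <- iter + 1L
    if (iter > maxIter) break
    # M step
    v <- es$vNum / (2 * es$gammaSum)
    D <- pmax((v - 2 * sigmaLoc^2) / (2 * dt), 0)
    rs <- rowSums(es$xiSum)
    if (all(rs > 0)) A <- es$xiSum / rs
    pi0 <- colSums(es$gamma1)
    pi0 <- pi0 / sum(pi0)
  }
  list(D = D, A = A, pi = pi0, logLik = ll, nIter = iter,
       converged = converged, trace = trace)
}

#' Fit a K-state switching-diffusion hidden Markov model
#'
#' Maximum-likelihood Baum-Welch EM over the per-trajectory jump
#' sequences of a \linkS4class{TrajectorySet}. The emission density of a
#' jump (dx, dy) in state s is isotropic bivariate Gaussian with per-axis
#' variance \code{2 D_s dt + 2 sigmaLoc^2}; in the M step D_s is solved in
#' closed form with the localization-noise term subtracted and floored at
#' zero. Setting \code{sigmaLoc = 0} reproduces the noise-uncorrected
#' variant. Several random restarts are run briefly and the best one is
#' refined to convergence (change in log-likelihood below \code{tol} nats,
#' or \code{maxIter} iterations). States are canonically ordered by
#' ascending D.
#'
#' @param ts a \linkS4class{TrajectorySet} with at least 100 jumps.
#' @param K number of diffusive states.
#' @param sigmaLoc localization error sigma (um).
#' @param seed integer seed for the restarts.
#' @param nRestarts random restarts (default 5).
#' @param tol convergence tolerance in nats (default 1e-6).
#' @param maxIter maximum EM iterations for the refinement run.
#' @return A \linkS4class{DiffusionHMM} carrying the maximized
#'   log-likelihood, iteration count and convergence flag.
#' @examples
#' sim <- simulateSwitchingDiffusion(
#'   simulationConfig(D = 0.1, occupancy = 1, nTrajectories = 100),
#'   seed = 1)
#' fitHMM(sim$trajectories, K = 1, seed = 1)
#' @export
fitHMM <- function(ts, K, sigmaLoc = 0.020, seed = NULL, nRestarts = 5L,
                   tol = 1e-6, maxIter = 500L) {
  jm <- jumpMatrix(ts)
  nj <- sum(jm$nJumps)
  if (nj < 100L) stop("need at least 100 jumps to fit an HMM")
  r2 <- jm$R2[!is.na(jm$R2)]
  if (stats::var(r2) == 0) stop("degenerate data: all jumps identical")
  dt <- frameInterval(ts)
  Dnaive <- pmax(r2 / (4 * dt) - sigmaLoc^2 / dt, 1e-6)

  withLocalSeed(seed, {
    probs <- (2 * seq_len(K) - 1) / (2 * K)
    starts <- vector("list", nRestarts)
    for (r in seq_len(nRestarts)) {
      D0 <- as.numeric(stats::quantile(Dnaive, probs))
      if (r > 1L) D0 <- D0 * exp(stats::rnorm(K, 0, 0.5))
      D0 <- sort(pmax(D0, 1e-6))
      A0 <- stickyTransitionMatrix(rep(1 / K, K), 0.8)
      starts[[r]] <- list(D = D0, A = A0, pi = rep(1 / K, K))
    }
    short <- lapply(starts, function(s)
      runEM(jm$R2, jm$nJumps, s$D, s$A, s$pi, sigmaLoc, dt,
            tol = 1e-4, maxIter = 30L))
    best <- short[[which.max(vapply(short, `[[`, numeric(1), "logLik"))]]
    fit <- runEM(jm$R2, jm$nJumps, best$D, best$A, best$pi, sigmaLoc, dt,
                 tol = tol, maxIter = maxIter)
    o <- order(fit$D)
    new("DiffusionHMM", K = as.integer(K), D = fit$D[o],
        A = fit$A[o, o, drop = FALSE], pi = fit$pi[o],
        sigmaLoc = sigmaLoc, frameInterval = dt, logLik = fit$logLik,
        nIter = fit$nIter, converged = fit$converged)
  })
}

#' Select the number of diffusive states up to a ceiling
#'
#' Fits models for K = 1..KMax and selects K by maximizing a model score,
#' the BIC approximation to the marginal likelihood: score = logLik -
#' (K^2 + K - 1)/2 * log(n_jumps), reported as such for every K.
#'
#' @inheritParams fitHMM
#' @param KMax state ceiling (default 4).
#' @return list with \code{K} (selected), \code{fits} (list of
#'   \linkS4class{DiffusionHMM} indexed by K) and \code{scores}
#'   (data.frame K, logLik, score).
#' @export
selectModel <- function(ts, KMax = 4L, sigmaLoc = 0.020, seed = NULL,
                        nRestarts = 5L, tol = 1e-6, maxIter = 500L) {
  nj <- sum(jumpMatrix(ts)$nJumps)
  fits <- vector("list", KMax)
  scores <- data.frame(K = seq_len(KMax), logLik = NA_real_,
                       score = NA_real_)
  for (K in seq_len(KMax)) {
    fits[[K]] <- fitHMM(ts, K, sigmaLoc = sigmaLoc, seed = seed,
                        nRestarts = nRestarts, tol = tol,
                        maxIter = maxIter)
    npar <- K^2 + K - 1
    scores$logLik[K] <- fits[[K]]@logLik
    scores$score[K] <- fits[[K]]@logLik - npar / 2 * log(nj)
  }
  Ksel <- which.max(scores$score)
  if (any(diff(scores$logLik) < -1e-6))
    warning("log-likelihood not monotone in K; see the score table")
  list(K = Ksel, fits = fits, scores = scores)
}

#' Decode per-jump states and per-trajectory mode states
#'
#' Labels every jump with its posterior-maximum state
#' (forward-backward), then assigns each trajectory the mode state of its
#' jumps (ties broken toward the slower state). Population proportions are
#' computed over whole trajectories from the mode states, which
#' counteracts the defocalization bias toward slow jumps; per-jump
#' proportions are retained alongside.
#'
#' @param hmm a fitted \linkS4class{DiffusionHMM}.
#' @param ts the \linkS4class{TrajectorySet} to decode.
#' @return A \linkS4class{StateAssignment}.
#' @export
decodeStates <- function(hmm, ts) {
  jm <- jumpMatrix(ts)
  es <- hmmEStep(jm$R2, jm$nJumps, hmm@D, hmm@A, hmm@pi, hmm@sigmaLoc,
                 hmm@frameInterval, keepGamma = TRUE)
  K <- hmm@K
  n <- length(jm$ids)
  lab <- matrix(NA_integer_, n, jm$Tmax)
  for (t in seq_len(jm$Tmax)) {
    at <- jm$nJumps >= t
    g <- matrix(es$gamma[, , t], n, K)
    # ties.method = "first" breaks posterior ties toward the slower state
    lab[at, t] <- max.col(g[at, , drop = FALSE], ties.method = "first")
  }
  row <- rep(seq_len(n), jm$nJumps)
  col <- unlist(lapply(jm$nJumps, seq_len), use.names = FALSE)
  jumps <- data.frame(trajectory_id = jm$ids[row], jump_index = col,
                      state = lab[cbind(row, col)])
  modes <- vapply(split(jumps$state, factor(jumps$trajectory_id,
                                            levels = jm$ids)),
                  modeStateOf, integer(1))
  trajectories <- data.frame(trajectory_id = jm$ids,
                             mode_state = as.integer(modes),
                             n_jumps = jm$nJumps)
  props <- tabulate(trajectories$mode_state, K) / nrow(trajectories)
  jprops <- tabulate(jumps$state, K) / nrow(jumps)
  new("StateAssignment", jumps = jumps, trajectories = trajectories,
      proportions = props, jumpProportions = jprops, K = as.integer(K))
}

#' Summarize state populations across nuclei
#'
#' Per-nucleus mode-state proportions, then across-nucleus mean and sd,
#' with per-state mean diffusion coefficients when fitted models are
#' supplied.
#'
#' @param assignments named list of \linkS4class{StateAssignment}, one per
#'   nucleus.
#' @param hmms optional named list of \linkS4class{DiffusionHMM} matching
#'   \code{assignments}.
#' @return data.frame with one row per state: \code{state},
#'   \code{mean_proportion}, \code{sd_proportion} and (when \code{hmms}
#'   given) \code{mean_D}, \code{sd_D}.
#' @export
populationSummary <- function(assignments, hmms = NULL) {
  if (!length(assignments)) stop("need at least one nucleus")
  K <- assignments[[1L]]@K
  P <- t(vapply(assignments, stateProportions, numeric(K)))
  out <- data.frame(state = seq_len(K),
                    mean_proportion = colMeans(P),
                    sd_proportion = apply(P, 2L, stats::sd))
  if (!is.null(hmms)) {
    Dm <- t(vapply(hmms, diffusionCoefficients, numeric(K)))
    out$mean_D <- colMeans(Dm)
    out$sd_D <- apply(Dm, 2L, stats::sd)
  }
  out
}
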