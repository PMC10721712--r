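# Cache of Monte-Carlo null quantile tables for the three-decision test,
# keyed by "n=<n>;M=<M>;alpha-free" (quantiles stored, alpha applied later).
.nullTableCache <- new.env(parent = emptyenv())

#' Per-trajectory diffusion coefficient (lag-1 estimator)
#'
#' D_hat = max(0, MSD(lag 1) / (4 dt) - sigmaLoc^2 / dt): the mean squared
#' one-frame displacement, corrected for the localization-noise floor and
#' floored at zero.
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param sigmaLoc localization error sigma (um); set 0 to skip the noise
#'   correction.
#' @return data.frame: \code{trajectory_id}, \code{D_traj} (um^2/s),
#'   \code{n} (localizations).
#' @export
estimateTrajDiffusion <- function(ts, sigmaLoc = 0.020) {
  jm <- jumpMatrix(ts)
  msd <- rowMeans(jm$R2, na.rm = TRUE)
  dt <- frameInterval(ts)
  data.frame(trajectory_id = jm$ids,
             D_traj = pmax(msd / (4 * dt) - sigmaLoc^2 / dt, 0),
             n = jm$nJumps + 1L)
}

# Monte-Carlo null quantiles of the max-excursion statistic for Brownian
# trajectories. The statistic is T = max_i ||X_i - X_0|| / sqrt(D_hat n
# dt) with D_hat the (uncorrected) lag-1 estimator, so its null law is
# free of D and dt and depends only on the track length n. All lengths up
# to nMax are calibrated in one incremental pass over M simulated tracks
# (running excursion maximum and running jump-variance estimate), under a
# fixed internal seed so reruns are bit-stable. A fine quantile grid is
# cached per length.
.nullProbGrid <- seq(0, 1, by = 5e-4)

nullExcursionQuantiles <- function(nMax, M = 1e5L) {
  key <- paste0("M=", M)
  cached <- .nullTableCache[[key]]
  if (!is.null(cached) && nrow(cached) >= nMax)
    return(cached)
  nMax <- max(nMax, 64L)                  # build headroom in one go
  Q <- matrix(NA_real_, nMax, length(.nullProbGrid))
  withLocalSeed(771003L, {
    x <- y <- sumr2 <- excmax <- numeric(M)
    for (n in 2:nMax) {
      dx <- stats::rnorm(M); dy <- stats::rnorm(M)
      x <- x + dx; y <- y + dy
      sumr2 <- sumr2 + dx^2 + dy^2
      excmax <- pmax(excmax, sqrt(x^2 + y^2))
      Dhat <- sumr2 / (4 * (n - 1))       # dt = 1
      Q[n, ] <- stats::quantile(excmax / sqrt(Dhat * n), .nullProbGrid,
                                names = FALSE)
    }
  })
  .nullTableCache[[key]] <- Q
  Q
}

nullExcursionQuantile <- function(n, prob, M = 1e5L) {
  Q <- nullExcursionQuantiles(n, M)
  stats::approx(.nullProbGrid, Q[n, ], xout = prob, rule = 2)$y
}

#' Three-decision motion-type test
#'
#' Nonparametric classification of a trajectory as Brownian,
#' sub-diffusive or super-diffusive. The statistic is the maximum
#' excursion from the start, T = max_i ||X_i - X_0|| / sqrt(D_hat n dt),
#' compared against Monte-Carlo null quantiles q_{alpha/2} and
#' q_{1-alpha/2} tabulated per trajectory length from \code{M} simulated
#' Brownian tracks: below the lower quantile the trajectory explores less
#' space than Brownian motion (sub-diffusive), above the upper quantile
#' more (super-diffusive). D_hat is the plain lag-1 estimator (no noise
#' subtraction) to match the calibration.
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param alpha test level (default 0.05).
#' @param minLength trajectories shorter than this many localizations are
#'   left unclassified (default 5).
#' @param M Monte-Carlo null sample size per trajectory length.
#' @return data.frame: \code{trajectory_id}, \code{D_traj},
#'   \code{motion_class} (factor brownian/subdiffusive/superdiffusive, NA
#'   when unclassified), \code{T} (statistic), \code{n}.
#' @export
threeDecisionTest <- function(ts, alpha = 0.05, minLength = 5L, M = 1e5L) {
  df <- orderLocs(localizations(ts))
  dt <- frameInterval(ts)
  sp <- split(df, df$trajectory_id)
  ids <- names(sp)
  n <- vapply(sp, nrow, integer(1))
  Tstat <- rep(NA_real_, length(sp))
  Dplain <- rep(NA_real_, length(sp))
  cls <- rep(NA_character_, length(sp))
  if (any(n >= minLength))
    nullExcursionQuantiles(max(n[n >= minLength]), M = M)  # one build
  for (i in seq_along(sp)) {
    P <- sp[[i]]
    dx <- diff(P$x); dy <- diff(P$y)
    Dplain[i] <- mean(dx^2 + dy^2) / (4 * dt)
    if (n[i] < minLength || Dplain[i] <= 0) next
    exc <- sqrt((P$x - P$x[1L])^2 + (P$y - P$y[1L])^2)
    Tstat[i] <- max(exc) / sqrt(Dplain[i] * n[i] * dt)
    qlo <- nullExcursionQuantile(n[i], alpha / 2, M = M)
    qhi <- nullExcursionQuantile(n[i], 1 - alpha / 2, M = M)
    cls[i] <- if (Tstat[i] < qlo) "subdiffusive"
      else if (Tstat[i] > qhi) "superdiffusive" else "brownian"
  }
  data.frame(trajectory_id = ids,
             D_traj = Dplain,
             motion_class = factor(cls, levels = c("brownian",
                                                   "subdiffusive",
                                                   "superdiffusive")),
             T = Tstat, n = n, row.names = NULL)
}

#' Classify all trajectories and summarize per nucleus
#'
#' Runs the three-decision test and the per-trajectory diffusion
#' estimator, then reports per-class proportions (over classified
#' trajectories) and mean noise-corrected diffusion coefficients.
#'
#' @inheritParams threeDecisionTest
#' @param sigmaLoc localization error for the reported D (um).
#' @return list with \code{table} (per-trajectory results, including the
#'   noise-corrected \code{D_corr}) and \code{summary} (per-class
#'   proportion and mean D).
#' @export
classifyAll <- function(ts, alpha = 0.05, sigmaLoc = 0.020,
                        minLength = 5L, M = 1e5L) {
  res <- threeDecisionTest(ts, alpha = alpha, minLength = minLength, M = M)
  Dcorr <- estimateTrajDiffusion(ts, sigmaLoc = sigmaLoc)
  res$D_corr <- Dcorr$D_traj[match(res$trajectory_id,
                                   Dcorr$trajectory_id)]
  ok <- !is.na(res$motion_class)
  prop <- table(res$motion_class[ok]) / sum(ok)
  meanD <- tapply(res$D_corr[ok], res$motion_class[ok], mean)
  list(table = res,
       summary = data.frame(motion_class = names(prop),
                            proportion = as.numeric(prop),
                            mean_D = as.numeric(meanD)))
}
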