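#' Barycentres of bound trajectories
#'
#' One point per bound trajectory: the mean of its localizations. Bound
#' trajectories are those whose mode state falls in \code{boundStates}
#' (by default the two slowest states).
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param assignment a \linkS4class{StateAssignment}.
#' @param boundStates integer state labels regarded as bound (default
#'   c(1, 2)).
#' @return matrix (n x 2) of barycentre coordinates (um), rownames =
#'   trajectory ids.
#' @export
trajectoryBarycentres <- function(ts, assignment, boundStates = c(1L, 2L)) {
  md <- modeStates(assignment)
  keep <- md$trajectory_id[md$mode_state %in% boundStates]
  if (!length(keep)) stop("no bound trajectories (states ",
                          paste(boundStates, collapse = ","), ")")
  df <- localizations(ts)
  df <- df[df$trajectory_id %in% keep, , drop = FALSE]
  bx <- tapply(df$x, df$trajectory_id, mean)
  by <- tapply(df$y, df$trajectory_id, mean)
  out <- cbind(x = as.numeric(bx), y = as.numeric(by))
  rownames(out) <- names(bx)
  out
}

#' k-th nearest-neighbour distances
#'
#' Euclidean distance of every point to its k-th nearest neighbour (self
#' excluded).
#'
#' @param points matrix (n x 2).
#' @param k neighbour order (default 11).
#' @return numeric vector of length n.
#' @export
knnDistances <- function(points, k = 11L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < k + 1L) stop("need at least k + 1 = ", k + 1L, " points")
  dd <- as.matrix(stats::dist(points))
  diag(dd) <- Inf
  unname(apply(dd, 1L, function(r) sort.int(r, partial = k)[k]))
}

# log density of the kNN-distance law of a homogeneous Poisson process of
# intensity lambda: D_k^2 ~ Gamma(k, rate = lambda * pi), so
# g(d) = 2 (lambda pi)^k d^(2k - 1) exp(-lambda pi d^2) / (k - 1)!
logKnnDensity <- function(d, k, lambda) {
  lr <- log(lambda * pi)
  k * lr + log(2) + (2 * k - 1) * log(d) - lambda * pi * d^2 - lgamma(k)
}

#' Fit the two-component Poisson mixture over kNN distances by EM
#'
#' Models the k-th NN distances as a mixture
#' p g(d; lambda1) + (1 - p) g(d; lambda2) of the transformed-gamma kNN
#' laws of two homogeneous Poisson processes (clustered points see a high
#' local intensity lambda1, clutter a low intensity lambda2). The E step
#' computes posterior responsibilities; the M step is closed form:
#' lambda_j = k sum(w_j) / (pi sum(w_j d^2)), p = mean responsibility.
#' Initialization from the 25th/75th distance percentiles; convergence at
#' a log-likelihood change below \code{tol} or \code{maxIter} iterations.
#' Components are ordered so lambda1 > lambda2. When the two fitted
#' intensities are within a factor 3 the data are effectively unimodal
#' (a forced split of one-component data settles near a ratio of 2) and
#' the model is flagged degenerate.
#'
#' @param distances numeric vector of kNN distances (>= 50 points).
#' @param k neighbour order the distances were computed with.
#' @param points optional (n x 2) coordinate matrix stored in the result.
#' @param tol convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations (default 1000).
#' @return A \linkS4class{ClusterModel}.
#' @export
fitKnnMixtureEM <- function(distances, k = 11L, points = NULL,
                            tol = 1e-8, maxIter = 1000L) {
  d <- as.numeric(distances)
  if (length(d) < 50L) stop("need at least 50 points for the mixture fit")
  if (any(d <= 0)) stop("distances must be positive")
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  # E[D_k^2] = k / (lambda pi) => moment-style inits from the quantiles
  lam <- c(k / (pi * q[1L]^2), k / (pi * q[2L]^2))
  p <- 0.5
  ll <- -Inf
  iter <- 0L
  repeat {
    l1 <- logKnnDensity(d, k, lam[1L]) + log(p)
    l2 <- logKnnDensity(d, k, lam[2L]) + log1p(-p)
    m <- pmax(l1, l2)
    den <- exp(l1 - m) + exp(l2 - m)
    llNew <- sum(m + log(den))
    w <- exp(l1 - m) / den
    if (is.finite(ll) && llNew - ll < tol) { ll <- llNew; break }
    ll <- llNew
    iter <- iter + 1L
    if (iter > maxIter) break
    s1 <- sum(w); s2 <- sum(1 - w)
    lam <- c(k * s1 / (pi * sum(w * d^2)),
             k * s2 / (pi * sum((1 - w) * d^2)))
    p <- s1 / length(d)
  }
  if (lam[1L] < lam[2L]) {      # canonical order: lambda1 > lambda2
    lam <- rev(lam)
    p <- 1 - p
    w <- 1 - w
  }
  degenerate <- lam[1L] / lam[2L] < 3
  new("ClusterModel", k = as.integer(k), p = p, lambda = lam,
      posterior = w, clustered = w > 0.5, distances = d,
      points = if (is.null(points)) matrix(numeric(0), 0L, 2L)
               else as.matrix(points),
      logLik = ll, degenerate = degenerate)
}

#' Identify clusters of bound-trajectory barycentres
#'
#' Convenience wrapper: barycentres of bound trajectories, k-th NN
#' distances, and the mixture EM.
#'
#' @inheritParams trajectoryBarycentres
#' @param k neighbour order (default 11).
#' @return A \linkS4class{ClusterModel}.
#' @export
clusterBoundTrajectories <- function(ts, assignment,
                                     boundStates = c(1L, 2L), k = 11L) {
  pts <- trajectoryBarycentres(ts, assignment, boundStates)
  fitKnnMixtureEM(knnDistances(pts, k), k = k, points = pts)
}

#' Flag diffusive jumps near bound clusters
#'
#' A diffusive jump is "near-cluster" when its starting localization lies
#' within \code{radius} of any clustered barycentre.
#'
#' @param jumpStarts matrix (n x 2) of jump starting positions (um).
#' @param clusteredPoints matrix of clustered barycentres.
#' @param radius search radius in um (default 0.550).
#' @return logical vector per jump; all FALSE (with a warning) when no
#'   clustered points exist.
#' @export
nearClusterJumps <- function(jumpStarts, clusteredPoints, radius = 0.550) {
  jumpStarts <- as.matrix(jumpStarts)
  if (is.null(clusteredPoints) || nrow(as.matrix(clusteredPoints)) == 0L) {
    warning("no clustered points; all jumps flagged away")
    return(rep(FALSE, nrow(jumpStarts)))
  }
  minCrossDist(jumpStarts, clusteredPoints) <= radius
}

#' Anisotropic proportions among near- and away-cluster jumps
#'
#' Fraction of turning angles flagged anisotropic within the near and the
#' away group, plus the fraction of all anisotropic angles that are near.
#'
#' @param anisotropic logical vector (from [flagAnisotropicJumps()]).
#' @param near logical vector of the same length.
#' @return list with \code{near}, \code{away} (anisotropic fraction per
#'   group; \code{NaN} for an empty group) and \code{nearShare} (fraction
#'   of anisotropic angles that are near).
#' @export
anisotropicProportion <- function(anisotropic, near) {
  stopifnot(length(anisotropic) == length(near))
  pn <- if (any(near)) mean(anisotropic[near]) else NaN
  pa <- if (any(!near)) mean(anisotropic[!near]) else NaN
  share <- if (any(anisotropic)) mean(near[anisotropic]) else NaN
  list(near = pn, away = pa, nearShare = share)
}

#' Shifted-cluster randomization control
#'
#' Null reference for the near-cluster anisotropy: all clustered points
#' are translated by one common random vector, the translation is
#' accepted when at least \code{containment} of the shifted points stay
#' inside the region of interest (the convex hull of the diffusive jump
#' starts), and the near-anisotropy proportion is recomputed against the
#' shifted clusters. The procedure attempts \code{nControl} translations
#' and averages over the accepted ones.
#'
#' @param clusteredPoints matrix of clustered barycentres (um).
#' @param jumpStarts matrix of diffusive jump starting positions.
#' @param anisotropic logical per jump angle (aligned with
#'   \code{jumpStarts}).
#' @param roi a \linkS4class{NucleusROI}; default = convex hull of
#'   \code{jumpStarts}.
#' @param radius near radius in um.
#' @param nControl attempted translations (default 100).
#' @param containment acceptance threshold (default 0.8).
#' @param seed integer seed.
#' @param shifts optional matrix of translation vectors (one row per
#'   attempt) replacing the random draws; row c(0, 0) reproduces the
#'   unshifted analysis exactly.
#' @return list with \code{mean} (mean control near-anisotropy
#'   proportion), \code{values} (per accepted repeat), \code{nAccepted}
#'   and \code{nAttempted}.
#' @export
shiftedClusterControl <- function(clusteredPoints, jumpStarts, anisotropic,
                                  roi = NULL, radius = 0.550,
                                  nControl = 100L, containment = 0.8,
                                  seed = NULL, shifts = NULL) {
  clusteredPoints <- as.matrix(clusteredPoints)
  jumpStarts <- as.matrix(jumpStarts)
  stopifnot(nrow(jumpStarts) == length(anisotropic))
  if (is.null(roi)) roi <- nucleusROI(jumpStarts)
  bb <- apply(roi@hull, 2L, range)
  cen <- colMeans(clusteredPoints)
  if (!is.null(shifts)) nControl <- nrow(shifts)
  withLocalSeed(seed, {
    vals <- numeric(0)
    for (i in seq_len(nControl)) {
      shift <- if (is.null(shifts))
        c(stats::runif(1, bb[1L, 1L], bb[2L, 1L]),
          stats::runif(1, bb[1L, 2L], bb[2L, 2L])) - cen
      else shifts[i, ]
      moved <- sweep(clusteredPoints, 2L, shift, "+")
      if (mean(pointsInROI(moved, roi)) < containment) next
      nearC <- minCrossDist(jumpStarts, moved) <= radius
      p <- anisotropicProportion(anisotropic, nearC)$near
      if (is.finite(p)) vals <- c(vals, p)
    }
    if (!length(vals)) stop("control failure: no accepted translations")
    list(mean = mean(vals), values = vals, nAccepted = length(vals),
         nAttempted = as.integer(nControl))
  })
}
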