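#' Detect the marked target locus in a marker image
#'
#' Gaussian-smooths the locus channel, thresholds it with Otsu's method
#' and keeps the largest connected foreground component as the locus
#' mask. Smaller components are discarded and counted.
#'
#' @param image numeric matrix (rows = y, cols = x), e.g. from
#'   [readLocusImage()].
#' @param pixelSize um per pixel.
#' @param smoothSigma Gaussian smoothing sigma in um (default one pixel).
#' @return A \linkS4class{LocusRegion}.
#' @export
detectLocus <- function(image, pixelSize = 0.110,
                        smoothSigma = pixelSize) {
  img <- as.matrix(image)
  rng <- range(img)
  if (diff(rng) == 0) stop("no locus found: image is constant")
  img <- (img - rng[1L]) / diff(rng)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                          sigma = smoothSigma / pixelSize))
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  fg <- sm > thr
  if (!any(fg)) stop("no locus found: empty foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  mask <- lab == biggest
  # image matrix is (y, x); centroid in um, pixel-centre convention
  ij <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(ij[, 2L]) - 0.5, mean(ij[, 1L]) - 0.5) * pixelSize
  new("LocusRegion", mask = mask, pixelSize = pixelSize,
      centroid = centroid, area = sum(mask) * pixelSize^2,
      nDiscarded = as.integer(length(sizes) - 1L))
}

# Distance (um) of points to the locus mask (0 inside), via a distance
# transform of the background so each query is a pixel lookup.
distanceToLocus <- function(xy, locus) {
  px <- locus@pixelSize
  dm <- EBImage::distmap(EBImage::Image(1 - locus@mask * 1)) * px
  dm <- matrix(as.numeric(dm), nrow(locus@mask), ncol(locus@mask))
  row <- pmin(pmax(floor(xy[, 2L] / px) + 1L, 1L), nrow(dm))
  col <- pmin(pmax(floor(xy[, 1L] / px) + 1L, 1L), ncol(dm))
  dm[cbind(row, col)]
}

#' Segregate trajectories into near- and away-locus groups
#'
#' A trajectory is "near" when any of its localizations lies within
#' \code{nearRadius} of the locus mask (Euclidean distance to the nearest
#' mask pixel; zero inside the mask); all other trajectories are "away".
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param locus a \linkS4class{LocusRegion}.
#' @param nearRadius distance threshold in um (default 0.550).
#' @return data.frame: \code{trajectory_id}, \code{group} (factor
#'   near/away), \code{min_dist} (um, closest approach to the mask).
#' @export
segregateNearAway <- function(ts, locus, nearRadius = 0.550) {
  df <- localizations(ts)
  d <- distanceToLocus(cbind(df$x, df$y), locus)
  mind <- tapply(d, df$trajectory_id, min)
  data.frame(trajectory_id = names(mind),
             group = factor(ifelse(mind <= nearRadius, "near", "away"),
                            levels = c("near", "away")),
             min_dist = as.numeric(mind), row.names = NULL)
}

# Area (um^2) of the near region: mask dilated by nearRadius, computed on
# the pixel grid via the distance transform.
nearRegionArea <- function(locus, nearRadius = 0.550) {
  px <- locus@pixelSize
  dm <- EBImage::distmap(EBImage::Image(1 - locus@mask * 1)) * px
  sum(dm <= nearRadius) * px^2
}

#' Locus enrichment ratio
#'
#' Fold increase of near-locus trajectory density over whole-nucleus
#' density: \code{(nNear / nTotal) * (nucleusArea / nearArea)}. Equals 1
#' when trajectories are spatially uniform. \code{nearArea} should be the
#' area of the \code{nearRadius}-dilated locus region so that the uniform
#' null is exactly 1.
#'
#' @param nNear number of near-locus trajectories.
#' @param nTotal total trajectories in the nucleus.
#' @param nearArea area of the near region (um^2).
#' @param nucleusArea nucleus area (um^2).
#' @return the dimensionless ratio.
#' @export
enrichmentRatio <- function(nNear, nTotal, nearArea, nucleusArea) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nearArea <= 0 || nucleusArea <= 0) stop("areas must be positive")
  (nNear / nTotal) * (nucleusArea / nearArea)
}

#' Relative near-minus-away difference
#'
#' \code{(near - away) / away}, applied per state-population proportion or
#' per motion-class diffusion coefficient; positive values indicate
#' enrichment (or faster diffusion) near the locus.
#'
#' @param metricNear,metricAway numeric vectors of matching length.
#' @return numeric vector; \code{NaN} where \code{metricAway} is 0.
#' @export
nearAwayRelative <- function(metricNear, metricAway) {
  out <- (metricNear - metricAway) / metricAway
  out[metricAway == 0] <- NaN
  out
}

#' Full near/away locus analysis for one nucleus
#'
#' Segregates trajectories at \code{nearRadius}, computes the enrichment
#' ratio (near-region density over nuclear density) and the relative
#' near-away difference of the mode-state population proportions.
#'
#' @inheritParams segregateNearAway
#' @param assignment a \linkS4class{StateAssignment} for the same set.
#' @return list with \code{groups} (per-trajectory labels),
#'   \code{ratio}, \code{counts}, \code{areas} and
#'   \code{relativeProportions} (per state).
#' @export
locusAnalysis <- function(ts, locus, assignment, nearRadius = 0.550) {
  gr <- segregateNearAway(ts, locus, nearRadius)
  df <- localizations(ts)
  roi <- nucleusROI(cbind(df$x, df$y))
  nearArea <- nearRegionArea(locus, nearRadius)
  nNear <- sum(gr$group == "near")
  ratio <- enrichmentRatio(nNear, nrow(gr), nearArea, roi@area)
  md <- modeStates(assignment)
  grp <- gr$group[match(md$trajectory_id, gr$trajectory_id)]
  K <- assignment@K
  pNear <- tabulate(md$mode_state[grp == "near"], K)
  pAway <- tabulate(md$mode_state[grp == "away"], K)
  pNear <- pNear / max(sum(pNear), 1L)
  pAway <- pAway / max(sum(pAway), 1L)
  list(groups = gr, ratio = ratio,
       counts = c(near = nNear, total = nrow(gr)),
       areas = c(near = nearArea, nucleus = roi@area),
       proportions = data.frame(state = seq_len(K), near = pNear,
                                away = pAway,
                                relative = nearAwayRelative(pNear, pAway)))
}
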