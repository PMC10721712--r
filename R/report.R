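#' Kernel density map of trajectory barycentres
#'
#' Gaussian-kernel density of the per-trajectory mean positions on a
#' regular grid covering the nucleus, in units of trajectories per
#' 0.0001 um^2 (i.e. integrating the map over the nucleus recovers the
#' trajectory count).
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param bandwidth Gaussian kernel sd in um (default 0.440).
#' @param gridSize grid points per axis (default 128).
#' @param pad um of padding beyond the data range (default 4 bandwidths,
#'   so the kernel mass is retained on the grid).
#' @return list with \code{x}, \code{y} (grid coordinates, um) and
#'   \code{z} (density matrix, trajectories per 0.0001 um^2).
#' @export
densityMap <- function(ts, bandwidth = 0.440, gridSize = 128L,
                       pad = 4 * bandwidth) {
  df <- localizations(ts)
  if (!nrow(df)) stop("empty TrajectorySet")
  bx <- tapply(df$x, df$trajectory_id, mean)
  by <- tapply(df$y, df$trajectory_id, mean)
  n <- length(bx)
  lims <- c(range(bx) + c(-pad, pad), range(by) + c(-pad, pad))
  # MASS::kde2d parameterizes h so the kernel sd is h/4
  kd <- MASS::kde2d(as.numeric(bx), as.numeric(by), h = 4 * bandwidth,
                    n = gridSize, lims = lims)
  list(x = kd$x, y = kd$y, z = kd$z * n * 1e-4)
}

#' Group comparison with automatic test selection
#'
#' Shapiro-Wilk normality at 0.05 on each sample decides the test: both
#' normal gives a two-sample t test (Welch when Bartlett rejects equal
#' variances at 0.05), otherwise Mann-Whitney U. For paired data: paired
#' t or Wilcoxon signed-rank. Constant samples force the rank test with a
#' warning. Significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param a,b numeric samples (>= 3 values each).
#' @param paired logical.
#' @return data.frame with \code{test}, \code{statistic}, \code{p} and
#'   \code{stars}.
#' @export
groupStats <- function(a, b, paired = FALSE) {
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 values per sample")
  constant <- stats::sd(a) == 0 || stats::sd(b) == 0 ||
    (paired && stats::sd(a - b) == 0)
  normal <- FALSE
  if (constant) {
    warning("constant sample(s): rank test forced")
  } else {
    normal <- stats::shapiro.test(a)$p.value >= 0.05 &&
      stats::shapiro.test(b)$p.value >= 0.05
  }
  if (paired) {
    if (normal) {
      tt <- stats::t.test(a, b, paired = TRUE)
      res <- list(test = "paired t", statistic = unname(tt$statistic),
                  p = tt$p.value)
    } else {
      wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
      res <- list(test = "wilcoxon signed-rank",
                  statistic = unname(wt$statistic), p = wt$p.value)
    }
  } else if (normal) {
    eqv <- stats::bartlett.test(list(a, b))$p.value >= 0.05
    tt <- stats::t.test(a, b, var.equal = eqv)
    res <- list(test = if (eqv) "t" else "welch t",
                statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    res <- list(test = "mann-whitney", statistic = unname(wt$statistic),
                p = wt$p.value)
  }
  stars <- if (res$p < 0.001) "***" else if (res$p < 0.01) "**"
    else if (res$p < 0.05) "*" else "ns"
  data.frame(test = res$test, statistic = res$statistic, p = res$p,
             stars = stars)
}

#' Run the full analysis pipeline on one nucleus
#'
#' Orchestrates the stages end to end: state segmentation (model
#' selection up to \code{config$KMax} or a fixed K), decoding, motion
#' classification, jump/angle geometry, locus segregation and enrichment
#' (when a locus image is given; skipped with a notice otherwise), bound
#' cluster analysis with the shifted-cluster control, and a density map.
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param config an [analysisConfig()] list.
#' @param locusImage optional list from [readLocusImage()].
#' @param K fixed number of states; NULL selects K up to
#'   \code{config$KMax}.
#' @param outDir optional directory; when given, result tables and a
#'   manifest are written with [writeResults()].
#' @return list of stage results (hmm, assignment, motion, jumpTable,
#'   profile, locus, clusters, control, densityMap, summary tables).
#' @export
runPipeline <- function(ts, config = analysisConfig(), locusImage = NULL,
                        K = NULL, outDir = NULL) {
  seed <- config$rngSeed
  if (is.null(K)) {
    sel <- selectModel(ts, KMax = config$KMax, sigmaLoc = config$sigmaLoc,
                       seed = seed)
    hmm <- sel$fits[[sel$K]]
  } else {
    sel <- NULL
    hmm <- fitHMM(ts, K, sigmaLoc = config$sigmaLoc, seed = seed)
  }
  assignment <- decodeStates(hmm, ts)
  Kfit <- hmm@K
  fastStates <- if (Kfit >= 2L) c(Kfit - 1L, Kfit) else Kfit
  boundStates <- if (Kfit >= 2L) c(1L, min(2L, Kfit - 1L)) else 1L

  motion <- classifyAll(ts, sigmaLoc = config$sigmaLoc)
  jt <- computeJumpTable(ts, assignment)
  profile <- tryCatch(
    anisotropyVsDisplacement(jt, states = fastStates,
                             dispRange = config$dispRange,
                             window = config$anisWindow,
                             nBoot = config$nBoot,
                             bootFrac = config$bootFrac,
                             seed = seed),
    error = function(e) NULL)

  locus <- NULL
  if (!is.null(locusImage)) {
    loc <- detectLocus(locusImage$image, pixelSize = locusImage$pixelSize)
    locus <- locusAnalysis(ts, loc, assignment,
                           nearRadius = config$nearRadius)
  } else {
    message("no locus image supplied; locus stage skipped")
  }

  clusters <- tryCatch(
    clusterBoundTrajectories(ts, assignment, boundStates = boundStates,
                             k = config$kNN),
    error = function(e) NULL)
  control <- NULL
  anis <- NULL
  if (!is.null(clusters) && any(clusteredFlags(clusters))) {
    ang <- jt@angles
    ang <- ang[!is.na(ang$state1) & ang$state1 %in% fastStates &
                 !is.na(ang$state2) & ang$state2 %in% fastStates, ,
               drop = FALSE]
    if (nrow(ang)) {
      df <- orderLocs(localizations(ts))
      key <- paste(df$trajectory_id,
                   stats::ave(df$frame, df$trajectory_id, FUN = seq_along))
      # jump angle i sits at the i-th localization + 1 of its trajectory;
      # use the shared localization of the two jumps as the jump start
      starts <- df[match(paste(ang$trajectory_id, ang$angle_index + 1L),
                         key), c("x", "y")]
      flags <- flagAnisotropicJumps(ang$theta, config$anisWindow)
      cl <- clusters@points[clusteredFlags(clusters), , drop = FALSE]
      nearC <- nearClusterJumps(starts, cl, radius = config$nearRadius)
      anis <- anisotropicProportion(flags, nearC)
      control <- tryCatch(
        shiftedClusterControl(cl, as.matrix(starts), flags,
                              radius = config$nearRadius,
                              nControl = config$nControl,
                              containment = config$containmentFrac,
                              seed = seed),
        error = function(e) NULL)
    }
  }

  dm <- densityMap(ts, bandwidth = config$kdeBandwidth)

  tables <- list(
    per_trajectory = merge(modeStates(assignment), motion$table,
                           by = "trajectory_id"),
    per_jump = assignment@jumps,
    state_proportions = data.frame(
      state = seq_len(Kfit),
      proportion = stateProportions(assignment),
      jump_proportion = stateProportions(assignment, perJump = TRUE),
      D = diffusionCoefficients(hmm)),
    motion_summary = motion$summary)
  if (!is.null(locus)) tables$locus_proportions <- locus$proportions
  if (!is.null(outDir))
    writeResults(tables, outDir, config = unclass(config), seed = seed)

  list(hmm = hmm, selection = sel, assignment = assignment,
       motion = motion, jumpTable = jt, profile = profile, locus = locus,
       clusters = clusters, anisotropy = anis, control = control,
       densityMap = dm, tables = tables)
}
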