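#' Accessors for TrajectorySet
#'
#' @param object a \linkS4class{TrajectorySet}.
#' @return \code{frameInterval}: the frame interval in seconds;
#'   \code{localizations}: the long-format localization data.frame;
#'   \code{trajectoryIds}: character vector of ids;
#'   \code{nTrajectories}: trajectory count.
#' @name TrajectorySet-accessors
NULL

#' @rdname TrajectorySet-accessors
#' @export
setMethod("frameInterval", "TrajectorySet", function(object)
  object@frameInterval)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("localizations", "TrajectorySet", function(object) object@locs)

#' @rdname TrajectorySet-accessors
#' @export
setMethod("trajectoryIds", "TrajectorySet", function(object)
  unique(object@locs$trajectory_id))

#' @rdname TrajectorySet-accessors
#' @export
setMethod("nTrajectories", "TrajectorySet", function(object)
  length(unique(object@locs$trajectory_id)))

setMethod("show", "TrajectorySet", function(object) {
  cat("TrajectorySet with", nTrajectories(object), "trajectories,",
      nrow(object@locs), "localizations\n")
  cat("  frame interval:", object@frameInterval, "s   nucleus:",
      object@nucleusId, "\n")
  if (object@dropped > 0L)
    cat("  (", object@dropped, "short trajectories/segments dropped )\n")
})

#' Accessors for DiffusionHMM
#'
#' @param object a \linkS4class{DiffusionHMM}.
#' @return \code{diffusionCoefficients}: per-state D (um^2/s, ascending);
#'   \code{transitionMatrix}: the per-frame K x K transition matrix.
#' @name DiffusionHMM-accessors
NULL

#' @rdname DiffusionHMM-accessors
#' @export
setMethod("diffusionCoefficients", "DiffusionHMM", function(object) object@D)

#' @rdname DiffusionHMM-accessors
#' @export
setMethod("transitionMatrix", "DiffusionHMM", function(object) object@A)

setMethod("show", "DiffusionHMM", function(object) {
  cat("DiffusionHMM with", object@K, "states\n")
  cat("  D (um^2/s):", paste(signif(object@D, 3), collapse = ", "), "\n")
  cat("  sigma_loc:", object@sigmaLoc, "um   dt:", object@frameInterval,
      "s\n")
  cat("  logLik:", format(object@logLik), " (", object@nIter, "iterations",
      if (object@converged) "converged" else "NOT converged", ")\n")
})

#' Accessors for StateAssignment
#'
#' @param object a \linkS4class{StateAssignment}.
#' @param perJump logical; if TRUE return per-jump state proportions
#'   instead of the default whole-trajectory (mode-state) proportions.
#' @param ... passed on.
#' @return \code{stateProportions}: numeric(K) proportions;
#'   \code{modeStates}: data.frame of per-trajectory mode states.
#' @name StateAssignment-accessors
NULL

#' @rdname StateAssignment-accessors
#' @export
setMethod("stateProportions", "StateAssignment",
  function(object, perJump = FALSE) {
    if (perJump) object@jumpProportions else object@proportions
  })

#' @rdname StateAssignment-accessors
#' @export
setMethod("modeStates", "StateAssignment", function(object)
  object@trajectories)

setMethod("show", "StateAssignment", function(object) {
  cat("StateAssignment over", nrow(object@trajectories), "trajectories,",
      nrow(object@jumps), "jumps,", object@K, "states\n")
  cat("  mode-state proportions:",
      paste(sprintf("%.3f", object@proportions), collapse = ", "), "\n")
})

#' Accessors for ClusterModel
#'
#' @param object a \linkS4class{ClusterModel}.
#' @return \code{clusteredFlags}: logical per point;
#'   \code{clusteredFraction}: fraction of points classified clustered.
#' @name ClusterModel-accessors
NULL

#' @rdname ClusterModel-accessors
#' @export
setMethod("clusteredFlags", "ClusterModel", function(object) object@clustered)

#' @rdname ClusterModel-accessors
#' @export
setMethod("clusteredFraction", "ClusterModel", function(object)
  mean(object@clustered))

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel (k =", object@k, ")\n")
  cat("  p =", signif(object@p, 3), "  lambda1 =", signif(object@lambda[1], 4),
      " lambda2 =", signif(object@lambda[2], 4), "points/um^2\n")
  cat("  clustered points:", sum(object@clustered), "of",
      length(object@clustered),
      if (object@degenerate) "  [degenerate fit]" else "", "\n")
})

setMethod("show", "LocusRegion", function(object) {
  cat("LocusRegion: area", signif(object@area, 4), "um^2, centroid (",
      paste(signif(object@centroid, 4), collapse = ", "), ") um\n")
})

setMethod("show", "AnisotropyProfile", function(object) {
  cat("AnisotropyProfile:", nrow(object@bins), "displacement bins, +/-",
      object@window, "deg windows,", object@nBoot, "bootstrap repeats\n")
  print(object@bins, row.names = FALSE, digits = 3)
})
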