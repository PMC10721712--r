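#' @import methods
NULL

#' TrajectorySet: ordered single-molecule localization sequences
#'
#' The universal currency of the pipeline. Localizations are stored as one
#' long-format data frame with columns \code{trajectory_id}, \code{frame},
#' \code{x}, \code{y} (micrometres) and \code{precision} (per-point
#' localization error sigma, micrometres). Within a trajectory frames are
#' strictly consecutive (the tracker allows no detection gaps) and every
#' trajectory has at least four localizations; constructors enforce both by
#' splitting at gaps and dropping short segments.
#'
#' @slot locs data.frame of localizations (long format, see above).
#' @slot frameInterval numeric(1), frame interval in seconds.
#' @slot nucleusId character(1) label for the nucleus/movie of origin.
#' @slot dropped integer(1), number of trajectories/segments discarded by
#'   the minimum-length filter at construction.
#'
#' @seealso [readTrajectories()], [simulateSwitchingDiffusion()]
#' @export
setClass("TrajectorySet",
  slots = c(
    locs = "data.frame",
    frameInterval = "numeric",
    nucleusId = "character",
    dropped = "integer"
  ),
  prototype = prototype(
    locs = data.frame(
      trajectory_id = character(), frame = integer(),
      x = numeric(), y = numeric(), precision = numeric()
    ),
    frameInterval = 0.05, nucleusId = "nucleus", dropped = 0L
  )
)

setValidity("TrajectorySet", function(object) {
  df <- object@locs
  need <- c("trajectory_id", "frame", "x", "y", "precision")
  if (!all(need %in% names(df)))
    return(paste("locs must have columns", paste(need, collapse = ", ")))
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  if (nrow(df)) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      return("x and y must be finite")
    if (any(df$frame < 0)) return("frames must be >= 0")
    if (any(df$precision <= 0)) return("precision must be > 0")
    len <- tabulate(factor(df$trajectory_id))
    if (any(len < 4L))
      return("every trajectory must have at least 4 localizations")
    bad <- vapply(split(df$frame, df$trajectory_id),
                  function(f) any(diff(f) != 1L), logical(1))
    if (any(bad))
      return(paste0("frames not strictly consecutive in trajectory '",
                    names(bad)[which(bad)[1L]], "'"))
  }
  TRUE
})

#' GroundTruth: latent labels emitted by the simulators
#'
#' Aligns one-to-one with the jumps and trajectories of the
#' \linkS4class{TrajectorySet} the simulator returned: \code{jumps} carries
#' per-jump latent state and trap membership, \code{trajectories} the
#' per-trajectory mode state.
#'
#' @slot jumps data.frame with columns \code{trajectory_id},
#'   \code{jump_index}, \code{state}, \code{in_trap}.
#' @slot trajectories data.frame with columns \code{trajectory_id},
#'   \code{mode_state}.
#' @export
setClass("GroundTruth",
  slots = c(jumps = "data.frame", trajectories = "data.frame"),
  prototype = prototype(
    jumps = data.frame(trajectory_id = character(), jump_index = integer(),
                       state = integer(), in_trap = logical()),
    trajectories = data.frame(trajectory_id = character(),
                              mode_state = integer())
  )
)

#' DiffusionHMM: K-state switching Brownian diffusion model
#'
#' A hidden Markov model over per-trajectory jump sequences. In state s the
#' jump (dx, dy) is isotropic Gaussian with per-axis variance
#' 2 D_s dt + 2 sigma_loc^2; states switch between frames according to a
#' row-stochastic transition matrix. States are canonically ordered by
#' increasing D so that state 1 is the slowest ("bound") population.
#'
#' @slot K integer, number of diffusive states.
#' @slot D numeric(K), diffusion coefficients in um^2/s, ascending.
#' @slot A K x K per-frame transition matrix (rows sum to 1).
#' @slot pi numeric(K), initial state distribution.
#' @slot sigmaLoc numeric(1), localization error (um) used in the emission.
#' @slot frameInterval numeric(1), seconds.
#' @slot logLik numeric(1), maximized log-likelihood (nats).
#' @slot nIter integer(1), EM iterations used.
#' @slot converged logical(1).
#' @export
setClass("DiffusionHMM",
  slots = c(K = "integer", D = "numeric", A = "matrix", pi = "numeric",
            sigmaLoc = "numeric", frameInterval = "numeric",
            logLik = "numeric", nIter = "integer", converged = "logical")
)

setValidity("DiffusionHMM", function(object) {
  K <- object@K
  if (length(object@D) != K) return("length(D) != K")
  if (any(object@D < 0)) return("D must be >= 0")
  if (is.unsorted(object@D)) return("D must be sorted ascending")
  if (!all(dim(object@A) == c(K, K))) return("A must be K x K")
  if (any(abs(rowSums(object@A) - 1) > 1e-8)) return("rows of A must sum to 1")
  if (length(object@pi) != K || abs(sum(object@pi) - 1) > 1e-8)
    return("pi must be a length-K distribution")
  TRUE
})

#' StateAssignment: decoded diffusive-state labels
#'
#' Per-jump posterior-maximum labels, per-trajectory mode states, and the
#' population proportions computed over whole trajectories (mode state),
#' which is the defocalization-robust summary; per-jump proportions are
#' kept alongside for comparison.
#'
#' @slot jumps data.frame: \code{trajectory_id}, \code{jump_index},
#'   \code{state}.
#' @slot trajectories data.frame: \code{trajectory_id}, \code{mode_state},
#'   \code{n_jumps}.
#' @slot proportions numeric(K), fraction of trajectories per mode state.
#' @slot jumpProportions numeric(K), fraction of jumps per state.
#' @slot K integer(1).
#' @export
setClass("StateAssignment",
  slots = c(jumps = "data.frame", trajectories = "data.frame",
            proportions = "numeric", jumpProportions = "numeric",
            K = "integer")
)

#' JumpTable: displacements and turning angles
#'
#' One row per jump (consecutive-localization displacement) and one row per
#' turning angle (triple of consecutive localizations). The turning angle
#' theta is measured between successive jump vectors, signed by the 2D
#' cross product and mapped to [0, 360): 0 means straight continuation,
#' 180 means reversal. Each angle carries the mean of its two adjacent jump
#' lengths as its displacement abscissa.
#'
#' @slot jumps data.frame: \code{trajectory_id}, \code{jump_index},
#'   \code{dx}, \code{dy}, \code{r}, \code{state}.
#' @slot angles data.frame: \code{trajectory_id}, \code{angle_index},
#'   \code{theta}, \code{mean_disp}, \code{state1}, \code{state2}.
#' @export
setClass("JumpTable",
  slots = c(jumps = "data.frame", angles = "data.frame")
)

#' AnisotropyProfile: f(180/0) against displacement with bootstrap errors
#'
#' @slot bins data.frame: \code{lo}, \code{hi}, \code{mid} (um), \code{f},
#'   \code{sd}, \code{n}, \code{masked} (TRUE when fewer than the minimum
#'   number of angles fell in the bin).
#' @slot window numeric(1), angular half-width (degrees) of the
#'   forward/backward windows.
#' @slot nBoot integer(1), bootstrap repeats behind \code{sd}.
#' @export
setClass("AnisotropyProfile",
  slots = c(bins = "data.frame", window = "numeric", nBoot = "integer")
)

#' ClusterModel: two-component Poisson mixture over kNN distances
#'
#' Models k-th nearest-neighbour distances of bound-molecule barycentres as
#' a superposition of two homogeneous Poisson processes: a high-intensity
#' (lambda1) process for clustered points and a low-intensity (lambda2)
#' clutter process. Component law: D_k^2 ~ Gamma(k, lambda * pi).
#'
#' @slot k integer, neighbour order.
#' @slot p numeric(1), mixture weight of the clustered component.
#' @slot lambda numeric(2), intensities (points/um^2), lambda1 > lambda2.
#' @slot posterior numeric, per-point probability of being clustered.
#' @slot clustered logical, hard assignment (posterior > 0.5).
#' @slot distances numeric, the kNN distances that were fitted.
#' @slot points matrix, the (x, y) coordinates (um).
#' @slot logLik numeric(1).
#' @slot degenerate logical(1), TRUE when the two intensities are too close
#'   (lambda1/lambda2 < 2) for the split to be meaningful.
#' @export
setClass("ClusterModel",
  slots = c(k = "integer", p = "numeric", lambda = "numeric",
            posterior = "numeric", clustered = "logical",
            distances = "numeric", points = "matrix",
            logLik = "numeric", degenerate = "logical")
)

#' LocusRegion: segmented target-locus mask
#'
#' @slot mask logical matrix on the image pixel grid (TRUE = locus).
#' @slot pixelSize numeric(1), um per pixel.
#' @slot centroid numeric(2), um (image convention: origin at the corner,
#'   y increasing downward).
#' @slot area numeric(1), um^2.
#' @slot nDiscarded integer(1), smaller foreground components discarded.
#' @export
setClass("LocusRegion",
  slots = c(mask = "matrix", pixelSize = "numeric", centroid = "numeric",
            area = "numeric", nDiscarded = "integer")
)

#' NucleusROI: nuclear region from the convex hull of localizations
#'
#' @slot hull matrix of hull vertices (x, y in um, closed implicitly).
#' @slot area numeric(1), um^2.
#' @export
setClass("NucleusROI", slots = c(hull = "matrix", area = "numeric"))
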