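#' @rdname TrajectorySet-accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("localizations", function(object) standardGeneric("localizations"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("trajectoryIds", function(object) standardGeneric("trajectoryIds"))

#' @rdname TrajectorySet-accessors
#' @export
setGeneric("nTrajectories", function(object) standardGeneric("nTrajectories"))

#' @rdname DiffusionHMM-accessors
#' @export
setGeneric("diffusionCoefficients",
           function(object) standardGeneric("diffusionCoefficients"))

#' @rdname DiffusionHMM-accessors
#' @export
setGeneric("transitionMatrix",
           function(object) standardGeneric("transitionMatrix"))

#' @rdname StateAssignment-accessors
#' @export
setGeneric("stateProportions",
           function(object, ...) standardGeneric("stateProportions"))

#' @rdname StateAssignment-accessors
#' @export
setGeneric("modeStates", function(object) standardGeneric("modeStates"))

#' @rdname ClusterModel-accessors
#' @export
setGeneric("clusteredFlags", function(object) standardGeneric("clusteredFlags"))

#' @rdname ClusterModel-accessors
#' @export
setGeneric("clusteredFraction",
           function(object) standardGeneric("clusteredFraction"))
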