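#' Construct a TrajectorySet from a localization table
#'
#' Validates a long-format localization table, splits trajectories at frame
#' gaps (gap-free tracking is assumed throughout the pipeline) and drops
#' segments shorter than four localizations. Coordinates are micrometres in
#' image convention (origin at the image corner, y increasing downward).
#'
#' @param locs data.frame with columns \code{trajectory_id}, \code{frame},
#'   \code{x}, \code{y} and optionally \code{precision} (um).
#' @param frameInterval frame interval in seconds (e.g. 0.050 or 0.010).
#' @param nucleusId label for the movie/nucleus of origin.
#' @param defaultPrecision localization error sigma (um) used when the
#'   table has no per-point \code{precision} column; default 0.020 um, the
#'   typical sub-pixel precision of Gaussian-fit localization.
#' @param minLength minimum localizations per trajectory (default 4).
#' @return A \linkS4class{TrajectorySet}. The number of dropped short
#'   segments is recorded in the object and reported by \code{show}.
#' @examples
#' df <- data.frame(trajectory_id = "a", frame = 0:4,
#'                  x = c(0, .1, .2, .3, .4), y = 0)
#' trajectorySet(df, frameInterval = 0.05)
#' @export
trajectorySet <- function(locs, frameInterval, nucleusId = "nucleus",
                          defaultPrecision = 0.020, minLength = 4L) {
  need <- c("trajectory_id", "frame", "x", "y")
  miss <- setdiff(need, names(locs))
  if (length(miss))
    stop("localization table is missing columns: ", paste(miss, collapse = ", "))
  locs$trajectory_id <- as.character(locs$trajectory_id)
  locs$frame <- as.integer(locs$frame)
  if (is.null(locs$precision)) locs$precision <- defaultPrecision
  locs$precision[is.na(locs$precision)] <- defaultPrecision
  locs <- orderLocs(locs)

  dup <- vapply(split(locs$frame, locs$trajectory_id),
                function(f) anyDuplicated(f) > 0L, logical(1))
  if (any(dup))
    stop("non-monotone or duplicated frames within trajectory '",
         names(dup)[which(dup)[1L]], "'")

  # split at frame gaps: a new segment starts wherever the frame step != 1
  newtraj <- c(TRUE, locs$trajectory_id[-1L] != locs$trajectory_id[-nrow(locs)] |
                 diff(locs$frame) != 1L)
  seg <- cumsum(newtraj)
  nseg <- max(seg)
  segOfTraj <- split(seg, locs$trajectory_id)
  multi <- vapply(segOfTraj, function(s) length(unique(s)) > 1L, logical(1))
  segid <- locs$trajectory_id
  if (any(multi)) {
    # suffix only trajectories that actually split
    within <- stats::ave(seg, locs$trajectory_id,
                         FUN = function(s) match(s, unique(s)))
    segid <- ifelse(locs$trajectory_id %in% names(multi)[multi],
                    paste0(locs$trajectory_id, ".", within),
                    locs$trajectory_id)
  }
  locs$trajectory_id <- segid

  len <- table(locs$trajectory_id)
  keep <- names(len)[len >= minLength]
  dropped <- length(len) - length(keep)
  locs <- locs[locs$trajectory_id %in% keep, , drop = FALSE]
  rownames(locs) <- NULL
  new("TrajectorySet", locs = locs, frameInterval = frameInterval,
      nucleusId = nucleusId, dropped = as.integer(dropped))
}

#' Read a trajectory table from delimited text
#'
#' Expects a comma-delimited file with header
#' \code{trajectory_id,frame,x_um,y_um[,precision_um]} (or the bare
#' \code{x,y,precision} names). Coordinates may be given in nanometres by
#' setting \code{units = "nm"}.
#'
#' @param path file path.
#' @param frameInterval frame interval in seconds.
#' @param units \code{"um"} (default) or \code{"nm"}.
#' @inheritParams trajectorySet
#' @return A \linkS4class{TrajectorySet}.
#' @export
readTrajectories <- function(path, frameInterval, units = c("um", "nm"),
                             nucleusId = "nucleus",
                             defaultPrecision = 0.020) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(x_um = "x", y_um = "y", precision_um = "precision",
           x_nm = "x", y_nm = "y", precision_nm = "precision")
  for (nm in names(ren))
    if (nm %in% names(df)) names(df)[names(df) == nm] <- ren[[nm]]
  need <- c("trajectory_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file is missing columns: ", paste(miss, collapse = ", "))
  if (units == "nm") {
    df$x <- df$x / 1000
    df$y <- df$y / 1000
    if (!is.null(df$precision)) df$precision <- df$precision / 1000
  }
  trajectorySet(df, frameInterval = frameInterval, nucleusId = nucleusId,
                defaultPrecision = defaultPrecision)
}

#' Write a TrajectorySet as delimited text
#'
#' Inverse of [readTrajectories()]: writes the header
#' \code{trajectory_id,frame,x_um,y_um,precision_um}.
#'
#' @param ts a \linkS4class{TrajectorySet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(ts, path) {
  df <- localizations(ts)
  out <- data.frame(trajectory_id = df$trajectory_id, frame = df$frame,
                    x_um = df$x, y_um = df$y, precision_um = df$precision)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes one CSV per named table plus \code{manifest.json} recording the
#' configuration, seed and file list, enough to reproduce the run.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory (created if needed).
#' @param config optional analysis configuration list stored in the
#'   manifest.
#' @param seed optional integer seed stored in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
writeResults <- function(tables, outDir, config = NULL, seed = NULL) {
  if (!length(tables)) stop("no result tables to write")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(outDir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(files = files, seed = seed, config = config,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   package = as.character(utils::packageVersion("TrackStates")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(manifest)
}

#' Read a single-channel locus-marker image
#'
#' Reads a single-plane grayscale TIFF (the locus channel) into a numeric
#' matrix together with its pixel size so pixel and micrometre coordinates
#' interconvert. Multi-channel or multi-plane images are rejected.
#'
#' @param path TIFF file path.
#' @param pixelSize um per pixel; the acquisition default is 0.110 um.
#'   There is no reliable TIFF metadata convention for pixel size, so it
#'   must be supplied explicitly.
#' @return list with \code{image} (numeric matrix, rows = y, cols = x) and
#'   \code{pixelSize}.
#' @export
readLocusImage <- function(path, pixelSize) {
  if (missing(pixelSize) || is.null(pixelSize))
    stop("pixelSize (um/px) must be supplied; no metadata fallback")
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) != 1L)
    stop("unsupported format: expected a single-plane image, got ",
         length(img), " planes")
  img <- img[[1L]]
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop("unsupported format: multi-channel image")
  }
  list(image = apply(img, 2L, as.numeric), pixelSize = pixelSize)
}

#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline with their standard
#' values: 550 nm near-locus / near-cluster radius, neighbour order k = 11,
#' +/- 30 degree anisotropy windows, the 50-350 nm displacement range for
#' anisotropy profiles, 50 bootstrap subsamples of 50\% of the angles, 100
#' shifted-cluster control repeats with 80\% containment, 440 nm density
#' bandwidth, and a ceiling of four diffusive states.
#'
#' @param nearRadius um, distance threshold for "near" classification.
#' @param kNN neighbour order for the cluster mixture.
#' @param anisWindow degrees, half-width of the forward/backward windows.
#' @param dispRange um, displacement bounds for anisotropy profiles.
#' @param nBoot bootstrap repeats.
#' @param bootFrac bootstrap subsample fraction, in (0, 1].
#' @param nControl shifted-cluster control repeats.
#' @param containmentFrac fraction of shifted points that must stay inside
#'   the ROI for a control translation to be accepted, in (0, 1].
#' @param kdeBandwidth um, Gaussian kernel sd for density maps.
#' @param KMax ceiling on the number of diffusive states.
#' @param sigmaLoc um, localization error.
#' @param pixelSize um per pixel of the locus channel.
#' @param rngSeed integer seed recorded with results.
#' @return A validated list with class \code{"AnalysisConfig"}.
#' @export
analysisConfig <- function(nearRadius = 0.550, kNN = 11L, anisWindow = 30,
                           dispRange = c(0.050, 0.350), nBoot = 50L,
                           bootFrac = 0.5, nControl = 100L,
                           containmentFrac = 0.8, kdeBandwidth = 0.440,
                           KMax = 4L, sigmaLoc = 0.020, pixelSize = 0.110,
                           rngSeed = 1L) {
  cfg <- list(nearRadius = nearRadius, kNN = as.integer(kNN),
              anisWindow = anisWindow, dispRange = dispRange,
              nBoot = as.integer(nBoot), bootFrac = bootFrac,
              nControl = as.integer(nControl),
              containmentFrac = containmentFrac,
              kdeBandwidth = kdeBandwidth, KMax = as.integer(KMax),
              sigmaLoc = sigmaLoc, pixelSize = pixelSize,
              rngSeed = as.integer(rngSeed))
  pos <- c("nearRadius", "anisWindow", "kdeBandwidth", "sigmaLoc",
           "pixelSize")
  for (nm in pos)
    if (cfg[[nm]] <= 0) stop(nm, " must be strictly positive")
  if (cfg$kNN < 1L || cfg$KMax < 1L || cfg$nBoot < 1L || cfg$nControl < 1L)
    stop("counts must be >= 1")
  if (cfg$bootFrac <= 0 || cfg$bootFrac > 1)
    stop("bootFrac must be in (0, 1]")
  if (cfg$containmentFrac <= 0 || cfg$containmentFrac > 1)
    stop("containmentFrac must be in (0, 1]")
  if (length(cfg$dispRange) != 2L || any(cfg$dispRange <= 0) ||
      diff(cfg$dispRange) <= 0)
    stop("dispRange must be two increasing positive numbers")
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysisConfig()]; unknown keys error.
#'
#' @param path YAML file.
#' @return An \code{AnalysisConfig} list.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysisConfig, vals)
}
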