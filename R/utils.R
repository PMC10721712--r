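# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG alone.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Shoelace polygon area for an (n x 2) vertex matrix.
polygonArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull of a 2-column point matrix as a NucleusROI.
#' Nuclear region of interest from localizations
#'
#' Builds the nucleus boundary as the convex hull of a point set and
#' computes its area, the denominator geometry for density normalization.
#'
#' @param xy matrix or data.frame with two columns (x, y in um).
#' @return A \linkS4class{NucleusROI}.
#' @export
nucleusROI <- function(xy) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  if (nrow(xy) < 3L) stop("need at least 3 points for a hull")
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  new("NucleusROI", hull = hull, area = polygonArea(hull))
}

# TRUE for points inside (or on) a convex-hull polygon.
pointsInROI <- function(xy, roi) {
  xy <- as.matrix(xy)
  mgcv::in.out(rbind(roi@hull, roi@hull[1L, ]), xy)
}

# Minimum distance from each row of `a` to any row of `b`, chunked to keep
# memory bounded.
minCrossDist <- function(a, b, chunk = 2000L) {
  a <- as.matrix(a); b <- as.matrix(b)
  out <- numeric(nrow(a))
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a))
    dx <- outer(a[i0:i1, 1L], b[, 1L], "-")
    dy <- outer(a[i0:i1, 2L], b[, 2L], "-")
    out[i0:i1] <- sqrt(apply(dx * dx + dy * dy, 1L, min))
  }
  out
}

# Order localization rows canonically (trajectory, then frame).
orderLocs <- function(df) {
  df[order(df$trajectory_id, df$frame), , drop = FALSE]
}
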