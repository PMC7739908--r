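#' Cell-depleted-layer thickness
#'
#' Operational cell-free-layer detector: for each x-column of a red-cell
#' volume-fraction map, the layer thickness is the distance from the wall to
#' the point where the volume fraction first exceeds a small threshold --
#' by default 1\% of the column's core (maximum) fraction. The crossing is
#' interpolated linearly between the bracketing bin centres and capped at
#' the local lumen half-height. Columns with no red cells at all return the
#' cap and are flagged.
#'
#' @param phi a [BinnedFieldMap-class] of kind \code{"volume_fraction"}.
#' @param wall \code{"glass"} (y = 0 side) or \code{"pdms"} (y = H side).
#' @param thresholdMode \code{"relative"}: threshold is \code{c} times the
#'   column maximum (default, the reading adopted for the 1\% rule);
#'   \code{"absolute"}: threshold is \code{c} itself.
#' @param c threshold fraction, default 0.01.
#' @param geometry optional [ChamberGeometry-class]; when supplied, the
#'   local wall position and lumen height follow the wall contour (so the
#'   layer is measured from the bump surface inside the stenotic section)
#'   and bins outside the lumen are ignored. Without it the map's y-extent
#'   is taken as a straight channel.
#' @return A [CFLProfile-class].
#' @export
cflThickness <- function(phi, wall = c("glass", "pdms"),
                         thresholdMode = c("relative", "absolute"),
                         c = 0.01, geometry = NULL) {
  wall <- match.arg(wall)
  thresholdMode <- match.arg(thresholdMode)
  if (!is(phi, "BinnedFieldMap") || phi@kind != "volume_fraction")
    stopSteno("stenoflowValidationError",
              "'phi' must be a volume_fraction BinnedFieldMap")
  xc <- binCentersX(phi)
  yc <- binCentersY(phi)
  if (is.null(geometry)) {
    yLow <- rep(min(phi@yEdges), length(xc))
    yHigh <- rep(max(phi@yEdges), length(xc))
  } else {
    lb <- lumenBounds(geometry, xc)
    yLow <- lb$yLow; yHigh <- lb$yHigh
  }
  wallY <- if (wall == "glass") yLow else yHigh
  cap <- (yHigh - yLow) / 2
  n <- length(xc)
  delta <- numeric(n)
  flagged <- logical(n)
  V <- phi@values
  for (i in seq_len(n)) {
    inLumen <- yc > yLow[i] & yc < yHigh[i]
    if (!any(inLumen)) { delta[i] <- cap[i]; flagged[i] <- TRUE; next }
    ycol <- yc[inLumen]
    v <- V[i, inLumen]
    dist <- abs(ycol - wallY[i])
    o <- order(dist)
    v <- v[o]; dist <- dist[o]
    ref <- if (thresholdMode == "relative") max(v) else 1
    thr <- c * ref
    above <- which(v > thr)
    if (ref <= 0 || !length(above)) {
      delta[i] <- cap[i]; flagged[i] <- TRUE; next
    }
    k <- above[1L]
    if (k == 1L) {
      # crossing between the wall (phi ~ 0) and the first bin centre
      delta[i] <- dist[1L] * thr / v[1L]
    } else {
      delta[i] <- dist[k - 1L] +
        (thr - v[k - 1L]) / (v[k] - v[k - 1L]) * (dist[k] - dist[k - 1L])
    }
    delta[i] <- min(max(delta[i], 0), cap[i])
  }
  new("CFLProfile", x = xc, delta = delta, wall = wall, threshold = c,
      mode = thresholdMode, flagged = flagged)
}
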