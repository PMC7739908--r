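#' Build an image stack
#'
#' @param frames nz-by-nx-by-nframes numeric array (rows: width/z, columns:
#'   flow/x), intensities in [0, 1], or a list of equally sized matrices.
#' @param timestamps frame times (s).
#' @param pixelSize pixel pitch (m/px).
#' @param modality \code{"WB"} or \code{"PRP"}.
#' @return An [ImageStack-class].
#' @export
imageStack <- function(frames, timestamps, pixelSize, modality) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1L]]), ncol(frames[[1L]]),
                            length(frames)))
  newValidated("ImageStack", "stenoflowValidationError",
               frames = frames, timestamps = timestamps,
               pixelSize = pixelSize, modality = modality)
}

#' Annotate the stenotic-region corners
#'
#' Replaces the interactive corner-clicking step with a coordinate table:
#' four corners for a chamber whose steep ramps collapse to single edges in
#' top view, eight when the contraction and expansion areas are resolved
#' separately. Corners are grouped by their x pixel to derive the
#' contraction/expansion borders; the upstream alignment reference is the
#' right border of the contraction area, i.e. the upstream end of the
#' throat.
#'
#' @param corners data.frame (or 2-column matrix) of pixel coordinates
#'   \code{x}, \code{z}; 4 or 8 rows.
#' @param chamber \code{"vanRooij"} or \code{"casa"}; inferred from the
#'   corner count when missing.
#' @return A [CornerAnnotation-class].
#' @export
cornerAnnotation <- function(corners, chamber = NULL) {
  corners <- as.data.frame(corners)
  names(corners)[1:2] <- c("x", "z")
  nc <- nrow(corners)
  if (is.null(chamber))
    chamber <- switch(as.character(nc), "4" = "vanRooij", "8" = "casa",
      stopSteno("stenoflowAnnotationError",
                "%d corners given; 4 (vanRooij) or 8 (casa) expected", nc))
  ng <- if (chamber == "vanRooij") 2L else 4L
  if (nc != 2L * ng)
    stopSteno("stenoflowAnnotationError",
              "%s annotation requires %d corners, got %d", chamber, 2L * ng, nc)
  o <- order(corners$x)
  gx <- vapply(seq_len(ng), function(k)
    mean(corners$x[o][(2L * k - 1L):(2L * k)]), numeric(1))
  xm <- if (chamber == "vanRooij") {
    c(contraction_start = gx[1L], throat_start = gx[1L],
      throat_end = gx[2L], expansion_end = gx[2L])
  } else {
    c(contraction_start = gx[1L], throat_start = gx[2L],
      throat_end = gx[3L], expansion_end = gx[4L])
  }
  newValidated("CornerAnnotation", "stenoflowAnnotationError",
               corners = corners, chamber = chamber,
               xMarks = xm, upstreamRef = unname(xm["throat_start"]))
}

#' Width-averaged intensity profile of one frame
#'
#' Converts a frame to the normalized mean-intensity curve used for
#' occlusion localization: pixel intensities are averaged over the channel
#' width (the z-pixel span of the annotated corners), PRP profiles are
#' inverted (platelet aggregates darken in PRP, brighten in whole blood),
#' the curve is min-max normalized to [0, 1], and x is re-referenced so the
#' upstream stenotic corner sits at 0. A flat frame cannot be normalized:
#' the profile is zeroed and flagged degenerate.
#'
#' @param stack an [ImageStack-class].
#' @param frame frame index.
#' @param corners a [CornerAnnotation-class].
#' @param modality overrides the stack modality if given.
#' @param invertOrder \code{"before"} (default): invert the raw profile,
#'   then normalize; \code{"after"}: normalize, then reflect. Identical
#'   results up to the min-max convention; both are exposed.
#' @return An [IntensityProfile-class].
#' @export
intensityProfile <- function(stack, frame, corners, modality = NULL,
                             invertOrder = c("before", "after")) {
  invertOrder <- match.arg(invertOrder)
  if (is.null(modality)) modality <- stack@modality
  d <- dim(stack@frames)
  if (frame < 1L || frame > d[3L])
    stopSteno("stenoflowValidationError",
              "frame %d outside the stack (1..%d)", frame, d[3L])
  cz <- corners@corners$z
  cx <- corners@corners$x
  if (any(cx < 1 | cx > d[2L]) || any(cz < 1 | cz > d[1L]))
    stopSteno("stenoflowAnnotationError",
              "corner coordinates fall outside the frame")
  zSpan <- round(range(cz))
  img <- stack@frames[, , frame]
  I <- colMeans(img[zSpan[1L]:zSpan[2L], , drop = FALSE])
  inverted <- identical(modality, "PRP")
  degenerate <- FALSE
  rng <- range(I)
  if (diff(rng) < 1e-12) {
    I <- rep(0, length(I))
    degenerate <- TRUE
  } else if (inverted && invertOrder == "before") {
    I <- -I
    I <- (I - min(I)) / (max(I) - min(I))
  } else {
    I <- (I - rng[1L]) / diff(rng)
    if (inverted) I <- 1 - I
  }
  x <- (seq_len(d[2L]) - corners@upstreamRef) * stack@pixelSize
  new("IntensityProfile", x = x, intensity = I, modality = modality,
      inverted = inverted, degenerate = degenerate)
}

#' Occlusion distance
#'
#' Distance from the upstream stenotic corner to the point of highest
#' normalized mean intensity -- the location of the occlusive platelet
#' aggregate. Ties are resolved to the first (most upstream) maximum and
#' flagged via the \code{"tie"} attribute.
#'
#' @param profile an aligned [IntensityProfile-class].
#' @return distance (m), with logical attribute \code{tie}.
#' @export
occlusionDistance <- function(profile) {
  if (profile@degenerate)
    stopSteno("stenoflowDegenerateProfileError",
              "profile is degenerate (flat frame); occlusion distance undefined")
  i <- which.max(profile@intensity)
  tie <- sum(profile@intensity == profile@intensity[i]) > 1L
  structure(profile@x[i], tie = tie)
}

#' Aggregate aligned profiles
#'
#' Pointwise mean of several corner-aligned profiles on their common
#' x-support (linear interpolation onto a shared grid), alongside the
#' individual curves. An optional y-shift of each curve's mean to zero
#' supports cross-modality shape comparison.
#'
#' @param profiles list of [IntensityProfile-class] objects.
#' @param yShift subtract each curve's mean before averaging?
#' @return list with \code{x}, \code{mean} and a curves matrix (one column
#'   per experiment).
#' @export
aggregateProfiles <- function(profiles, yShift = FALSE) {
  if (!length(profiles))
    stopSteno("stenoflowValidationError", "no profiles supplied")
  lo <- max(vapply(profiles, function(p) min(p@x), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p@x), numeric(1)))
  if (lo >= hi)
    stopSteno("stenoflowAlignmentError",
              "profiles have disjoint x-supports; cannot align")
  ref <- profiles[[1L]]
  grid <- ref@x[ref@x >= lo & ref@x <= hi]
  curves <- vapply(profiles, function(p)
    stats::approx(p@x, p@intensity, xout = grid)$y, numeric(length(grid)))
  curves <- matrix(curves, nrow = length(grid))
  if (yShift) curves <- sweep(curves, 2L, colMeans(curves))
  list(x = grid, mean = rowMeans(curves), curves = curves)
}

#' End-to-end occlusion analysis
#'
#' Runs the full experimental pipeline on one experiment: evaporation
#' correction (when a reference is present), occlusion-time detection,
#' occlusion-frame lookup, width-averaged intensity profiling of that
#' frame, and occlusion-distance measurement.
#'
#' @param stack an [ImageStack-class].
#' @param trace a [MassTrace-class].
#' @param corners a [CornerAnnotation-class].
#' @param epsilon plateau tolerance (kg), see [occlusionTime()].
#' @param ... passed to [intensityProfile()].
#' @return An [OcclusionResult-class].
#' @export
analyzeOcclusion <- function(stack, trace, corners, epsilon = 2e-6, ...) {
  if (!trace@corrected && !is.null(trace@refTime))
    trace <- correctEvaporation(trace)
  occ <- occlusionTime(trace, epsilon = epsilon,
                       timestamps = stack@timestamps)
  prof <- intensityProfile(stack, occ$frameIndex, corners, ...)
  dist <- occlusionDistance(prof)
  flags <- occ$flags
  if (isTRUE(attr(dist, "tie"))) flags <- c(flags, "tie")
  new("OcclusionResult", time = occ$time,
      frameIndex = as.numeric(occ$frameIndex),
      distance = as.numeric(dist), flags = flags)
}
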