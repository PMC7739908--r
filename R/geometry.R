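#' Construct a chamber geometry
#'
#' Low-level constructor. Exactly one of \code{downstream} or \code{L} may be
#' omitted, in which case it is derived from the identity
#' \code{L = upstream + 2 * ramp_run + Ls + downstream} with
#' \code{ramp_run = (H - hs) / tan(theta)} and throat height
#' \code{hs = (1 - s) * H}.
#'
#' @param H channel height (m).
#' @param W channel width (m).
#' @param s stenosis severity in (0, 1): the fraction of lumen height
#'   removed, so \code{hs = (1 - s) * H}.
#' @param theta ramp angle from the wall plane (degrees, in (0, 90]).
#' @param Ls flat throat length (m).
#' @param upstream straight length before the contraction (m).
#' @param downstream straight length after the expansion (m), or \code{NULL}.
#' @param L total domain length (m), or \code{NULL}.
#' @param stenoticWall \code{"pdms"} (bump on the y = H wall, the default)
#'   or \code{"glass"}.
#' @return A [ChamberGeometry-class].
#' @examples
#' g <- chamberGeometry(H = 130e-6, W = 480e-6, s = 0.5, theta = 80,
#'                      Ls = 150e-6, upstream = 200e-6, L = 572e-6)
#' throatHeight(g)   # 65 um
#' @export
chamberGeometry <- function(H, W, s, theta, Ls, upstream,
                            downstream = NULL, L = NULL,
                            stenoticWall = "pdms") {
  for (nm in c("H", "W", "s", "theta", "Ls", "upstream"))
    assertScalarNumeric(get(nm), nm)
  if (is.null(downstream) && is.null(L))
    stopSteno("stenoflowValidationError",
              "one of 'downstream_length' or 'domain_length' must be given")
  hs <- (1 - s) * H
  if (!is.finite(hs) || hs <= 0 || s <= 0 || s >= 1)
    stopSteno("stenoflowValidationError",
              "field 'stenosis_severity' must lie strictly between 0 and 1")
  if (theta <= 0 || theta > 90)
    stopSteno("stenoflowValidationError",
              "field 'ramp_angle' must lie in (0, 90] degrees")
  run <- (H - hs) / tan(theta * pi / 180)
  if (is.null(downstream)) downstream <- L - upstream - 2 * run - Ls
  if (is.null(L)) L <- upstream + 2 * run + Ls + downstream
  if (!is.finite(downstream) || downstream <= 0)
    stopSteno("stenoflowValidationError",
              "field 'downstream_length' must be strictly positive (domain too short for the stenotic feature)")
  newValidated("ChamberGeometry", "stenoflowValidationError",
               H = H, W = W, L = L, s = s, theta = theta,
               Ls = Ls, upstream = upstream, downstream = downstream,
               stenoticWall = stenoticWall)
}

#' Stenotic micro-chamber presets
#'
#' Default parameter set for the single-stenosis micro-chamber used
#' throughout the package: 130 um channel height, 50\% stenosis with 80
#' degree contraction/expansion ramps and a 150 um flat throat, 200 um of
#' straight channel upstream, and a total modelled length of 572 um (the
#' ~1 um trigonometric residual of the ramp runs is absorbed into the
#' downstream straight section). The \code{"as-built"} variant carries the
#' profilometry-measured heights (131 um channel, 65.7 um throat) instead of
#' the design values. The width is 480 um for the physical device and 50 um
#' for the width-periodic simulation slab; either is a pure scale factor for
#' the 2-D side-view flow problem.
#'
#' @param variant \code{"design"} (default) or \code{"as-built"}.
#' @param width \code{"experiment"} (480 um, default) or
#'   \code{"simulation"} (50 um).
#' @param overrides named list of overrides; recognized keys are the
#'   geometry file field names: \code{channel_height}, \code{channel_width},
#'   \code{domain_length}, \code{stenosis_severity}, \code{ramp_angle},
#'   \code{throat_length}, \code{upstream_length}, \code{downstream_length},
#'   \code{stenotic_wall}. Unrecognized keys raise a validation error.
#' @return A [ChamberGeometry-class].
#' @examples
#' g <- vanRooijGeometry()
#' throatHeight(g) * 1e6   # 65
#' rampRun(g) * 1e6        # about 11.5
#' @export
vanRooijGeometry <- function(variant = c("design", "as-built"),
                             width = c("experiment", "simulation"),
                             overrides = list()) {
  variant <- match.arg(variant)
  width <- match.arg(width)
  par <- list(
    channel_height = if (variant == "design") 130e-6 else 131e-6,
    channel_width = if (width == "experiment") 480e-6 else 50e-6,
    domain_length = 572e-6,
    stenosis_severity = if (variant == "design") 0.5 else 1 - 65.7 / 131,
    ramp_angle = 80,
    throat_length = 150e-6,
    upstream_length = 200e-6,
    downstream_length = NULL,
    stenotic_wall = "pdms"
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(par))
    if (length(bad))
      stopSteno("stenoflowValidationError",
                "unrecognized geometry override key(s): %s",
                paste(bad, collapse = ", "))
    # an explicit downstream_length replaces the derived one
    if ("downstream_length" %in% names(overrides) &&
        !("domain_length" %in% names(overrides)))
      par$domain_length <- NULL
    par[names(overrides)] <- overrides
  }
  chamberGeometry(
    H = par$channel_height, W = par$channel_width,
    s = par$stenosis_severity, theta = par$ramp_angle,
    Ls = par$throat_length, upstream = par$upstream_length,
    downstream = par$downstream_length, L = par$domain_length,
    stenoticWall = par$stenotic_wall
  )
}

# ---- accessors -------------------------------------------------------------

#' Geometry accessors
#'
#' @param g a [ChamberGeometry-class].
#' @return Numeric scalars in SI units; \code{throatHeight} is
#'   \code{hs = (1 - s) * H}, \code{rampRun} the flow-wise extent
#'   \code{(H - hs) / tan(theta)} of each ramp, and \code{bumpX} the four
#'   flow-wise stations of the bump (contraction start/end, expansion
#'   start/end).
#' @name geometry-accessors
#' @examples
#' bumpX(vanRooijGeometry()) * 1e6
NULL

#' @rdname geometry-accessors
#' @export
channelHeight <- function(g) g@H
#' @rdname geometry-accessors
#' @export
channelWidth <- function(g) g@W
#' @rdname geometry-accessors
#' @export
domainLength <- function(g) g@L
#' @rdname geometry-accessors
#' @export
stenosisSeverity <- function(g) g@s
#' @rdname geometry-accessors
#' @export
rampAngle <- function(g) g@theta
#' @rdname geometry-accessors
#' @export
throatLength <- function(g) g@Ls
#' @rdname geometry-accessors
#' @export
throatHeight <- function(g) (1 - g@s) * g@H
#' @rdname geometry-accessors
#' @export
rampRun <- function(g) (g@H - throatHeight(g)) / tan(g@theta * pi / 180)
#' @rdname geometry-accessors
#' @export
upstreamLength <- function(g) g@upstream
#' @rdname geometry-accessors
#' @export
downstreamLength <- function(g) g@downstream
#' @rdname geometry-accessors
#' @export
bumpX <- function(g) {
  x1 <- g@upstream
  x2 <- x1 + rampRun(g)
  x3 <- x2 + g@Ls
  x4 <- x3 + rampRun(g)
  c(contraction_start = x1, contraction_end = x2,
    expansion_start = x3, expansion_end = x4)
}

#' Local lumen bounds
#'
#' Lower and upper fluid boundary at given flow-wise positions. The bump
#' reduces the lumen from the stenotic wall; the opposite wall is flat.
#'
#' @param g a [ChamberGeometry-class].
#' @param x positions (m), vectorized.
#' @return list with numeric vectors \code{yLow} and \code{yHigh}.
#' @export
lumenBounds <- function(g, x) {
  bx <- bumpX(g)
  tanT <- tan(g@theta * pi / 180)
  hBump <- g@H - throatHeight(g)
  h <- numeric(length(x))
  onC <- x >= bx[1L] & x < bx[2L]
  onT <- x >= bx[2L] & x <= bx[3L]
  onE <- x > bx[3L] & x <= bx[4L]
  h[onC] <- (x[onC] - bx[1L]) * tanT
  h[onT] <- hBump
  h[onE] <- (bx[4L] - x[onE]) * tanT
  h <- pmin(h, hBump)
  if (g@stenoticWall == "pdms") {
    list(yLow = rep(0, length(x)), yHigh = g@H - h)
  } else {
    list(yLow = h, yHigh = rep(g@H, length(x)))
  }
}

#' Analytic side-view fluid area
#'
#' Area of the fluid polygon (rectangle minus the trapezoidal bump):
#' \code{L*H - (Ls + ramp_run) * (H - hs)}.
#'
#' @param g a [ChamberGeometry-class].
#' @return area (m^2).
#' @export
analyticFluidArea <- function(g)
  g@L * g@H - (g@Ls + rampRun(g)) * (g@H - throatHeight(g))

# ---- rasterization ---------------------------------------------------------

#' Rasterize a chamber geometry to a solid mask
#'
#' Discretizes the side-view fluid polygon on a regular grid. A cell is
#' fluid iff its centre lies strictly inside the fluid polygon. The throat
#' must be resolved by at least 8 cells.
#'
#' @param g a [ChamberGeometry-class].
#' @param dx grid spacing (m); must satisfy \code{dx <= hs / 8}.
#' @return A [SolidMask-class].
#' @examples
#' m <- rasterizeGeometry(vanRooijGeometry(), dx = 2e-6)
#' fluidArea(m) / analyticFluidArea(vanRooijGeometry())
#' @export
rasterizeGeometry <- function(g, dx) {
  assertScalarNumeric(dx, "dx", positive = TRUE)
  hs <- throatHeight(g)
  if (dx > hs / 8)
    stopSteno("stenoflowResolutionError",
              "dx = %.3g m too coarse: at least 8 cells across the %.3g m throat required (dx <= %.3g m)",
              dx, hs, hs / 8)
  nx <- max(1L, round(g@L / dx))
  ny <- max(1L, round(g@H / dx))
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dx
  lb <- lumenBounds(g, xc)
  fluid <- outer(seq_len(nx), seq_len(ny), function(i, j)
    yc[j] > lb$yLow[i] & yc[j] < lb$yHigh[i])
  new("SolidMask", dx = dx, solid = !fluid,
      origin = c(dx / 2, dx / 2), geometry = g)
}

#' Mask accessors
#'
#' @param m a [SolidMask-class].
#' @return \code{gridSpacing}: the cell size (m); \code{fluidArea}: fluid
#'   cell count times \code{dx^2} (m^2); \code{isSolid}: the logical
#'   occupancy matrix.
#' @name mask-accessors
NULL

#' @rdname mask-accessors
#' @export
gridSpacing <- function(m) m@dx
#' @rdname mask-accessors
#' @export
fluidArea <- function(m) sum(!m@solid) * m@dx^2
#' @rdname mask-accessors
#' @export
isSolid <- function(m) m@solid

# ---- wall-offset sampling --------------------------------------------------

#' Sample points at a fixed offset from a wall
#'
#' Returns an ordered polyline of points displaced from the wall contour by
#' \code{offset} along the inward wall normal. On the flat wall this is a
#' straight line; on the stenotic wall the curve follows the ramps and the
#' throat. At concave corners the join is mitred so each sample keeps the
#' requested distance from both adjacent faces; at convex (bump) corners the
#' bisector point lies on the exact offset arc. Samples within \code{2 um}
#' of a ramp corner (along the contour) are flagged, since shear sampled
#' there carries corner artefacts.
#'
#' @param g a [ChamberGeometry-class].
#' @param wall \code{"glass"} (flat side) or \code{"pdms"} (stenotic side);
#'   when the bump sits on the glass wall the roles swap accordingly.
#' @param offset inward offset (m); must be \code{< hs / 2}.
#' @param spacing approximate arc-length spacing of the samples (m).
#' @param cornerFlagDist contour distance within which samples are flagged
#'   as corner-affected (m).
#' @return data.frame with columns \code{x}, \code{y} (m) and logical
#'   \code{corner}.
#' @export
wallOffsetSamples <- function(g, wall = c("glass", "pdms"), offset,
                              spacing = 0.5e-6, cornerFlagDist = 2e-6) {
  wall <- match.arg(wall)
  assertScalarNumeric(offset, "offset")
  if (offset < 0)
    stopSteno("stenoflowOffsetError", "offset must be non-negative")
  hs <- throatHeight(g)
  if (offset >= hs / 2)
    stopSteno("stenoflowOffsetError",
              "offset %.3g m exceeds half the throat height (%.3g m)",
              offset, hs / 2)
  bumpOnWall <- (wall == g@stenoticWall)
  if (!bumpOnWall) {
    # flat wall: straight offset line
    yFlat <- if (wall == "glass") 0 else g@H
    sgn <- if (wall == "glass") 1 else -1
    x <- seq(0, g@L, by = spacing)
    return(data.frame(x = x, y = rep(yFlat + sgn * offset, length(x)),
                      corner = FALSE))
  }
  # stenotic wall: polyline in "bump-on-top" frame, mirrored afterwards
  bx <- bumpX(g)
  H <- g@H
  verts <- cbind(
    x = c(0, bx[[1L]], bx[[2L]], bx[[3L]], bx[[4L]], g@L),
    y = c(H, H, hs, hs, H, H)
  )
  segs <- cbind(verts[-nrow(verts), , drop = FALSE],
                verts[-1L, , drop = FALSE])
  pts <- NULL
  nrm <- NULL
  segId <- NULL
  for (k in seq_len(nrow(segs))) {
    p0 <- segs[k, 1:2]; p1 <- segs[k, 3:4]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(len / spacing) + 1L)
    tt <- seq(0, 1, length.out = n)
    P <- cbind(p0[1L] + tt * (p1[1L] - p0[1L]),
               p0[2L] + tt * (p1[2L] - p0[2L]))
    d <- (p1 - p0) / len
    # right-hand normal of the left-to-right traversal points into the
    # fluid everywhere on the top wall (down on the flats, away from the
    # bump on both ramps)
    inward <- c(d[2L], -d[1L])
    pts <- rbind(pts, P)
    nrm <- rbind(nrm, matrix(inward, n, 2, byrow = TRUE))
    segId <- c(segId, rep(k, n))
  }
  # merge duplicated vertex points, averaging normals (mitre join)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-15)
  mitre <- rep(1, nrow(pts))
  dupIdx <- which(!keep)
  for (i in dupIdx) {
    n1 <- nrm[i - 1L, ]; n2 <- nrm[i, ]
    nb <- n1 + n2
    nb <- nb / sqrt(sum(nb^2))
    # convexity seen from the fluid: bump corners (hs level) are convex,
    # wall-level corners are concave and need mitre scaling
    convex <- abs(pts[i, 2L] - hs) < 1e-12
    fac <- if (convex) 1 else sqrt(2 / (1 + sum(n1 * n2)))
    nrm[i - 1L, ] <- nb
    mitre[i - 1L] <- fac
  }
  pts <- pts[keep, , drop = FALSE]
  nrm <- nrm[keep, , drop = FALSE]
  mitre <- mitre[keep]
  out <- pts + nrm * (offset * mitre)
  # corner flags: contour distance to the four ramp-corner vertices
  cornerXY <- verts[2:5, , drop = FALSE]
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  arcC <- vapply(seq_len(nrow(cornerXY)), function(k) {
    i <- which.min((pts[, 1L] - cornerXY[k, 1L])^2 +
                   (pts[, 2L] - cornerXY[k, 2L])^2)
    arc[i]
  }, numeric(1))
  cornerFlag <- vapply(arc, function(a)
    any(abs(a - arcC) <= cornerFlagDist), logical(1))
  y <- out[, 2L]
  if (g@stenoticWall == "glass") y <- g@H - y   # mirror frame back
  data.frame(x = out[, 1L], y = y, corner = cornerFlag)
}
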