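#' @describeIn ChamberGeometry-class compact parameter summary
#' @param object a \code{ChamberGeometry}.
#' @export
setMethod("show", "ChamberGeometry", function(object) {
  cat(sprintf(
    "ChamberGeometry: H = %.4g um, W = %.4g um, L = %.4g um\n",
    object@H * 1e6, object@W * 1e6, object@L * 1e6))
  cat(sprintf(
    "  stenosis %.3g%% on the %s wall (hs = %.4g um), ramps %.3g deg (run %.3g um), throat %.4g um\n",
    100 * object@s, object@stenoticWall, throatHeight(object) * 1e6,
    object@theta, rampRun(object) * 1e6, object@Ls * 1e6))
  invisible(NULL)
})

#' @describeIn SolidMask-class grid and fluid-fraction summary
#' @param object a \code{SolidMask}.
#' @export
setMethod("show", "SolidMask", function(object) {
  cat(sprintf(
    "SolidMask: %d x %d cells at dx = %.3g um, %.1f%% fluid\n",
    nrow(object@solid), ncol(object@solid), object@dx * 1e6,
    100 * mean(!object@solid)))
  invisible(NULL)
})

#' @describeIn FlowField-class solve summary
#' @param object a \code{FlowField}.
#' @export
setMethod("show", "FlowField", function(object) {
  cat(sprintf(
    "FlowField: %d x %d nodes at dx = %.3g um, Q = %.3g m^3/s (W = %.3g um)\n",
    length(object@x), length(object@y), object@dx * 1e6,
    object@Q, object@W * 1e6))
  cat(sprintf("  %s (residual %.2g), body force %.4g N/m^3, max |u| = %.4g m/s\n",
              if (object@converged) "converged" else "NOT converged",
              object@residual, object@bodyForce, max(abs(object@ux))))
  invisible(NULL)
})

#' @describeIn CellSnapshotSeries-class snapshot and census summary
#' @param object a \code{CellSnapshotSeries}.
#' @export
setMethod("show", "CellSnapshotSeries", function(object) {
  ts <- unique(object@data$t)
  census <- table(object@data$type[object@data$t == ts[1L]])
  cat(sprintf(
    "CellSnapshotSeries: %d snapshots every %.3g ms (%s)\n",
    length(ts), object@dtSnap * 1e3,
    paste(sprintf("%s: %d", names(census), as.integer(census)),
          collapse = ", ")))
  invisible(NULL)
})

#' @describeIn BinnedFieldMap-class map summary
#' @param object a \code{BinnedFieldMap}.
#' @export
setMethod("show", "BinnedFieldMap", function(object) {
  cat(sprintf(
    "BinnedFieldMap [%s]: %d x %d bins, window %.3g-%.3g s, range %.3g..%.3g\n",
    object@kind, nrow(object@values), ncol(object@values),
    object@window[1L], object@window[2L],
    min(object@values, na.rm = TRUE), max(object@values, na.rm = TRUE)))
  invisible(NULL)
})

#' @describeIn MassTrace-class trace summary
#' @param object a \code{MassTrace}.
#' @export
setMethod("show", "MassTrace", function(object) {
  cat(sprintf(
    "MassTrace: %d samples over %.4g s, %scorrected%s\n",
    length(object@time), diff(range(object@time)),
    if (object@corrected) "" else "un",
    if (is.null(object@refTime)) "" else ", evaporation reference attached"))
  invisible(NULL)
})

#' @describeIn ImageStack-class stack summary
#' @param object an \code{ImageStack}.
#' @export
setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageStack [%s]: %d frames of %d x %d px at %.3g um/px\n",
    object@modality, d[3L], d[1L], d[2L], object@pixelSize * 1e6))
  invisible(NULL)
})

#' @describeIn OcclusionResult-class result summary
#' @param object an \code{OcclusionResult}.
#' @export
setMethod("show", "OcclusionResult", function(object) {
  cat(sprintf(
    "OcclusionResult: t = %.4g s (frame %d), distance = %.4g um%s\n",
    object@time, as.integer(object@frameIndex), object@distance * 1e6,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ", "), "]")
    else ""))
  invisible(NULL)
})

#' Plot a binned field map
#'
#' Filled image of the per-bin values with the flow direction horizontal.
#'
#' @param x a [BinnedFieldMap-class].
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @export
setMethod("plot", signature(x = "BinnedFieldMap", y = "missing"),
  function(x, y, ...) {
    graphics::image(binCentersX(x) * 1e6, binCentersY(x) * 1e6, x@values,
                    xlab = "x (um)", ylab = "y (um)",
                    main = x@kind, useRaster = TRUE, ...)
    invisible(NULL)
  })

#' Plot a wall-offset shear profile
#'
#' @param x a [WallProfile-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "WallProfile", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@x * 1e6, abs(x@gammaDot), type = "l",
                   xlab = "x (um)", ylab = "|shear rate| (1/s)",
                   main = sprintf("%s wall, offset %.3g um",
                                  x@wall, x@offset * 1e6), ...)
    if (any(x@corner))
      graphics::points(x@x[x@corner] * 1e6, abs(x@gammaDot)[x@corner],
                       col = "grey60", pch = 16, cex = 0.4)
    invisible(NULL)
  })

#' Plot an intensity profile
#'
#' @param x an [IntensityProfile-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "IntensityProfile", y = "missing"),
  function(x, y, ...) {
    graphics::plot(x@x * 1e6, x@intensity, type = "l",
                   xlab = "x from upstream corner (um)",
                   ylab = "normalized intensity", ...)
    graphics::abline(v = 0, lty = 3, col = "grey50")
    invisible(NULL)
  })
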