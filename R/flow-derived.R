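#' Shear-rate and shear-stress fields
#'
#' Derives the xy-component of the shear rate,
#' \code{gamma_dot = d(ux)/dy + d(uy)/dx}, by centred differences
#' (second-order one-sided at the y-boundaries), and the Newtonian stress
#' \code{tau = mu * gamma_dot}. In this slot-like geometry the other tensor
#' components are negligible. On wall nodes the centred stencil is replaced
#' by the converged wall vorticity (\code{gamma_dot = -omega} on a flat
#' no-slip wall), which is second-order accurate.
#'
#' @param flow a converged [FlowField-class].
#' @param fluid a [FluidSpec-class].
#' @return list with matrices \code{gammaDot} (s^-1) and \code{tau} (Pa)
#'   plus the node coordinate vectors \code{x}, \code{y}.
#' @export
shearFields <- function(flow, fluid) {
  if (!is(flow, "FlowField"))
    stopSteno("stenoflowValidationError", "'flow' must be a FlowField")
  if (!flow@converged)
    stopSteno("stenoflowStateError",
              "flow field is not converged (residual %.3g)", flow@residual)
  dx <- flow@dx
  ux <- flow@ux; uy <- flow@uy
  nyn <- ncol(ux)
  dudy <- (cbind(ux[, -1L, drop = FALSE], 0) -
           cbind(0, ux[, -nyn, drop = FALSE])) / (2 * dx)
  # second-order one-sided at the two y-boundaries
  dudy[, 1L] <- (-3 * ux[, 1L] + 4 * ux[, 2L] - ux[, 3L]) / (2 * dx)
  dudy[, nyn] <- (3 * ux[, nyn] - 4 * ux[, nyn - 1L] + ux[, nyn - 2L]) / (2 * dx)
  dvdx <- (shiftXp(uy) - shiftXm(uy)) / (2 * dx)
  gammaDot <- dudy + dvdx
  wallSel <- flow@nodeType == 2L
  gammaDot[wallSel] <- -flow@omega[wallSel]
  gammaDot[flow@nodeType == 0L] <- 0
  mu <- fluid@rho * fluid@nu
  list(gammaDot = gammaDot, tau = mu * gammaDot, x = flow@x, y = flow@y)
}

#' Wall-offset shear profile
#'
#' Samples the shear-rate and shear-stress fields along the curve a fixed
#' offset inward from one wall (see [wallOffsetSamples()]) by bilinear
#' interpolation. Samples near the ramp corners are retained -- the spikes
#' there may be artefacts of taking only the xy tensor component -- but
#' flagged in the \code{corner} slot.
#'
#' @param flow a converged [FlowField-class].
#' @param fluid a [FluidSpec-class].
#' @param g the [ChamberGeometry-class] the flow was solved on.
#' @param wall \code{"glass"} or \code{"pdms"}.
#' @param offset inward offset (m), 1 um by default.
#' @return A [WallProfile-class].
#' @export
wallProfile <- function(flow, fluid, g, wall = c("glass", "pdms"),
                        offset = 1e-6) {
  wall <- match.arg(wall)
  samples <- wallOffsetSamples(g, wall, offset, spacing = flow@dx)
  lb <- lumenBounds(g, samples$x)
  inFluid <- samples$y > lb$yLow & samples$y < lb$yHigh
  if (!all(inFluid))
    stopSteno("stenoflowGeometryError",
              "%d offset samples leave the fluid region", sum(!inFluid))
  sf <- shearFields(flow, fluid)
  gd <- bilinearAt(samples$x, samples$y, sf$x, sf$y, sf$gammaDot,
                   periodicX = TRUE)
  mu <- fluid@rho * fluid@nu
  new("WallProfile", x = samples$x, gammaDot = gd, tau = mu * gd,
      wall = wall, offset = offset, corner = samples$corner)
}

#' Velocity at arbitrary points
#'
#' Bilinear interpolation of the velocity field; x is treated as periodic.
#'
#' @param flow a [FlowField-class].
#' @param x,y query positions (m), vectorized.
#' @return list with numeric vectors \code{ux} and \code{uy} (m s^-1).
#' @export
velocityAt <- function(flow, x, y) {
  list(ux = bilinearAt(x, y, flow@x, flow@y, flow@ux, periodicX = TRUE),
       uy = bilinearAt(x, y, flow@x, flow@y, flow@uy, periodicX = TRUE))
}

#' Channel Reynolds number
#'
#' \code{Re = (Q / (W * H)) * H / nu = Q / (W * nu)}: mean-velocity
#' Reynolds number with the channel height as characteristic length and the
#' plasma kinematic viscosity. With the full experimental width this
#' reproduces the order-4 value characteristic of the chamber at its
#' working flow rates.
#'
#' @param Q volumetric flow rate (m^3 s^-1), positive.
#' @param g a [ChamberGeometry-class] (supplies H and W).
#' @param fluid a [FluidSpec-class] (supplies nu).
#' @param characteristic characteristic length: \code{"height"} (default)
#'   or \code{"throat"} (uses hs instead of H).
#' @return dimensionless Reynolds number.
#' @examples
#' reynoldsNumber(2.1e-9, vanRooijGeometry(), prpFluid())  # about 4
#' @export
reynoldsNumber <- function(Q, g, fluid, characteristic = c("height", "throat")) {
  characteristic <- match.arg(characteristic)
  assertScalarNumeric(Q, "Q", positive = TRUE)
  len <- if (characteristic == "height") g@H else throatHeight(g)
  meanU <- Q / (g@W * len)
  meanU * len / fluid@nu
}
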