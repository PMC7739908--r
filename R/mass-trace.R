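#' Build a mass-balance trace
#'
#' @param time sample times (s), strictly increasing.
#' @param mass cumulative outflow mass (kg).
#' @param refTime,refMass optional paired evaporation-reference trace from
#'   a dish of the same mixture on an adjacent balance.
#' @param rho fluid density (kg m^-3), used by [flowRate()].
#' @return A [MassTrace-class] (uncorrected).
#' @export
massTrace <- function(time, mass, refTime = NULL, refMass = NULL,
                      rho = 1025) {
  newValidated("MassTrace", "stenoflowValidationError",
               time = as.numeric(time), mass = as.numeric(mass),
               refTime = if (is.null(refTime)) NULL else as.numeric(refTime),
               refMass = if (is.null(refMass)) NULL else as.numeric(refMass),
               rho = rho, corrected = FALSE)
}

#' Evaporation correction
#'
#' Subtracts the evaporation signal recorded by the reference dish:
#' \code{corrected = mass - (ref - ref[first])}, after linear resampling of
#' the reference onto the trace times. Trace samples outside the reference
#' time support are dropped.
#'
#' @param trace a [MassTrace-class].
#' @param refTime,refMass reference trace; defaults to the one stored in
#'   \code{trace}.
#' @return A corrected [MassTrace-class].
#' @export
correctEvaporation <- function(trace, refTime = trace@refTime,
                               refMass = trace@refMass) {
  if (is.null(refTime) || is.null(refMass))
    stopSteno("stenoflowConfigurationError",
              "no evaporation-reference trace available")
  keep <- trace@time >= min(refTime) & trace@time <= max(refTime)
  if (!any(keep))
    stopSteno("stenoflowAlignmentError",
              "trace and evaporation reference have no overlapping time support")
  tt <- trace@time[keep]
  ref <- stats::approx(refTime, refMass, xout = tt, rule = 1)$y
  corrected <- trace@mass[keep] - (ref - ref[1L])
  new("MassTrace", time = tt, mass = corrected,
      refTime = refTime, refMass = refMass,
      rho = trace@rho, corrected = TRUE)
}

#' Volumetric flow rate from a mass trace
#'
#' Least-squares slope of mass versus time over a pre-occlusion window,
#' divided by the fluid density. Multiply by 1e9 for ul/s.
#'
#' @param trace a corrected [MassTrace-class] (an uncorrected trace is
#'   accepted when it carries no reference, e.g. synthetic evaporation-free
#'   data).
#' @param window \code{c(t_start, t_end)} (s); must contain at least 5
#'   samples and should lie inside the pre-occlusion regime.
#' @return flow rate (m^3 s^-1).
#' @export
flowRate <- function(trace, window = range(trace@time)) {
  sel <- trace@time >= window[1L] & trace@time <= window[2L]
  if (sum(sel) < 5L)
    stopSteno("stenoflowWindowError",
              "flow-rate window holds %d samples; at least 5 required", sum(sel))
  slope <- stats::coef(stats::lm(m ~ t,
    data = data.frame(t = trace@time[sel], m = trace@mass[sel])))[[2L]]
  slope / trace@rho
}

#' Occlusion time from a mass trace
#'
#' The channel is occluded when the cumulative outflow mass stops growing.
#' The detector finds the plateau of samples within \code{epsilon} of the
#' plateau level (the trace maximum, refined by a median step so a noise
#' spike cannot inflate it):
#' \itemize{
#'   \item an interior plateau returns its temporal centre (the rule used
#'     when the balance plateaus for a couple of seconds before declining);
#'   \item a plateau that runs to the final sample returns the plateau
#'     start -- the first time the maximum level is reached -- flagged
#'     \code{"plateau_open"}, since the centre of an open-ended plateau
#'     would depend on when the recording stopped;
#'   \item a trace still rising at the final sample is flagged
#'     \code{"right_censored"} (no occlusion observed).
#' }
#'
#' @param trace a corrected [MassTrace-class].
#' @param epsilon plateau tolerance (kg); default 2e-6, twice a 1 mg
#'   balance resolution.
#' @param timestamps optional frame timestamps (s); when given, the nearest
#'   frame index is reported.
#' @return list with \code{time} (s), \code{frameIndex} (integer or
#'   \code{NA}), \code{plateau} (\code{c(start, end)}, s) and \code{flags}
#'   (character).
#' @export
occlusionTime <- function(trace, epsilon = 2e-6, timestamps = NULL) {
  m <- trace@mass
  tt <- trace@time
  n <- length(m)
  # robust noise scale of the trace; the plateau EXTENT uses a tolerance
  # widened to ~4 sigma so single noise excursions cannot truncate it,
  # while the plateau ONSET keeps the user tolerance
  sigmaHat <- if (n > 2L) stats::mad(diff(m)) / sqrt(2) else 0
  epsWide <- max(epsilon, 4 * sigmaHat)
  PW <- which(m >= max(m) - epsWide)
  level <- stats::median(m[PW])          # spike-free plateau level
  PW <- which(m >= level - epsWide)
  aW <- min(PW)
  b <- max(PW)
  # onset: first of two consecutive samples at the plateau level (a lone
  # spike does not start the plateau)
  ok <- m >= level - epsilon
  cons <- ok & c(ok[-1L], TRUE)
  a <- which(cons)[1L]
  if (is.na(a) || a > b) a <- aW
  flags <- character(0)
  # the plateau is interior only when the trace after it sits systematically
  # below the plateau level (a genuine decline, not a noise dip at the end)
  openEnded <- b >= n ||
    mean(m[(b + 1L):n]) >= level - epsWide
  if (openEnded) {
    # occlusion followed by end of recording -- unless the trace only
    # reaches the plateau band at the very last sample, i.e. it is still
    # climbing when the recording stops
    stillRising <- a >= n
    if (stillRising) {
      flags <- "right_censored"
      tOcc <- tt[n]
    } else {
      flags <- "plateau_open"
      tOcc <- tt[a]
    }
  } else {
    tOcc <- (tt[aW] + tt[b]) / 2
  }
  frameIndex <- NA_integer_
  if (!is.null(timestamps))
    frameIndex <- which.min(abs(timestamps - tOcc))
  list(time = tOcc, frameIndex = frameIndex,
       plateau = c(tt[min(a, aW)], tt[b]), flags = flags)
}
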