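#' Margination specification for the snapshot generator
#'
#' Defaults reflect the cell-resolved study conditions the generator
#' emulates: 10703 red cells and 952 platelets in the 572 x 130 x 50 um
#' periodic slab at a 33\% core tube haematocrit, a 5 um red-cell-free
#' layer, a 0.5 um platelet-free sliver at the wall and a near-wall
#' platelet enhancement factor of 2 for whole blood (1 for platelet-rich
#' plasma, which also carries no red cells).
#'
#' @param cflWidth red-cell-free layer width delta* (m).
#' @param enhancement near-wall platelet enhancement factor f; 2 = whole
#'   blood margination, 1 = no enhancement (PRP).
#' @param coreHematocrit core red-cell volume fraction.
#' @param bandAmplitude relative excess amplitude of the quarter-/three-
#'   quarter-height platelet bands (0 disables).
#' @param bandWidth width of those bands (m).
#' @param sliver platelet-free sliver at the wall (m).
#' @param nRbc,nPlt cell counts.
#' @param jitterSigma per-snapshot isotropic positional jitter (m).
#' @param seed RNG seed.
#' @return A [MarginationSpec-class].
#' @export
marginationSpec <- function(cflWidth = 5e-6, enhancement = 2,
                            coreHematocrit = 0.33, bandAmplitude = 0,
                            bandWidth = 10e-6, sliver = 0.5e-6,
                            nRbc = 10703, nPlt = 952,
                            jitterSigma = 0.3e-6, seed = 1) {
  newValidated("MarginationSpec", "stenoflowSpecError", cflWidth = cflWidth,
               enhancement = enhancement, coreHematocrit = coreHematocrit,
               bandAmplitude = bandAmplitude, bandWidth = bandWidth,
               sliver = sliver, nRbc = nRbc, nPlt = nPlt,
               jitterSigma = jitterSigma, seed = seed)
}

#' @rdname marginationSpec
#' @param ... overrides passed on to [marginationSpec()].
#' @export
prpMarginationSpec <- function(...) {
  args <- list(enhancement = 1, nRbc = 0, nPlt = 941)
  over <- list(...)
  args[names(over)] <- over
  do.call(marginationSpec, args)
}

# draw from a piecewise-constant density on [0, H] given break points and
# relative weights per piece
samplePiecewise <- function(n, breaks, weights) {
  widths <- diff(breaks)
  probs <- weights * widths
  tot <- sum(probs)
  if (tot <= 0 || n == 0) return(numeric(n))
  piece <- sample.int(length(widths), n, replace = TRUE, prob = probs / tot)
  breaks[piece] + stats::runif(n) * widths[piece]
}

plateletBreaks <- function(spec, H) {
  s <- spec@sliver
  band <- 5e-6                      # near-wall enhancement band width
  breaks <- c(0, s, s + band, H - s - band, H - s, H)
  weights <- c(0, spec@enhancement, 1, spec@enhancement, 0)
  if (spec@bandAmplitude > 0) {
    # carve the quarter- and three-quarter-height bands out of the core
    w <- spec@bandWidth / 2
    q1 <- H / 4; q3 <- 3 * H / 4
    breaks <- c(0, s, s + band, q1 - w, q1 + w, q3 - w, q3 + w,
                H - s - band, H - s, H)
    a <- 1 + spec@bandAmplitude
    weights <- c(0, spec@enhancement, 1, a, 1, a, 1, spec@enhancement, 0)
  }
  list(breaks = breaks, weights = weights)
}

#' Generate a labelled cell snapshot series
#'
#' Draws cell positions with the prescribed margination statistics and
#' advects them with the local flow. Red-cell y-positions are uniform in
#' the core and zero within \code{cflWidth} of each wall; platelet
#' y-positions carry a platelet-free sliver at the wall, an
#' \code{enhancement}-fold enriched band over the first 5 um beyond the
#' sliver, optional mid-height bands, and are uniform elsewhere. x and z
#' are uniform and periodic. Between snapshots, x advects cumulatively with
#' the local velocity plus jitter, while y and z are re-drawn as base
#' position plus fresh jitter each snapshot, so the prescribed transverse
#' distribution is maintained (margination is prescribed statistically, not
#' simulated mechanistically).
#'
#' @param spec a [MarginationSpec-class].
#' @param flow a converged [FlowField-class]; its mask geometry defines the
#'   domain. Cells are placed in the fluid region only.
#' @param T duration (s); at least two snapshot intervals.
#' @param dtSnap snapshot interval (s), default 5 ms.
#' @return A [CellSnapshotSeries-class] with snapshots at
#'   \code{t = dtSnap, 2 dtSnap, ..., <= T}.
#' @export
synthCellSnapshots <- function(spec, flow, T = 0.35, dtSnap = 5e-3) {
  if (!is(flow, "FlowField") || !flow@converged)
    stopSteno("stenoflowStateError", "'flow' must be a converged FlowField")
  if (T < 2 * dtSnap)
    stopSteno("stenoflowSpecError", "duration must cover at least 2 snapshots")
  g <- flow@mask@geometry
  H <- max(flow@y)
  Lx <- (length(flow@x)) * flow@dx
  W <- flow@W
  nR <- as.integer(spec@nRbc); nP <- as.integer(spec@nPlt)
  # feasibility: packed cell volume must fit in the domain
  Vdom <- Lx * H * W
  Vcells <- nR * 90e-18 + nP * 6e-18
  if (Vcells > 0.74 * Vdom)
    stopSteno("stenoflowSpecError",
              "cell counts infeasible for the domain volume")
  if (spec@cflWidth >= H / 2)
    stopSteno("stenoflowSpecError", "cflWidth must be below H/2")
  set.seed(spec@seed)

  sampleY <- function(n, breaks, weights) samplePiecewise(n, breaks, weights)
  drawCells <- function(n, breaks, weights) {
    x <- stats::runif(n, 0, Lx)
    y <- sampleY(n, breaks, weights)
    if (!is.null(g)) {  # resample cells landing inside the bump
      for (it in 1:100) {
        lb <- lumenBounds(g, x)
        bad <- y <= lb$yLow | y >= lb$yHigh
        if (!any(bad)) break
        x[bad] <- stats::runif(sum(bad), 0, Lx)
        y[bad] <- sampleY(sum(bad), breaks, weights)
      }
    }
    list(x = x, y = y, z = stats::runif(n, 0, W))
  }
  pb <- plateletBreaks(spec, H)
  rb <- list(breaks = c(0, spec@cflWidth, H - spec@cflWidth, H),
             weights = c(0, 1, 0))
  if (spec@cflWidth == 0) rb <- list(breaks = c(0, H), weights = 1)
  rbc <- drawCells(nR, rb$breaks, rb$weights)
  plt <- drawCells(nP, pb$breaks, pb$weights)

  base <- data.frame(
    id = seq_len(nR + nP),
    type = rep(c("RBC", "PLT"), c(nR, nP)),
    x = c(rbc$x, plt$x), y = c(rbc$y, plt$y), z = c(rbc$z, plt$z),
    stringsAsFactors = FALSE
  )
  nSnap <- floor(T / dtSnap)
  nCell <- nrow(base)
  sig <- spec@jitterSigma
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  # transverse jitter is reflected at each type's support boundary, so the
  # prescribed sharp edges (red-cell-free layer, platelet-free sliver)
  # survive in the observed positions; reflection of a locally uniform
  # density at its support edge leaves the density unchanged
  isRbc <- base$type == "RBC"
  yLoSup <- ifelse(isRbc, min(spec@cflWidth, H / 2 - 1e-9),
                   min(spec@sliver, H / 2 - 1e-9))
  yHiSup <- H - yLoSup
  out <- vector("list", nSnap)
  xCur <- base$x
  for (k in seq_len(nSnap)) {
    u <- velocityAt(flow, xCur, base$y)$ux
    xCur <- (xCur + u * dtSnap + stats::rnorm(nCell, 0, sig)) %% Lx
    yObs <- reflect(base$y + stats::rnorm(nCell, 0, sig), yLoSup, yHiSup)
    zObs <- reflect(base$z + stats::rnorm(nCell, 0, sig), 0, W)
    out[[k]] <- data.frame(t = k * dtSnap, id = base$id, type = base$type,
                           x = xCur, y = yObs, z = zObs,
                           stringsAsFactors = FALSE)
  }
  cellSnapshotSeries(
    do.call(rbind, out),
    bounds = c(xmin = 0, xmax = Lx, ymin = 0, ymax = H, zmin = 0, zmax = W)
  )
}

#' Synthetic experiment specification
#'
#' Defaults emulate a typical run: the stenotic chamber at its working
#' PRP flow rate 2.4e-9 m^3/s, occlusion at 60 s into a 75 s recording,
#' the clot centred 85 um downstream of the upstream stenotic corner,
#' 2 Hz imaging at 2 um/px over a 600 x 600 um field of view, 1 Hz balance
#' sampling with 1 mg noise, and an evaporation rate of -2e-8 kg/s.
#'
#' @param geometry a [ChamberGeometry-class].
#' @param Q flow rate (m^3 s^-1).
#' @param tOcclusion programmed occlusion time t* (s).
#' @param clotCenter clot centre (m downstream of the upstream corner).
#' @param clotSigma numeric(2), Gaussian clot sd in (x, z) (m).
#' @param clotAmplitude peak intensity change at occlusion.
#' @param modality \code{"WB"} or \code{"PRP"}.
#' @param imageNoise per-pixel Gaussian noise sd.
#' @param balanceNoise balance noise sd (kg).
#' @param evapRate evaporation rate (kg s^-1, negative).
#' @param rampDuration flow ramp-down duration before t* (s).
#' @param rho fluid density (kg m^-3).
#' @param frameRate,balanceRate acquisition rates (Hz).
#' @param pixelSize pixel pitch (m/px).
#' @param fov numeric(2), field of view (x, z) (m).
#' @param upstreamInView distance from the left image edge to the upstream
#'   stenotic corner (m).
#' @param duration recording length (s).
#' @param seed RNG seed.
#' @return An [ExperimentSpec-class].
#' @export
experimentSpec <- function(geometry = vanRooijGeometry(), Q = 2.4e-9,
                           tOcclusion = 60, clotCenter = 85e-6,
                           clotSigma = c(15e-6, 120e-6),
                           clotAmplitude = 0.4,
                           modality = "WB", imageNoise = 0.01,
                           balanceNoise = 1e-6, evapRate = -2e-8,
                           rampDuration = 0, rho = 1025,
                           frameRate = 2, balanceRate = 1,
                           pixelSize = 2e-6, fov = c(600e-6, 600e-6),
                           upstreamInView = 200e-6, duration = 75,
                           seed = 1) {
  newValidated("ExperimentSpec", "stenoflowSpecError",
               geometry = geometry, Q = Q,
               tOcclusion = tOcclusion, clotCenter = clotCenter,
               clotSigma = clotSigma, clotAmplitude = clotAmplitude,
               modality = modality, imageNoise = imageNoise,
               balanceNoise = balanceNoise, evapRate = evapRate,
               rampDuration = rampDuration, rho = rho, frameRate = frameRate,
               balanceRate = balanceRate, pixelSize = pixelSize, fov = fov,
               upstreamInView = upstreamInView, duration = duration,
               seed = seed)
}

#' Synthetic mass-balance trace
#'
#' Cumulative outflow mass for a flow that runs at \code{Q} until the
#' programmed occlusion time and stops (optionally through a smooth
#' quadratic ramp-down of length \code{rampDuration}), plus a linear
#' evaporation drift and Gaussian balance noise. The paired reference
#' trace carries the evaporation and noise only.
#'
#' @param spec an [ExperimentSpec-class].
#' @return A [MassTrace-class] with the reference trace attached.
#' @export
synthMassTrace <- function(spec) {
  set.seed(spec@seed + 1L)
  tt <- seq(0, spec@duration, by = 1 / spec@balanceRate)
  tStar <- spec@tOcclusion
  tau <- spec@rampDuration
  if (tau > 0) {
    # flow Q for t < t*-tau, linear ramp to 0 at t*: quadratic mass blend
    outflow <- ifelse(tt <= tStar - tau, tt,
               ifelse(tt >= tStar,
                      tStar - tau / 2,
                      (tStar - tau) + (tt - (tStar - tau)) -
                        (tt - (tStar - tau))^2 / (2 * tau)))
  } else {
    outflow <- pmin(tt, tStar)
  }
  mass <- spec@rho * spec@Q * outflow + spec@evapRate * tt +
    stats::rnorm(length(tt), 0, spec@balanceNoise)
  refMass <- 0.05 + spec@evapRate * tt +
    stats::rnorm(length(tt), 0, spec@balanceNoise)
  massTrace(tt, mass, refTime = tt, refMass = refMass, rho = spec@rho)
}

#' Synthetic bright-field image stack
#'
#' Frames show the channel span (brighter band between two darker wall
#' margins) with the stenotic borders marked by short ticks in the margin
#' outside the channel, and a separable-Gaussian clot centred
#' \code{clotCenter} downstream of the upstream stenotic corner whose
#' amplitude grows linearly until the occlusion time. Whole-blood clots add
#' intensity, PRP clots subtract it. Gaussian pixel noise is added and
#' intensities clipped to [0, 1]. The exact corner pixel coordinates are
#' returned alongside.
#'
#' @param spec an [ExperimentSpec-class].
#' @return list with elements \code{stack} ([ImageStack-class]) and
#'   \code{corners} ([CornerAnnotation-class]).
#' @export
synthImageStack <- function(spec) {
  set.seed(spec@seed + 2L)
  px <- spec@pixelSize
  nx <- round(spec@fov[1L] / px)
  nz <- round(spec@fov[2L] / px)
  chanW <- spec@geometry@W
  margin <- max(2L, round((nz - chanW / px) / 2))
  z0 <- margin + 1L; z1 <- nz - margin          # channel rows
  if (z1 <= z0)
    stopSteno("stenoflowSpecError", "field of view narrower than the channel")
  xUp <- round(spec@upstreamInView / px)        # upstream stenotic corner
  bx <- bumpX(spec@geometry)
  xDown <- xUp + round((bx[["expansion_start"]] - bx[["contraction_end"]]) / px)
  if (xDown > nx)
    stopSteno("stenoflowSpecError", "stenotic section leaves the field of view")
  xcPix <- xUp + spec@clotCenter / px
  zcPix <- (z0 + z1) / 2
  nFrames <- max(2L, floor(spec@duration * spec@frameRate))
  ts <- seq_len(nFrames) / spec@frameRate
  base <- matrix(0.45, nz, nx)
  base[z0:z1, ] <- 0.55
  # stenosis border ticks in the margins (outside the averaged channel rows)
  tick <- c(pmax(z0 - 4L, 1L):(z0 - 1L), (z1 + 1L):pmin(z1 + 4L, nz))
  base[tick, c(xUp, xDown)] <- 0.2
  gx <- exp(-(seq_len(nx) - xcPix)^2 / (2 * (spec@clotSigma[1L] / px)^2))
  gz <- exp(-(seq_len(nz) - zcPix)^2 / (2 * (spec@clotSigma[2L] / px)^2))
  clot <- outer(gz, gx)
  sgn <- if (spec@modality == "WB") 1 else -1
  frames <- array(0, dim = c(nz, nx, nFrames))
  for (k in seq_len(nFrames)) {
    amp <- spec@clotAmplitude * min(ts[k] / spec@tOcclusion, 1)
    f <- base + sgn * amp * clot +
      matrix(stats::rnorm(nz * nx, 0, spec@imageNoise), nz, nx)
    frames[, , k] <- pmin(pmax(f, 0), 1)
  }
  corners <- cornerAnnotation(
    data.frame(x = c(xUp, xUp, xDown, xDown),
               z = c(z0, z1, z0, z1)),
    chamber = "vanRooij")
  list(stack = imageStack(frames, ts, px, spec@modality),
       corners = corners)
}
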