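#' Build a cell snapshot series
#'
#' @param data data.frame with columns \code{t} (s), \code{id}, \code{type}
#'   (\code{"RBC"}/\code{"PLT"}), \code{x}, \code{y}, \code{z} (m).
#' @param bounds named numeric(6) domain bounds (xmin, xmax, ymin, ymax,
#'   zmin, zmax); x is treated as periodic over \code{[xmin, xmax)}.
#' @param cellVolumes named numeric, cell volume per type (m^3). Defaults
#'   to literature values: 90 um^3 per red cell, 6 um^3 per platelet.
#' @param plateletDiameter platelet diameter (m); sets the translocation
#'   distance used by [residenceTimeMap()].
#' @return A [CellSnapshotSeries-class].
#' @export
cellSnapshotSeries <- function(data, bounds,
                               cellVolumes = c(RBC = 90e-18, PLT = 6e-18),
                               plateletDiameter = 2e-6) {
  ts <- sort(unique(data$t))
  dtSnap <- if (length(ts) > 1L) mean(diff(ts)) else 0
  newValidated("CellSnapshotSeries", "stenoflowValidationError",
               data = as.data.frame(data), dtSnap = dtSnap,
               cellVolumes = cellVolumes,
               plateletDiameter = plateletDiameter, bounds = bounds)
}

snapshotTimes <- function(series) sort(unique(series@data$t))

# shared binning setup: edges covering the (x, y) bounds
binEdges <- function(series, bins) {
  b <- series@bounds
  nbx <- max(1L, ceiling((b[["xmax"]] - b[["xmin"]]) / bins - 1e-9))
  nby <- max(1L, ceiling((b[["ymax"]] - b[["ymin"]]) / bins - 1e-9))
  list(x = b[["xmin"]] + bins * (0:nbx),
       y = b[["ymin"]] + bins * (0:nby))
}

binIndex <- function(v, edges) {
  i <- floor((v - edges[1L]) / (edges[2L] - edges[1L])) + 1L
  pmin.int(pmax.int(i, 1L), length(edges) - 1L)
}

windowOrDefault <- function(series, window) {
  if (is.null(window)) {
    ts <- snapshotTimes(series)
    c(ts[1L] - series@dtSnap, ts[length(ts)])
  } else window
}

#' Cell flux map
#'
#' Time-averaged count of cell presences per spatial bin: the number of
#' cells of the requested type observed in each (x, y) bin, summed over all
#' snapshots in the window and divided by the window length. z is collapsed.
#' A stationary cell seen in every one of \code{n} snapshots over a window
#' of length \code{T} therefore contributes \code{n / T} (s^-1) to its bin.
#'
#' @param series a [CellSnapshotSeries-class].
#' @param type \code{"PLT"} or \code{"RBC"}.
#' @param bins square bin width (m).
#' @param window \code{c(t_start, t_end)} (s); snapshots with
#'   \code{t_start < t <= t_end} are used. Defaults to the full series.
#' @return A [BinnedFieldMap-class] of kind \code{"flux"}.
#' @export
fluxMap <- function(series, type = c("PLT", "RBC"), bins = 2e-6,
                    window = NULL) {
  type <- match.arg(type)
  window <- windowOrDefault(series, window)
  d <- series@data
  d <- d[d$type == type & d$t > window[1L] & d$t <= window[2L], , drop = FALSE]
  nSnap <- length(unique(d$t))
  if (length(unique(series@data$t[series@data$t > window[1L] &
                                  series@data$t <= window[2L]])) < 2L)
    stopSteno("stenoflowWindowError",
              "window [%g, %g] s contains fewer than 2 snapshots",
              window[1L], window[2L])
  e <- binEdges(series, bins)
  nbx <- length(e$x) - 1L; nby <- length(e$y) - 1L
  counts <- matrix(0, nbx, nby)
  if (nrow(d)) {
    ix <- binIndex(d$x, e$x); iy <- binIndex(d$y, e$y)
    tab <- tabulate(ix + (iy - 1L) * nbx, nbins = nbx * nby)
    counts <- matrix(tab, nbx, nby)
  }
  new("BinnedFieldMap", xEdges = e$x, yEdges = e$y,
      values = counts / diff(window), kind = "flux", window = window,
      extra = list(nSnapshots = nSnap))
}

#' Platelet residence-time map
#'
#' The residence time of a platelet visit is the time it takes the platelet
#' to translocate its own diameter: starting from each snapshot position,
#' the first time lag at which the cumulative path length of the (minimum-
#' image unwrapped) trajectory reaches \code{d}, linearly interpolated
#' between snapshots. Each visit is assigned to the bin of the platelet's
#' position at the visit start; the bin value is the mean over uncensored
#' visits. Platelets that never translocate \code{d} inside the window are
#' censored at the window end and tallied separately
#' (\code{extra$censored}).
#'
#' @inheritParams fluxMap
#' @param d translocation distance (m); defaults to the platelet diameter.
#' @return A [BinnedFieldMap-class] of kind \code{"residence"}; unvisited
#'   bins are \code{NA}.
#' @export
residenceTimeMap <- function(series, bins = 2e-6, window = NULL,
                             d = series@plateletDiameter) {
  window <- windowOrDefault(series, window)
  dat <- series@data
  dat <- dat[dat$type == "PLT" & dat$t > window[1L] & dat$t <= window[2L], ,
             drop = FALSE]
  if (anyDuplicated(dat[, c("id", "t")]))
    stopSteno("stenoflowTrajectoryError",
              "duplicate (id, t) records: trajectories are not linkable")
  e <- binEdges(series, bins)
  nbx <- length(e$x) - 1L; nby <- length(e$y) - 1L
  Lx <- series@bounds[["xmax"]] - series@bounds[["xmin"]]
  dat <- dat[order(dat$id, dat$t), , drop = FALSE]
  kAll <- resAll <- kCensAll <- list()
  for (sp in split(dat, dat$id)) {
    n <- nrow(sp)
    if (n < 2L) next
    dxs <- diff(sp$x)
    dxs <- dxs - Lx * round(dxs / Lx)      # minimum-image unwrap in x
    step <- sqrt(dxs^2 + diff(sp$y)^2 + diff(sp$z)^2)
    S <- c(0, cumsum(step))
    tv <- sp$t
    k <- binIndex(sp$x, e$x) + (binIndex(sp$y, e$y) - 1L) * nbx
    # first arc-length station at which the cumulative path from visit i
    # reaches d, interpolated linearly inside the crossing step
    target <- S + d
    cens <- target > S[n]
    mi <- pmin.int(findInterval(target, S), n)
    need <- S[mi] < target                 # crossing lies inside step mi
    mi2 <- pmin.int(mi + 1L, n)
    frac <- (target - S[mi]) / pmax(S[mi2] - S[mi], .Machine$double.xmin)
    tEnd <- ifelse(need, tv[mi] + frac * (tv[mi2] - tv[mi]), tv[mi])
    res <- tEnd - tv
    kAll <- c(kAll, list(k[!cens]))
    resAll <- c(resAll, list(res[!cens]))
    kCensAll <- c(kCensAll, list(k[cens]))
  }
  sums <- matrix(0, nbx, nby)
  nVis <- matrix(0L, nbx, nby)
  nCens <- matrix(0L, nbx, nby)
  kAll <- unlist(kAll); resAll <- unlist(resAll); kCensAll <- unlist(kCensAll)
  if (length(kAll)) {
    agg <- rowsum(resAll, kAll)
    idx <- as.integer(rownames(agg))
    sums[idx] <- agg[, 1L]
    nVis[] <- tabulate(kAll, nbins = nbx * nby)
  }
  if (length(kCensAll)) nCens[] <- tabulate(kCensAll, nbins = nbx * nby)
  vals <- sums / nVis
  vals[nVis == 0L] <- NA_real_
  new("BinnedFieldMap", xEdges = e$x, yEdges = e$y, values = vals,
      kind = "residence", window = window,
      extra = list(visits = nVis, censored = nCens,
                   censoredTime = diff(window)))
}

#' Red-blood-cell volume-fraction map
#'
#' Mean red-cell count per bin per snapshot, converted to a volume fraction
#' with the per-cell volume and the bin volume (bin area times the domain
#' width), clipped to [0, 1].
#'
#' @inheritParams fluxMap
#' @return A [BinnedFieldMap-class] of kind \code{"volume_fraction"}.
#' @export
rbcVolumeFraction <- function(series, bins = 2e-6, window = NULL) {
  if (!("RBC" %in% names(series@cellVolumes)) ||
      !is.finite(series@cellVolumes[["RBC"]]))
    stopSteno("stenoflowConfigurationError",
              "red-cell volume 'cellVolumes[\"RBC\"]' is required")
  window <- windowOrDefault(series, window)
  d <- series@data
  d <- d[d$type == "RBC" & d$t > window[1L] & d$t <= window[2L], ,
         drop = FALSE]
  ts <- unique(series@data$t)
  nSnap <- sum(ts > window[1L] & ts <= window[2L])
  if (nSnap < 1L)
    stopSteno("stenoflowWindowError", "window contains no snapshots")
  e <- binEdges(series, bins)
  nbx <- length(e$x) - 1L; nby <- length(e$y) - 1L
  counts <- matrix(0, nbx, nby)
  if (nrow(d)) {
    ix <- binIndex(d$x, e$x); iy <- binIndex(d$y, e$y)
    counts <- matrix(tabulate(ix + (iy - 1L) * nbx, nbins = nbx * nby),
                     nbx, nby)
  }
  Wz <- series@bounds[["zmax"]] - series@bounds[["zmin"]]
  vr <- series@cellVolumes[["RBC"]]
  phi <- (counts / nSnap) * vr / (bins^2 * Wz)
  phi <- pmin(pmax(phi, 0), 1)
  new("BinnedFieldMap", xEdges = e$x, yEdges = e$y, values = phi,
      kind = "volume_fraction", window = window,
      extra = list(nSnapshots = nSnap))
}

#' Map accessors
#'
#' @param m a [BinnedFieldMap-class].
#' @return \code{mapValues}: the per-bin value matrix; \code{binCentersX},
#'   \code{binCentersY}: bin centre coordinates (m).
#' @name map-accessors
NULL

#' @rdname map-accessors
#' @export
mapValues <- function(m) m@values
#' @rdname map-accessors
#' @export
binCentersX <- function(m) (m@xEdges[-1L] + m@xEdges[-length(m@xEdges)]) / 2
#' @rdname map-accessors
#' @export
binCentersY <- function(m) (m@yEdges[-1L] + m@yEdges[-length(m@yEdges)]) / 2
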