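#' @import methods
NULL

setClassUnion("numericOrNULL", members = c("numeric", "NULL"))

#' Parametric stenotic flow-chamber geometry
#'
#' Side-view parameterisation of a rectangular micro-channel carrying a single
#' trapezoidal stenotic bump on one wall. Coordinates are flow-wise \code{x}
#' and cross-channel \code{y} (with \code{y = 0} on the flat glass wall);
#' the channel width \code{W} spans the third (\code{z}) direction, which the
#' side-view treatment collapses. All lengths are SI metres, the ramp angle is
#' in degrees measured between the ramp face and the channel wall.
#'
#' @slot H channel height (m).
#' @slot W channel width (m); a pure scale factor for 2-D flow solutions.
#' @slot L total flow-wise domain length (m).
#' @slot s stenosis severity, the fraction of lumen height removed (0-1).
#' @slot theta contraction/expansion ramp angle from the wall plane (degrees).
#' @slot Ls flat throat length (m), excluding the ramps.
#' @slot upstream,downstream straight lengths before/after the stenotic
#'   feature (m).
#' @slot stenoticWall which wall carries the bump: \code{"pdms"} (the
#'   \code{y = H} side) or \code{"glass"} (\code{y = 0}).
#'
#' @seealso [chamberGeometry()], [vanRooijGeometry()]
#' @export
setClass("ChamberGeometry",
  representation(
    H = "numeric", W = "numeric", L = "numeric",
    s = "numeric", theta = "numeric", Ls = "numeric",
    upstream = "numeric", downstream = "numeric",
    stenoticWall = "character"
  )
)

setValidity("ChamberGeometry", function(object) {
  fields <- c(
    channel_height = object@H, channel_width = object@W,
    domain_length = object@L, throat_length = object@Ls,
    upstream_length = object@upstream, downstream_length = object@downstream
  )
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("field '%s' must be a strictly positive length", nm))
  }
  if (length(object@s) != 1L || !is.finite(object@s) ||
      object@s <= 0 || object@s >= 1)
    return("field 'stenosis_severity' must lie strictly between 0 and 1")
  if (length(object@theta) != 1L || !is.finite(object@theta) ||
      object@theta <= 0 || object@theta > 90)
    return("field 'ramp_angle' must lie in (0, 90] degrees")
  hs <- (1 - object@s) * object@H
  if (hs <= 0) return("throat lumen height hs = (1 - s) * H must be positive")
  if (!object@stenoticWall %in% c("pdms", "glass"))
    return("field 'stenotic_wall' must be \"pdms\" or \"glass\"")
  run <- (object@H - hs) / tan(object@theta * pi / 180)
  tot <- object@upstream + 2 * run + object@Ls + object@downstream
  if (abs(tot - object@L) > 1e-9 + 1e-5 * object@L)
    return(sprintf(
      "field 'domain_length' (%.6g m) inconsistent with upstream + 2*ramp_run + throat + downstream (%.6g m)",
      object@L, tot))
  TRUE
})

setClassUnion("ChamberGeometryOrNULL", members = c("ChamberGeometry", "NULL"))

#' Rasterized solid mask of a chamber geometry
#'
#' Boolean occupancy grid of the side-view geometry. A cell is fluid iff its
#' centre lies strictly inside the fluid polygon (half-open, centre-sampled
#' rule). Cell centres sit at \code{origin + (index - 1) * dx}.
#'
#' @slot dx grid spacing (m).
#' @slot solid logical Nx-by-Ny matrix, \code{TRUE} for solid cells.
#' @slot origin numeric(2), the (x, y) position of the first cell centre.
#' @slot geometry the source [ChamberGeometry-class], or \code{NULL} for
#'   hand-built masks.
#'
#' @seealso [rasterizeGeometry()]
#' @export
setClass("SolidMask",
  representation(
    dx = "numeric", solid = "matrix", origin = "numeric",
    geometry = "ChamberGeometryOrNULL"
  )
)

setValidity("SolidMask", function(object) {
  if (length(object@dx) != 1L || !is.finite(object@dx) || object@dx <= 0)
    return("grid spacing 'dx' must be a positive length")
  if (!is.logical(object@solid)) return("'solid' must be a logical matrix")
  if (length(object@origin) != 2L) return("'origin' must be numeric(2)")
  TRUE
})

#' Newtonian fluid parameters
#'
#' Density and kinematic viscosity of the continuum fluid; the dynamic
#' viscosity is derived as \code{mu = rho * nu} and therefore consistent to
#' machine precision by construction.
#'
#' @slot rho density (kg m^-3).
#' @slot nu kinematic viscosity (m^2 s^-1).
#'
#' @seealso [fluidSpec()], [prpFluid()], [wholeBloodFluid()]
#' @export
setClass("FluidSpec", representation(rho = "numeric", nu = "numeric"))

setValidity("FluidSpec", function(object) {
  if (length(object@rho) != 1L || !is.finite(object@rho) || object@rho <= 0)
    return("'rho' must be a positive density")
  if (length(object@nu) != 1L || !is.finite(object@nu) || object@nu <= 0)
    return("'nu' must be a positive kinematic viscosity")
  TRUE
})

#' Steady 2-D flow field on a regular node grid
#'
#' Solution of the steady incompressible flow problem in the rasterized
#' chamber, stored on grid nodes (multiples of \code{dx}; walls lie on
#' nodes). Velocities derive from the streamfunction, so the flow-wise
#' volumetric flux is identical at every x-station by construction.
#'
#' @slot dx node spacing (m).
#' @slot x,y node coordinates (m); x is periodic with period \code{L}.
#' @slot ux,uy velocity components (m s^-1), Nx-by-(Ny+1) matrices.
#' @slot psi streamfunction (m^2 s^-1).
#' @slot omega vorticity (s^-1); second-order wall values on wall nodes.
#' @slot nodeType integer matrix: 0 solid, 1 interior fluid, 2 wall node.
#' @slot Q imposed volumetric flow rate (m^3 s^-1); \code{W} the width used
#'   to scale it.
#' @slot bodyForce equivalent driving body force (N m^-3), recovered from the
#'   dissipation balance.
#' @slot residual relative linear-system residual of the discrete solution.
#' @slot converged logical.
#' @slot mask the [SolidMask-class] the problem was solved on.
#'
#' @seealso [solveFlow()]
#' @export
setClass("FlowField",
  representation(
    dx = "numeric", x = "numeric", y = "numeric",
    ux = "matrix", uy = "matrix", psi = "matrix", omega = "matrix",
    nodeType = "matrix", Q = "numeric", W = "numeric",
    bodyForce = "numeric", residual = "numeric", converged = "logical",
    mask = "SolidMask"
  )
)

#' Wall-offset shear profile
#'
#' Shear rate and stress sampled along a curve displaced a fixed offset from
#' one wall, following the wall contour (ramps and throat included on the
#' stenotic side). Samples near ramp corners are retained but flagged, since
#' the xy-component of the shear develops spike artefacts there.
#'
#' @slot x flow-wise sample positions (m).
#' @slot gammaDot xy shear rate (s^-1).
#' @slot tau xy shear stress (Pa), \code{mu * gammaDot} exactly.
#' @slot wall \code{"glass"} or \code{"pdms"}.
#' @slot offset inward offset from the wall (m).
#' @slot corner logical flag, \code{TRUE} for samples near a ramp corner.
#'
#' @seealso [wallProfile()]
#' @export
setClass("WallProfile",
  representation(
    x = "numeric", gammaDot = "numeric", tau = "numeric",
    wall = "character", offset = "numeric", corner = "logical"
  )
)

#' Timestamped labelled cell-position series
#'
#' Periodic snapshots of cell positions with type labels, the raw material
#' for flux, residence-time and volume-fraction maps. Positions are 3-D; the
#' analysis collapses z.
#'
#' @slot data data.frame with columns \code{t, id, type, x, y, z} (SI units,
#'   type in \code{"RBC"}/\code{"PLT"}).
#' @slot dtSnap snapshot interval (s), constant within 1\%.
#' @slot cellVolumes named numeric, per-type cell volume (m^3).
#' @slot plateletDiameter platelet diameter (m), default 2 um.
#' @slot bounds named numeric(6): xmin, xmax, ymin, ymax, zmin, zmax.
#'
#' @seealso [cellSnapshotSeries()], [synthCellSnapshots()]
#' @export
setClass("CellSnapshotSeries",
  representation(
    data = "data.frame", dtSnap = "numeric", cellVolumes = "numeric",
    plateletDiameter = "numeric", bounds = "numeric"
  )
)

setValidity("CellSnapshotSeries", function(object) {
  need <- c("t", "id", "type", "x", "y", "z")
  if (!all(need %in% names(object@data)))
    return(sprintf("snapshot data must have columns %s",
                   paste(need, collapse = ", ")))
  ts <- sort(unique(object@data$t))
  if (length(ts) < 1L) return("snapshot series is empty")
  if (length(ts) > 1L) {
    dts <- diff(ts)
    if (any(dts <= 0)) return("snapshot times must be strictly increasing")
    if ((max(dts) - min(dts)) > 0.01 * mean(dts))
      return("snapshot interval must be constant within 1%")
  }
  b <- object@bounds
  if (length(b) != 6L ||
      !all(c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax") %in% names(b)))
    return("'bounds' must be named numeric(6): xmin..zmax")
  with(object@data, {
    if (any(x < b["xmin"] - 1e-12) || any(x > b["xmax"] + 1e-12) ||
        any(y < b["ymin"] - 1e-12) || any(y > b["ymax"] + 1e-12) ||
        any(z < b["zmin"] - 1e-12) || any(z > b["zmax"] + 1e-12))
      return("cell positions fall outside the stated domain bounds")
    TRUE
  })
})

#' Binned (x, y) field map
#'
#' z-collapsed map of a per-bin quantity averaged over a time window: cell
#' flux (s^-1), residence time (s) or volume fraction (dimensionless).
#'
#' @slot xEdges,yEdges bin edges (m).
#' @slot values matrix of per-bin values, \code{length(xEdges)-1} by
#'   \code{length(yEdges)-1}; unvisited bins are \code{NA} for residence maps.
#' @slot kind one of \code{"flux"}, \code{"residence"}, \code{"volume_fraction"}.
#' @slot window averaging window \code{c(t_start, t_end)} (s).
#' @slot extra list of auxiliary maps (e.g. censored-visit counts).
#'
#' @export
setClass("BinnedFieldMap",
  representation(
    xEdges = "numeric", yEdges = "numeric", values = "matrix",
    kind = "character", window = "numeric", extra = "list"
  )
)

setValidity("BinnedFieldMap", function(object) {
  if (!object@kind %in% c("flux", "residence", "volume_fraction"))
    return("kind must be one of flux, residence, volume_fraction")
  if (!identical(dim(object@values),
                 c(length(object@xEdges) - 1L, length(object@yEdges) - 1L)))
    return("values matrix does not match the bin edges")
  v <- object@values
  if (object@kind == "flux" && any(v < 0, na.rm = TRUE))
    return("flux values must be non-negative")
  if (object@kind == "volume_fraction" &&
      (any(v < 0, na.rm = TRUE) || any(v > 1, na.rm = TRUE)))
    return("volume fractions must lie in [0, 1]")
  TRUE
})

#' Cell-depleted-layer thickness profile
#'
#' Per-x-station thickness of the near-wall layer containing at most a
#' stated fraction of the red-cell volume fraction, for one wall.
#'
#' @slot x flow-wise positions (m, bin centres of the source map).
#' @slot delta layer thickness (m), capped at the local lumen half-height.
#' @slot wall \code{"glass"} or \code{"pdms"}.
#' @slot threshold the fraction used (default 0.01).
#' @slot mode \code{"relative"} (fraction of the column maximum) or
#'   \code{"absolute"}.
#' @slot flagged logical: columns where no red cells were seen and the cap
#'   was returned.
#'
#' @seealso [cflThickness()]
#' @export
setClass("CFLProfile",
  representation(
    x = "numeric", delta = "numeric", wall = "character",
    threshold = "numeric", mode = "character", flagged = "logical"
  )
)

#' Mass-balance outflow trace
#'
#' Cumulative outflow mass versus time from the collection balance, with an
#' optional paired evaporation-reference trace recorded from a dish of the
#' same mixture on an adjacent balance.
#'
#' @slot time sample times (s), strictly increasing.
#' @slot mass cumulative mass (kg).
#' @slot refTime,refMass evaporation-reference trace, or \code{NULL}.
#' @slot rho fluid density (kg m^-3) used to convert mass slope to flow.
#' @slot corrected logical: has the evaporation correction been applied?
#'
#' @seealso [massTrace()], [correctEvaporation()], [flowRate()],
#'   [occlusionTime()]
#' @export
setClass("MassTrace",
  representation(
    time = "numeric", mass = "numeric",
    refTime = "numericOrNULL", refMass = "numericOrNULL",
    rho = "numeric", corrected = "logical"
  )
)

setValidity("MassTrace", function(object) {
  if (length(object@time) != length(object@mass))
    return("time and mass must have equal length")
  if (any(diff(object@time) <= 0))
    return("times must be strictly increasing")
  if (!is.null(object@refTime)) {
    if (is.null(object@refMass) ||
        length(object@refTime) != length(object@refMass))
      return("reference trace must pair times with masses")
    if (any(diff(object@refTime) <= 0))
      return("reference times must be strictly increasing")
  }
  TRUE
})

#' Grey-scale image stack
#'
#' Time-lapse bright-field frames of the chamber seen from above: rows are
#' the width (z) direction, columns the flow (x) direction. Intensities are
#' in [0, 1].
#'
#' @slot frames numeric array, nz-by-nx-by-nframes.
#' @slot timestamps frame times (s), increasing.
#' @slot pixelSize pixel pitch (m/px).
#' @slot modality \code{"WB"} (aggregates brighten) or \code{"PRP"}
#'   (aggregates darken).
#'
#' @seealso [imageStack()], [synthImageStack()]
#' @export
setClass("ImageStack",
  representation(
    frames = "array", timestamps = "numeric",
    pixelSize = "numeric", modality = "character"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an nz x nx x nframes array")
  if (length(object@timestamps) != d[3L])
    return("one timestamp per frame required")
  if (d[3L] > 1L && any(diff(object@timestamps) <= 0))
    return("timestamps must be increasing")
  if (!object@modality %in% c("WB", "PRP"))
    return("modality must be \"WB\" or \"PRP\"")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a positive length")
  TRUE
})

#' Stenotic-region corner annotation
#'
#' Pixel coordinates of the stenotic-region corners clicked/marked on an
#' early frame: four corners for a chamber whose near-vertical ramps collapse
#' to single edges in top view, eight when contraction and expansion areas
#' are resolved. The x-pixels of the contraction/expansion borders and the
#' upstream alignment reference are derived.
#'
#' @slot corners data.frame with pixel columns \code{x}, \code{z}, ordered.
#' @slot chamber \code{"vanRooij"} (4 corners) or \code{"casa"} (8 corners).
#' @slot xMarks named numeric: \code{contraction_start}, \code{throat_start},
#'   \code{throat_end}, \code{expansion_end} (x pixels).
#' @slot upstreamRef x pixel of the upstream stenotic corner (the alignment
#'   reference, equal to \code{throat_start}).
#'
#' @seealso [cornerAnnotation()]
#' @export
setClass("CornerAnnotation",
  representation(
    corners = "data.frame", chamber = "character",
    xMarks = "numeric", upstreamRef = "numeric"
  )
)

setValidity("CornerAnnotation", function(object) {
  if (!object@chamber %in% c("vanRooij", "casa"))
    return("chamber must be \"vanRooij\" or \"casa\"")
  nc <- nrow(object@corners)
  if (object@chamber == "vanRooij" && nc != 4L)
    return("vanRooij annotation requires 4 corners")
  if (object@chamber == "casa" && nc != 8L)
    return("casa annotation requires 8 corners")
  m <- object@xMarks
  need <- c("contraction_start", "throat_start", "throat_end", "expansion_end")
  if (!all(need %in% names(m)))
    return("xMarks must name contraction_start, throat_start, throat_end, expansion_end")
  if (!(m["contraction_start"] <= m["throat_start"] &&
        m["throat_start"] < m["throat_end"] &&
        m["throat_end"] <= m["expansion_end"]))
    return("corner x marks must be ordered: contraction <= throat start < throat end <= expansion")
  TRUE
})

#' Width-averaged, normalized, corner-aligned intensity profile
#'
#' Mean pixel intensity over the channel width as a function of the flow
#' coordinate, min-max normalized, with the upstream stenotic corner at
#' \code{x = 0}. PRP profiles are inverted so that more platelets always
#' means higher intensity.
#'
#' @slot x aligned positions (m); 0 at the upstream stenotic corner.
#' @slot intensity normalized intensity in [0, 1] (all 0 when degenerate).
#' @slot modality \code{"WB"} or \code{"PRP"}.
#' @slot inverted was the raw profile inverted?
#' @slot degenerate flat-frame flag: normalization was impossible.
#'
#' @seealso [intensityProfile()], [occlusionDistance()]
#' @export
setClass("IntensityProfile",
  representation(
    x = "numeric", intensity = "numeric", modality = "character",
    inverted = "logical", degenerate = "logical"
  )
)

#' Occlusion analysis result
#'
#' @slot time occlusion time (s).
#' @slot frameIndex index of the occlusion frame in the stack.
#' @slot distance distance from the upstream stenotic corner to the
#'   intensity peak (m).
#' @slot flags character vector of qualifiers (\code{"plateau_open"},
#'   \code{"right_censored"}, \code{"tie"}).
#'
#' @seealso [analyzeOcclusion()]
#' @export
setClass("OcclusionResult",
  representation(
    time = "numeric", frameIndex = "numeric",
    distance = "numeric", flags = "character"
  )
)

#' Margination statistics for the cell snapshot generator
#'
#' Prescribes the statistical structure of the generated suspension: a
#' red-cell-depleted layer of width \code{cflWidth} at each wall, a
#' platelet-free sliver immediately at the wall, a near-wall platelet
#' enhancement band (factor \code{enhancement} over the first 5 um beyond
#' the sliver; 2 for whole blood, 1 for platelet-rich plasma), and optional
#' quarter-/three-quarter-height platelet bands.
#'
#' @slot cflWidth red-cell-free layer width delta* (m).
#' @slot enhancement near-wall platelet enhancement factor f (>= 1).
#' @slot coreHematocrit core red-cell volume fraction (0-0.6).
#' @slot bandAmplitude relative amplitude of the mid-height platelet bands
#'   (0 disables them).
#' @slot bandWidth width of those bands (m).
#' @slot sliver platelet-free sliver width at the wall (m).
#' @slot nRbc,nPlt cell counts.
#' @slot jitterSigma per-snapshot isotropic positional jitter (m).
#' @slot seed RNG seed.
#'
#' @seealso [marginationSpec()], [synthCellSnapshots()]
#' @export
setClass("MarginationSpec",
  representation(
    cflWidth = "numeric", enhancement = "numeric",
    coreHematocrit = "numeric", bandAmplitude = "numeric",
    bandWidth = "numeric", sliver = "numeric",
    nRbc = "numeric", nPlt = "numeric",
    jitterSigma = "numeric", seed = "numeric"
  )
)

setValidity("MarginationSpec", function(object) {
  if (object@enhancement < 1) return("enhancement factor f must be >= 1")
  if (object@coreHematocrit <= 0 || object@coreHematocrit >= 0.6)
    return("coreHematocrit must lie in (0, 0.6)")
  if (object@cflWidth < 0) return("cflWidth must be non-negative")
  if (object@nRbc < 0 || object@nPlt < 0) return("cell counts must be >= 0")
  TRUE
})

#' Synthetic occlusion-experiment specification
#'
#' Ground truth for a complete synthetic experiment: imposed flow rate,
#' programmed occlusion time, clot centre (measured downstream from the
#' upstream stenotic corner), acquisition rates and noise levels.
#'
#' @slot geometry the chamber.
#' @slot Q volumetric flow rate (m^3 s^-1).
#' @slot tOcclusion programmed occlusion time t* (s).
#' @slot clotCenter clot centre x0 (m, downstream of the upstream corner).
#' @slot clotSigma numeric(2): Gaussian clot widths in (x, z) (m).
#' @slot clotAmplitude peak intensity change at occlusion (image units).
#' @slot modality \code{"WB"} or \code{"PRP"}.
#' @slot imageNoise per-pixel Gaussian noise sd.
#' @slot balanceNoise balance noise sd (kg).
#' @slot evapRate evaporation mass rate (kg s^-1, typically negative).
#' @slot rampDuration flow ramp-down duration before t* (s; 0 = abrupt).
#' @slot rho fluid density (kg m^-3).
#' @slot frameRate image acquisition rate (Hz).
#' @slot balanceRate balance sampling rate (Hz).
#' @slot pixelSize image pixel pitch (m/px).
#' @slot fov numeric(2): imaged field of view in (x, z) (m).
#' @slot upstreamInView distance from the left image edge to the upstream
#'   stenotic corner (m).
#' @slot duration recording length (s).
#' @slot seed RNG seed.
#'
#' @seealso [experimentSpec()], [synthMassTrace()], [synthImageStack()]
#' @export
setClass("ExperimentSpec",
  representation(
    geometry = "ChamberGeometry", Q = "numeric", tOcclusion = "numeric",
    clotCenter = "numeric", clotSigma = "numeric", clotAmplitude = "numeric",
    modality = "character", imageNoise = "numeric", balanceNoise = "numeric",
    evapRate = "numeric", rampDuration = "numeric", rho = "numeric",
    frameRate = "numeric", balanceRate = "numeric", pixelSize = "numeric",
    fov = "numeric", upstreamInView = "numeric", duration = "numeric",
    seed = "numeric"
  )
)

setValidity("ExperimentSpec", function(object) {
  if (object@tOcclusion <= 0 || object@tOcclusion >= object@duration)
    return("occlusion time must fall inside the recording")
  if (!object@modality %in% c("WB", "PRP"))
    return("modality must be \"WB\" or \"PRP\"")
  xmax <- object@fov[1L] - object@upstreamInView
  if (object@clotCenter < -object@upstreamInView || object@clotCenter > xmax)
    return("clot centre x0 must lie inside the imaged span")
  if (!all(is.finite(c(object@Q, object@imageNoise, object@balanceNoise,
                       object@evapRate, object@rampDuration))))
    return("all rates must be finite")
  TRUE
})
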