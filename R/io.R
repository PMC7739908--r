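# Plain-text interchange formats: YAML/JSON for geometry and corners, CSV
# (+ JSON sidecar) for traces, snapshots, profiles and fields, TIFF for
# image stacks.

geometryFields <- c("channel_height", "channel_width", "domain_length",
                    "stenosis_severity", "ramp_angle", "throat_length",
                    "upstream_length", "downstream_length", "stenotic_wall")

#' Read / write chamber geometry files
#'
#' Geometry parameter files are YAML or JSON maps whose keys are exactly
#' the field names \code{channel_height}, \code{channel_width},
#' \code{domain_length}, \code{stenosis_severity}, \code{ramp_angle},
#' \code{throat_length}, \code{upstream_length}, \code{downstream_length},
#' \code{stenotic_wall}, all lengths in metres. The format follows the
#' file extension (\code{.yaml}/\code{.yml} or \code{.json}).
#'
#' @param g a [ChamberGeometry-class].
#' @param path file path.
#' @return \code{readGeometry}: a [ChamberGeometry-class];
#'   \code{writeGeometry}: the path, invisibly.
#' @export
writeGeometry <- function(g, path) {
  rec <- list(
    channel_height = g@H, channel_width = g@W, domain_length = g@L,
    stenosis_severity = g@s, ramp_angle = g@theta, throat_length = g@Ls,
    upstream_length = g@upstream, downstream_length = g@downstream,
    stenotic_wall = g@stenoticWall
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(rec, path, precision = 15L)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  bad <- setdiff(names(rec), geometryFields)
  if (length(bad))
    stopSteno("stenoflowValidationError",
              "unrecognized geometry key(s): %s", paste(bad, collapse = ", "))
  chamberGeometry(
    H = rec$channel_height, W = rec$channel_width,
    s = rec$stenosis_severity, theta = rec$ramp_angle,
    Ls = rec$throat_length, upstream = rec$upstream_length,
    downstream = rec$downstream_length, L = rec$domain_length,
    stenoticWall = if (is.null(rec$stenotic_wall)) "pdms" else rec$stenotic_wall
  )
}

#' Read / write cell snapshot CSV
#'
#' Long-format CSV with columns \code{t, id, type, x, y, z}; the domain
#' bounds travel in a JSON sidecar \code{<path>.json}.
#'
#' @param series a [CellSnapshotSeries-class].
#' @param path CSV file path.
#' @return \code{readSnapshots}: a [CellSnapshotSeries-class].
#' @export
writeSnapshots <- function(series, path) {
  utils::write.csv(series@data, path, row.names = FALSE)
  meta <- list(bounds = as.list(series@bounds),
               cellVolumes = as.list(series@cellVolumes),
               plateletDiameter = series@plateletDiameter)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSnapshots
#' @export
readSnapshots <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cellSnapshotSeries(d, bounds = unlist(meta$bounds),
                     cellVolumes = unlist(meta$cellVolumes),
                     plateletDiameter = meta$plateletDiameter)
}

#' Read / write mass-balance CSV
#'
#' Columns \code{t, mass} and optionally \code{ref_mass} (a reference
#' sampled on the same grid); density is stored in the header comment-free
#' sidecar \code{<path>.json}.
#'
#' @param trace a [MassTrace-class].
#' @param path CSV file path.
#' @return \code{readMassTrace}: a [MassTrace-class].
#' @export
writeMassTrace <- function(trace, path) {
  d <- data.frame(t = trace@time, mass = trace@mass)
  if (!is.null(trace@refTime) &&
      length(trace@refTime) == length(trace@time) &&
      isTRUE(all.equal(trace@refTime, trace@time))) {
    d$ref_mass <- trace@refMass
  }
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(list(rho = trace@rho, corrected = trace@corrected),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMassTrace
#' @export
readMassTrace <- function(path) {
  d <- utils::read.csv(path)
  metaPath <- paste0(path, ".json")
  rho <- 1025
  if (file.exists(metaPath))
    rho <- jsonlite::read_json(metaPath, simplifyVector = TRUE)$rho
  massTrace(d$t, d$mass,
            refTime = if ("ref_mass" %in% names(d)) d$t else NULL,
            refMass = if ("ref_mass" %in% names(d)) d$ref_mass else NULL,
            rho = rho)
}

#' Read / write corner annotations (JSON)
#'
#' Ordered list of \code{(x, z)} pixel pairs plus the chamber tag.
#'
#' @param corners a [CornerAnnotation-class].
#' @param path JSON file path.
#' @return \code{readCorners}: a [CornerAnnotation-class].
#' @export
writeCorners <- function(corners, path) {
  jsonlite::write_json(
    list(chamber = corners@chamber,
         corners = corners@corners[, c("x", "z")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCorners
#' @export
readCorners <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  cornerAnnotation(rec$corners, chamber = rec$chamber)
}

#' Read / write image stacks (TIFF + JSON sidecar)
#'
#' Multi-frame grey-scale TIFF; timestamps, pixel size and modality travel
#' in \code{<path>.json}.
#'
#' @param stack an [ImageStack-class].
#' @param path TIFF file path.
#' @param bitsPerSample TIFF bit depth (16 by default).
#' @return \code{readImageStack}: an [ImageStack-class].
#' @export
writeImageStack <- function(stack, path, bitsPerSample = 16L) {
  frames <- lapply(seq_len(dim(stack@frames)[3L]),
                   function(k) stack@frames[, , k])
  tiff::writeTIFF(frames, path, bits.per.sample = bitsPerSample)
  jsonlite::write_json(
    list(timestamps = stack@timestamps, pixel_size = stack@pixelSize,
         modality = stack@modality),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname readImageStack
#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  imageStack(frames, timestamps = meta$timestamps,
             pixelSize = meta$pixel_size, modality = meta$modality)
}

#' Write a wall profile to CSV
#'
#' Columns \code{x, gamma_dot, tau, corner} (corner-artefact flag).
#'
#' @param profile a [WallProfile-class].
#' @param path CSV file path.
#' @export
writeWallProfile <- function(profile, path) {
  utils::write.csv(
    data.frame(x = profile@x, gamma_dot = profile@gammaDot,
               tau = profile@tau, corner = profile@corner),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a binned field map to CSV
#'
#' Long format: \code{x, y} (bin centres) and \code{value}.
#'
#' @param map a [BinnedFieldMap-class].
#' @param path CSV file path.
#' @export
writeFieldMap <- function(map, path) {
  xc <- binCentersX(map); yc <- binCentersY(map)
  d <- expand.grid(x = xc, y = yc)
  d$value <- as.vector(map@values)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
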