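#' Default montage geometry configuration
#'
#' Parameterizes the schematic 12-tile montage: a 2 x 3 tile grid per
#' hemisphere in a flat head-surface frame (mm; x left to right, y posterior
#' to anterior). The default pitches are chosen so that the tile-averaged
#' channel census matches the headset this montage emulates: 44 tile-pair
#' channels of 15-60 mm center-to-center length (22 per hemisphere) and 36
#' dual-wavelength tile pairs in the 25-45 mm band.
#'
#' @param tilesPerHemisphere number of tiles per hemisphere (1..6); tiles are
#'   taken innermost-posterior first, so reduced montages keep the motor-ROI
#'   tiles.
#' @param columnPitch,rowPitch tile grid pitches (mm).
#' @param hemisphereOffset |x| of the innermost tile column (mm).
#' @param wavelengths source wavelengths (nm).
#' @param roiRadius radius (mm) around each motor-ROI center within which a
#'   channel midpoint is given a motor ROI label.
#' @param sourceOffsets,detectorOffsets within-tile optode offsets, matrices
#'   [n x 3] (mm).
#' @return a list usable as `config` for [buildDefaultMontage()].
#' @export
defaultGeometryConfig <- function(tilesPerHemisphere = 6,
                                  columnPitch = 14,
                                  rowPitch = 40,
                                  hemisphereOffset = 33,
                                  wavelengths = c(735, 850),
                                  roiRadius = 25,
                                  sourceOffsets = NULL,
                                  detectorOffsets = NULL) {
  ang <- function(deg) deg * pi / 180
  if (is.null(sourceOffsets)) {
    a <- ang(c(90, 210, 330))
    sourceOffsets <- cbind(5.5 * cos(a), 5.5 * sin(a), 0)
  }
  if (is.null(detectorOffsets)) {
    a <- ang(c(30, 150, 270))
    detectorOffsets <- rbind(c(0, 0, 0), cbind(8 * cos(a), 8 * sin(a), 0))
  }
  # tile slots per hemisphere ordered innermost-posterior first
  slots <- data.frame(
    col = c(0, 1, 2, 0, 1, 2),
    row = c(0, 0, 0, 1, 1, 1)
  )
  list(
    tilesPerHemisphere = tilesPerHemisphere,
    columnPitch = columnPitch, rowPitch = rowPitch,
    hemisphereOffset = hemisphereOffset,
    wavelengths = wavelengths, roiRadius = roiRadius,
    sourceOffsets = sourceOffsets, detectorOffsets = detectorOffsets,
    slots = slots
  )
}

#' Build the default tiled montage
#'
#' Constructs the full montage object from a geometry configuration: tile
#' centers, optode positions, and the exhaustive wavelength-resolved channel
#' table with source-detector lengths, midpoints, depth proxies (length/4)
#' and motor-ROI labels. The motor ROI on each hemisphere is centered on the
#' (up to two) innermost posterior-row tiles.
#'
#' @param config geometry configuration, see [defaultGeometryConfig()].
#' @return a [Montage-class] object.
#' @examples
#' m <- buildDefaultMontage()
#' nrow(channels(m))  # 3456 wavelength-resolved channels
#' @export
buildDefaultMontage <- function(config = defaultGeometryConfig()) {
  k <- config$tilesPerHemisphere
  stopIfNot(k >= 1 && k <= nrow(config$slots), "tilesPerHemisphere out of range")
  slots <- config$slots[seq_len(k), , drop = FALSE]
  tl <- do.call(rbind, lapply(c(-1, 1), function(s) {
    data.frame(
      hemisphere = if (s < 0) "left" else "right",
      cx = s * (config$hemisphereOffset + slots$col * config$columnPitch),
      cy = -config$rowPitch / 2 + slots$row * config$rowPitch,
      cz = 0, row = slots$row, col = slots$col
    )
  }))
  tl <- tl[order(tl$hemisphere == "right", tl$row, tl$col), ]
  tl$id <- seq_len(nrow(tl))
  rownames(tl) <- NULL

  mkOptodes <- function(offsets, kind, prefix, perTile) {
    do.call(rbind, lapply(seq_len(nrow(tl)), function(i) {
      data.frame(
        id = sprintf("%s%02d", prefix, (i - 1) * perTile + seq_len(perTile)),
        kind = kind, tile_id = tl$id[i],
        x = tl$cx[i] + offsets[, 1], y = tl$cy[i] + offsets[, 2],
        z = tl$cz[i] + offsets[, 3]
      )
    }))
  }
  src <- mkOptodes(config$sourceOffsets, "source", "S", nrow(config$sourceOffsets))
  det <- mkOptodes(config$detectorOffsets, "detector", "D", nrow(config$detectorOffsets))
  op <- rbind(src, det)
  rownames(op) <- NULL
  if (anyDuplicated(op$id)) stop("duplicate optode ids in geometry config")

  # ROI centers: mean of up to 2 innermost posterior-row tiles per hemisphere
  roiC <- t(vapply(c("left", "right"), function(h) {
    sub <- tl[tl$hemisphere == h & tl$row == 0, ]
    sub <- sub[order(abs(sub$cx)), ][seq_len(min(2, nrow(sub))), ]
    c(mean(sub$cx), mean(sub$cy), mean(sub$cz))
  }, numeric(3)))

  # exhaustive channel enumeration
  pairs <- expand.grid(si = seq_len(nrow(src)), di = seq_len(nrow(det)),
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[order(pairs$si, pairs$di), ]
  dx <- src$x[pairs$si] - det$x[pairs$di]
  dy <- src$y[pairs$si] - det$y[pairs$di]
  dz <- src$z[pairs$si] - det$z[pairs$di]
  len <- sqrt(dx^2 + dy^2 + dz^2)
  mid <- cbind(
    (src$x[pairs$si] + det$x[pairs$di]) / 2,
    (src$y[pairs$si] + det$y[pairs$di]) / 2,
    (src$z[pairs$si] + det$z[pairs$di]) / 2
  )
  sTile <- src$tile_id[pairs$si]
  dTile <- det$tile_id[pairs$di]
  hemi <- ifelse(tl$hemisphere[sTile] == tl$hemisphere[dTile],
                 tl$hemisphere[sTile], "cross")
  dl <- sqrt((mid[, 1] - roiC[1, 1])^2 + (mid[, 2] - roiC[1, 2])^2 +
               (mid[, 3] - roiC[1, 3])^2)
  dr <- sqrt((mid[, 1] - roiC[2, 1])^2 + (mid[, 2] - roiC[2, 2])^2 +
               (mid[, 3] - roiC[2, 3])^2)
  roi <- ifelse(dl <= config$roiRadius, "left_motor",
                ifelse(dr <= config$roiRadius, "right_motor", "none"))
  npair <- nrow(pairs)
  ch <- do.call(rbind, lapply(seq_along(config$wavelengths), function(wi) {
    data.frame(
      pair_id = seq_len(npair),
      source_id = src$id[pairs$si], detector_id = det$id[pairs$di],
      source_tile = sTile, detector_tile = dTile,
      wavelength = config$wavelengths[wi],
      length = len, mid_x = mid[, 1], mid_y = mid[, 2], mid_z = mid[, 3],
      depth_proxy = len / 4, hemisphere = hemi, roi = roi
    )
  }))
  ch <- ch[order(ch$pair_id, ch$wavelength), ]
  ch <- cbind(id = seq_len(nrow(ch)), ch)
  rownames(ch) <- NULL

  new("Montage",
      optodes = op, tiles = tl[, c("id", "hemisphere", "cx", "cy", "cz", "row", "col")],
      channels = ch, wavelengths = config$wavelengths,
      roiCenters = roiC, geometry = config)
}

#' Reduced desk-scale montage
#'
#' A small montage for simulation studies: one (enlarged) tile per
#' hemisphere over the motor ROIs, with within-tile optode offsets scaled so
#' that source-detector separations span the cortically sensitive 16-40 mm
#' range (96 wavelength-resolved channels, 48 pairs). Hemisphere offset is
#' widened so cross-hemisphere channels stay long (and noise-dominated).
#'
#' @param tilesPerHemisphere tiles kept per hemisphere.
#' @param optodeScale multiplier on within-tile optode offsets.
#' @param hemisphereOffset |x| of the tile column (mm).
#' @return a [Montage-class].
#' @export
reducedMontage <- function(tilesPerHemisphere = 1, optodeScale = 3,
                           hemisphereOffset = 60) {
  cfg <- defaultGeometryConfig(tilesPerHemisphere = tilesPerHemisphere,
                               hemisphereOffset = hemisphereOffset)
  cfg$sourceOffsets <- cfg$sourceOffsets * optodeScale
  cfg$detectorOffsets <- cfg$detectorOffsets * optodeScale
  buildDefaultMontage(cfg)
}

#' Read a montage geometry configuration from YAML
#'
#' @param path YAML file giving any subset of the [defaultGeometryConfig()]
#'   parameters; missing entries fall back to the defaults.
#' @return a geometry config list.
#' @export
readGeometryConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- defaultGeometryConfig()
  for (nm in intersect(names(y), names(cfg))) {
    v <- y[[nm]]
    if (nm %in% c("sourceOffsets", "detectorOffsets")) v <- do.call(rbind, v)
    cfg[[nm]] <- v
  }
  cfg
}

#' Export a montage to JSON
#'
#' Writes tiles, optodes and the channel table (including the geometry
#' configuration metadata) as JSON.
#' @param montage a [Montage-class].
#' @param path output file.
#' @export
writeMontageJSON <- function(montage, path) {
  cfg <- montage@geometry
  cfg$sourceOffsets <- unname(apply(cfg$sourceOffsets, 1, c, simplify = FALSE))
  cfg$detectorOffsets <- unname(apply(cfg$detectorOffsets, 1, c, simplify = FALSE))
  jsonlite::write_json(
    list(
      wavelengths = montage@wavelengths,
      tiles = tiles(montage), optodes = optodes(montage),
      channels = channels(montage),
      roi_centers = list(left = montage@roiCenters[1, ],
                         right = montage@roiCenters[2, ]),
      geometry = cfg
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' Restrict a channel table (or session) to a source-detector length band
#'
#' Keeps channels whose length satisfies `min_mm <= length <= max_mm`
#' (inclusive bounds).
#'
#' @param x a channel table (data.frame) or [NirsSession-class].
#' @param min_mm,max_mm length bounds in mm.
#' @return object of the same type with retained channels (and, for sessions,
#'   the matching intensity rows).
#' @export
channelLengthFilter <- function(x, min_mm = 0, max_mm = Inf) {
  stopIfNot(min_mm <= max_mm, "min_mm must not exceed max_mm")
  if (is(x, "NirsSession")) {
    keep <- x@channels$length >= min_mm & x@channels$length <= max_mm
    if (!any(keep)) stop("length filter removed every channel")
    x@intensity <- x@intensity[keep, , drop = FALSE]
    x@channels <- x@channels[keep, , drop = FALSE]
    rownames(x@channels) <- NULL
    return(x)
  }
  keep <- x$length >= min_mm & x$length <= max_mm
  if (!any(keep)) stop("length filter removed every channel")
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
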