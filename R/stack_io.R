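# Reading/writing stacks, ROIs, masks and feature tables.
#
# Conventions used throughout the package:
#   * voxel arrays are R arrays of dim (ny, nx, nz), 1-based [y, x, z];
#   * ROI polygons are in (x, y) pixel units, where the centre of the
#     pixel in column x, row y is the point (x, y);
#   * stacks hold non-negative integer photon counts.

#' Image stack
#'
#' One channel's 3D voxel grid plus its physical geometry. Values are
#' non-negative integers (photon counts); `bit_depth` is 12 for raw
#' photon-counting acquisitions and 16 after [adjust_to_16bit()].
#'
#' @param voxels 3D numeric array, dim (ny, nx, nz), non-negative integers.
#' @param bit_depth 12 or 16.
#' @param geometry A [voxel_geometry()].
#' @param channel Label, e.g. "mito", "neurofilament", "nuclei".
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, bit_depth, geometry, channel = "mito") {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(12L, 16L)) stop("bit_depth must be 12 or 16")
  if (any(voxels < 0)) stop("voxel values must be non-negative")
  if (any(voxels > 2^bit_depth - 1)) {
    stop(sprintf("voxel values exceed 2^%d - 1", bit_depth))
  }
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(voxels = voxels, bit_depth = bit_depth,
                 geometry = geometry, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack '%s': %d x %d x %d voxels, %d-bit, max %g\n",
              x$channel, d[1], d[2], d[3], x$bit_depth, max(x$voxels)))
  print(x$geometry)
  invisible(x)
}

#' Read a TIFF / OME-TIFF stack
#'
#' Pages become z-slices. Voxel geometry comes from embedded OME-XML
#' physical sizes when present, otherwise from the `geometry` argument;
#' with `prefer_file_geometry = FALSE` the argument wins even when
#' metadata exists.
#'
#' @param path TIFF file with >= 1 page; all pages must share one shape.
#' @param geometry Optional [voxel_geometry()] fallback/override.
#' @param bit_depth Declared bit depth of the data (default 16).
#' @param prefer_file_geometry Use embedded metadata when present (default).
#' @param channel Channel label for the result.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, geometry = NULL, bit_depth = 16L,
                       prefer_file_geometry = TRUE, channel = "mito") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("TIFF has no pages: ", path)
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop("TIFF pages have inconsistent shapes: ", path)
  }
  vox <- array(0, dim = c(shp[1], shp[2], length(pages)))
  for (z in seq_along(pages)) vox[, , z] <- pages[[z]]
  file_geom <- NULL
  desc <- attr(pages[[1L]], "description")
  if (!is.null(desc)) file_geom <- parse_ome_geometry(desc)
  g <- if (prefer_file_geometry && !is.null(file_geom)) file_geom else geometry
  if (is.null(g)) g <- file_geom
  if (is.null(g)) {
    stop("no voxel geometry: none embedded in ", path,
         " and none supplied via `geometry`")
  }
  image_stack(vox, bit_depth = bit_depth, geometry = g, channel = channel)
}

#' Extract voxel geometry from OME-XML
#'
#' Parses `PhysicalSizeX/Y/Z` attributes of an OME `Pixels` element, as
#' embedded in the ImageDescription of OME-TIFF files. Sizes are assumed
#' to be in micrometres (the OME default unit).
#'
#' @param xml_text Character scalar holding (OME-)XML.
#' @return A [voxel_geometry()], or NULL when no physical sizes are found.
#' @export
parse_ome_geometry <- function(xml_text) {
  if (is.null(xml_text) || !nzchar(xml_text)) return(NULL)
  grab <- function(attrib) {
    m <- regmatches(xml_text,
                    regexpr(sprintf('%s\\s*=\\s*"[0-9.eE+-]+"', attrib), xml_text))
    if (length(m) == 0L) return(NA_real_)
    as.numeric(sub('.*"([0-9.eE+-]+)"', "\\1", m))
  }
  dx <- grab("PhysicalSizeX"); dy <- grab("PhysicalSizeY"); dz <- grab("PhysicalSizeZ")
  if (is.na(dx) || is.na(dy)) return(NULL)
  voxel_geometry(dx, dy, if (is.na(dz)) 0.18 else dz)
}

#' Write a stack (or mask) as multi-page TIFF
#'
#' Stacks are written as 16-bit pages; binary masks as 8-bit 0/255.
#' Voxel values round-trip bit-exactly through [read_stack()] /
#' [read_mask()]. Geometry is not embedded (plain TIFF; keep it in the
#' pipeline config or a sidecar).
#'
#' @param stack An [image_stack()] or a 3D logical array (mask).
#' @param path Output file.
#' @export
write_stack <- function(stack, path) {
  if (is.array(stack) && is.logical(stack)) return(write_mask(stack, path))
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[3]), function(z) stack$voxels[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  pages <- lapply(seq_len(d[3]), function(z) (mask[, , z] != 0) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path TIFF file of 0/255 pages.
#' @return 3D logical array.
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1L]])
  m <- array(FALSE, dim = c(shp[1], shp[2], length(pages)))
  for (z in seq_along(pages)) m[, , z] <- pages[[z]] > 0
  m
}

#' Adjust a 12-bit stack to 16 bit
#'
#' Rescales so the stack maximum maps to the 16-bit maximum: each voxel
#' `v` becomes `round(v * 65535 / max(stack))` (half away from zero),
#' preserving the ordering of intensities. The maximum is taken over the
#' whole stack, not per slice.
#'
#' @param stack A 12-bit [image_stack()] with at least one nonzero voxel.
#' @return A 16-bit [image_stack()] whose maximum is exactly 65535.
#' @export
adjust_to_16bit <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$bit_depth != 12L) stop("adjust_to_16bit expects a 12-bit stack")
  mx <- max(stack$voxels)
  if (mx <= 0) stop("all-zero stack: 16-bit scale undefined")
  v <- floor(stack$voxels * (65535 / mx) + 0.5)  # round half away from zero
  image_stack(v, bit_depth = 16L, geometry = stack$geometry,
              channel = stack$channel)
}

#' Ganglion ROI: per-slice polygons
#'
#' The ganglion outline is drawn slice by slice (no interpolation between
#' slices). Each polygon is a closed ring of >= 3 vertices in (x, y)
#' pixel units.
#'
#' @param slices Integer vector of 1-based slice indices, one per polygon.
#' @param polygons List of n x 2 matrices (columns x, y), one per slice.
#' @return An object of class `ganglion_roi`.
#' @export
ganglion_roi <- function(slices, polygons) {
  slices <- as.integer(slices)
  if (length(slices) != length(polygons)) {
    stop("slices and polygons must have equal length")
  }
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L) {
      stop("each ROI polygon needs >= 3 (x, y) vertices")
    }
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    p
  })
  structure(list(slices = slices, polygons = polygons), class = "ganglion_roi")
}

#' Read / write ROI JSON
#'
#' The on-disk schema is a JSON array of objects
#' `{"slice": <1-based z>, "vertices": [[x, y], ...]}`.
#'
#' @param path JSON file.
#' @export
read_roi <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0L) return(ganglion_roi(integer(0), list()))
  slices <- vapply(raw, function(e) as.integer(e$slice), integer(1))
  polys <- lapply(raw, function(e) {
    do.call(rbind, lapply(e$vertices, function(v) as.numeric(unlist(v))))
  })
  ganglion_roi(slices, polys)
}

#' @rdname read_roi
#' @param roi A [ganglion_roi()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "ganglion_roi"))
  entries <- lapply(seq_along(roi$slices), function(i) {
    list(slice = roi$slices[i],
         vertices = lapply(seq_len(nrow(roi$polygons[[i]])),
                           function(r) as.numeric(roi$polygons[[i]][r, ])))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Boundary-inclusive point-in-polygon (even-odd ray casting; points on an
# edge count as inside). Vectorised over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment test
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
              py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onedge <- onedge | (abs(cross) <= eps * (1 + abs(xj - xi) + abs(yj - yi)) & within)
    # even-odd crossing test (half-open rule avoids double-counted vertices)
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | onedge
}

#' Rasterize a ganglion ROI to a 3D mask
#'
#' A voxel is true iff its pixel centre lies inside or on the boundary of
#' that slice's polygon. Slices without a polygon are all-false.
#'
#' @param roi A [ganglion_roi()].
#' @param shape Integer vector (ny, nx, nz) of the target stack.
#' @param strict Error on an empty ROI (default); otherwise warn and
#'   return an all-false mask.
#' @return 3D logical array of dim `shape`.
#' @export
rasterize_roi <- function(roi, shape, strict = TRUE) {
  stopifnot(inherits(roi, "ganglion_roi"), length(shape) == 3L)
  if (length(roi$slices) == 0L) {
    if (strict) stop("empty ROI: no polygons to rasterize")
    warning("empty ROI: returning all-false mask")
    return(array(FALSE, dim = shape))
  }
  if (any(roi$slices < 1L | roi$slices > shape[3])) {
    stop("ROI slice index outside stack depth")
  }
  mask <- array(FALSE, dim = shape)
  cx <- rep(seq_len(shape[2]), each = shape[1])   # pixel-centre x per column
  cy <- rep(seq_len(shape[1]), times = shape[2])  # pixel-centre y per row
  for (i in seq_along(roi$slices)) {
    z <- roi$slices[i]
    hit <- points_in_polygon(cx, cy, roi$polygons[[i]])
    mask[, , z] <- mask[, , z] | matrix(hit, shape[1], shape[2])
  }
  mask
}

#' Write / read the per-ganglion feature table
#'
#' CSV, UTF-8, '.' decimal separator; one row per ganglion. Missing
#' values (e.g. clinical scores, or mean features of an empty ganglion)
#' are empty cells, never 0. Round-trips losslessly.
#'
#' @param records Data frame of feature vectors (see [ganglion_features()]).
#' @param path Output CSV.
#' @export
write_feature_table <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    if (length(records) == 0L) stop("no records to write")
    nm <- names(records[[1L]])
    ok <- vapply(records, function(r) identical(names(r), nm), logical(1))
    if (!all(ok)) stop("heterogeneous records: field sets differ")
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
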