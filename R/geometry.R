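#' Voxel geometry
#'
#' Physical size of one voxel. Confocal stacks of submucosal ganglia are
#' strongly anisotropic: the axial step (`dz`, default 0.18 um, the z-step
#' used for acquisition) is usually coarser than the lateral pixel size.
#' The lateral pixel size depends on the scan zoom and has no universal
#' default, so `dx` and `dy` must always be supplied.
#'
#' @param dx,dy Lateral pixel size in micrometres (x resp. y).
#' @param dz Axial step between slices in micrometres. Default 0.18.
#' @return An object of class `voxel_geometry` with fields `dx`, `dy`, `dz`.
#' @examples
#' g <- voxel_geometry(0.1, 0.1)
#' voxel_volume(g)  # 0.0018 um^3
#' @export
voxel_geometry <- function(dx, dy = dx, dz = 0.18) {
  dx <- as.numeric(dx); dy <- as.numeric(dy); dz <- as.numeric(dz)
  if (length(dx) != 1L || length(dy) != 1L || length(dz) != 1L ||
      !is.finite(dx) || !is.finite(dy) || !is.finite(dz) ||
      dx <= 0 || dy <= 0 || dz <= 0) {
    stop("voxel sizes dx, dy, dz must be single positive finite numbers")
  }
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_geometry")
}

#' @rdname voxel_geometry
#' @param geometry A `voxel_geometry`.
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$dx * geometry$dy * geometry$dz
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: dx = %g um, dy = %g um, dz = %g um (%g um^3/voxel)\n",
              x$dx, x$dy, x$dz, voxel_volume(x)))
  invisible(x)
}
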