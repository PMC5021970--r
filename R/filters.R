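# Linear filters used by the segmentation rules and the stack simulator.
# All filters use replicate-edge padding: reflective of a sample that
# continues beyond the field of view, and it avoids the spurious dark
# borders that zero padding would create (which would inflate the
# local-contrast ratio at image edges).

#' 2D linear filtering with replicate-edge padding
#'
#' Correlates a slice with a kernel. For odd kernel sizes the window is
#' centred; for even sizes (the 10x10 and 20x20 background averages) the
#' window covers offsets `-K/2 .. K/2-1`, i.e. the centre sits just
#' right/below the geometric middle, the convention used by MATLAB-style
#' imaging toolboxes.
#'
#' @param mat Numeric matrix (one z-slice).
#' @param kernel Numeric matrix of filter weights.
#' @return Filtered matrix of the same size.
#' @keywords internal
conv2_replicate <- function(mat, kernel) {
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- nrow(kernel); kc <- ncol(kernel)
  oy <- seq_len(kr) - (kr %/% 2L) - 1L
  ox <- seq_len(kc) - (kc %/% 2L) - 1L
  out <- matrix(0, nr, nc)
  ys <- seq_len(nr); xs <- seq_len(nc)
  for (i in seq_len(kr)) {
    ry <- pmin(pmax(ys + oy[i], 1L), nr)
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      rx <- pmin(pmax(xs + ox[j], 1L), nc)
      out <- out + w * mat[ry, rx]
    }
  }
  out
}

# Apply a 2D kernel independently to every z-slice of a 3D array.
filter_stack_2d <- function(voxels, kernel) {
  d <- dim(voxels)
  out <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    out[, , z] <- conv2_replicate(voxels[, , z], kernel)
  }
  out
}

#' Gaussian kernel
#'
#' A `size` x `size` Gaussian kernel, truncated and renormalised to unit
#' sum. The segmentation's local rule uses `size = 5`, `sigma = 2`.
#'
#' @param size Odd kernel width in pixels.
#' @param sigma Standard deviation in pixels.
#' @keywords internal
gaussian_kernel2d <- function(size = 5L, sigma = 2) {
  stopifnot(size >= 1L, size %% 2L == 1L, sigma > 0)
  r <- (size - 1L) / 2
  g1 <- exp(-(seq(-r, r)^2) / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

box_kernel2d <- function(size) {
  matrix(1 / (size * size), size, size)
}

# Separable 3D Gaussian blur (simulator PSF). sigma is length-3
# (y, x, z) in voxels; a zero entry skips that axis.
gaussian_blur_3d <- function(voxels, sigma) {
  stopifnot(length(sigma) == 3L, all(sigma >= 0))
  out <- voxels
  d <- dim(voxels)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s == 0) next
    r <- max(1L, ceiling(3 * s))
    taps <- exp(-(seq(-r, r)^2) / (2 * s^2))
    taps <- taps / sum(taps)
    acc <- array(0, dim = d)
    n <- d[ax]
    pos <- seq_len(n)
    for (t in seq_along(taps)) {
      off <- t - r - 1L
      src <- pmin(pmax(pos + off, 1L), n)
      acc <- acc + taps[t] * switch(ax,
        out[src, , , drop = FALSE],
        out[, src, , drop = FALSE],
        out[, , src, drop = FALSE])
    }
    out <- acc
  }
  out
}
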