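# Internal helpers shared across modules.

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards. With seed = NULL the global stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable derivation of per-stage child seeds from one top-level seed, so a
# stage re-run in isolation sees the same stream as inside the pipeline.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

# Shift a 3D logical/numeric array by (dy, dx, dz), filling with `fill`.
shift3d <- function(a, dy, dx, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
  ysrc <- ys - dy; xsrc <- xs - dx; zsrc <- zs - dz
  keep_y <- ysrc >= 1L & ysrc <= d[1]
  keep_x <- xsrc >= 1L & xsrc <= d[2]
  keep_z <- zsrc >= 1L & zsrc <= d[3]
  out[ys[keep_y], xs[keep_x], zs[keep_z]] <-
    a[ysrc[keep_y], xsrc[keep_x], zsrc[keep_z]]
  out
}

# Neighbour offset table for a given 3D connectivity (6 faces, 18 faces+
# edges, 26 full). Rows are (dy, dx, dz).
neighbor_offsets <- function(connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be one of 6, 18, 26")
  }
  g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1L,
                 "18" = ord <= 2L,
                 "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

# Convert linear indices of an array of dims d to a 3-column (y, x, z)
# coordinate matrix, and back.
idx_to_coord <- function(idx, d) {
  idx0 <- idx - 1L
  y <- idx0 %% d[1]
  x <- (idx0 %/% d[1]) %% d[2]
  z <- idx0 %/% (d[1] * d[2])
  unname(cbind(y + 1L, x + 1L, z + 1L))
}

coord_to_idx <- function(coord, d) {
  as.vector(coord[, 1L] + (coord[, 2L] - 1L) * d[1] +
              (coord[, 3L] - 1L) * d[1] * d[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
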