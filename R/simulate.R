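# Ground-truthed simulation: synthetic deconvolved confocal stacks
# (tubular/branched mitochondria in an ellipsoidal ganglion, non-uniform
# illumination, Gaussian PSF, Poisson photon noise) and two-group
# morphometric cohorts with imposed effect directions.

#' Specification of one simulated mitochondrial object
#'
#' @param shape "rod" (straight tubule), "ybranch" (three rods meeting at
#'   a point) or "blob" (sphere).
#' @param center Numeric (y, x, z) voxel position.
#' @param length_vox Rod / arm length in voxels (rod, ybranch).
#' @param radius_vox Tube / sphere radius in voxels.
#' @param orientation Unit-ish direction vector (y, x, z) for rods; for
#'   ybranch, the first arm direction (the other two are rotated in-plane).
#' @param peak Peak intensity in photon counts (> 0).
#' @return An object of class `mito_object_spec`.
#' @export
mito_object_spec <- function(shape = c("rod", "ybranch", "blob"),
                             center, length_vox = 10, radius_vox = 1.2,
                             orientation = c(0, 1, 0), peak = 150) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3L, peak > 0, radius_vox > 0, length_vox > 0)
  structure(list(shape = shape, center = as.numeric(center),
                 length_vox = length_vox, radius_vox = radius_vox,
                 orientation = as.numeric(orientation), peak = peak),
            class = "mito_object_spec")
}

#' Specification of a simulated stack
#'
#' Defaults emulate a deconvolved 12-bit photon-counting acquisition of
#' one submucosal ganglion: a 128 x 128 x 20 voxel field at 0.1 um
#' lateral / 0.18 um axial sampling, an ellipsoidal ganglion region, 30
#' bright tubular objects, a dim planar illumination gradient, a residual
#' post-deconvolution Gaussian PSF of 0.8 voxels, and Poisson noise.
#'
#' @param shape Stack dimensions (ny, nx, nz).
#' @param geometry A [voxel_geometry()].
#' @param ganglion_center,ganglion_semiaxes Ellipsoid centre and
#'   semi-axes in voxels (y, x, z).
#' @param objects List of [mito_object_spec()]s; `NULL` draws
#'   `n_objects` random rods/branches inside the ganglion.
#' @param n_objects Number of random objects when `objects` is NULL.
#' @param background Base background level in photon counts.
#' @param gradient_amplitude Peak-to-centre amplitude of the planar
#'   illumination ramp (photon counts; 0 disables).
#' @param psf_sigma Gaussian PSF standard deviations (y, x, z) in voxels.
#' @param noise "poisson" or "none".
#' @param seed Integer; fixes the realization completely.
#' @return An object of class `stack_sim_spec`.
#' @export
stack_sim_spec <- function(shape = c(128L, 128L, 20L),
                           geometry = voxel_geometry(0.1, 0.1, 0.18),
                           ganglion_center = (shape + 1) / 2,
                           ganglion_semiaxes = c(shape[1] * 0.42, shape[2] * 0.42,
                                                 shape[3] * 0.45),
                           objects = NULL, n_objects = 30L,
                           background = 5, gradient_amplitude = 3,
                           psf_sigma = c(0.8, 0.8, 0.8),
                           noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(shape) == 3L, all(shape >= 4L), background >= 0,
            gradient_amplitude >= 0, all(psf_sigma >= 0))
  structure(list(shape = as.integer(shape), geometry = geometry,
                 ganglion_center = ganglion_center,
                 ganglion_semiaxes = ganglion_semiaxes,
                 objects = objects, n_objects = as.integer(n_objects),
                 background = background,
                 gradient_amplitude = gradient_amplitude,
                 psf_sigma = psf_sigma, noise = noise,
                 seed = as.integer(seed)),
            class = "stack_sim_spec")
}

# Voxelize one object spec into linear indices of a stack of dims d.
render_object_mask <- function(obj, d) {
  r <- obj$radius_vox
  segs <- object_segments(obj)
  if (obj$shape == "blob") r <- max(r, obj$length_vox / 2)
  lo <- pmax(floor(apply(do.call(rbind, segs), 2, min) - r - 1), 1)
  hi <- pmin(ceiling(apply(do.call(rbind, segs), 2, max) + r + 1), d)
  ys <- seq(lo[1], hi[1]); xs <- seq(lo[2], hi[2]); zs <- seq(lo[3], hi[3])
  grid <- cbind(rep(ys, times = length(xs) * length(zs)),
                rep(rep(xs, each = length(ys)), times = length(zs)),
                rep(zs, each = length(ys) * length(xs)))
  hit <- rep(FALSE, nrow(grid))
  for (s in segs) {
    a <- s[1, ]; b <- s[2, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(grid, 2, a)
    t <- if (len2 > 0) pmin(pmax(rel %*% ab / len2, 0), 1) else rep(0, nrow(grid))
    closest <- outer(as.vector(t), ab) ; closest <- sweep(closest, 2, a, `+`)
    dist2 <- rowSums((grid - closest)^2)
    hit <- hit | dist2 <= r^2
  }
  if (!any(hit)) stop("object renders to zero voxels (radius too small?)")
  coord_to_idx(grid[hit, , drop = FALSE], d)
}

# Ellipsoidal ganglion mask.
ellipsoid_mask <- function(d, center, semiaxes) {
  ys <- (seq_len(d[1]) - center[1]) / semiaxes[1]
  xs <- (seq_len(d[2]) - center[2]) / semiaxes[2]
  zs <- (seq_len(d[3]) - center[3]) / semiaxes[3]
  q <- outer(outer(ys^2, xs^2, `+`), zs^2, `+`)
  q <= 1
}

# Closest distance between two 3D segments (voxel units).
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c_ <- sum(d1 * r)
    if (e <= eps) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > eps) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

# Centreline segments of an object spec (list of 2x3 matrices).
object_segments <- function(obj) {
  u <- obj$orientation / sqrt(sum(obj$orientation^2))
  switch(obj$shape,
    rod = list(rbind(obj$center - u * obj$length_vox / 2,
                     obj$center + u * obj$length_vox / 2)),
    ybranch = {
      rot <- function(v, ang) c(cos(ang) * v[1] - sin(ang) * v[2],
                                sin(ang) * v[1] + cos(ang) * v[2], v[3])
      lapply(list(u, rot(u, 2 * pi / 3), rot(u, -2 * pi / 3)),
             function(w) rbind(obj$center, obj$center + w * obj$length_vox))
    },
    blob = list(rbind(obj$center, obj$center)))
}

# Random object specs inside the ganglion ellipsoid. Objects are kept
# disjoint by requiring a minimum gap between centrelines of
# radius_i + radius_j + `gap` voxels, so segmented components cannot
# merge even after PSF blur.
random_object_specs <- function(n, d, center, semiaxes, peak = 150,
                                gap = 4) {
  specs <- list()
  placed <- list()   # list of (segments, radius)
  tries <- 0L
  while (length(specs) < n && tries < 50000L) {
    tries <- tries + 1L
    u <- stats::runif(3, -0.85, 0.85)
    pos <- center + u * semiaxes
    shape <- sample(c("rod", "rod", "ybranch"), 1L)
    ang <- stats::runif(1, 0, pi)
    zt <- stats::runif(1, -0.15, 0.15)   # mostly in-plane (anisotropic voxels)
    ori <- c(sin(ang), cos(ang), zt)
    len <- if (shape == "ybranch") stats::runif(1, 5, 7) else stats::runif(1, 7, 12)
    rad <- stats::runif(1, 1.1, 1.4)
    obj <- mito_object_spec(shape = shape, center = pos, length_vox = len,
                            radius_vox = rad, orientation = ori, peak = peak)
    segs <- object_segments(obj)
    pts <- do.call(rbind, segs)
    # lateral margin leaves room for the PSF halo; the axial margin only
    # needs the tube radius (thin stacks would otherwise be infeasible)
    m_xy <- rad + 2; m_z <- rad
    if (any(pts[, 1] < m_xy + 1) || any(pts[, 1] > d[1] - m_xy) ||
        any(pts[, 2] < m_xy + 1) || any(pts[, 2] > d[2] - m_xy) ||
        any(pts[, 3] < m_z + 1) || any(pts[, 3] > d[3] - m_z)) next
    # whole centreline must lie inside the ganglion ellipsoid
    rel <- sweep(sweep(pts, 2, center), 2, semiaxes, `/`)
    if (any(rowSums(rel^2) > 0.92^2)) next
    ok <- TRUE
    for (p in placed) {
      for (s1 in segs) {
        for (s2 in p$segments) {
          if (segment_distance(s1[1, ], s1[2, ], s2[1, ], s2[2, ]) <
              rad + p$radius + gap) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (!ok) next
    specs[[length(specs) + 1L]] <- obj
    placed[[length(placed) + 1L]] <- list(segments = segs, radius = rad)
  }
  if (length(specs) < n) stop("could not place ", n, " separated objects")
  specs
}

#' Simulate one ganglion stack with ground truth
#'
#' Renders the objects at their peak intensity, adds the base background
#' and a planar illumination ramp, convolves with the Gaussian PSF,
#' applies Poisson noise if requested, and clips to the 12-bit range.
#' The ground truth records the pre-blur object masks.
#'
#' @param spec A [stack_sim_spec()].
#' @return List with `stack` (a 12-bit [image_stack()]) and `truth`
#'   (object index list, object specs, ganglion mask, per-object volume
#'   in um^3, nominal node counts).
#' @export
simulate_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_sim_spec"))
  d <- spec$shape
  with_seed(spec$seed, {
    objects <- spec$objects
    if (is.null(objects)) {
      objects <- if (spec$n_objects > 0L) {
        random_object_specs(spec$n_objects, d, spec$ganglion_center,
                            spec$ganglion_semiaxes, peak = 150)
      } else list()
    }
    canvas <- array(0, dim = d)
    truth_idx <- vector("list", length(objects))
    for (i in seq_along(objects)) {
      idx <- render_object_mask(objects[[i]], d)
      truth_idx[[i]] <- idx
      canvas[idx] <- pmax(canvas[idx], objects[[i]]$peak)
    }
    # smooth illumination field: planar ramp across x and y
    field <- array(spec$background, dim = d)
    if (spec$gradient_amplitude > 0) {
      ramp <- outer((seq_len(d[1]) - 1) / max(d[1] - 1, 1),
                    (seq_len(d[2]) - 1) / max(d[2] - 1, 1),
                    function(a, b) (a + b) / 2)
      for (z in seq_len(d[3])) {
        field[, , z] <- field[, , z] + spec$gradient_amplitude * ramp
      }
    }
    img <- canvas + field
    if (any(spec$psf_sigma > 0)) img <- gaussian_blur_3d(img, spec$psf_sigma)
    if (spec$noise == "poisson") {
      img <- array(stats::rpois(length(img), lambda = img), dim = d)
    } else {
      img <- round(img)
    }
    img <- pmin(pmax(img, 0), 4095)
    nominal_nodes <- vapply(objects, function(o) {
      switch(o$shape, rod = 2L, ybranch = 4L, blob = 1L)
    }, integer(1))
    list(stack = image_stack(img, bit_depth = 12L, geometry = spec$geometry),
         truth = list(
           objects = truth_idx,
           specs = objects,
           ganglion = ellipsoid_mask(d, spec$ganglion_center, spec$ganglion_semiaxes),
           volumes_um3 = vapply(truth_idx, length, integer(1)) *
             voxel_volume(spec$geometry),
           nominal_nodes = nominal_nodes))
  })
}

#' Specification of a simulated two-group cohort
#'
#' Per-ganglion morphometric features are drawn from log-normal
#' distributions: all features are strictly positive and are analysed on
#' log scales, which the log-normal reproduces. Patients and colon side
#' act multiplicatively. Default control-group locations and the patient
#' effects emulate the published effect directions: patients have smaller
#' ganglia (x0.63), more mitochondria per volume and a higher total
#' mitochondrial mass; ganglia are larger in the right colon.
#'
#' @param n_per_group Ganglia per group (default 50).
#' @param features Named list; each entry has `meanlog` and `sdlog` for
#'   the control group, left colon.
#' @param patient_effect Named multiplicative effects (patient vs control).
#' @param side_effect Named multiplicative effects (right vs left colon).
#' @param n_subjects Subjects per group that ganglia are attributed to
#'   (default 8 patients / 4 controls scaled to group sizes).
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_per_group = c(patient = 50L, control = 50L),
                            features = default_cohort_features(),
                            patient_effect = default_patient_effects(),
                            side_effect = c(GanglionVolume = 1.25),
                            n_subjects = c(patient = 8L, control = 4L),
                            seed = 1L) {
  if (length(n_per_group) == 1L) {
    n_per_group <- c(patient = n_per_group, control = n_per_group)
  }
  stopifnot(all(n_per_group > 0),
            all(vapply(features, function(f) f$sdlog > 0, logical(1))),
            all(patient_effect > 0), all(side_effect > 0))
  structure(list(n_per_group = n_per_group, features = features,
                 patient_effect = patient_effect, side_effect = side_effect,
                 n_subjects = n_subjects, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' @rdname cohort_sim_spec
#' @export
default_cohort_features <- function() {
  list(
    GanglionVolume          = list(meanlog = log(25000), sdlog = 0.5),
    MitoCount               = list(meanlog = log(0.020), sdlog = 0.35),
    MitoVolumeMean          = list(meanlog = log(0.25),  sdlog = 0.35),
    MitoVolumeTotal         = list(meanlog = log(0.005), sdlog = 0.35),
    MitoSurfaceFractionMean = list(meanlog = log(0.85),  sdlog = 0.08),
    MitoNodesMean           = list(meanlog = log(2.6),   sdlog = 0.25),
    MitoNodeDegreeMean      = list(meanlog = log(6.0),   sdlog = 0.30),
    MitoSkeletonLengthMean  = list(meanlog = log(1.2),   sdlog = 0.35)
  )
}

#' @rdname cohort_sim_spec
#' @export
default_patient_effects <- function() {
  c(GanglionVolume = 0.63, MitoCount = 1.4, MitoVolumeMean = 0.9,
    MitoVolumeTotal = 1.3, MitoSurfaceFractionMean = 1.05,
    MitoNodesMean = 0.9, MitoNodeDegreeMean = 0.9,
    MitoSkeletonLengthMean = 0.9)
}

#' Simulate a two-group feature cohort
#'
#' Draws each feature independently from its log-normal with the group
#' and side multipliers applied to the scale; attaches ganglion, subject,
#' group and side labels. Deterministic under the spec's seed.
#'
#' @param spec A [cohort_sim_spec()].
#' @return Data frame, one row per ganglion.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    rows <- list()
    gid <- 0L
    for (grp in c("patient", "control")) {
      n <- spec$n_per_group[[grp]]
      nsub <- max(1L, spec$n_subjects[[grp]])
      subj <- sprintf("%s_%02d", substr(grp, 1, 1), ((seq_len(n) - 1L) %% nsub) + 1L)
      side <- rep(c("right", "left"), length.out = n)
      for (i in seq_len(n)) {
        gid <- gid + 1L
        rec <- list(ganglion_id = sprintf("g%04d", gid), subject_id = subj[i],
                    group = grp, side = side[i])
        for (f in names(spec$features)) {
          mult <- 1
          if (grp == "patient" && f %in% names(spec$patient_effect)) {
            mult <- mult * spec$patient_effect[[f]]
          }
          if (side[i] == "right" && f %in% names(spec$side_effect)) {
            mult <- mult * spec$side_effect[[f]]
          }
          rec[[f]] <- stats::rlnorm(1, meanlog = spec$features[[f]]$meanlog +
                                      log(mult),
                                    sdlog = spec$features[[f]]$sdlog)
        }
        rows[[gid]] <- as.data.frame(rec, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
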