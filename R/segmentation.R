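# Mitochondrial segmentation: two pixel rules (local contrast + global
# Otsu on illumination-corrected stacks), connected components, size
# filtering and ganglion gating.

#' Local-contrast mitochondrial pixel rule
#'
#' A voxel passes when the local signal — a 5-pixel Gaussian filter with
#' standard deviation 2, applied 2D per z-slice — is at least 25%
#' brighter than the surrounding background, defined by a 10x10 average
#' filter on the same slice. Both filters use replicate-edge padding.
#' Where the background average is zero, any positive smoothed signal
#' passes (the ratio is infinite).
#'
#' @param stack A 16-bit [image_stack()].
#' @param ratio Brightness ratio (default 1.25, i.e. 25% brighter).
#' @param gaussian_size,gaussian_sigma Local filter (default 5 px, sigma 2).
#' @param background_size Background average filter width (default 10 px).
#' @return 3D logical mask.
#' @export
local_rule_mask <- function(stack, ratio = 1.25, gaussian_size = 5L,
                            gaussian_sigma = 2, background_size = 10L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (d[1] < background_size || d[2] < background_size) {
    warning("stack smaller than the background filter support; ",
            "replicate padding dominates the estimate")
  }
  sm <- filter_stack_2d(stack$voxels, gaussian_kernel2d(gaussian_size, gaussian_sigma))
  bg <- filter_stack_2d(stack$voxels, box_kernel2d(background_size))
  (bg > 0 & sm >= ratio * bg) | (bg <= 0 & sm > 0)
}

#' Illumination correction
#'
#' Subtracts a 20x20 average-filtered version of each slice from the
#' slice itself, removing smooth non-uniform illumination; the result is
#' clamped at zero (photon counts are non-negative).
#'
#' @param stack An [image_stack()].
#' @param background_size Average filter width (default 20 px).
#' @return 3D numeric array of corrected intensities (>= 0).
#' @export
illumination_correct <- function(stack, background_size = 20L) {
  stopifnot(inherits(stack, "image_stack"))
  bg <- filter_stack_2d(stack$voxels, box_kernel2d(background_size))
  pmax(stack$voxels - bg, 0)
}

#' Otsu global threshold
#'
#' Selects the threshold maximizing the between-class variance of the
#' intensity histogram (256 equal-width bins over the value range of the
#' whole 3D stack). Foreground is strictly above the threshold. Ties are
#' broken towards the lowest threshold.
#'
#' @param x 3D numeric array (e.g. the illumination-corrected stack), or
#'   an [image_stack()].
#' @param n_bins Histogram bins (default 256).
#' @return List with `threshold` (intensity value at the selected bin's
#'   upper edge) and `mask` (voxels strictly above it).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  if (inherits(x, "image_stack")) x <- x$voxels
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant stack: Otsu threshold undefined")
  counts <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L),
                          n_bins), nbins = n_bins)
  k <- otsu_from_counts(counts)
  thr <- lo + k * (hi - lo) / n_bins
  list(threshold = thr, mask = x > thr)
}

# Between-class-variance maximizer on a histogram of bin counts; bins are
# indexed 1..n with representative values at bin midpoints. Returns the
# split index k (foreground = bins > k), 1 <= k <= n-1.
otsu_from_counts <- function(counts) {
  n <- length(counts)
  total <- sum(counts)
  if (total <= 0) stop("empty histogram")
  p <- counts / total
  mids <- seq_len(n) - 0.5
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n]
  w0k <- w0[-n]; mu0k <- mu0[-n]
  w1k <- 1 - w0k
  valid <- w0k > 0 & w1k > 0
  if (!any(valid)) stop("histogram has a single occupied bin")
  bcv <- rep(-Inf, n - 1L)
  bcv[valid] <- (mu_t * w0k[valid] - mu0k[valid])^2 / (w0k[valid] * w1k[valid])
  which.max(bcv)  # ties -> lowest k
}

#' Combined mitochondrial pixel mask
#'
#' A voxel is mitochondrial when it satisfies both rules: the local
#' contrast rule ([local_rule_mask()]) and the global Otsu rule computed
#' on the illumination-corrected stack ([illumination_correct()] then
#' [otsu_threshold()]).
#'
#' @param stack A 16-bit [image_stack()].
#' @param ... Passed to [local_rule_mask()].
#' @return List with `mask` (logical array), `otsu_threshold`, and the
#'   two sub-masks (`local`, `global`).
#' @export
mito_pixel_mask <- function(stack, ...) {
  local <- local_rule_mask(stack, ...)
  ot <- otsu_threshold(illumination_correct(stack))
  list(mask = local & ot$mask, otsu_threshold = ot$threshold,
       local = local, global = ot$mask)
}

#' Label 3D connected components
#'
#' Maximal connected sets of true voxels under 6-, 18- or 26-connectivity
#' (default 26), labelled contiguously from 1 by a vectorised frontier
#' flood fill.
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer array, 0 = background) and
#'   `components`, a list of `mito_component` objects (fields `id`,
#'   `indices` — linear voxel indices — and `voxel_count`).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  pd <- d + 2L
  padded <- array(FALSE, dim = pd)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  offs <- neighbor_offsets(connectivity)
  loff <- offs[, 1L] + offs[, 2L] * pd[1] + offs[, 3L] * pd[1] * pd[2]
  labels_p <- array(0L, dim = pd)
  todo <- which(padded)
  components <- list()
  lab <- 0L
  remaining <- todo[labels_p[todo] == 0L]
  while (length(remaining) > 0L) {
    lab <- lab + 1L
    seed <- remaining[1L]
    labels_p[seed] <- lab
    frontier <- seed
    members <- seed
    while (length(frontier) > 0L) {
      nb <- rep(frontier, each = length(loff)) + loff
      nb <- nb[padded[nb] & labels_p[nb] == 0L]
      if (length(nb) > 0L) {
        nb <- unique(nb)
        labels_p[nb] <- lab
        members <- c(members, nb)
      }
      frontier <- nb
    }
    components[[lab]] <- members
    remaining <- remaining[labels_p[remaining] == 0L]
  }
  # map padded linear indices back to the original array
  co_all <- idx_to_coord(unlist(components) %||% integer(0), pd)
  labels <- array(0L, dim = d)
  comps <- vector("list", lab)
  pos <- 0L
  for (i in seq_len(lab)) {
    nI <- length(components[[i]])
    co <- co_all[pos + seq_len(nI), , drop = FALSE] - 1L  # unpad
    idx <- coord_to_idx(co, d)
    idx <- sort(idx)
    labels[idx] <- i
    comps[[i]] <- structure(list(id = i, indices = idx, voxel_count = nI),
                            class = "mito_component")
    pos <- pos + nI
  }
  list(labels = labels, components = comps, dim = d,
       connectivity = as.integer(connectivity))
}

#' Size-filter components
#'
#' Keeps components whose voxel count is at least `min_voxels` (default
#' 8, removing photon-counting shot noise) and at most `max_voxels`
#' (default 1e6, removing implausibly large structures). Both bounds are
#' inclusive.
#'
#' @param components List of `mito_component`s (from [label_components()]).
#' @param min_voxels,max_voxels Inclusive bounds (defaults 8 and 1e6).
#' @export
filter_components <- function(components, min_voxels = 8, max_voxels = 1e6) {
  if (!is.null(components$components)) components <- components$components
  keep <- vapply(components, function(cc) {
    cc$voxel_count >= min_voxels && cc$voxel_count <= max_voxels
  }, logical(1))
  components[keep]
}

#' Gate components by the ganglion volume
#'
#' Keeps whole components that intersect the ganglion mask in at least
#' one voxel; no clipping is performed.
#'
#' @param components List of `mito_component`s.
#' @param ganglion 3D logical ganglion mask, congruent with the stack.
#' @export
gate_by_ganglion <- function(components, ganglion) {
  if (!is.null(components$components)) components <- components$components
  stopifnot(is.array(ganglion))
  if (!any(ganglion)) stop("empty ganglion mask: nothing can intersect it")
  keep <- vapply(components, function(cc) any(ganglion[cc$indices]), logical(1))
  components[keep]
}

#' Segment mitochondria in one stack
#'
#' The full per-stack segmentation: two-rule pixel mask, connected
#' components, size filter, ganglion gating. Input must already be
#' 16-bit ([adjust_to_16bit()] for 12-bit acquisitions).
#'
#' @param stack A 16-bit [image_stack()].
#' @param ganglion 3D logical ganglion mask (same shape).
#' @param connectivity Component connectivity (default 26).
#' @param min_voxels,max_voxels Size filter bounds (default 8 and 1e6).
#' @param ... Passed to [local_rule_mask()].
#' @return List with `components` (filtered, gated), `labels` (relabelled
#'   integer array over the kept components), and `report` (thresholds
#'   and per-step counts, for the JSON run report).
#' @export
segment_stack <- function(stack, ganglion, connectivity = 26,
                          min_voxels = 8, max_voxels = 1e6, ...) {
  mm <- mito_pixel_mask(stack, ...)
  lc <- label_components(mm$mask, connectivity = connectivity)
  n_all <- length(lc$components)
  fc <- filter_components(lc$components, min_voxels, max_voxels)
  n_filt <- length(fc)
  gc_ <- gate_by_ganglion(fc, ganglion)
  labels <- array(0L, dim = dim(ganglion))
  comps <- vector("list", length(gc_))
  for (i in seq_along(gc_)) {
    comps[[i]] <- gc_[[i]]
    comps[[i]]$id <- i
    labels[comps[[i]]$indices] <- i
  }
  list(components = comps, labels = labels,
       report = list(otsu_threshold = mm$otsu_threshold,
                     local_rule_ratio = 1.25,
                     min_voxels = min_voxels, max_voxels = max_voxels,
                     connectivity = connectivity,
                     n_components_raw = n_all,
                     n_removed_size = n_all - n_filt,
                     n_removed_gate = n_filt - length(gc_),
                     n_components = length(gc_)))
}

#' Match segmented components against ground-truth objects
#'
#' Greedy one-to-one matching by Jaccard overlap (intersection over
#' union of voxel sets), used to evaluate segmentation on simulated
#' stacks with known objects.
#'
#' @param truth List of ground-truth voxel index vectors (one per object).
#' @param components List of `mito_component`s.
#' @param min_jaccard Overlap required to count an object as recovered
#'   (default 0.5).
#' @return List with `recovered` (logical per truth object), `jaccard`
#'   (best overlap per truth object), `n_spurious` (components matched to
#'   no object), and `recovery_rate`.
#' @export
match_components <- function(truth, components, min_jaccard = 0.5) {
  if (!is.null(components$components)) components <- components$components
  nt <- length(truth); nc <- length(components)
  jac <- matrix(0, nrow = max(nt, 1L), ncol = max(nc, 1L))
  if (nt > 0L && nc > 0L) {
    for (i in seq_len(nt)) {
      ti <- truth[[i]]
      for (j in seq_len(nc)) {
        cj <- components[[j]]$indices
        inter <- length(intersect(ti, cj))
        if (inter > 0L) jac[i, j] <- inter / (length(ti) + length(cj) - inter)
      }
    }
  }
  used <- logical(nc)
  best <- numeric(nt)
  if (nt > 0L && nc > 0L) {
    ord <- order(jac, decreasing = TRUE)
    for (o in ord) {
      if (jac[o] <= 0) break
      i <- (o - 1L) %% nrow(jac) + 1L
      j <- (o - 1L) %/% nrow(jac) + 1L
      if (i <= nt && j <= nc && best[i] == 0 && !used[j]) {
        best[i] <- jac[i, j]
        used[j] <- TRUE
      }
    }
  }
  recovered <- best >= min_jaccard
  list(recovered = recovered, jaccard = best,
       n_spurious = if (nc > 0L) sum(!used) else 0L,
       recovery_rate = if (nt > 0L) mean(recovered) else NA_real_)
}
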