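# Shared fixture builders (everything is generated in code; no binary
# fixtures are stored).

# Straight rod mask along z, 1 voxel wide, in a padded box.
make_rod_mask <- function(len = 10L, box = c(3L, 3L, len + 2L)) {
  m <- array(FALSE, dim = box)
  m[2L, 2L, 1L + seq_len(len)] <- TRUE
  m
}

# Y-shaped skeleton: one branchpoint with three arms of `arm` voxels
# along mutually non-adjacent diagonal directions, so the 26-adjacency
# graph is exactly the intended tree.
make_y_skeleton <- function(arm = 3L) {
  n <- 2L * arm + 3L
  m <- array(FALSE, dim = c(n, n, 3L))
  c0 <- arm + 2L
  m[c0, c0, 2L] <- TRUE
  for (k in seq_len(arm)) {
    m[c0 - k, c0 - k, 2L] <- TRUE   # arm towards (-y, -x)
    m[c0 + k, c0 + k, 2L] <- TRUE   # arm towards (+y, +x)
    m[c0 - k, c0 + k, 2L] <- TRUE   # arm towards (-y, +x)
  }
  m
}

# Random connected "blobby" component: a random walk dilated by chance.
random_component_mask <- function(box = c(12L, 12L, 8L), n_steps = 30L) {
  m <- array(FALSE, dim = box)
  pos <- pmax(pmin(round(box / 2), box - 1L), 2L)
  m[pos[1], pos[2], pos[3]] <- TRUE
  for (i in seq_len(n_steps)) {
    step <- sample(c(-1L, 0L, 1L), 3L, replace = TRUE)
    cand <- pos + step
    if (any(cand < 1L) || any(cand > box)) next
    pos <- cand
    m[pos[1], pos[2], pos[3]] <- TRUE
  }
  m
}

# Random tree skeleton embedded in 3D: grow arms of random diagonal
# steps from a backbone; the oracle reads the realized adjacency, so the
# construction does not need to avoid incidental contacts.
random_tree_skeleton <- function(box = c(16L, 16L, 10L), n_branches = 3L) {
  m <- array(FALSE, dim = box)
  pos <- pmax(pmin(round(box / 2), box - 2L), 3L)
  m[pos[1], pos[2], pos[3]] <- TRUE
  anchors <- matrix(pos, nrow = 1)
  for (b in seq_len(n_branches)) {
    start <- anchors[sample.int(nrow(anchors), 1L), ]
    dir <- sample(c(-1L, 1L), 3L, replace = TRUE) * sample(0:1, 3L, replace = TRUE)
    if (all(dir == 0L)) dir <- c(0L, 1L, 0L)
    cur <- start
    for (k in seq_len(sample(2:5, 1L))) {
      cand <- cur + dir
      if (any(cand < 1L) || any(cand > box)) break
      cur <- cand
      m[cur[1], cur[2], cur[3]] <- TRUE
    }
    anchors <- rbind(anchors, cur)
  }
  m
}

# Tiny cohort feature matrix for classifier tests: two well separated
# Gaussian clouds in `p` dimensions.
separable_toy <- function(n = 20L, p = 7L, gap = 6, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), ncol = p),
             matrix(rnorm(n * p, mean = gap), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(c("control", "patient"), each = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulated-stack pipeline setup: writes n 12-bit stacks and
# ganglion masks into `dir` and returns a ready-to-run config list.
make_pipeline_fixture <- function(dir, n = 4L) {
  manifest <- list()
  for (i in seq_len(n)) {
    sim <- simulate_stack(stack_sim_spec(shape = c(64L, 64L, 8L), n_objects = 5L,
                                         seed = i))
    sp <- file.path(dir, sprintf("stack%d.tif", i))
    mp <- file.path(dir, sprintf("mask%d.tif", i))
    write_stack(sim$stack, sp)
    write_mask(sim$truth$ganglion, mp)
    manifest[[i]] <- list(stack = sp, ganglion_mask = mp,
                          ganglion_id = sprintf("g%02d", i),
                          subject_id = sprintf("s%d", (i + 1L) %/% 2L),
                          group = if (i %% 2L == 1L) "patient" else "control",
                          side = c("right", "left")[i %% 2L + 1L])
  }
  list(geometry = list(dx = 0.1, dy = 0.1, dz = 0.18), bit_depth = 12,
       manifest = manifest, stats = list(n_perm = 200L),
       output_dir = file.path(dir, "out"), seed = 7L)
}
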