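# Erosion, skeletonization, node analysis, per-component shapes,
# per-ganglion features.

geom_iso <- voxel_geometry(0.1, 0.1, 0.18)

test_that("6-connected erosion: single voxel, cube, thin rod", {
  one <- array(FALSE, dim = c(3, 3, 3)); one[2, 2, 2] <- TRUE
  e <- erode_6conn(one)
  expect_equal(sum(e$body), 0)
  expect_equal(sum(e$surface), 1)
  cube <- array(FALSE, dim = c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  e2 <- erode_6conn(cube)
  expect_equal(sum(e2$body), 1)          # only the centre survives
  expect_true(e2$body[3, 3, 3])
  expect_equal(sum(e2$surface), 26)
  rod <- make_rod_mask(10L)
  e3 <- erode_6conn(rod)
  expect_equal(sum(e3$body), 0)          # every rod voxel misses lateral neighbours
  expect_equal(sum(e3$surface), 10)
})

test_that("erosion at the image border treats outside as background", {
  full <- array(TRUE, dim = c(4, 4, 4))
  e <- erode_6conn(full)
  expect_equal(sum(e$body), 2 * 2 * 2)   # interior only
})

test_that("surface + body partitions every component", {
  set.seed(13)
  for (i in 1:60) {
    m <- random_component_mask()
    e <- erode_6conn(m)
    expect_equal(sum(e$surface) + sum(e$body), sum(m))
    expect_false(any(e$surface & e$body))
  }
})

test_that("skeletonization fixed points and thick-rod thinning", {
  one <- array(FALSE, dim = c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(skeletonize3d(one), one)
  rod <- make_rod_mask(10L)
  expect_equal(skeletonize3d(rod), rod)  # already-thin curve is unchanged
  thick <- array(FALSE, dim = c(5, 5, 11)); thick[2:4, 2:4, 2:10] <- TRUE
  sk <- skeletonize3d(thick)
  expect_true(all(thick[sk]))            # skeleton inside the object
  g <- skeleton_graph(sk)
  expect_equal(g$node_count, 2L)         # a single path: two endpoints
  # endpoints lie in the rod's end faces
  d <- dim(sk)
  ends <- arrayInd(g$node_indices, d)
  expect_setequal(ends[, 3], c(2L, 10L))
  # connectivity is preserved
  expect_equal(length(label_components(sk, 26)$components), 1L)
  expect_error(skeletonize3d(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("thinning preserves the topology of a loop", {
  ring <- array(FALSE, dim = c(9, 9, 3))
  ring[3:7, 3:7, 2] <- TRUE
  ring[4:6, 4:6, 2] <- FALSE   # square annulus
  sk <- skeletonize3d(ring)
  g <- skeleton_graph(sk)
  expect_equal(g$node_count, 0L)   # closed loop: no endpoints, no branchpoints
  expect_equal(length(label_components(sk, 26)$components), 1L)
})

test_that("node detection: path, Y, isolated voxel", {
  path <- make_rod_mask(10L)
  n <- detect_nodes(path)
  expect_equal(n$node_count, 2L)
  expect_equal(n$node_degrees, c(9L, 9L))   # 8 interior + the far endpoint
  y <- make_y_skeleton(arm = 3L)
  ny <- detect_nodes(y)
  expect_equal(ny$node_count, 4L)           # 3 endpoints + 1 branchpoint
  expect_equal(sort(ny$graph_degrees), c(1L, 1L, 1L, 3L))
  bp <- which(ny$graph_degrees == 3L)
  expect_equal(ny$node_degrees[bp], 9L)     # cumulated pixels of the 3 arms
  expect_equal(ny$node_degrees[-bp], rep(3L, 3))  # 2 interior + the branchpoint
  iso <- array(FALSE, dim = c(3, 3, 3)); iso[2, 2, 2] <- TRUE
  ni <- detect_nodes(iso)
  expect_equal(ni$node_count, 1L)
  expect_equal(ni$node_degrees, 0L)
})

test_that("node analysis agrees with the igraph oracle on random trees", {
  set.seed(41)
  for (i in 1:40) {
    sk <- random_tree_skeleton(n_branches = sample(2:4, 1))
    got <- detect_nodes(sk)
    want <- oracle_skeleton_nodes(sk)
    expect_equal(got$node_count, want$node_count, info = paste("rep", i))
    expect_equal(sort(got$node_degrees), sort(want$node_degrees),
                 info = paste("rep", i))
  }
})

test_that("component shape: cube example and unit arithmetic", {
  cube <- array(FALSE, dim = c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- TRUE
  s <- component_shape(cube, geometry = geom_iso)
  expect_equal(s$volume_vox, 8)
  expect_equal(s$body_vox, 0)       # 2x2x2 has no interior under 6-erosion
  expect_equal(s$surface_vox, 8)
  rod <- make_rod_mask(10L)
  s2 <- component_shape(rod, geometry = geom_iso)
  expect_equal(s2$volume_um3, 10 * 0.1 * 0.1 * 0.18)
  expect_equal(s2$skeleton_length_um, 9 * 0.18)  # 9 axial steps of dz
})

test_that("component_shape via indices matches the mask route", {
  set.seed(19)
  m <- random_component_mask()
  comps <- label_components(m)$components
  big <- comps[[which.max(vapply(comps, `[[`, integer(1), "voxel_count"))]]
  s_idx <- component_shape(big, dim_stack = dim(m), geometry = geom_iso)
  sub <- array(FALSE, dim = dim(m)); sub[big$indices] <- TRUE
  s_mask <- component_shape(sub, geometry = geom_iso)
  expect_equal(s_idx$volume_vox, s_mask$volume_vox)
  expect_equal(s_idx$surface_vox, s_mask$surface_vox)
  expect_equal(s_idx$node_count, s_mask$node_count)
})

test_that("ganglion volume arithmetic and linearity in dz", {
  set.seed(3)
  m <- array(FALSE, dim = c(20, 20, 5)); m[sample(length(m), 1000)] <- TRUE
  expect_equal(ganglion_volume(m, geom_iso), 1000 * 0.1 * 0.1 * 0.18)
  g2 <- voxel_geometry(0.1, 0.1, 0.36)
  expect_equal(ganglion_volume(m, g2), 2 * ganglion_volume(m, geom_iso))
  full <- array(TRUE, dim = c(64, 64, 10))
  expect_equal(ganglion_volume(full, voxel_geometry(1, 1, 1)), 40960)
  expect_error(ganglion_volume(array(FALSE, c(2, 2, 2)), geom_iso), "empty")
})

test_that("feature aggregation follows the definitions", {
  mk <- function(vol_um3) structure(list(volume_vox = 10L, volume_um3 = vol_um3,
                                         surface_vox = 6L, body_vox = 4L,
                                         skeleton_vox = 5L, skeleton_length_um = 0.5,
                                         node_count = 2L, node_degrees = c(4L, 4L),
                                         graph_degrees = c(1L, 1L)),
                                    class = "component_shape")
  f <- ganglion_features(list(mk(0.01), mk(0.03)), ganglion_vol = 10,
                         metadata = list(ganglion_id = "g1", group = "patient"))
  expect_equal(f$MitoCount, 0.2)
  expect_equal(f$MitoVolumeTotal, 0.004)
  expect_equal(f$MitoVolumeMean, 0.02)
  expect_equal(f$MitoSurfaceFractionMean, 0.6)
  expect_equal(f$MitoNodesMean, 2)
  expect_equal(f$MitoNodeDegreeMean, 4)
  # homogeneity: doubling object volumes doubles the volume features only
  f2 <- ganglion_features(list(mk(0.02), mk(0.06)), ganglion_vol = 10,
                          metadata = list(ganglion_id = "g1", group = "patient"))
  expect_equal(f2$MitoVolumeMean, 2 * f$MitoVolumeMean)
  expect_equal(f2$MitoVolumeTotal, 2 * f$MitoVolumeTotal)
  expect_equal(f2$MitoCount, f$MitoCount)
  # empty ganglion: counts zero, means missing
  f0 <- ganglion_features(list(), ganglion_vol = 10)
  expect_equal(f0$MitoCount, 0)
  expect_equal(f0$MitoVolumeTotal, 0)
  expect_true(is.na(f0$MitoVolumeMean))
  expect_true(is.na(f0$MitoNodesMean))
})

test_that("features are invariant under translation and 90-degree rotation", {
  set.seed(59)
  m <- array(FALSE, dim = c(16, 16, 6))
  m[4:9, 5:7, 2:4] <- TRUE
  m[6, 8:12, 3] <- TRUE
  iso <- voxel_geometry(0.1, 0.1, 0.1)   # isotropic so rotation is exact
  s0 <- component_shape(m, geometry = iso)
  # translate by (2, 1, 1)
  mt <- array(FALSE, dim = dim(m))
  idx <- which(m)
  co <- arrayInd(idx, dim(m))
  mt[cbind(co[, 1] + 2L, co[, 2] + 1L, co[, 3] + 1L)] <- TRUE
  st <- component_shape(mt, geometry = iso)
  # rotate 90 degrees in the (y, x) plane
  mr <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE]
  sr <- component_shape(mr, geometry = iso)
  for (s in list(st, sr)) {
    expect_equal(s$volume_vox, s0$volume_vox)
    expect_equal(s$surface_vox, s0$surface_vox)
    expect_equal(s$node_count, s0$node_count)
    expect_equal(s$skeleton_length_um, s0$skeleton_length_um, tolerance = 1e-8)
  }
})
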