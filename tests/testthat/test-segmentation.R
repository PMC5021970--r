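# Two-rule pixel mask, Otsu, component labeling, size filter, gating.

stack_of <- function(v, bit = 16L) {
  image_stack(v, bit, voxel_geometry(0.1, 0.1, 0.18))
}

test_that("flat and empty stacks yield no local-rule pixels", {
  g <- array(500, dim = c(32, 32, 3))
  expect_false(any(local_rule_mask(stack_of(g))))   # 1 < 1.25 everywhere
  expect_false(any(local_rule_mask(stack_of(array(0, dim = c(32, 32, 3))))))
})

test_that("local rule matches hand-computed filter responses on a bright square", {
  v <- array(0, dim = c(32, 32, 1))
  v[15:17, 15:17, 1] <- 1000
  got <- local_rule_mask(stack_of(v))
  # independent responses: naive per-pixel filters with the same padding
  k <- outer(exp(-(-2:2)^2 / 8), exp(-(-2:2)^2 / 8))
  k <- k / sum(k)
  sm <- matrix(0, 32, 32)
  for (y in 1:32) for (x in 1:32) {
    acc <- 0
    for (dy in -2:2) for (dx in -2:2) {
      acc <- acc + k[dy + 3, dx + 3] *
        v[min(max(y + dy, 1), 32), min(max(x + dx, 1), 32), 1]
    }
    sm[y, x] <- acc
  }
  bg <- oracle_box_filter(v[, , 1], 10L)
  want <- (bg > 0 & sm >= 1.25 * bg) | (bg <= 0 & sm > 0)
  expect_equal(got[, , 1], want)
  expect_true(any(got))
})

test_that("illumination correction subtracts the 20x20 background field", {
  # constant image -> all zeros
  expect_true(all(illumination_correct(stack_of(array(77, c(40, 40, 2)))) == 0))
  # planar ramp: interior values near 0 (only the boundary band deviates)
  v <- array(rep(seq(0, 39) * 10, each = 40), dim = c(40, 40, 1))
  corr <- illumination_correct(stack_of(v))
  expect_lt(max(abs(corr[15:25, 15:25, 1])), 6)
  # single bright voxel: interior centre value b - b/400, clamped elsewhere
  v2 <- array(0, dim = c(41, 41, 1))
  v2[21, 21, 1] <- 4000
  corr2 <- illumination_correct(stack_of(v2))
  expect_equal(corr2[21, 21, 1], 4000 - 4000 / 400)
  # oracle agreement on the ramp, interior and boundary alike
  expect_equal(corr[, , 1], pmax(v[, , 1] - oracle_box_filter(v[, , 1], 20L), 0))
})

test_that("Otsu separates two point masses and rejects constant stacks", {
  x <- array(c(rep(10, 1000), rep(200, 1000)), dim = c(10, 10, 20))
  ot <- otsu_threshold(x)
  expect_gt(ot$threshold, 10)
  expect_lt(ot$threshold, 200)
  expect_equal(sum(ot$mask), 1000)
  expect_error(otsu_threshold(array(5, c(4, 4, 4))), "constant")
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(5)
  for (i in 1:50) {
    counts <- rpois(256, lambda = sample(c(1, 5, 50), 256, replace = TRUE,
                                         prob = c(0.6, 0.3, 0.1)))
    if (sum(counts > 0) < 2) next
    expect_equal(mitoganglia:::otsu_from_counts(counts), oracle_otsu_split(counts))
  }
})

test_that("connectivity semantics: corner-touching voxels", {
  m <- array(FALSE, dim = c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE   # shares only a corner
  expect_length(label_components(m, 26)$components, 1L)
  expect_length(label_components(m, 6)$components, 2L)
  e <- array(FALSE, dim = c(2, 2, 2))
  expect_length(label_components(e)$components, 0L)
})

test_that("component labeling agrees with a flood-fill oracle on random masks", {
  set.seed(23)
  for (i in 1:12) {
    conn <- sample(c(6, 18, 26), 1)
    m <- array(runif(10 * 10 * 6) < 0.25, dim = c(10, 10, 6))
    lc <- label_components(m, conn)
    expect_equal(length(lc$components), oracle_flood_fill(m, conn),
                 info = sprintf("rep %d conn %d", i, conn))
    # labels partition the mask
    expect_equal(sort(unlist(lapply(lc$components, `[[`, "indices"))), which(m))
    expect_equal(sum(lc$labels > 0), sum(m))
  }
})

test_that("size filter keeps [8, 1e6] inclusive", {
  fake <- function(n) structure(list(id = 1L, indices = seq_len(n), voxel_count = n),
                                class = "mito_component")
  comps <- lapply(c(7, 8, 1e6, 1e6 + 1), fake)
  kept <- filter_components(comps)
  expect_equal(vapply(kept, `[[`, numeric(1), "voxel_count"), c(8, 1e6))
})

test_that("ganglion gating keeps whole intersecting components", {
  m <- array(FALSE, dim = c(6, 6, 2))
  m[1:2, 1, 1] <- TRUE          # component A: touches ganglion in 1 voxel
  m[5:6, 6, 2] <- TRUE          # component B: fully outside
  comps <- label_components(m)$components
  gang <- array(FALSE, dim = c(6, 6, 2))
  gang[2, 1, 1] <- TRUE
  kept <- gate_by_ganglion(comps, gang)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$voxel_count, 2L)   # kept whole, not clipped
  # full-grid ganglion is the identity
  expect_length(gate_by_ganglion(comps, array(TRUE, dim = c(6, 6, 2))), 2L)
  expect_error(gate_by_ganglion(comps, array(FALSE, dim = c(6, 6, 2))), "empty")
})

test_that("filtering and gating commute (both are per-component predicates)", {
  set.seed(77)
  m <- array(runif(16 * 16 * 8) < 0.3, dim = c(16, 16, 8))
  gang <- array(FALSE, dim = c(16, 16, 8))
  gang[5:12, 5:12, 3:6] <- TRUE
  comps <- label_components(m)$components
  a <- gate_by_ganglion(filter_components(comps, 4, 1e6), gang)
  b <- filter_components(gate_by_ganglion(comps, gang), 4, 1e6)
  expect_equal(lapply(a, `[[`, "indices"), lapply(b, `[[`, "indices"))
})

test_that("the combined mask is contained in both sub-masks", {
  sim <- simulate_stack(stack_sim_spec(shape = c(64L, 64L, 8L), n_objects = 5L,
                                       seed = 3L))
  st <- adjust_to_16bit(sim$stack)
  mm <- mito_pixel_mask(st)
  expect_false(any(mm$mask & !mm$local))
  expect_false(any(mm$mask & !mm$global))
})

test_that("segmentation recovers simulated rods inside the ganglion", {
  sim <- simulate_stack(stack_sim_spec(shape = c(96L, 96L, 12L), n_objects = 10L,
                                       seed = 9L))
  st <- adjust_to_16bit(sim$stack)
  res <- segment_stack(st, sim$truth$ganglion)
  m <- match_components(sim$truth$objects, res$components)
  expect_equal(length(res$components), 10L)
  expect_true(all(m$recovered))
  # true-positive voxel fraction against ground truth
  tp <- sum(res$labels[unlist(sim$truth$objects)] > 0)
  expect_gt(tp / length(unlist(sim$truth$objects)), 0.8)
})
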