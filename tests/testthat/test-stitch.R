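test_that("reference slice selection honours manual and auto modes", {
  d <- array(0, c(10, 10, 100))
  d[3:6, 4:8, 20] <- 1                # the only structured inferior slice
  d[2:9, 2:9, 60] <- 5                # structure outside the inferior quartile
  d[5, 5, ] <- 0.01                   # keep every slice nonconstant
  v <- scalar_volume(d, spacing = c(1, 1, 1))

  expect_identical(select_reference_slice(v, "manual", 40)$z_index_in_brain, 40L)
  expect_error(select_reference_slice(v, "manual", 200), "range")
  expect_identical(select_reference_slice(v, "auto")$z_index_in_brain, 20L)
})

test_that("raw correlation profile reproduces the worked 2x2 example", {
  A <- matrix(c(1, 3, 2, 4), 2, 2)            # A(x, y): rows x, cols y
  B <- array(0, c(2, 2, 2))
  B[, , 1] <- diag(2)
  B[, , 2] <- 2
  prof <- correlation_profile(A, B, normalize = FALSE)
  expect_equal(prof$scores, c(5, 20))
  expect_identical(prof$z_best, 2L)           # second slice (1-based)
})

test_that("correlation profile finds an embedded reference and flags degeneracy", {
  withr::with_seed(3, ref <- matrix(runif(64), 8, 8))
  B <- array(0, c(8, 8, 7))
  B[, , 4] <- ref
  prof <- correlation_profile(ref, B, normalize = FALSE)
  expect_identical(prof$z_best, 4L)

  expect_warning(p0 <- correlation_profile(matrix(0, 8, 8), B), "degenerate")
  expect_true(all(p0$scores == 0))
  expect_true(p0$degenerate)
})

test_that("normalized profile scores stay within [-1, 1]", {
  withr::with_seed(5, {
    for (i in 1:5) {
      ref <- matrix(rnorm(100), 10, 10)
      B <- array(rnorm(100 * 6), c(10, 10, 6))
      prof <- correlation_profile(ref, B)
      expect_true(all(prof$scores >= -1 - 1e-12 & prof$scores <= 1 + 1e-12))
    }
  })
})

# analytic asymmetric test pattern evaluated at arbitrary (0-based) coords
pattern_at <- function(px, py) {
  exp(-((px - 14)^2 / 30 + (py - 16)^2 / 18)) +
    0.7 * exp(-((px - 21)^2 / 8 + (py - 14)^2 / 10))
}
pattern_slice <- function(n = 32, theta = 0, shift = c(0, 0)) {
  c0 <- (n - 1) / 2
  g <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  th <- theta * pi / 180
  px <- c0 + cos(th) * (g$i - c0) - sin(th) * (g$j - c0) - shift[1]
  py <- c0 + sin(th) * (g$i - c0) + cos(th) * (g$j - c0) - shift[2]
  matrix(pattern_at(px, py), n, n)
}

test_that("rigid refinement recovers identity, translations and rotations", {
  A <- pattern_slice()
  p0 <- refine_rigid(A, A)
  expect_equal(c(p0$theta, p0$dx, p0$dy), c(0, 0, 0))

  # moving slice = reference translated by (+2, +1): parameters map it back
  B <- dtistitch:::shift_slice_int(A, c(2, 1))
  pt <- refine_rigid(A, B)
  expect_equal(c(pt$theta, pt$dx, pt$dy), c(0, -2, -1))

  # moving slice = reference rotated by 8 degrees about the slice centre
  Brot <- pattern_slice(theta = 8)
  pr <- refine_rigid(A, Brot)
  expect_equal(pr$theta, 8)
  expect_lte(abs(pr$dx) + abs(pr$dy), 2)

  expect_error(refine_rigid(A, matrix(1, 32, 32)), "degenerate")
})

test_that("transform application is exact for identity and rotates bvecs", {
  gv <- tiny_gv(dims = c(8, 8, 4), bvals = c(0, 1000))
  same <- apply_transform(gv, rigid_params(0, 0, 0))
  expect_identical(same$data, gv$data)

  gvx <- gradient_volume(gv$data, spacing = gv$spacing, bvals = c(0, 1000),
                         bvecs = cbind(c(0, 0, 0), c(1, 0, 0)))
  rot <- apply_transform(gvx, rigid_params(90, 0, 0))
  expect_equal(rot$bvecs[, 2], c(0, 1, 0), tolerance = 1e-9)

  # 90 + 90 composes to 180 up to interpolation error on a smooth slice
  sl <- pattern_slice(24)
  v <- scalar_volume(array(sl, c(24, 24, 1)), spacing = c(1, 1, 1))
  twice <- apply_transform(apply_transform(v, rigid_params(90, 0, 0)),
                           rigid_params(90, 0, 0))
  once <- apply_transform(v, rigid_params(180, 0, 0))
  expect_lt(max(abs(twice$data - once$data)), 1e-6)
})

test_that("fusion feathers the overlap and copies sources verbatim outside it", {
  mk <- function(val, nz) {
    arr <- array(val, c(4, 4, nz, 2))
    gradient_volume(arr, spacing = c(2, 2, 2), bvals = c(0, 1000),
                    bvecs = cbind(0, c(1, 0, 0)))
  }
  brain <- mk(0, 8)
  cord <- mk(1, 9)
  st <- fuse(brain, cord, z_offset = 4, blend = "feather")
  # overlap = fused slices 5:9; cord weight ramps 1 -> 0 superior-ward
  expect_identical(st$overlap_range, c(5L, 9L))
  w <- sapply(5:9, function(f) st$data[1, 1, f, 1])
  expect_equal(w, c(1, 0.75, 0.5, 0.25, 0))
  expect_identical(st$source_labels[1:4], rep("cord", 4))
  expect_identical(st$source_labels[10:12], rep("brain", 3))
  # outside the overlap the b0 equals its source bit-exactly
  expect_identical(st$data[, , 1:4, 1], cord$data[, , 1:4, 1])
  expect_identical(st$data[, , 10:12, 1], brain$data[, , 6:8, 1])

  # identical overlap content fuses to that content for any blend
  cord2 <- mk(0.5, 9); brain2 <- mk(0.5, 8)
  for (bl in c("feather", "brain_priority", "cord_priority")) {
    stb <- fuse(brain2, cord2, 4, blend = bl)
    expect_true(all(stb$data[, , 5:9, 1] == 0.5))
  }

  # brain_priority takes the brain verbatim across the overlap
  stp <- fuse(brain, cord, 4, blend = "brain_priority")
  expect_true(all(stp$data[, , 5:9, 1] == 0))

  # DWI blocks are kept verbatim with a merged gradient table
  expect_identical(dim(st$data)[4], 3L)
  expect_identical(st$bvals, c(0, 1000, 1000))
  expect_identical(dim(st$frame_valid), c(3L, 12L))

  expect_error(fuse(brain, cord, z_offset = 20), "overlap")
})

test_that("stitch transform estimation recovers a known phantom truth", {
  pair <- generate_pair(phantom_spec(n_dirs = 2))
  b0b <- extract_b0(pair$brain); b0c <- extract_b0(pair$cord)
  p <- estimate_stitch_transform(b0b, b0c,
                                 brain_mask = nervous_system_mask(b0b),
                                 cord_mask = nervous_system_mask(b0c))
  expect_equal(p$theta, pair$truth$theta)
  expect_lte(abs(p$dx - pair$truth$dx), 1)
  expect_lte(abs(p$dy - pair$truth$dy), 1)
  expect_identical(p$z_offset, pair$truth$z_offset)
  expect_true(nrow(attr(p, "per_slice")) >= 5)
})

test_that("self-overlap of a volume with its inferior half is the identity", {
  pair <- generate_pair(phantom_spec(n_dirs = 2, theta_true = 0,
                                     shift_true = c(0, 0)))
  b0b <- extract_b0(pair$brain)
  half <- scalar_volume(b0b$data[, , 1:20], spacing = b0b$spacing,
                        affine = b0b$affine)
  p <- estimate_stitch_transform(b0b, half, min_overlap_slices = 5)
  expect_identical(p$z_offset, 0L)
  expect_lte(abs(p$theta), 4)
  expect_lte(abs(p$dx) + abs(p$dy), 1)
})

test_that("structureless inputs produce a stitch failure", {
  pair <- generate_pair(phantom_spec(n_dirs = 2))
  b0b <- extract_b0(pair$brain)
  flat <- scalar_volume(array(0, c(32, 32, 48)), spacing = c(2, 2, 2))
  expect_error(estimate_stitch_transform(b0b, flat), "stitch failure")
})
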