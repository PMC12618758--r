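test_that("noiseless tensor fit recovers the diffusion tensor exactly", {
  D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  bvals <- c(0, rep(1000, 32))
  bvecs <- cbind(0, dtistitch:::fibonacci_directions(32))
  s <- tensor_signal(D, bvals, bvecs, s0 = 250)
  gv <- gradient_volume(array(rep(s, each = 27), c(3, 3, 3, 33)),
                        spacing = c(2, 2, 2), bvals = bvals, bvecs = bvecs)
  tf <- fit_tensor(gv)
  expect_lt(max(abs(tf$tensors[2, 2, 2, ] - c(diag(D), 0, 0, 0))), 1e-9)
  expect_equal(abs(tf$v1[2, 2, 2, ]), c(1, 0, 0), tolerance = 1e-9)
  expect_true(all(tf$valid_mask))

  # too few directions is an error
  few <- gradient_volume(gv$data[, , , 1:6], spacing = c(2, 2, 2),
                         bvals = bvals[1:6], bvecs = bvecs[, 1:6])
  expect_error(fit_tensor(few), "directions")
})

test_that("fractional anisotropy honours its analytic limits", {
  expect_equal(fa_from_eigenvalues(c(1e-3, 1e-3, 1e-3)), 0, tolerance = 1e-12)
  expect_equal(fa_from_eigenvalues(c(1, 0, 0)), 1, tolerance = 1e-12)
  # isotropic voxel through the full fit
  bvals <- c(0, rep(1000, 8))
  bvecs <- cbind(0, dtistitch:::fibonacci_directions(8))
  s <- tensor_signal(diag(rep(7e-4, 3)), bvals, bvecs)
  gv <- gradient_volume(array(rep(s, each = 8), c(2, 2, 2, 9)),
                        spacing = c(1, 1, 1), bvals = bvals, bvecs = bvecs)
  expect_lt(max(fit_tensor(gv)$fa), 1e-10)
})

test_that("FA from the fit is invariant under rotations of the tensor", {
  D <- diag(c(1.7e-3, 0.3e-3, 0.3e-3))
  bvals <- c(0, rep(1000, 20))
  bvecs <- cbind(0, dtistitch:::fibonacci_directions(20))
  fa_ref <- fa_from_eigenvalues(diag(D))
  withr::with_seed(19, {
    for (i in 1:6) {
      R <- qr.Q(qr(matrix(rnorm(9), 3)))
      DR <- R %*% D %*% t(R)
      s <- tensor_signal(DR, bvals, bvecs)
      gv <- gradient_volume(array(s, c(1, 1, 1, 21)), spacing = c(1, 1, 1),
                            bvals = bvals, bvecs = bvecs)
      expect_lt(abs(fit_tensor(gv)$fa[1, 1, 1] - fa_ref), 1e-10)
    }
  })
})

test_that("FA bias stays small under Rician noise at SNR 20", {
  clean <- generate_pair(phantom_spec(n_dirs = 16, snr = Inf))
  noisy <- generate_pair(phantom_spec(n_dirs = 16, snr = 20))
  fa_true <- fa_from_eigenvalues(dtistitch:::PHANTOM_TUBE_EVALS)
  tf0 <- fit_tensor(clean$cord)
  interior <- abs(tf0$fa - fa_true) < 1e-6          # fully inside the tube
  expect_gt(sum(interior), 200)
  tfn <- fit_tensor(noisy$cord, mask = interior)
  expect_lt(abs(median(tfn$fa[interior]) - fa_true), 0.05)
})

test_that("tracking follows the tube geometry and respects its thresholds", {
  tf <- tube_field()                                 # 30 slices x 2 mm = 60 mm
  mask <- array(1, dim(tf$fa))
  ss <- track(tf, mask = mask, fa_threshold = 0.2, rng_seed = 17)
  expect_gt(length(ss$streamlines), 50)
  expect_true(all(ss$lengths >= 58 & ss$lengths <= 62))

  expect_warning(none <- track(tf, mask = mask, fa_threshold = 0.9),
                 "zero streamlines")
  expect_identical(length(none$streamlines), 0L)

  ss2 <- track(tf, mask = mask, fa_threshold = 0.2, rng_seed = 17)
  expect_identical(ss$streamlines, ss2$streamlines)  # determinism

  expect_error(track(tf, mask = array(0, dim(tf$fa))), "empty")
})

test_that("tracking is equivariant under integer-voxel shifts of the field", {
  tf <- tube_field(dims = c(16, 16, 30), z_range = c(6, 25))
  shift <- c(2L, 1L, 0L)
  tfs <- tf
  tfs$fa <- array(0, dim(tf$fa))
  tfs$fa[(1 + shift[1]):16, (1 + shift[2]):16, ] <-
    tf$fa[1:(16 - shift[1]), 1:(16 - shift[2]), ]
  tfs$v1 <- tf$v1
  seeds <- generate_seeds(array(as.integer(tf$fa > 0.5), dim(tf$fa)),
                          tf$affine, seed = 23, max_seeds = 40)
  seeds_s <- sweep(seeds, 2, shift * tf$spacing, "+")
  a <- track(tf, seeds = seeds, mask = array(1, dim(tf$fa)), fa_threshold = 0.2)
  b <- track(tfs, seeds = seeds_s, mask = array(1, dim(tf$fa)), fa_threshold = 0.2)
  expect_identical(length(a$streamlines), length(b$streamlines))
  for (i in seq_along(a$streamlines))
    expect_equal(sweep(a$streamlines[[i]], 2, shift * tf$spacing, "+"),
                 b$streamlines[[i]], tolerance = 1e-8)
})

test_that("adaptive FA threshold separates modes and clamps degenerate maps", {
  tf <- tube_field(fa_in = 0.7)
  tf$fa[tf$fa == 0] <- 0.1                           # background mode at 0.1
  thr <- adaptive_fa_threshold(tf)
  expect_gt(thr, 0.1)
  expect_lte(thr, 0.35)                              # upper clamp

  flat <- tf; flat$fa[] <- 0.5
  expect_warning(t2 <- adaptive_fa_threshold(flat), "constant")
  expect_identical(t2, 0.08)

  expect_identical(adaptive_fa_threshold(tf, override = 0.2), 0.2)
})

test_that("fiber length statistics summarize medians as printed", {
  st <- fiber_length_stats(c(180, 195, 189, 197))
  expect_identical(st$median, 192)
  expect_identical(st$n, 4L)
  expect_identical(fiber_length_stats(c(102, 108, 127, 115))$median, 111.5)
  expect_identical(fiber_length_stats(42.5)$median, 42.5)
  expect_error(fiber_length_stats(numeric(0)), "empty")
})

test_that("FOV length comparison ranks stitched against single FOVs", {
  withr::with_seed(31, {
    brain <- rnorm(300, 80, 6); cord <- rnorm(300, 95, 6)
    stitched <- rnorm(300, 104, 6)
  })
  rep <- compare_fov_lengths(brain, cord, stitched)
  expect_true(rep$stitched_longer)
  expect_lt(rep$tests$stitched_vs_brain, 0.05)
  expect_lt(rep$tests$stitched_vs_cord, 0.05)

  same <- compare_fov_lengths(cord, cord, cord)
  expect_equal(same$stats$stitched$median - same$stats$brain$median, 0)
  expect_false(same$stitched_longer)

  expect_error(compare_fov_lengths(numeric(0), cord, stitched), "empty")
})
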