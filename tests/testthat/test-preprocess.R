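test_that("upsampling doubles the grid, halves spacing and preserves geometry", {
  v <- scalar_volume(array(7, c(4, 4, 4)), spacing = c(2, 2, 2))
  up <- upsample_by_2(v)
  expect_identical(dim(up$data), c(8L, 8L, 8L))
  expect_equal(up$spacing, c(1, 1, 1))
  expect_true(all(up$data == 7))                    # constant stays constant

  # a linear ramp keeps its world-coordinate gradient at the new voxel centres
  dims <- c(6, 5, 4)
  affine <- diag(c(2, 2, 2, 1)); affine[1:3, 4] <- c(-5, 0, 3)
  wx <- affine[1, 1] * (seq_len(dims[1]) - 1) + affine[1, 4]
  ramp <- array(rep(2.5 * wx, times = prod(dims[2:3])), dims)
  up2 <- upsample_by_2(scalar_volume(ramp, spacing = c(2, 2, 2), affine = affine))
  wx_new <- up2$affine[1, 1] * (seq_len(2 * dims[1]) - 1) + up2$affine[1, 4]
  interior <- 2:(2 * dims[1] - 1)                   # edge voxels are clamped
  expect_equal(up2$data[interior, 3, 3], 2.5 * wx_new[interior],
               tolerance = 1e-12)

  # world bounding box of voxel centres preserved to within one output voxel
  old_lo <- affine[1:3, 4] - affine[c(1, 6, 11)] / 2
  new_lo <- up2$affine[1:3, 4] - up2$affine[c(1, 6, 11)] / 2
  expect_true(all(abs(old_lo - new_lo) <= up2$spacing + 1e-12))

  # 4D volumes are upsampled per frame with the gradient table untouched
  gv <- tiny_gv(dims = c(4, 4, 4), bvals = c(0, 1000))
  upg <- upsample_by_2(gv)
  expect_identical(dim(upg$data), c(8L, 8L, 8L, 2L))
  expect_identical(upg$bvals, gv$bvals)
  expect_identical(upg$bvecs, gv$bvecs)
})

test_that("mask generation thresholds, removes speckle, and validates", {
  d <- array(0, c(12, 12, 6))
  d[4:9, 4:9, 2:5] <- 100                          # the object
  v <- scalar_volume(d, spacing = c(1, 1, 1))
  m <- make_mask(v, threshold = 50)
  expect_identical(m$data == 1, d == 100)

  auto <- make_mask(v, threshold = "auto")
  expect_identical(auto$data, m$data)              # Otsu lands between the modes
  expect_gt(auto$threshold_used, 0)
  expect_lt(auto$threshold_used, 100)

  expect_error(make_mask(v, threshold = 101), "empty")

  d[1, 1, 1] <- 100                                # isolated speckle voxel
  m2 <- make_mask(scalar_volume(d, spacing = c(1, 1, 1)), threshold = 50)
  expect_equal(m2$data[1, 1, 1], 0L)
  expect_equal(sum(m2$data), 6 * 6 * 4)
})

test_that("mutual information matches histogram identities", {
  half <- array(rep(c(0, 1), each = 500), c(10, 10, 10))
  expect_equal(mutual_information(half, half), 1)   # H of a fair binary image
  expect_equal(mutual_information(half, array(3, dim(half))), 0)

  withr::with_seed(7, {
    a <- array(rnorm(32^3), c(32, 32, 32))
    b <- array(rnorm(32^3), c(32, 32, 32))
  })
  expect_lt(mutual_information(a, b, bins = 16), 0.1)
  expect_error(mutual_information(a, array(0, c(4, 4, 4))), "shape")
})

test_that("self-information bounds MI against any other image", {
  withr::with_seed(11, {
    for (i in 1:5) {
      a <- array(rnorm(16^3), c(16, 16, 16))
      b <- array(rnorm(16^3)^2, c(16, 16, 16))
      expect_gte(mutual_information(a, a) + 1e-9, mutual_information(a, b))
    }
  })
})

test_that("motion registration recovers frame shifts and rotates bvecs", {
  base <- smooth_blob()
  q <- 4
  arr <- array(rep(base, q), c(dim(base), q))
  bvals <- c(0, rep(1000, q - 1))
  bvecs <- cbind(0, dtistitch:::fibonacci_directions(q - 1))
  aligned <- gradient_volume(arr, spacing = c(2, 2, 2), bvals = bvals,
                             bvecs = bvecs)
  res0 <- register_dwi_to_b0(aligned)
  expect_lt(max(abs(res0$transforms[-1, ])), 0.51)  # near-identity transforms

  # frame 3 shifted by +3 voxels in y (content moved +y)
  shifted <- arr
  shifted[, , , 3] <- dtistitch:::shift_array_int(base, c(0, -3, 0))
  gv <- gradient_volume(shifted, spacing = c(2, 2, 2), bvals = bvals,
                        bvecs = bvecs)
  res <- register_dwi_to_b0(gv)
  expect_lt(abs(res$transforms[3, "dy"] - 3), 0.5)
  expect_lt(max(abs(res$transforms[3, c("rx", "ry", "rz")])), 1)

  # bvec contract: the recovered rotation premultiplies the direction
  R <- dtistitch:::euler_rotation(res$transforms[3, 1:3])
  expect_equal(res$volume$bvecs[, 3], as.numeric(R %*% bvecs[, 3]),
               tolerance = 1e-12)
})

test_that("motion registration recovers a pure in-plane rotation", {
  base <- smooth_blob()
  pert <- dtistitch:::.rigid3d_resample(base, c(0, 0, 4), c(0, 0, 0))
  arr <- array(c(base, pert), c(dim(base), 2))
  gv <- gradient_volume(arr, spacing = c(2, 2, 2), bvals = c(0, 1000),
                        bvecs = cbind(0, c(1, 0, 0)))
  res <- register_dwi_to_b0(gv)
  expect_lt(abs(res$transforms[2, "rz"] - (-4)), 1)   # inverse of the perturbation
  expect_lt(max(abs(res$transforms[2, 4:6])), 0.5)
})

test_that("external distortion hook passes through, substitutes, and fails loudly", {
  gv <- tiny_gv()
  expect_identical(run_external_distortion_correction(
    gv, list(mode = "passthrough")), gv)

  expect_error(run_external_distortion_correction(
    gv, list(cmd = "no_such_binary_xyz {in} {out}", mode = "run",
             config_key = "preprocess.topup_cmd")),
    "preprocess.topup_cmd")

  argv <- dtistitch:::build_tool_argv("topup --imain={in} --out={out} -v",
                                      "/tmp/a.nii.gz", "/tmp/b.nii.gz")
  expect_identical(argv, c("topup", "--imain=/tmp/a.nii.gz",
                           "--out=/tmp/b.nii.gz", "-v"))
})
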