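test_that("gradient volume validates frame count against the gradient table", {
  gv <- tiny_gv(bvals = c(0, rep(1000, 32)))
  expect_equal(dim(gv$data)[4], 33L)
  expect_equal(length(gv$bvals), 33L)

  expect_error(
    gradient_volume(array(0, c(4, 4, 4, 33)), spacing = c(2, 2, 2),
                    bvals = rep(1000, 32),
                    bvecs = matrix(1 / sqrt(3), 3, 32)),
    "mismatch")
})

test_that("non-unit gradient directions with b > 0 are rejected by index", {
  bvecs <- cbind(c(0, 0, 0), diag(3), c(0.6, 0.6, 0.6),
                 c(0, 1, 0), c(0, 0, 1))
  err <- expect_error(
    gradient_volume(array(1, c(2, 2, 2, 7)), spacing = c(1, 1, 1),
                    bvals = c(0, rep(1000, 6)), bvecs = bvecs),
    "unit vector")
  expect_match(conditionMessage(err), "bvec 5")
  expect_match(conditionMessage(err), "1.039")
})

test_that("b0 extraction averages the qualifying frames", {
  d <- array(0, c(3, 3, 2, 3))
  d[, , , 1] <- 5          # b = 0
  d[, , , 2] <- 15         # b = 0
  d[, , , 3] <- 99         # b = 1000
  gv <- gradient_volume(d, spacing = c(1, 1, 1), bvals = c(0, 0, 1000),
                        bvecs = cbind(0, 0, c(1, 0, 0)))
  b0 <- extract_b0(gv)
  expect_true(all(b0$data == 10))

  one <- gradient_volume(d[, , , c(1, 3), drop = FALSE], spacing = c(1, 1, 1),
                         bvals = c(0, 1000), bvecs = cbind(0, c(1, 0, 0)))
  expect_true(all(extract_b0(one)$data == 5))

  allb <- gradient_volume(d[, , , 3, drop = FALSE], spacing = c(1, 1, 1),
                          bvals = 1000, bvecs = cbind(c(1, 0, 0)))
  expect_error(extract_b0(allb), "b0")
})

test_that("NIfTI round-trip preserves data, affine and gradient table", {
  withr::with_seed(42, {
    arr <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  })
  affine <- diag(c(2, 2, 2, 1)); affine[1:3, 4] <- c(-7, -7, 10)
  gv <- gradient_volume(arr, spacing = c(2, 2, 2), affine = affine,
                        bvals = c(0, rep(1000, 3)),
                        bvecs = cbind(0, diag(3)))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(gv, path)
  stem <- sub("\\.nii\\.gz$", "", path)
  back <- read_gradient_volume(path, paste0(stem, ".bval"), paste0(stem, ".bvec"))
  expect_equal(back$data, gv$data, tolerance = 1e-7)   # float32 storage
  expect_equal(back$affine, gv$affine, tolerance = 1e-5, ignore_attr = TRUE)
  expect_identical(back$bvals, gv$bvals)
  expect_equal(back$bvecs, gv$bvecs, ignore_attr = TRUE)

  sv <- scalar_volume(arr[, , , 1], spacing = c(2, 2, 2), affine = affine)
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(sv, p2)
  back2 <- read_scalar_volume(p2)
  expect_equal(back2$data, sv$data, tolerance = 1e-7)
  expect_equal(back2$affine, sv$affine, tolerance = 1e-5, ignore_attr = TRUE)
})
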