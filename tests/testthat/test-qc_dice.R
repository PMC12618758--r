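test_that("FA binarization uses an inclusive threshold", {
  expect_false(any(binarize_fa(matrix(0, 4, 4))))
  expect_true(all(binarize_fa(matrix(0.35, 4, 4))))      # boundary included
  cb <- matrix(c(0.2, 0.5), 4, 4)
  expect_identical(binarize_fa(cb), cb == 0.5)
})

test_that("central component keeps the dominant or centre-most region", {
  single <- matrix(FALSE, 11, 11); single[3:5, 3:5] <- TRUE
  expect_identical(central_component(single), single)

  # equal areas: the centred one wins on centroid distance
  two <- matrix(FALSE, 15, 15)
  two[7:9, 7:9] <- TRUE                                  # centred 3x3
  two[1:3, 1:3] <- TRUE                                  # cornered 3x3
  cc <- central_component(two)
  expect_true(all(cc[7:9, 7:9]))
  expect_false(any(cc[1:3, 1:3]))

  # dominant area wins even off-centre
  blob <- matrix(FALSE, 20, 20)
  blob[6:15, 6:15] <- TRUE                               # 100 px central blob
  blob[1:2, 19:20] <- TRUE; blob[20, 20] <- TRUE         # 5 px speck
  cb <- central_component(blob)
  expect_identical(sum(cb), 100L)

  expect_identical(sum(central_component(matrix(FALSE, 5, 5))), 0L)
})

test_that("components touching diagonally are one 8-connected region", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE
  expect_identical(sum(central_component(m)), 3L)
})

test_that("Dice coefficient matches its defining identities", {
  masks <- generate_qc_masks()
  expect_identical(dice(masks$identical$a, masks$identical$b), 1)
  expect_identical(dice(masks$disjoint$a, masks$disjoint$b), 0)
  expect_identical(sum(masks$partial$a), masks$partial$size_a)
  expect_identical(sum(masks$partial$b), masks$partial$size_b)
  expect_identical(sum(masks$partial$a & masks$partial$b),
                   masks$partial$intersection)
  expect_identical(dice(masks$partial$a, masks$partial$b), 0.6)

  expect_warning(both <- dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)),
                 "empty")
  expect_identical(both, 1)
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("Dice is symmetric on random masks", {
  withr::with_seed(13, {
    for (i in 1:6) {
      a <- matrix(runif(64) > 0.6, 8, 8)
      b <- matrix(runif(64) > 0.6, 8, 8)
      expect_identical(dice(a, b), dice(b, a))
    }
  })
})

# FA stack with a centred disk per slice, optionally shifted in x
fa_stack <- function(nz = 6, shift = 0, r = 6) {
  d <- array(0, c(24, 24, nz))
  xs <- seq_len(24) - 12.5 - shift
  ys <- seq_len(24) - 12.5
  disk <- outer(xs^2, ys^2, "+") <= r^2
  for (k in seq_len(nz)) d[, , k] <- disk * 0.8
  d
}

test_that("dice report aggregates per-slice scores over the overlap", {
  fa <- fa_stack()
  rep <- dice_report(fa, fa, overlap_range = c(1, 6))
  expect_identical(rep$aggregate, 1)
  expect_identical(rep$slices_used, 6L)
  expect_true(all(rep$per_slice$dice == 1))

  mis <- dice_report(fa, fa_stack(shift = 1), overlap_range = c(1, 6))
  expect_lt(mis$aggregate, 1)

  expect_error(dice_report(fa * 0, fa * 0, overlap_range = c(1, 6)),
               "no QC-eligible")
})

test_that("aggregate Dice decreases monotonically with misalignment", {
  fa <- fa_stack(r = 7)
  aggs <- sapply(0:5, function(s)
    dice_report(fa, fa_stack(shift = s, r = 7), overlap_range = c(1, 6))$aggregate)
  expect_true(all(diff(aggs) <= 1e-12))
  expect_identical(aggs[1], 1)
})
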