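# shared builders for small in-code fixtures

# minimal gradient volume: constant or supplied 4D data
tiny_gv <- function(dims = c(4, 4, 4), bvals = c(0, 1000, 1000, 1000, 1000,
                                                 1000, 1000),
                    data = NULL, spacing = c(2, 2, 2)) {
  q <- length(bvals)
  dirs <- dtistitch:::fibonacci_directions(max(sum(bvals > 0), 1))
  bvecs <- matrix(0, 3, q)
  bvecs[, bvals > 0] <- dirs[, seq_len(sum(bvals > 0))]
  if (is.null(data)) data <- array(as.numeric(seq_len(prod(dims) * q)), c(dims, q))
  gradient_volume(data, spacing = spacing, bvals = bvals, bvecs = bvecs)
}

# analytic tensor field: straight tube along z with given FA inside
tube_field <- function(dims = c(20, 20, 40), spacing = 2, radius_mm = 6,
                       z_range = c(6, 35), fa_in = 0.8) {
  fa <- array(0, dims)
  v1 <- array(0, c(dims, 3))
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * spacing
  ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * spacing
  inside <- outer(xs^2, ys^2, "+") <= radius_mm^2
  for (k in z_range[1]:z_range[2]) fa[, , k] <- inside * fa_in
  v1[, , , 3] <- 1
  structure(list(fa = fa, v1 = v1, spacing = rep(spacing, 3),
                 affine = diag(c(rep(spacing, 3), 1)),
                 valid_mask = fa > 0),
            class = "TensorField")
}

# smooth asymmetric 3D intensity pattern for registration tests
smooth_blob <- function(dims = c(24, 24, 20)) {
  xs <- seq_len(dims[1]); ys <- seq_len(dims[2]); zs <- seq_len(dims[3])
  g <- expand.grid(x = xs, y = ys, z = zs)
  v <- exp(-((g$x - 10)^2 / 40 + (g$y - 13)^2 / 24 + (g$z - 10)^2 / 30)) +
    0.6 * exp(-((g$x - 16)^2 / 10 + (g$y - 8)^2 / 14 + (g$z - 12)^2 / 20))
  array(v, dims)
}
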