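#' Specification of the two-FOV synthetic phantom
#'
#' The phantom emulates a brain acquisition and a cervical-cord acquisition
#' of one subject taken in the same session: a single world-space scene --
#' an elongated "brainstem/cord" tube with anisotropic diffusion along its
#' axis plus an ellipsoidal isotropic "brain" blob -- sampled into two
#' partially overlapping axial stacks. The cord FOV is additionally related
#' to the brain FOV by a known in-plane rigid transform
#' (`theta_true`, `shift_true`) and a through-slice offset
#' (`z_offset_true`), which the stitcher must recover.
#'
#' The tube cross-section is an ellipse with an attached circular side lobe
#' (breaking rotational symmetry, as the midbrain outline does in vivo) and
#' widens linearly toward the superior end, so every axial slice has a
#' unique scale and the slice-matching problem is well posed.
#'
#' @param shape_brain,shape_cord voxel dimensions of the two FOVs.
#' @param spacing isotropic voxel size in mm.
#' @param theta_true in-plane rotation of the cord FOV (degrees).
#' @param shift_true in-plane translation of the cord FOV (voxels).
#' @param z_offset_true through-slice offset: cord slice `k + z_offset_true`
#'   samples the same world z as brain slice `k`.
#' @param snr Rician signal-to-noise ratio on the tube-interior b0 signal;
#'   `Inf` (default) is noise-free.
#' @param n_dirs number of `b = 1000` gradient directions per FOV.
#' @param seed RNG seed for noise (and nothing else).
#' @param tube_radius_mm major semi-axis of the tube cross-section at the
#'   inferior end (minor axis and lobe scale with it).
#' @param tube_length_mm length of the tube along z.
#' @return A `PhantomSpec` list.
#' @export
phantom_spec <- function(shape_brain = c(48L, 48L, 40L),
                         shape_cord = c(32L, 32L, 48L),
                         spacing = 2, theta_true = 4,
                         shift_true = c(3, -2), z_offset_true = 12L,
                         snr = Inf, n_dirs = 16L, seed = 17L,
                         tube_radius_mm = 8, tube_length_mm = 140) {
  stopifnot(z_offset_true >= 1, abs(theta_true) <= 12)
  if (shape_cord[3] - z_offset_true < 5)
    stop("spec implies an overlap shorter than 5 slices")
  structure(list(shape_brain = as.integer(shape_brain),
                 shape_cord = as.integer(shape_cord),
                 spacing = spacing, theta_true = theta_true,
                 shift_true = shift_true,
                 z_offset_true = as.integer(z_offset_true),
                 snr = snr, n_dirs = as.integer(n_dirs),
                 seed = as.integer(seed),
                 tube_radius_mm = tube_radius_mm,
                 tube_length_mm = tube_length_mm),
            class = "PhantomSpec")
}

# diffusion eigenvalues of the phantom tissue (mm^2/s)
PHANTOM_TUBE_EVALS <- c(1.7e-3, 0.3e-3, 0.3e-3)
PHANTOM_BLOB_ADC <- 0.7e-3
PHANTOM_BODY_ADC <- 1.0e-3

# roughly uniform directions on the sphere (deterministic Fibonacci spiral)
fibonacci_directions <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  g <- unname(rbind(r * cos(phi), r * sin(phi), z))
  g / rep(sqrt(colSums(g^2)), each = 3)
}

# Evaluate the phantom signal at world points (mm) for one gradient frame.
# Regions, inner to outer: tapered anisotropic tube (cord/brainstem, S0 = 1),
# isotropic brain blob (S0 = 0.8), isotropic surrounding tissue cylinder
# ("neck/head", S0 = 0.5) and background 0. The tissue compartment matters:
# FA-threshold masks only behave like their in vivo counterparts if
# partial-volume voxels at the cord edge mix anisotropic with isotropic
# signal and so lose anisotropy, rather than bordering on empty space.
phantom_signal <- function(x, y, z, b, g, spec) {
  zlo <- -10
  zhi <- zlo + spec$tube_length_mm
  s <- 1 + 0.9 * pmin(pmax((z - zlo) / (zhi - zlo), 0), 1)
  a_maj <- spec$tube_radius_mm
  a_min <- a_maj * 5 / 8
  r_lobe <- a_maj * 3 / 8
  u <- x / s
  v <- y / s
  in_tube <- ((u / a_maj)^2 + (v / a_min)^2 <= 1 |
                (u - 1.125 * a_maj)^2 + v^2 <= r_lobe^2) &
    z >= zlo & z <= zhi
  in_blob <- (x / 26)^2 + ((y - 8) / 20)^2 + ((z - 95) / 18)^2 <= 1
  in_body <- (x^2 + y^2 <= (3 * a_maj * s)^2) & z >= zlo & z <= zhi
  adc_tube <- PHANTOM_TUBE_EVALS[2] +
    (PHANTOM_TUBE_EVALS[1] - PHANTOM_TUBE_EVALS[2]) * g[3]^2
  sig <- numeric(length(x))
  sig[in_body] <- 0.5 * exp(-b * PHANTOM_BODY_ADC)
  sig[in_blob] <- 0.8 * exp(-b * PHANTOM_BLOB_ADC)
  sig[in_tube] <- exp(-b * adc_tube)
  sig
}

# sample one FOV of the scene; rigid = list(theta, shift) in-plane, in voxels
sample_fov <- function(shape, spacing, z0_mm, bvals, bvecs, spec,
                       rigid = NULL) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  g <- expand.grid(i = seq_len(nx) - 1, j = seq_len(ny) - 1)
  if (is.null(rigid)) {
    wx <- (g$i - cx) * spacing
    wy <- (g$j - cy) * spacing
  } else {
    th <- rigid$theta * pi / 180
    pi_ <- g$i - cx; pj <- g$j - cy
    ui <- cos(th) * pi_ - sin(th) * pj - rigid$shift[1]
    uj <- sin(th) * pi_ + cos(th) * pj - rigid$shift[2]
    wx <- ui * spacing
    wy <- uj * spacing
  }
  data <- array(0, c(nx, ny, nz, length(bvals)))
  for (k in seq_len(nz)) {
    wz <- z0_mm + (k - 1) * spacing
    for (q in seq_along(bvals))
      data[, , k, q] <- phantom_signal(wx, wy, rep(wz, length(wx)),
                                       bvals[q], bvecs[, q], spec)
  }
  affine <- diag(c(rep(spacing, 3), 1))
  affine[1:3, 4] <- c(-cx * spacing, -cy * spacing, z0_mm)
  gradient_volume(data, spacing = rep(spacing, 3), affine = affine,
                  bvals = bvals, bvecs = bvecs)
}

add_rician_noise <- function(gv, snr, seed) {
  if (!is.finite(snr)) return(gv)
  sigma <- 1 / snr                      # SNR defined on the tube-interior b0 (S0 = 1)
  gv$data <- with_local_seed(seed, {
    n1 <- array(rnorm(length(gv$data), 0, sigma), dim(gv$data))
    n2 <- array(rnorm(length(gv$data), 0, sigma), dim(gv$data))
    sqrt((gv$data + n1)^2 + n2^2)
  })
  gv
}

#' Generate a paired brain/cord phantom with known ground truth
#'
#' Samples the phantom scene into the two FOVs. Both are resampled views of
#' one world-space ground truth, so the stitching problem is well posed by
#' construction; the cord FOV is generated through the inverse of the true
#' in-plane transform, meaning [apply_transform()] with the returned truth
#' maps it exactly back onto the brain grid. Rician noise (magnitude-MRI
#' noise model) is applied at `spec$snr`; output is bit-reproducible from
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `brain` and `cord` ([gradient_volume()]s) and `truth`
#'   (a `RigidParams2D` holding `theta_true`, `shift_true`, `z_offset_true`).
#' @export
generate_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  bvals <- c(0, rep(1000, spec$n_dirs))
  bvecs <- cbind(c(0, 0, 0), fibonacci_directions(spec$n_dirs))
  z0_cord <- 0
  z0_brain <- spec$z_offset_true * spec$spacing
  brain <- sample_fov(spec$shape_brain, spec$spacing, z0_brain, bvals, bvecs,
                      spec)
  cord <- sample_fov(spec$shape_cord, spec$spacing, z0_cord, bvals, bvecs,
                     spec, rigid = list(theta = spec$theta_true,
                                        shift = spec$shift_true))
  brain <- add_rician_noise(brain, spec$snr, spec$seed)
  cord <- add_rician_noise(cord, spec$snr, spec$seed + 1L)
  truth <- rigid_params(theta = spec$theta_true, dx = spec$shift_true[1],
                        dy = spec$shift_true[2],
                        z_offset = spec$z_offset_true)
  list(brain = brain, cord = cord, truth = truth)
}

#' Small deterministic mask pairs for Dice unit tests
#'
#' Fixtures with known set sizes: a pair with `|A| = 4`, `|B| = 6`,
#' `|A n B| = 3` (Dice 0.6), an identical pair (Dice 1) and a disjoint pair
#' (Dice 0).
#'
#' @return A named list of mask pairs, each a list with `a`, `b` and the
#'   expected counts.
#' @export
generate_qc_masks <- function() {
  a <- matrix(FALSE, 8, 8); a[3:4, 3:4] <- TRUE              # |A| = 4
  b <- matrix(FALSE, 8, 8); b[3:5, 3:4] <- TRUE              # |B| = 6, |A n B| = 3
  b[4, 4] <- FALSE; b[6, 5] <- TRUE
  ident <- matrix(FALSE, 8, 8); ident[2:5, 2:3] <- TRUE
  d1 <- matrix(FALSE, 8, 8); d1[1:2, 1:2] <- TRUE
  d2 <- matrix(FALSE, 8, 8); d2[6:7, 6:7] <- TRUE
  list(partial = list(a = a, b = b, size_a = 4L, size_b = 6L, intersection = 3L),
       identical = list(a = ident, b = ident),
       disjoint = list(a = d1, b = d2))
}
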