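#' Upsample a volume by a factor of two
#'
#' Doubles every spatial dimension, halves the spacing and updates the
#' affine so that the world-space extent of the sampled field is preserved
#' (new voxel centres interleave the old ones). Interpolation is trilinear
#' by default; 4D volumes are upsampled frame by frame with the gradient
#' table untouched.
#'
#' @param vol a `ScalarVolume` or `GradientVolume`.
#' @param interpolation `"trilinear"` (default). Values outside the original
#'   grid are clamped to the nearest edge voxel.
#' @return A volume of the same class with doubled spatial dimensions.
#' @export
upsample_by_2 <- function(vol, interpolation = "trilinear") {
  interpolation <- match.arg(interpolation, "trilinear")
  is4d <- inherits(vol, "GradientVolume")
  d <- dim(vol$data)
  nd <- d[1:3] * 2L
  # new voxel j (1-based) sits at old 0-based coordinate (j - 1)/2 - 0.25
  coords <- as.matrix(expand.grid(x = (seq_len(nd[1]) - 1) / 2 - 0.25,
                                  y = (seq_len(nd[2]) - 1) / 2 - 0.25,
                                  z = (seq_len(nd[3]) - 1) / 2 - 0.25))
  up_frame <- function(frame) {
    array(.interp3(frame, coords, TRUE), dim = nd)
  }
  shift <- vol$affine[1:3, 1:3] %*% rep(-0.25, 3)
  affine <- vol$affine
  affine[1:3, 1:3] <- affine[1:3, 1:3] / 2
  affine[1:3, 4] <- affine[1:3, 4] + shift
  if (is4d) {
    q <- d[4]
    out <- array(0, c(nd, q))
    for (i in seq_len(q)) out[, , , i] <- up_frame(vol$data[, , , i])
    gradient_volume(out, spacing = vol$spacing / 2, affine = affine,
                    bvals = vol$bvals, bvecs = vol$bvecs)
  } else {
    scalar_volume(up_frame(vol$data), spacing = vol$spacing / 2, affine = affine)
  }
}

#' Intensity-threshold mask with speckle removal
#'
#' Binarizes a volume at `threshold` (inclusive) and keeps only connected
#' components whose size is at least `min_component_frac` of the largest
#' component, dropping isolated speckle. `threshold = "auto"` picks Otsu's
#' threshold on the intensity histogram.
#'
#' @param vol a `ScalarVolume`.
#' @param threshold numeric intensity cutoff, or `"auto"`.
#' @param min_component_frac minimum component size as a fraction of the
#'   largest component (default 0.01).
#' @return A `MaskVolume` with binary `data` and the `threshold_used`.
#' @export
make_mask <- function(vol, threshold = "auto", min_component_frac = 0.01) {
  stopifnot(inherits(vol, "ScalarVolume"))
  if (identical(threshold, "auto")) threshold <- otsu_threshold(vol$data)
  if (threshold > max(vol$data))
    stop(sprintf("threshold %g exceeds the volume maximum %g: mask would be empty",
                 threshold, max(vol$data)))
  m <- array(as.integer(vol$data >= threshold), dim = dim(vol$data))
  if (any(m > 0)) {
    lab <- .label_components(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_frac * max(sizes))
    m <- array(as.integer(lab %in% keep & lab > 0), dim = dim(m))
  }
  structure(list(data = m, threshold_used = threshold,
                 spacing = vol$spacing, affine = vol$affine),
            class = c("MaskVolume", "ScalarVolume"))
}

#' Nervous-system mask for registration
#'
#' The stitch correlates b0 images; surrounding tissue (neck muscle, fat)
#' shares no structure across the two FOVs and corrupts the similarity, so
#' it is masked out first, keeping only the brain/brainstem/cord. The
#' threshold is found hierarchically: Otsu separates tissue from
#' background, then a second Otsu on the within-tissue histogram separates
#' the bright nervous system from other tissue (the automated analogue of a
#' manually adjusted intensity threshold).
#'
#' @param vol a `ScalarVolume` (b0 image).
#' @param min_component_frac speckle-removal cutoff, as in [make_mask()].
#' @return A `MaskVolume`.
#' @export
nervous_system_mask <- function(vol, min_component_frac = 0.01) {
  stopifnot(inherits(vol, "ScalarVolume"))
  t1 <- otsu_threshold(vol$data)
  tissue <- vol$data[vol$data >= t1]
  t2 <- if (length(tissue) > 1 && diff(range(tissue)) > 0)
    otsu_threshold(tissue) else t1
  make_mask(vol, threshold = max(t1, t2),
            min_component_frac = min_component_frac)
}

# Otsu's threshold via EBImage on intensities rescaled to [0, 1]
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (v - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                       range = c(0, 1), levels = levels)
  rng[1] + t01 * diff(rng)
}

#' Mutual information between two volumes
#'
#' Histogram estimator of the mutual information (in bits) between the
#' intensities of two same-shaped volumes: a joint histogram over `bins x
#' bins` equal-width bins spanning the 1st-99th intensity percentile of each
#' image (outliers clamped into the end bins), from which
#' `MI = H(a) + H(b) - H(a, b)`.
#'
#' @param a,b `ScalarVolume`s (or plain arrays) of identical shape.
#' @param bins number of histogram bins per image (default 32).
#' @param mask optional logical/binary array restricting the voxels used.
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(a, b, bins = 32L, mask = NULL) {
  av <- if (inherits(a, "ScalarVolume")) a$data else a
  bv <- if (inherits(b, "ScalarVolume")) b$data else b
  if (!identical(dim(av), dim(bv))) stop("volumes must have identical shape")
  av <- as.numeric(av); bv <- as.numeric(bv)
  if (!is.null(mask)) {
    if (inherits(mask, "MaskVolume")) mask <- mask$data
    sel <- as.logical(mask)
    av <- av[sel]; bv <- bv[sel]
  }
  bin_index <- function(x) {
    lim <- quantile(x, c(0.01, 0.99), names = FALSE)
    if (diff(lim) == 0) return(rep(1L, length(x)))
    i <- floor((x - lim[1]) / diff(lim) * bins) + 1L
    pmin(pmax(i, 1L), as.integer(bins))
  }
  ia <- bin_index(av); ib <- bin_index(bv)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  max(ent(pa) + ent(pb) - ent(p), 0)
}

# MI objective for a 6-parameter rigid candidate (rotations deg, shifts vox)
.rigid_mi <- function(par, target, frame, bins) {
  moved <- .rigid3d_resample(frame, par[1:3], par[4:6])
  mutual_information(target, moved, bins = bins)
}

#' Register each diffusion-weighted frame to the mean b0
#'
#' Motion correction: every `b > 0` frame is rigidly aligned (6 parameters:
#' three rotations about the volume centre, three voxel translations) to the
#' mean b0 by maximizing mutual information. The search is a coarse
#' deterministic grid (integer translations within `±max_shift` voxels, then
#' per-axis rotations) followed by Nelder-Mead refinement. The rotation part
#' of each recovered transform is applied to that frame's gradient
#' direction.
#'
#' @param gv a [gradient_volume()] containing at least one b0 frame.
#' @param max_shift coarse translation search bound in voxels.
#' @param max_angle coarse rotation search bound in degrees.
#' @param bins histogram bins for the mutual-information metric.
#' @param rotate_bvecs apply recovered rotations to the gradient table.
#' @return A list with `volume` (the registered [gradient_volume()]) and
#'   `transforms` (per-frame `c(rx, ry, rz, dx, dy, dz)`; NA rows for b0
#'   frames).
#' @export
register_dwi_to_b0 <- function(gv, max_shift = 4L, max_angle = 4,
                               bins = 32L, rotate_bvecs = TRUE) {
  stopifnot(inherits(gv, "GradientVolume"))
  target <- extract_b0(gv)$data
  out <- gv$data
  bvecs <- gv$bvecs
  q <- dim(gv$data)[4]
  transforms <- matrix(NA_real_, q, 6,
                       dimnames = list(NULL, c("rx", "ry", "rz", "dx", "dy", "dz")))
  for (f in which(gv$bvals > 50)) {
    frame <- gv$data[, , , f]
    # coarse: integer translations at zero rotation
    best <- c(0, 0, 0, 0, 0, 0)
    best_mi <- .rigid_mi(best, target, frame, bins)
    for (dz in -max_shift:max_shift)
      for (dy in -max_shift:max_shift)
        for (dx in -max_shift:max_shift) {
          if (dx == 0 && dy == 0 && dz == 0) next
          shifted <- shift_array_int(frame, c(dx, dy, dz))
          mi <- mutual_information(target, shifted, bins = bins)
          if (mi > best_mi) { best_mi <- mi; best <- c(0, 0, 0, dx, dy, dz) }
        }
    # coarse: per-axis rotations about the current translation
    for (axis in 1:3)
      for (ang in setdiff(seq(-max_angle, max_angle, by = 2), 0)) {
        cand <- best; cand[axis] <- ang
        mi <- .rigid_mi(cand, target, frame, bins)
        if (mi > best_mi) { best_mi <- mi; best <- cand }
      }
    fit <- tryCatch(
      optim(best, function(p) -.rigid_mi(p, target, frame, bins),
            method = "Nelder-Mead",
            control = list(reltol = 1e-6, maxit = 400)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("frame %d: rigid optimizer failed; frame left untouched", f))
      next
    }
    par <- fit$par
    out[, , , f] <- .rigid3d_resample(frame, par[1:3], par[4:6])
    transforms[f, ] <- par
    if (rotate_bvecs)
      bvecs[, f] <- as.numeric(euler_rotation(par[1:3]) %*% bvecs[, f])
  }
  vol <- gradient_volume(out, spacing = gv$spacing, affine = gv$affine,
                         bvals = gv$bvals, bvecs = bvecs)
  list(volume = vol, transforms = transforms)
}

# integer-voxel shift with zero fill: out[x] = in[x + d]
shift_array_int <- function(a, d) {
  dm <- dim(a)
  out <- array(0, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    s <- seq_len(dm[k])
    src_k <- s + d[k]
    ok <- src_k >= 1 & src_k <= dm[k]
    src[[k]] <- src_k[ok]; dst[[k]] <- s[ok]
    if (!any(ok)) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# R = Rz(rz) Ry(ry) Rx(rx), angles in degrees (content rotation)
euler_rotation <- function(rot_deg) {
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Hook for an external susceptibility/eddy-current correction tool
#'
#' Distortion correction (FSL `topup`/`eddy`) is invoked as an external
#' command, never reimplemented. The command template substitutes `{in}` and
#' `{out}` placeholders; `mode = "passthrough"` returns the input unchanged
#' so the pipeline stays testable end to end without the tool.
#'
#' @param gv a [gradient_volume()].
#' @param tool_spec list with `cmd` (template string), `mode` (`"run"` or
#'   `"passthrough"`) and optionally `config_key` used in error messages.
#' @param work_dir scratch directory for the tool's input/output files.
#' @return The corrected (or passed-through) [gradient_volume()].
#' @export
run_external_distortion_correction <- function(gv, tool_spec,
                                               work_dir = tempdir()) {
  stopifnot(inherits(gv, "GradientVolume"))
  mode <- tool_spec$mode %||% "run"
  if (identical(mode, "passthrough")) return(gv)
  key <- tool_spec$config_key %||% "preprocess.topup_cmd"
  if (is.null(tool_spec$cmd))
    stop(sprintf("no command configured under '%s'", key))
  exe <- strsplit(trimws(tool_spec$cmd), "\\s+")[[1]][1]
  if (Sys.which(exe) == "")
    stop(sprintf("external tool '%s' not found on PATH; check config key '%s'",
                 exe, key))
  in_path <- file.path(work_dir, "distcorr_in.nii.gz")
  out_path <- file.path(work_dir, "distcorr_out.nii.gz")
  write_volume(gv, in_path)
  argv <- build_tool_argv(tool_spec$cmd, in_path, out_path)
  status <- system2(argv[1], argv[-1])
  if (status != 0)
    stop(sprintf("external tool '%s' exited with status %d", exe, status))
  stem <- sub("\\.nii(\\.gz)?$", "", in_path)
  read_gradient_volume(out_path, paste0(stem, ".bval"), paste0(stem, ".bvec"))
}

# substitute {in}/{out} placeholders and split into argv
build_tool_argv <- function(template, in_path, out_path) {
  cmd <- gsub("{in}", in_path, template, fixed = TRUE)
  cmd <- gsub("{out}", out_path, cmd, fixed = TRUE)
  strsplit(trimws(cmd), "\\s+")[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
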