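#' Select the reference slice for overlap localization
#'
#' The overlap search correlates one distinctive axial brain slice (in
#' practice the midbrain, whose "Mickey Mouse" outline is easy to match)
#' against every slice of the cord volume. `mode = "manual"` takes a given z
#' index; `mode = "auto"` picks, within the inferior quartile of the brain
#' volume (where the brainstem sits), the slice with the largest intensity
#' variance -- a proxy for a distinctive shape.
#'
#' @param brain_b0 a `ScalarVolume` (mean b0 of the brain FOV).
#' @param mode `"auto"` or `"manual"`.
#' @param z_index slice index (1-based) for manual mode.
#' @param mask optional `MaskVolume`; auto mode then scores the variance over
#'   in-mask pixels only.
#' @return A `ReferenceSlice`: list with `data` (2D), `z_index_in_brain`,
#'   `provenance`.
#' @export
select_reference_slice <- function(brain_b0, mode = c("auto", "manual"),
                                   z_index = NULL, mask = NULL) {
  mode <- match.arg(mode)
  nz <- dim(brain_b0$data)[3]
  if (mode == "manual") {
    if (is.null(z_index) || z_index < 1 || z_index > nz)
      stop(sprintf("z_index %s out of range [1, %d]",
                   deparse(substitute(z_index)), nz))
    z <- as.integer(z_index)
  } else {
    zs <- seq_len(ceiling(nz / 4))         # inferior quartile
    score <- vapply(zs, function(k) {
      s <- brain_b0$data[, , k]
      if (!is.null(mask)) {
        inm <- mask$data[, , k] > 0
        if (sum(inm) < 2) return(-Inf)
        s <- s[inm]
      }
      var(as.numeric(s))
    }, numeric(1))
    if (all(!is.finite(score)))
      stop("no slice in the inferior quartile has enough in-mask pixels")
    z <- zs[which.max(score)]
  }
  slice <- brain_b0$data[, , z]
  if (var(as.numeric(slice)) == 0)
    stop("reference slice is constant; choose a structured slice")
  structure(list(data = slice, z_index_in_brain = z, provenance = mode),
            class = "ReferenceSlice")
}

# 3x3 binomial smoothing (replicated edges). Correlation scoring low-passes
# both slices first so that candidate transforms are compared on structure
# rather than on interpolation sharpness: resampling at theta != 0 blurs the
# moving slice, and without smoothing the unblurred theta = 0 candidate is
# systematically favoured on sharp-edged images.
smooth_slice <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m <- (m[c(1, seq_len(n1 - 1)), , drop = FALSE] + 2 * m +
          m[c(seq_len(n1 - 1) + 1, n1), , drop = FALSE]) / 4
  (m[, c(1, seq_len(n2 - 1)), drop = FALSE] + 2 * m +
     m[, c(seq_len(n2 - 1) + 1, n2), drop = FALSE]) / 4
}

# Centre-pad or centre-crop a 2D slice (or each slice of a 3D array) to a
# target in-plane shape, assuming equal spacing and aligned grid centres.
match_inplane <- function(a, target_shape) {
  d <- dim(a)
  ns <- target_shape[1:2]
  if (identical(as.integer(d[1:2]), as.integer(ns))) return(a)
  pad1 <- floor((ns[1] - d[1]) / 2)
  pad2 <- floor((ns[2] - d[2]) / 2)
  idx1 <- seq_len(ns[1]) - pad1
  idx2 <- seq_len(ns[2]) - pad2
  ok1 <- idx1 >= 1 & idx1 <= d[1]
  ok2 <- idx2 >= 1 & idx2 <= d[2]
  if (length(d) == 2) {
    out <- matrix(0, ns[1], ns[2])
    out[ok1, ok2] <- a[idx1[ok1], idx2[ok2]]
  } else {
    out <- array(0, c(ns, d[3]))
    out[ok1, ok2, ] <- a[idx1[ok1], idx2[ok2], ]
  }
  out
}

#' Slice-wise cross-correlation profile
#'
#' Scores the reference slice `A` against every axial slice `B(., ., z)` of
#' the moving volume. `normalize = FALSE` computes the raw double sum
#' `CC(z) = sum_x sum_y A(x, y) * B(x, y, z)`; the default normalized mode
#' computes the zero-mean, unit-norm (Pearson) correlation, which is robust
#' to the different intensity scales of the two FOVs. The moving volume is
#' centre-padded/cropped to the reference grid first. Ties at the maximum
#' are broken toward the superior-most slice.
#'
#' @param ref a `ReferenceSlice` (or plain 2D matrix).
#' @param moving a `ScalarVolume` (or 3D array).
#' @param normalize logical; default `TRUE`.
#' @param mask optional 2D logical mask on the reference grid restricting the
#'   scored pixels.
#' @return A `CorrelationProfile`: list with per-slice `scores`, the argmax
#'   `z_best`, and a `degenerate` flag.
#' @export
correlation_profile <- function(ref, moving, normalize = TRUE, mask = NULL) {
  A <- if (inherits(ref, "ReferenceSlice")) ref$data else ref
  B <- if (inherits(moving, "ScalarVolume")) moving$data else moving
  B <- match_inplane(B, dim(A))
  sel <- if (is.null(mask)) rep(TRUE, length(A)) else as.logical(mask)
  a <- as.numeric(A)[sel]
  degenerate <- var(a) == 0
  if (degenerate)
    warning("degenerate reference: constant slice, all correlation scores set to 0")
  nz <- dim(B)[3]
  scores <- vapply(seq_len(nz), function(z) {
    b <- as.numeric(B[, , z])[sel]
    if (degenerate) return(0)
    if (!normalize) return(sum(a * b))
    if (var(b) == 0) return(0)
    suppressWarnings(stats::cor(a, b))
  }, numeric(1))
  scores[!is.finite(scores)] <- 0
  z_best <- max(which(scores >= max(scores) - 1e-12))
  structure(list(scores = scores, z_best = z_best, normalize = normalize,
                 degenerate = degenerate),
            class = "CorrelationProfile")
}

#' Refine the in-plane rigid transform for one slice pair
#'
#' Maximizes `CC(theta, dx, dy) = sum_x sum_y A(x, y) B'(x + dx, y + dy,
#' theta)` where `B'` is the moving slice rotated by `theta` about its
#' centre (bilinear, zero fill). Rotations are searched over a small grid --
#' by default the seven evenly spaced angles `{-12, -8, -4, 0, 4, 8, 12}`
#' degrees -- and translations exhaustively over integer shifts within
#' `±max_shift` voxels. Ties are broken toward the smallest `|theta|`, then
#' the smallest `|dx| + |dy|`, then lexicographically; the search is fully
#' deterministic.
#'
#' @param ref a `ReferenceSlice` or 2D matrix.
#' @param moving_slice 2D matrix on (or padded to) the reference grid.
#' @param angles rotation grid in degrees.
#' @param max_shift translation bound in voxels (default 10).
#' @param normalize use Pearson correlation (default) instead of the raw sum.
#' @param mask optional 2D logical mask restricting the scored pixels.
#' @param presmooth low-pass both slices (3x3 binomial) before scoring.
#' @param center centre of the translation search window, for local
#'   refinement around a prior estimate (default the origin).
#' @param shift_step stride of the translation grid (1 = exhaustive).
#' @return A `RigidParams2D`: list with `theta` (deg), `dx`, `dy` (voxels),
#'   `score`, `angle_scores` and `z_offset = NA`.
#' @export
refine_rigid <- function(ref, moving_slice, angles = stitch_angle_grid(),
                         max_shift = 10L, normalize = TRUE, mask = NULL,
                         presmooth = FALSE, center = c(0L, 0L),
                         shift_step = 1L) {
  A <- if (inherits(ref, "ReferenceSlice")) ref$data else ref
  B <- match_inplane(moving_slice, dim(A))
  if (var(as.numeric(A)) == 0 || var(as.numeric(B)) == 0)
    stop("degenerate input: constant slice")
  if (isTRUE(presmooth)) { A <- smooth_slice(A); B <- smooth_slice(B) }
  m <- if (is.null(mask)) NULL else matrix(as.logical(mask), nrow(A), ncol(A))
  res <- .cc_search(A, B, as.numeric(angles), as.integer(max_shift),
                    isTRUE(normalize), m, as.integer(shift_step),
                    as.integer(center[1]), as.integer(center[2]))
  rigid_params(theta = res$theta, dx = res$dx, dy = res$dy,
               z_offset = NA_integer_, score = res$score,
               angle_scores = setNames(res$angle_scores, angles))
}

#' Seven-angle rotation grid spanning -12 to 12 degrees
#' @param n number of angles (default 7).
#' @param limit half-range in degrees (default 12).
#' @return Numeric vector of evenly spaced angles.
#' @export
stitch_angle_grid <- function(n = 7L, limit = 12) seq(-limit, limit, length.out = n)

#' @rdname refine_rigid
#' @param theta,dx,dy,z_offset,score,angle_scores fields of the transform.
#' @export
rigid_params <- function(theta, dx, dy, z_offset = NA_integer_, score = NA_real_,
                         angle_scores = NULL) {
  structure(list(theta = theta, dx = dx, dy = dy,
                 z_offset = z_offset, score = score,
                 angle_scores = angle_scores),
            class = "RigidParams2D")
}

#' @export
print.RigidParams2D <- function(x, ...) {
  cat(sprintf("RigidParams2D: theta = %g deg, shift = (%g, %g) vox, z_offset = %s, score = %s\n",
              x$theta, x$dx, x$dy, format(x$z_offset), format(x$score)))
  invisible(x)
}

#' Estimate the global brain-cord stitch transform
#'
#' Two stages. First the through-slice offset: the reference slice is
#' correlated against every cord slice ([correlation_profile()]) and the
#' peak gives `z_offset` such that cord slice `k + z_offset` corresponds to
#' brain slice `k`. Second the in-plane transform: [refine_rigid()] runs on
#' every overlapping slice pair, and the returned global `(theta, dx, dy)`
#' is the coordinate-wise median over the pairs whose score exceeds the 25th
#' percentile (a robust aggregate; per-slice parameters are retained for
#' QC).
#'
#' @param brain_b0,cord_b0 `ScalarVolume`s (mean b0 of each FOV), already
#'   preprocessed.
#' @param brain_mask,cord_mask optional nervous-system masks
#'   (`MaskVolume` or binary array). When given, each b0 is zeroed outside
#'   its mask before any correlation, the in vivo step that keeps
#'   surrounding tissue from corrupting the similarity (see
#'   [nervous_system_mask()]).
#' @param ref optional `ReferenceSlice`; default auto-selected from
#'   `brain_b0`.
#' @param angles,max_shift,normalize passed to [refine_rigid()].
#' @param min_overlap_slices fail if fewer overlapping slices than this.
#' @param score_quantile per-slice score cutoff quantile for the aggregate.
#' @param warn_score warn if the best correlation falls below this.
#' @return A `RigidParams2D` with `z_offset` set, plus attributes
#'   `per_slice` (data frame of per-pair refinements) and `profile`.
#' @export
estimate_stitch_transform <- function(brain_b0, cord_b0, brain_mask = NULL,
                                      cord_mask = NULL, ref = NULL,
                                      angles = stitch_angle_grid(),
                                      max_shift = 10L, normalize = TRUE,
                                      min_overlap_slices = 5L,
                                      score_quantile = 0.25,
                                      warn_score = 0.2) {
  mask_data <- function(vol, mask) {
    if (is.null(mask)) return(vol)
    m <- if (inherits(mask, "MaskVolume")) mask$data else mask
    vol$data <- vol$data * (m > 0)
    vol
  }
  brain_b0 <- mask_data(brain_b0, brain_mask)
  cord_b0 <- mask_data(cord_b0, cord_mask)
  if (is.null(ref)) ref <- select_reference_slice(brain_b0, "auto")
  nz_b <- dim(brain_b0$data)[3]
  nz_c <- dim(cord_b0$data)[3]
  cord_matched <- match_inplane(cord_b0$data, dim(brain_b0$data))
  # Correlations are only meaningful where the (usually smaller) moving FOV
  # actually acquired data: scoring brain-only pixels against the padding
  # would bias every stage, so all stages share the moving-FOV footprint.
  foot <- match_inplane(matrix(1, dim(cord_b0$data)[1], dim(cord_b0$data)[2]),
                        dim(brain_b0$data)) >= 0.5
  # Stage 1 -- slice localization must not be fooled by the unknown in-plane
  # transform: each cord slice is scored by its best correlation over the
  # rotation grid and a stride-2 translation grid, a transform-invariant
  # version of the plain profile (exposed separately as
  # correlation_profile()). The coarse stride suffices here: stage 2 fixes
  # the offset and stage 3 re-estimates the transform exhaustively.
  inv <- lapply(seq_len(nz_c), function(z) {
    B <- cord_matched[, , z]
    if (var(as.numeric(B)) == 0) return(list(score = -Inf))
    coarse <- .cc_search(ref$data, B, as.numeric(angles),
                         as.integer(max_shift), isTRUE(normalize), foot,
                         2L, 0L, 0L)
    # the stride-2 grid lands within one voxel of the optimum; a +/-1
    # refinement around it restores the exact per-slice peak
    .cc_search(ref$data, B, as.numeric(angles), 1L, isTRUE(normalize), foot,
               1L, coarse$dx, coarse$dy)
  })
  inv_scores <- vapply(inv, `[[`, numeric(1), "score")
  if (!is.finite(max(inv_scores)) || max(inv_scores) <= 0)
    stop("stitch failure: no correlation peak between the two volumes")
  z_peak <- max(which(inv_scores >= max(inv_scores) - 1e-12))
  prof <- structure(list(scores = inv_scores, z_best = z_peak,
                         normalize = normalize, degenerate = FALSE),
                    class = "CorrelationProfile")
  # Stage 2 -- the single-slice peak is refined by whole-overlap consensus:
  # the provisional transform from the peak slice is applied to the cord b0
  # once, and candidate offsets near the peak are scored by the mean
  # slice-wise correlation over all overlapping pairs; the offset using the
  # full stack of matched pairs is far less sensitive to interpolation
  # noise than any single slice.
  cand0 <- inv[[z_peak]]
  prelim <- rigid_params(cand0$theta, cand0$dx, cand0$dy)
  aligned_b0 <- apply_transform(
    scalar_volume(cord_b0$data, cord_b0$spacing, cord_b0$affine),
    prelim, target_shape = dim(brain_b0$data)[1:2])$data
  foot_aligned <- .rigid2d_resample(foot + 0, prelim$theta, prelim$dx,
                                    prelim$dy) >= 0.5
  z0 <- z_peak - ref$z_index_in_brain
  mean_overlap_score <- function(dz) {
    kb <- seq_len(nz_b)
    kc <- kb + dz
    ok <- kc >= 1 & kc <= nz_c
    if (sum(ok) < min_overlap_slices) return(-Inf)
    s <- vapply(kb[ok], function(k) {
      a <- as.numeric(brain_b0$data[, , k])[foot_aligned]
      b <- as.numeric(aligned_b0[, , k + dz])[foot_aligned]
      if (var(a) == 0 || var(b) == 0) return(NA_real_)
      suppressWarnings(stats::cor(a, b))
    }, numeric(1))
    s <- s[is.finite(s)]
    if (!length(s)) return(-Inf)
    mean(s)
  }
  dz_cand <- (z0 - 5):(z0 + 5)
  dz_scores <- vapply(dz_cand, mean_overlap_score, numeric(1))
  if (!any(is.finite(dz_scores)))
    stop(sprintf("stitch failure: overlap shorter than min_overlap_slices = %d",
                 min_overlap_slices))
  top <- which(dz_scores >= max(dz_scores) - 1e-12)
  z_offset <- dz_cand[top[which.min(abs(dz_cand[top] - z0))]]
  prof$z_best <- z_offset + ref$z_index_in_brain
  kb <- seq_len(nz_b)
  kc <- kb + z_offset
  ok <- kc >= 1 & kc <= nz_c
  if (sum(ok) < min_overlap_slices)
    stop(sprintf("stitch failure: overlap of %d slice(s) is shorter than min_overlap_slices = %d",
                 sum(ok), min_overlap_slices))
  # Stage 3 -- exhaustive per-slice refinement within a window centred on
  # the provisional transform (the translation is already known to a voxel
  # or two; the window keeps the search exact where it matters).
  per <- lapply(kb[ok], function(k) {
    A <- brain_b0$data[, , k]
    B <- cord_matched[, , k + z_offset]
    if (var(as.numeric(A)) == 0 || var(as.numeric(B)) == 0) return(NULL)
    p <- refine_rigid(A, B, angles = angles,
                      max_shift = min(as.integer(max_shift), 5L),
                      center = round(c(prelim$dx, prelim$dy)),
                      normalize = normalize, mask = foot)
    data.frame(z_brain = k, z_cord = k + z_offset, theta = p$theta,
               dx = p$dx, dy = p$dy, score = p$score)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || !nrow(per))
    stop("stitch failure: no structured overlapping slice pairs")
  cut <- quantile(per$score, score_quantile, names = FALSE)
  top <- per[per$score >= cut, , drop = FALSE]
  out <- rigid_params(theta = median(top$theta), dx = median(top$dx),
                      dy = median(top$dy), z_offset = as.integer(z_offset),
                      score = max(per$score))
  if (out$score < warn_score)
    warning(sprintf("best slice correlation %.3f below warn threshold %.3f; stitch may be unreliable",
                    out$score, warn_score))
  attr(out, "per_slice") <- per
  attr(out, "profile") <- prof
  out
}

#' Apply an in-plane rigid transform to a diffusion volume
#'
#' Resamples every frame slice by slice under `(theta, dx, dy)` (rotation
#' about the in-plane centre, then translation; bilinear with zero fill) so
#' that the moving volume lands on the reference grid. Each gradient
#' direction is premultiplied by the 3D embedding of the rotation about the
#' z axis, keeping the gradient table consistent with the resampled frames
#' (disable with `rotate_bvecs = FALSE`).
#'
#' @param gv a `GradientVolume` or `ScalarVolume`.
#' @param p a `RigidParams2D`.
#' @param rotate_bvecs logical, default `TRUE`.
#' @param target_shape optional in-plane shape to centre-pad to before
#'   resampling (used to move the cord FOV onto the brain grid).
#' @return The transformed volume, same class as `gv`.
#' @export
apply_transform <- function(gv, p, rotate_bvecs = TRUE, target_shape = NULL) {
  is4d <- inherits(gv, "GradientVolume")
  d <- dim(gv$data)
  frames <- if (is4d) d[4] else 1L
  arr <- gv$data
  if (!is.null(target_shape)) {
    tmp <- if (is4d) array(0, c(target_shape[1:2], d[3], frames)) else
      array(0, c(target_shape[1:2], d[3]))
    for (f in seq_len(frames)) {
      fr <- if (is4d) arr[, , , f] else arr
      m <- match_inplane(fr, target_shape)
      if (is4d) tmp[, , , f] <- m else tmp <- m
    }
    arr <- tmp
    d <- dim(arr)
  }
  identity_tf <- p$theta == 0 && p$dx == as.integer(p$dx) &&
    p$dy == as.integer(p$dy)
  out <- array(0, d)
  for (f in seq_len(frames)) {
    for (k in seq_len(d[3])) {
      sl <- if (is4d) arr[, , k, f] else arr[, , k]
      res <- if (identity_tf) shift_slice_int(sl, c(p$dx, p$dy)) else
        .rigid2d_resample(sl, p$theta, p$dx, p$dy)
      if (is4d) out[, , k, f] <- res else out[, , k] <- res
    }
  }
  if (!is4d) return(scalar_volume(out, spacing = gv$spacing, affine = gv$affine))
  bvecs <- gv$bvecs
  if (rotate_bvecs && p$theta != 0) {
    Rz <- euler_rotation(c(0, 0, p$theta))
    bvecs <- Rz %*% bvecs
  }
  gradient_volume(out, spacing = gv$spacing, affine = gv$affine,
                  bvals = gv$bvals, bvecs = bvecs)
}

# exact integer-shift resample for the theta = 0 fast path: out[x] = in[x + d]
shift_slice_int <- function(sl, d) {
  dm <- dim(sl)
  out <- matrix(0, dm[1], dm[2])
  i <- seq_len(dm[1]) + d[1]
  j <- seq_len(dm[2]) + d[2]
  ok1 <- i >= 1 & i <= dm[1]
  ok2 <- j >= 1 & j <= dm[2]
  out[ok1, ok2] <- sl[i[ok1], j[ok2]]
  out
}

#' Fuse two aligned diffusion volumes into one stitched volume
#'
#' Builds the fused stack on the union of the two z ranges: fused slice `f`
#' holds cord slice `f` and brain slice `f - z_offset` where those exist.
#' Outside the overlap, slices are copied verbatim from their only source.
#' Inside the overlap the b0 images are combined by linear feathering along
#' z (brain weight ramps 0 to 1 going superior, cord the reverse);
#' `blend = "brain_priority"` / `"cord_priority"` take one source verbatim.
#' Because the two acquisitions may use different gradient schemes, the
#' diffusion-weighted frames are never mixed: the fused volume stores the
#' blended b0 plus both DWI blocks with a merged gradient table, and a
#' frame-coverage matrix records which frames are valid on which slices
#' (consumed by [fit_tensor()]).
#'
#' @param brain a `GradientVolume` on the fused in-plane grid.
#' @param cord_aligned the cord `GradientVolume` after [apply_transform()],
#'   centre-padded to the same in-plane grid.
#' @param z_offset integer: cord slice `k_b + z_offset` matches brain slice
#'   `k_b`.
#' @param blend `"feather"` (default), `"brain_priority"` or
#'   `"cord_priority"`.
#' @param transform optional `RigidParams2D` recorded in the result.
#' @return A `StitchedVolume` (also a `GradientVolume`) with fields
#'   `overlap_range` (fused z indices), `source_labels`, `frame_valid`
#'   (q x nz logical) and `transform`.
#' @export
fuse <- function(brain, cord_aligned, z_offset,
                 blend = c("feather", "brain_priority", "cord_priority"),
                 transform = NULL) {
  blend <- match.arg(blend)
  stopifnot(inherits(brain, "GradientVolume"),
            inherits(cord_aligned, "GradientVolume"))
  db <- dim(brain$data); dc <- dim(cord_aligned$data)
  if (!identical(db[1:2], dc[1:2]))
    stop("volumes must share an in-plane grid; apply_transform with target_shape first")
  z_offset <- as.integer(z_offset)
  nz <- max(dc[3], db[3] + z_offset)
  b0b <- extract_b0(brain)$data
  b0c <- extract_b0(cord_aligned)$data
  has_brain <- (seq_len(nz) - z_offset) >= 1 & (seq_len(nz) - z_offset) <= db[3]
  has_cord <- seq_len(nz) <= dc[3]
  ov <- which(has_brain & has_cord)
  if (!length(ov)) stop("empty overlap: z_offset places the volumes apart")
  w_brain <- rep(0, nz); w_brain[has_brain & !has_cord] <- 1
  if (blend == "feather") {
    w_brain[ov] <- if (length(ov) == 1) 0.5 else
      seq(0, 1, length.out = length(ov))
  } else if (blend == "brain_priority") w_brain[ov] <- 1
  # cord_priority leaves w_brain[ov] at 0
  qb <- which(brain$bvals > 50)
  qc <- which(cord_aligned$bvals > 50)
  nq <- 1L + length(qb) + length(qc)
  fused <- array(0, c(db[1:2], nz, nq))
  frame_valid <- matrix(FALSE, nq, nz)
  for (f in seq_len(nz)) {
    wb <- w_brain[f]
    kb <- f - z_offset
    b0 <- 0
    if (has_brain[f]) b0 <- b0 + wb * b0b[, , kb]
    if (has_cord[f]) b0 <- b0 + (1 - wb) * b0c[, , f]
    fused[, , f, 1] <- b0
    if (has_brain[f]) {
      fused[, , f, 1 + seq_along(qb)] <- brain$data[, , kb, qb]
      frame_valid[1 + seq_along(qb), f] <- TRUE
    }
    if (has_cord[f]) {
      fused[, , f, 1 + length(qb) + seq_along(qc)] <- cord_aligned$data[, , f, qc]
      frame_valid[1 + length(qb) + seq_along(qc), f] <- TRUE
    }
  }
  frame_valid[1, ] <- has_brain | has_cord
  labels <- ifelse(has_brain & has_cord, "blended",
                   ifelse(has_brain, "brain", "cord"))
  if (blend == "brain_priority") labels[ov] <- "brain"
  if (blend == "cord_priority") labels[ov] <- "cord"
  affine <- cord_aligned$affine        # fused grid starts at the cord's inferior end
  affine[1:3, 4] <- brain$affine[1:3, 4] -
    brain$affine[1:3, 1:3] %*% c(0, 0, z_offset)
  out <- gradient_volume(fused, spacing = brain$spacing, affine = affine,
                         bvals = c(0, brain$bvals[qb], cord_aligned$bvals[qc]),
                         bvecs = cbind(0, brain$bvecs[, qb, drop = FALSE],
                                       cord_aligned$bvecs[, qc, drop = FALSE]))
  out$overlap_range <- range(ov)
  out$source_labels <- labels
  out$frame_valid <- frame_valid
  out$transform <- transform
  class(out) <- c("StitchedVolume", class(out))
  out
}

#' Stitch two diffusion FOVs end to end
#'
#' Convenience wrapper: estimates the stitch transform from the two b0
#' images, applies it to the cord diffusion volume and fuses. Returns the
#' `StitchedVolume` with the transform attached.
#'
#' @param brain,cord `GradientVolume`s (brain and cord FOVs).
#' @param ref optional `ReferenceSlice`.
#' @param blend passed to [fuse()].
#' @param ... passed to [estimate_stitch_transform()].
#' @return A `StitchedVolume`.
#' @export
stitch_volumes <- function(brain, cord, ref = NULL, blend = "feather",
                           brain_mask = NULL, cord_mask = NULL, ...) {
  p <- estimate_stitch_transform(extract_b0(brain), extract_b0(cord),
                                 brain_mask = brain_mask,
                                 cord_mask = cord_mask, ref = ref, ...)
  cord_aligned <- apply_transform(cord, p, target_shape = dim(brain$data)[1:2])
  fuse(brain, cord_aligned, p$z_offset, blend = blend, transform = p)
}
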