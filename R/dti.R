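#' Fit diffusion tensors and derive FA and principal directions
#'
#' Per-voxel weighted log-linear least-squares fit of the single-tensor
#' signal model `S(b, g) = S0 * exp(-b * g' D g)`: an ordinary
#' least-squares solve of `log S` against the diffusion design matrix,
#' followed by one reweighting pass with weights `S^2` (the standard
#' variance stabilization for log-transformed magnitude data). Eigenvalues
#' are clipped at zero before fractional anisotropy,
#' `FA = sqrt(3/2 * sum((lambda - mean)^2) / sum(lambda^2))`, and the
#' principal eigenvector's sign is fixed deterministically. Voxels with
#' non-positive signal, non-finite values or a failed solve are flagged
#' invalid.
#'
#' For a stitched volume whose frames cover different slice ranges (the two
#' FOVs keep separate DWI blocks), `frame_valid` restricts the fit in each
#' slice to the frames acquired there; [fit_tensor()] picks it up
#' automatically from a `StitchedVolume`.
#'
#' @param gv a [gradient_volume()] with at least 6 non-collinear `b > 0`
#'   directions and one b0.
#' @param mask optional `MaskVolume` (or logical/binary 3D array); voxels
#'   outside are not fitted.
#' @param frame_valid optional q x nz logical matrix of per-slice frame
#'   coverage.
#' @param weighted use the reweighted pass (default `TRUE`).
#' @return A `TensorField`: list with `fa`, `v1` (4D, last dim 3),
#'   `tensors` (4D, last dim 6: xx, yy, zz, xy, xz, yz), `evals`,
#'   `valid_mask`, plus spacing/affine.
#' @export
fit_tensor <- function(gv, mask = NULL, frame_valid = NULL, weighted = TRUE) {
  stopifnot(inherits(gv, "GradientVolume"))
  if (is.null(frame_valid) && !is.null(gv$frame_valid))
    frame_valid <- gv$frame_valid
  d <- dim(gv$data)
  nvox <- prod(d[1:3])
  msk <- if (is.null(mask)) rep(TRUE, nvox) else {
    m <- if (inherits(mask, "MaskVolume")) mask$data else mask
    as.logical(m)
  }
  fa <- numeric(nvox)
  valid <- logical(nvox)
  v1 <- matrix(0, nvox, 3)
  tensors <- matrix(0, nvox, 6)
  evals <- matrix(0, nvox, 3)
  # group slices by identical frame coverage so each group is one batched fit
  patterns <- if (is.null(frame_valid)) rep(1L, d[3]) else
    match(apply(frame_valid, 2, paste, collapse = ""),
          unique(apply(frame_valid, 2, paste, collapse = "")))
  zidx <- rep(seq_len(d[3]), each = prod(d[1:2]))
  Sall <- matrix(aperm(gv$data, c(4, 1, 2, 3)), d[4], nvox)
  for (pat in unique(patterns)) {
    frames <- if (is.null(frame_valid)) seq_len(d[4]) else
      which(frame_valid[, match(pat, patterns)])
    bv <- gv$bvals[frames]
    if (sum(bv > 0) < 6 || !any(bv == 0)) {
      check_directions(gv$bvals, gv$bvecs, error = is.null(frame_valid))
      next
    }
    check_directions(bv, gv$bvecs[, frames, drop = FALSE])
    vox <- which(msk & zidx %in% which(patterns == pat))
    if (!length(vox)) next
    S <- Sall[frames, vox, drop = FALSE]
    fit <- .dti_fit(S, bv, gv$bvecs[, frames, drop = FALSE], weighted)
    fa[vox] <- fit$fa
    v1[vox, ] <- t(fit$v1)
    tensors[vox, ] <- t(fit$tensors)
    evals[vox, ] <- t(fit$evals)
    valid[vox] <- fit$valid
  }
  structure(list(fa = array(fa, d[1:3]),
                 v1 = array(v1, c(d[1:3], 3)),
                 tensors = array(tensors, c(d[1:3], 6)),
                 evals = array(evals, c(d[1:3], 3)),
                 valid_mask = array(valid, d[1:3]),
                 spacing = gv$spacing, affine = gv$affine),
            class = "TensorField")
}

check_directions <- function(bvals, bvecs, error = TRUE) {
  dirs <- bvecs[, bvals > 0, drop = FALSE]
  ok <- ncol(dirs) >= 6 && qr(crossprod(design_cols(dirs)))$rank == 6
  if (!ok && error)
    stop("tensor fit needs at least 6 non-collinear b > 0 directions and a b0")
  invisible(ok)
}

design_cols <- function(g) {
  t(rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
          2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ]))
}

#' Fractional anisotropy of a set of eigenvalues
#'
#' `FA = sqrt(3/2 * sum((lambda - mean(lambda))^2) / sum(lambda^2))`,
#' ranging from 0 (isotropic) to 1 (a single nonzero eigenvalue). Negative
#' eigenvalues are clipped at zero first.
#'
#' @param evals numeric length-3 eigenvalues, or an n x 3 matrix.
#' @return FA value(s) in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(evals) {
  ev <- if (is.matrix(evals)) evals else matrix(evals, 1)
  ev <- pmax(ev, 0)
  m <- rowMeans(ev)
  denom <- rowSums(ev^2)
  fa <- sqrt(1.5 * rowSums((ev - m)^2) / ifelse(denom > 0, denom, 1))
  fa[denom == 0] <- 0
  if (is.matrix(evals)) fa else fa[1]
}

#' Forward-simulate diffusion signal from a tensor
#'
#' @param D 3x3 symmetric diffusion tensor (mm^2/s).
#' @param bvals,bvecs gradient table.
#' @param s0 non-diffusion-weighted signal.
#' @return Numeric vector of signals, one per frame.
#' @export
tensor_signal <- function(D, bvals, bvecs, s0 = 1) {
  adc <- colSums(bvecs * (D %*% bvecs))
  s0 * exp(-bvals * adc)
}

#' Adaptive FA threshold for tracking
#'
#' A compromise between anatomical detail and noise: Otsu's threshold on
#' the in-mask FA histogram, clamped to `[0.08, 0.35]`. A user override
#' short-circuits the estimate.
#'
#' @param tf a `TensorField`.
#' @param mask optional mask restricting the histogram.
#' @param override numeric FA threshold to use verbatim, or `NULL`.
#' @param clamp lower/upper clamp (default `c(0.08, 0.35)`).
#' @return FA threshold in `[0, 1]`.
#' @export
adaptive_fa_threshold <- function(tf, mask = NULL, override = NULL,
                                  clamp = c(0.08, 0.35)) {
  if (!is.null(override)) return(override)
  fa <- tf$fa
  if (!is.null(mask)) {
    m <- if (inherits(mask, "MaskVolume")) mask$data else mask
    fa <- fa[as.logical(m)]
  }
  if (length(fa) == 0 || diff(range(fa)) == 0) {
    warning(sprintf("constant FA map; falling back to the lower clamp %.2f", clamp[1]))
    return(clamp[1])
  }
  min(max(otsu_threshold(fa), clamp[1]), clamp[2])
}

#' Deterministic seed placement within a mask
#'
#' Seeds are placed at `density` seeds per mask voxel (default 0.5, i.e.
#' every other voxel on average), positions jittered uniformly within the
#' voxel by a seeded RNG so runs are exactly reproducible. The total is
#' capped at `max_seeds`.
#'
#' @param mask binary 3D array or `MaskVolume`.
#' @param affine voxel-to-world affine (required when `mask` is an array).
#' @param density seeds per voxel.
#' @param seed RNG seed (default 17).
#' @param max_seeds cap on the total seed count (default 50000).
#' @return n x 3 matrix of world-coordinate seed positions (mm).
#' @export
generate_seeds <- function(mask, affine = NULL, density = 0.5, seed = 17L,
                           max_seeds = 50000L) {
  if (inherits(mask, "MaskVolume")) {
    affine <- mask$affine
    mask <- mask$data
  }
  if (is.null(affine)) stop("affine required when mask is a plain array")
  vox <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(vox)) stop("empty mask: no seed voxels")
  n <- min(round(density * nrow(vox)), max_seeds)
  with_local_seed(seed, {
    pick <- sort(sample.int(nrow(vox), n, replace = density > 1))
    jitter <- matrix(runif(3 * length(pick), -0.5, 0.5), ncol = 3)
    voxc <- vox[pick, , drop = FALSE] - 1 + jitter     # 0-based continuous
    t(affine %*% rbind(t(voxc), 1))[, 1:3, drop = FALSE]
  })
}

#' Deterministic streamline tractography
#'
#' Bidirectional Euler integration along the principal eigenvector field
#' (FACT-like): from each seed the tracker steps `step_mm` (default 0.1 mm)
#' along the trilinearly interpolated `v1`, with per-corner sign alignment
#' to the incoming direction, and stops when FA falls below the threshold,
#' the turning angle exceeds `angle_max_deg` (default 90), the streamline
#' leaves the mask, or the length cap is reached. Streamlines with arc
#' length outside `length_bounds_mm` (default 10-1000 mm) are discarded.
#'
#' @param tf a `TensorField`.
#' @param seeds n x 3 matrix of world seed positions, or `NULL` to place
#'   them with [generate_seeds()] from `seed_mask`.
#' @param mask tracking mask (`MaskVolume` or binary array): streamlines
#'   stop on exit.
#' @param fa_threshold stopping FA threshold, or `"auto"` for
#'   [adaptive_fa_threshold()].
#' @param step_mm integration step (mm).
#' @param angle_max_deg maximal turning angle per step (degrees).
#' @param length_bounds_mm keep streamlines with arc length in this range.
#' @param seed_mask mask used for seed placement (defaults to voxels inside
#'   `mask` with FA at or above the threshold).
#' @param density,rng_seed,max_seeds passed to [generate_seeds()].
#' @return A `StreamlineSet`: list with `streamlines` (list of n x 3 world
#'   matrices), `lengths` (mm), `seed_count` and `params`.
#' @export
track <- function(tf, seeds = NULL, mask = NULL, fa_threshold = "auto",
                  step_mm = 0.1, angle_max_deg = 90,
                  length_bounds_mm = c(10, 1000), seed_mask = NULL,
                  density = 0.5, rng_seed = 17L, max_seeds = 50000L) {
  stopifnot(inherits(tf, "TensorField"))
  m <- if (is.null(mask)) array(1, dim(tf$fa)) else
    if (inherits(mask, "MaskVolume")) mask$data else mask
  if (!any(m > 0)) stop("empty tracking mask")
  thr <- if (identical(fa_threshold, "auto"))
    adaptive_fa_threshold(tf, mask = m) else fa_threshold
  if (is.null(seeds)) {
    sm <- if (is.null(seed_mask)) (m > 0) & (tf$fa >= thr) else
      if (inherits(seed_mask, "MaskVolume")) seed_mask$data else seed_mask
    if (!any(sm > 0)) {
      warning(sprintf("FA threshold %.3f is above the maximal in-mask FA; zero streamlines", thr))
      return(streamline_set(list(), step_mm, angle_max_deg, thr,
                            length_bounds_mm, 0L))
    }
    seeds <- generate_seeds(array(as.integer(sm), dim(tf$fa)), tf$affine,
                            density = density, seed = rng_seed,
                            max_seeds = max_seeds)
  }
  lines <- .track_streamlines(tf$fa, tf$v1, array(as.numeric(m > 0), dim(tf$fa)),
                              seeds, solve(tf$affine), step_mm, thr,
                              angle_max_deg, length_bounds_mm[2])
  lines <- Filter(Negate(is.null), lines)
  lens <- vapply(lines, function(l) {
    if (nrow(l) < 2) return(0)
    sum(sqrt(rowSums(diff(l)^2)))
  }, numeric(1))
  keep <- lens >= length_bounds_mm[1] & lens <= length_bounds_mm[2]
  streamline_set(lines[keep], step_mm, angle_max_deg, thr, length_bounds_mm,
                 nrow(seeds), lengths = lens[keep])
}

streamline_set <- function(lines, step_mm, angle_max_deg, fa_threshold,
                           length_bounds_mm, seed_count, lengths = numeric(0)) {
  structure(list(streamlines = lines, lengths = lengths,
                 seed_count = seed_count,
                 params = list(step_mm = step_mm,
                               angle_max_deg = angle_max_deg,
                               fa_threshold = fa_threshold,
                               length_bounds_mm = length_bounds_mm)),
            class = "StreamlineSet")
}

#' @export
print.StreamlineSet <- function(x, ...) {
  cat(sprintf("StreamlineSet: %d streamlines from %d seeds; median length %s mm\n",
              length(x$streamlines), x$seed_count,
              if (length(x$lengths)) format(median(x$lengths)) else "NA"))
  invisible(x)
}

#' Summary statistics of streamline lengths
#'
#' @param x a `StreamlineSet`, or a numeric vector of fiber lengths (mm).
#' @return A list with `n`, `median`, `mean`, `iqr`, `q25`, `q75` (mm).
#' @export
fiber_length_stats <- function(x) {
  lens <- if (inherits(x, "StreamlineSet")) x$lengths else as.numeric(x)
  if (!length(lens)) stop("empty streamline set: no lengths to summarize")
  qs <- quantile(lens, c(0.25, 0.75), names = FALSE)
  list(n = length(lens), median = median(lens), mean = mean(lens),
       iqr = qs[2] - qs[1], q25 = qs[1], q75 = qs[2])
}

#' Compare fiber lengths across FOVs
#'
#' Per-FOV [fiber_length_stats()] plus Mann-Whitney (Wilcoxon rank-sum)
#' tests of the stitched lengths against each single FOV, the
#' operationalization of "stitched fibers are longer": a one-sided test at
#' alpha = 0.05 on per-streamline lengths.
#'
#' @param brain_ss,cord_ss,stitched_ss `StreamlineSet`s (or length vectors).
#' @param alpha significance level.
#' @return A `FiberLengthReport` list: `stats` per FOV, `tests` with
#'   p-values, and `stitched_longer` (logical).
#' @export
compare_fov_lengths <- function(brain_ss, cord_ss, stitched_ss, alpha = 0.05) {
  get_lens <- function(x) if (inherits(x, "StreamlineSet")) x$lengths else as.numeric(x)
  lens <- lapply(list(brain = brain_ss, cord = cord_ss, stitched = stitched_ss),
                 get_lens)
  stats <- lapply(lens, fiber_length_stats)
  test <- function(a, b) suppressWarnings(
    wilcox.test(a, b, alternative = "greater", exact = FALSE)$p.value)
  tests <- list(stitched_vs_brain = test(lens$stitched, lens$brain),
                stitched_vs_cord = test(lens$stitched, lens$cord))
  structure(list(stats = stats, tests = tests, alpha = alpha,
                 stitched_longer =
                   stats$stitched$median > max(stats$brain$median,
                                               stats$cord$median) &&
                   all(unlist(tests) < alpha)),
            class = "FiberLengthReport")
}

#' Write streamlines to a plain-text CSV
#'
#' One row per point with columns `streamline`, `x`, `y`, `z` (world mm).
#'
#' @param ss a `StreamlineSet`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_streamlines_csv <- function(ss, path) {
  rows <- do.call(rbind, lapply(seq_along(ss$streamlines), function(i)
    cbind(streamline = i, ss$streamlines[[i]])))
  if (is.null(rows)) rows <- matrix(numeric(0), 0, 4)
  colnames(rows) <- c("streamline", "x", "y", "z")
  write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}
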