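#' Binarize an FA slice at a fixed threshold
#'
#' `mask = FA >= threshold` (inclusive boundary). The default 0.35 isolates
#' regions of high anisotropy, i.e. coherent white matter.
#'
#' @param fa_slice 2D numeric matrix with values in `[0, 1]`.
#' @param threshold FA cutoff, default 0.35.
#' @return Logical matrix.
#' @export
binarize_fa <- function(fa_slice, threshold = 0.35) {
  fa_slice >= threshold
}

#' Largest central connected component of a 2D mask
#'
#' Components are labeled with 8-connectivity and ranked by area; among the
#' components within 10% of the largest area, the one whose centroid is
#' nearest the geometric image centre is returned. This makes the "largest
#' component closest to the centre" rule deterministic when areas nearly
#' tie. An empty mask returns an empty mask.
#'
#' @param mask_2d logical or 0/1 matrix.
#' @param area_tie_frac components within this fraction of the largest area
#'   compete on centroid distance (default 0.1).
#' @return Logical matrix containing a single component (or all `FALSE`).
#' @export
central_component <- function(mask_2d, area_tie_frac = 0.1) {
  m <- matrix(as.integer(mask_2d != 0), nrow(mask_2d), ncol(mask_2d))
  if (!any(m > 0)) return(m > 0)
  lab <- matrix(.label_components(m), nrow(m), ncol(m))
  areas <- tabulate(lab[lab > 0])
  cand <- which(areas >= (1 - area_tie_frac) * max(areas))
  centre <- (dim(m) + 1) / 2
  d2 <- vapply(cand, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    sum((colMeans(idx) - centre)^2)
  }, numeric(1))
  lab == cand[which.min(d2)]
}

#' Dice similarity coefficient of two binary masks
#'
#' `Dice(A, B) = 2 |A n B| / (|A| + |B|)`: 1 is perfect spatial
#' correspondence, 0 is no overlap. Two empty masks are degenerate and
#' return 1 with a warning.
#'
#' @param a,b logical or 0/1 matrices/arrays of the same shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have the same shape")
  a <- a != 0; b <- b != 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty: Dice defined as 1 (degenerate)")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Slice-wise Dice QC of stitch alignment
#'
#' The alignment check on thresholded FA: for each slice pair in the
#' overlap, both FA slices are binarized at `threshold`, reduced to their
#' central connected component, and scored with [dice()]. The subject-level
#' aggregate is the mean over slices where both masks are nonempty.
#'
#' @param fa_fixed,fa_moving aligned FA volumes (3D arrays or
#'   `ScalarVolume`s); by convention the brain-FOV FA is fixed and the
#'   transformed cord-FOV FA is moving.
#' @param overlap_range length-2 integer vector of z indices (1-based,
#'   inclusive) to score; for volumes on the two source grids, supply the
#'   matching index pairs via `z_fixed`/`z_moving` instead.
#' @param threshold FA threshold (default 0.35).
#' @param z_fixed,z_moving optional explicit slice index vectors (same
#'   length), overriding `overlap_range`.
#' @return A `DiceReport`: `per_slice` data frame (`z`, `dice`, `size_a`,
#'   `size_b`, `intersection`), `aggregate`, `fa_threshold`, `slices_used`.
#' @export
dice_report <- function(fa_fixed, fa_moving, overlap_range = NULL,
                        threshold = 0.35, z_fixed = NULL, z_moving = NULL) {
  fx <- if (inherits(fa_fixed, "ScalarVolume")) fa_fixed$data else fa_fixed
  mv <- if (inherits(fa_moving, "ScalarVolume")) fa_moving$data else fa_moving
  if (is.null(z_fixed)) {
    if (is.null(overlap_range)) stop("supply overlap_range or z_fixed/z_moving")
    z_fixed <- z_moving <- seq(overlap_range[1], overlap_range[2])
  }
  if (length(z_fixed) != length(z_moving) || !length(z_fixed))
    stop("empty overlap: no slice pairs to score")
  mv <- match_inplane(mv, dim(fx))
  rows <- lapply(seq_along(z_fixed), function(i) {
    a <- central_component(binarize_fa(fx[, , z_fixed[i]], threshold))
    b <- central_component(binarize_fa(mv[, , z_moving[i]], threshold))
    if (!sum(a) || !sum(b)) return(NULL)
    data.frame(z = z_fixed[i], dice = dice(a, b), size_a = sum(a),
               size_b = sum(b), intersection = sum(a & b))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows))
    stop("no QC-eligible slices: every slice pair has an empty thresholded mask")
  structure(list(per_slice = rows, aggregate = mean(rows$dice),
                 fa_threshold = threshold, slices_used = nrow(rows)),
            class = "DiceReport")
}

#' @export
print.DiceReport <- function(x, ...) {
  cat(sprintf("DiceReport: aggregate %.4f over %d slices (FA >= %.2f)\n",
              x$aggregate, x$slices_used, x$fa_threshold))
  invisible(x)
}
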