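#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline knows, with defaults. Unknown
#' keys in a user configuration are rejected, so a config file cannot
#' silently misspell an option.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    input = list(mode = "phantom",            # "phantom" or "files"
                 brain_image = NULL, brain_bval = NULL, brain_bvec = NULL,
                 cord_image = NULL, cord_bval = NULL, cord_bvec = NULL),
    phantom = list(snr = Inf, seed = 17L, theta_true = 4,
                   shift_true = c(3, -2), z_offset_true = 12L, n_dirs = 16L),
    preprocess = list(upsample = TRUE, mask_threshold = "auto",
                      register_dwi = FALSE,
                      topup_cmd = NULL, eddy_cmd = NULL,
                      distortion_mode = "passthrough"),
    stitch = list(ref_slice = "auto", angles_n = 7L, angles_limit = 12,
                  max_shift = 10L, mode = "normalized", blend = "feather",
                  min_overlap_slices = 5L),
    track = list(fa_threshold = "auto", step_mm = 0.1, angle_max_deg = 90,
                 min_len_mm = 10, max_len_mm = 1000, seed_density = 0.5,
                 seed = 17L, max_seeds = 50000L),
    qc = list(fa_threshold = 0.35),
    out_dir = NULL,
    write_volumes = TRUE,          # stitched NIfTI (large); JSON sidecars always
    write_streamlines = FALSE)     # full polyline CSVs (very large)
}

#' Validate a pipeline configuration against the defaults
#'
#' Fills unset keys with defaults and rejects unknown keys at any nesting
#' level.
#'
#' @param config nested list, or a path to a YAML file.
#' @return The merged configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  merge_checked <- function(def, user, path) {
    extra <- setdiff(names(user), names(def))
    if (length(extra))
      stop(errorCondition(
        sprintf("unknown configuration key%s: %s",
                if (length(extra) > 1) "s" else "",
                paste0(path, extra, collapse = ", ")),
        class = c("dtistitch_validation_error", "error", "condition")))
    for (k in names(user)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(user[[k]]) &&
                      !is.null(names(def[[k]])))
        merge_checked(def[[k]], user[[k]], paste0(path, k, ".")) else user[[k]]
    }
    def
  }
  merge_checked(default_config(), config, "")
}

#' Run the full stitching pipeline
#'
#' Orchestrates preprocess, stitch, tensor/tracking and Dice QC:
#' \enumerate{
#'   \item load the two FOVs (or generate the phantom pair),
#'   \item optional external distortion-correction hook, upsampling by 2 and
#'     per-frame motion registration,
#'   \item estimate and apply the stitch transform, fuse,
#'   \item fit tensors and FA for the brain FOV, the aligned cord FOV and
#'     the stitched volume,
#'   \item Dice QC of brain-vs-cord FA over the overlap,
#'   \item deterministic tractography on all three volumes and the
#'     fiber-length comparison.
#' }
#' When `config$out_dir` is set, artifacts are written there: the stitched
#' volume (NIfTI + gradient table), a JSON sidecar with the transform,
#' per-slice scores, overlap range and full configuration, the Dice report,
#' the fiber-length comparison and per-FOV streamline CSVs.
#'
#' @param config nested list or YAML path; see [default_config()].
#' @return A list with `stitched`, `transform`, `dice`, `lengths`,
#'   `tracts`, `config` and `artifact_paths`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)

  if (identical(cfg$input$mode, "phantom")) {
    ph <- cfg$phantom
    pair <- generate_pair(phantom_spec(snr = ph$snr, seed = ph$seed,
                                       theta_true = ph$theta_true,
                                       shift_true = ph$shift_true,
                                       z_offset_true = ph$z_offset_true,
                                       n_dirs = ph$n_dirs))
    brain <- pair$brain; cord <- pair$cord
  } else {
    brain <- read_gradient_volume(cfg$input$brain_image, cfg$input$brain_bval,
                                  cfg$input$brain_bvec)
    cord <- read_gradient_volume(cfg$input$cord_image, cfg$input$cord_bval,
                                 cfg$input$cord_bvec)
  }

  tool <- list(cmd = cfg$preprocess$topup_cmd,
               mode = cfg$preprocess$distortion_mode,
               config_key = "preprocess.topup_cmd")
  brain <- run_external_distortion_correction(brain, tool)
  cord <- run_external_distortion_correction(cord, tool)
  if (isTRUE(cfg$preprocess$upsample)) {
    brain <- upsample_by_2(brain)
    cord <- upsample_by_2(cord)
  }
  if (isTRUE(cfg$preprocess$register_dwi)) {
    brain <- register_dwi_to_b0(brain)$volume
    cord <- register_dwi_to_b0(cord)$volume
  }

  brain_b0 <- extract_b0(brain)
  cord_b0 <- extract_b0(cord)
  brain_mask <- make_mask(brain_b0, cfg$preprocess$mask_threshold)
  cord_mask <- make_mask(cord_b0, cfg$preprocess$mask_threshold)

  brain_ns <- nervous_system_mask(brain_b0)
  cord_ns <- nervous_system_mask(cord_b0)
  ref <- if (identical(cfg$stitch$ref_slice, "auto"))
    select_reference_slice(
      scalar_volume(brain_b0$data * (brain_ns$data > 0), brain_b0$spacing,
                    brain_b0$affine), "auto") else
      select_reference_slice(brain_b0, "manual", z_index = cfg$stitch$ref_slice)
  p <- estimate_stitch_transform(
    brain_b0, cord_b0, brain_mask = brain_ns, cord_mask = cord_ns, ref = ref,
    angles = stitch_angle_grid(cfg$stitch$angles_n, cfg$stitch$angles_limit),
    max_shift = cfg$stitch$max_shift,
    normalize = !identical(cfg$stitch$mode, "raw"),
    min_overlap_slices = cfg$stitch$min_overlap_slices)
  cord_aligned <- apply_transform(cord, p, target_shape = dim(brain$data)[1:2])
  stitched <- fuse(brain, cord_aligned, p$z_offset, blend = cfg$stitch$blend,
                   transform = p)

  cord_aligned_mask <- apply_transform(
    scalar_volume(cord_mask$data + 0, cord$spacing, cord$affine), p,
    target_shape = dim(brain$data)[1:2])
  cord_aligned_mask$data <- array(as.integer(cord_aligned_mask$data >= 0.5),
                                  dim(cord_aligned_mask$data))
  stitched_mask <- fuse_masks(brain_mask$data, cord_aligned_mask$data,
                              p$z_offset, dim(stitched$data)[1:3])

  tf_brain <- fit_tensor(brain, mask = brain_mask)
  tf_cord <- fit_tensor(cord_aligned, mask = cord_aligned_mask$data)
  tf_stitched <- fit_tensor(stitched, mask = stitched_mask)

  kb <- seq_len(dim(brain$data)[3])
  kc <- kb + p$z_offset
  ok <- kc >= 1 & kc <= dim(cord_aligned$data)[3]
  qc <- dice_report(tf_brain$fa, tf_cord$fa, threshold = cfg$qc$fa_threshold,
                    z_fixed = kb[ok], z_moving = kc[ok])

  tr <- cfg$track
  run_track <- function(tf, mask) {
    track(tf, mask = mask, fa_threshold = tr$fa_threshold,
          step_mm = tr$step_mm, angle_max_deg = tr$angle_max_deg,
          length_bounds_mm = c(tr$min_len_mm, tr$max_len_mm),
          density = tr$seed_density, rng_seed = tr$seed,
          max_seeds = tr$max_seeds)
  }
  tracts <- list(brain = run_track(tf_brain, brain_mask$data),
                 cord = run_track(tf_cord, cord_aligned_mask$data),
                 stitched = run_track(tf_stitched, stitched_mask))
  lengths <- compare_fov_lengths(tracts$brain, tracts$cord, tracts$stitched)

  paths <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    if (isTRUE(cfg$write_volumes))
      write_volume(stitched, paths$stitched <- out("stitched.nii.gz"))
    sidecar <- list(
      package_version = as.character(utils::packageVersion("dtistitch")),
      config = cfg,
      transform = p[c("theta", "dx", "dy", "z_offset", "score")],
      per_slice_scores = attr(p, "per_slice"),
      correlation_profile = attr(p, "profile")$scores,
      overlap_range = stitched$overlap_range,
      source_labels = stitched$source_labels)
    jsonlite::write_json(sidecar, paths$sidecar <- out("stitched.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
    jsonlite::write_json(
      list(aggregate = qc$aggregate, fa_threshold = qc$fa_threshold,
           slices_used = qc$slices_used, per_slice = qc$per_slice),
      paths$dice <- out("dice_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    jsonlite::write_json(
      list(stats = lengths$stats, tests = lengths$tests,
           stitched_longer = lengths$stitched_longer),
      paths$lengths <- out("fiber_lengths.json"), auto_unbox = TRUE,
      digits = NA)
    for (nm in names(tracts)) {
      lens <- data.frame(streamline = seq_along(tracts[[nm]]$lengths),
                         length_mm = tracts[[nm]]$lengths)
      write.csv(lens, paths[[paste0("lengths_", nm)]] <-
                  out(sprintf("fiber_lengths_%s.csv", nm)), row.names = FALSE)
      if (isTRUE(cfg$write_streamlines))
        write_streamlines_csv(tracts[[nm]],
                              paths[[paste0("tracts_", nm)]] <-
                                out(sprintf("tracts_%s.csv", nm)))
    }
  }
  list(stitched = stitched, transform = p, dice = qc, lengths = lengths,
       tracts = tracts, config = cfg, artifact_paths = paths)
}

# union of the two masks on the fused slice stack
fuse_masks <- function(brain_mask, cord_mask, z_offset, fused_dim) {
  out <- array(0L, fused_dim)
  nzc <- dim(cord_mask)[3]
  cm <- match_inplane(cord_mask, fused_dim[1:2])
  out[, , seq_len(min(nzc, fused_dim[3]))] <-
    cm[, , seq_len(min(nzc, fused_dim[3]))]
  kb <- seq_len(dim(brain_mask)[3])
  f <- kb + z_offset
  ok <- f >= 1 & f <= fused_dim[3]
  out[, , f[ok]] <- pmax(out[, , f[ok], drop = FALSE],
                         brain_mask[, , kb[ok], drop = FALSE])
  out
}

#' Map a pipeline error to a shell exit code
#'
#' 0 success, 2 validation error, 3 stitch failure, 4 external-tool failure,
#' 1 anything else. Used by the command-line front end.
#'
#' @param e a condition object.
#' @return Integer exit code.
#' @export
error_exit_code <- function(e) {
  if (inherits(e, "dtistitch_validation_error")) return(2L)
  msg <- conditionMessage(e)
  if (grepl("stitch failure", msg, fixed = TRUE)) return(3L)
  if (grepl("external tool|not found on PATH", msg)) return(4L)
  1L
}
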