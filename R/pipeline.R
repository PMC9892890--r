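frame_has_signal <- function(contrast, k = 5, min_px = 4L) {
  dev <- abs(contrast - median(contrast))
  s <- mad(contrast)
  if (s <= 0) return(any(dev > 0))
  sum(dev > k * s) >= min_px
}

#' Run the full enumeration pipeline on a hologram stack
#'
#' Orchestrates the complete workflow on an acquired or simulated stack:
#' background estimation over all frames, per-frame background subtraction and
#' flat-field normalization, angular-spectrum volume reconstruction, 3D
#' localization with plane-of-best-focus cropping, multiple-count removal,
#' s-Net classification and decision-threshold gating, ending in a per-mL
#' concentration. Frames whose normalized contrast never rises above the
#' noise floor contain no cells and can be skipped before the (dominant)
#' reconstruction step (`skip_empty`, on by default).
#'
#' @param stack A `hologram_stack` (simulated or read from TIFF).
#' @param model A fitted [snet()] classifier.
#' @param optics An [optical_config()]; defaults to the stack's own.
#' @param flow A [flow_config()]; defaults to the stack's own.
#' @param alpha Decision threshold for tumor calls.
#' @param dedup A [dedup_config()].
#' @param k Detection threshold for [detect_2d()].
#' @param skip_empty Skip reconstruction of frames with no above-noise signal.
#' @param verbose Print per-stage progress.
#' @return Object of class `pipeline_result`: list with `result`
#'   (an `enumeration_result`), `detections`, `unique_detections`, `scores`,
#'   `crops` (of the unique detections) and `manifest` (stage counts, config
#'   hashes and seeds; counts are non-increasing from detections to unique to
#'   gated positives).
#' @export
run_pipeline <- function(stack, model, optics = stack$optics,
                         flow = stack$flow, alpha = 0.9999999,
                         dedup = dedup_config(), k = 6, skip_empty = TRUE,
                         verbose = FALSE) {
  if (is.null(stack$frames)) stop("stack has no rendered frames")
  if (is.null(optics) || is.null(flow))
    stop("optics and flow configurations are required")
  n_frames <- dim(stack$frames)[3]
  bg <- estimate_background(stack)
  det_list <- list()
  crop_list <- list()
  n_processed <- 0L
  for (f in seq_len(n_frames)) {
    cleaned <- subtract_background(stack$frames[, , f], bg)
    contrast <- contrast_field(cleaned, bg)
    if (skip_empty && !frame_has_signal(contrast)) next
    n_processed <- n_processed + 1L
    recon <- reconstruct_volume(contrast, optics)
    loc <- localize_frame(recon, frame_index = f, k = k, verbose = verbose)
    if (nrow(loc$detections)) {
      det_list[[length(det_list) + 1L]] <- loc$detections
      crop_list[[length(crop_list) + 1L]] <- loc$crops
    }
    if (verbose && f %% 100 == 0)
      message(sprintf("frame %d/%d: %d detections so far",
                      f, n_frames, sum(vapply(det_list, nrow, 1L))))
  }
  detections <- if (length(det_list)) do.call(rbind, det_list) else
    data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
               z_um = numeric(), focus_score = numeric(), area_px = integer())
  n_det <- nrow(detections)
  crops <- array(0, c(36, 36, n_det))
  pos <- 0L
  for (cl in crop_list) {
    nc <- dim(cl)[3]
    if (nc) crops[, , pos + seq_len(nc)] <- cl
    pos <- pos + nc
  }
  if (!is.null(stack$truth) && nrow(detections))
    detections <- match_truth(detections, stack$truth)
  detections$crop_id <- seq_len(n_det)
  unique_det <- remove_multiple_counts(detections, dedup)
  unique_crops <- crops[, , unique_det$crop_id, drop = FALSE]
  scores <- if (nrow(unique_det))
    predict(model, unique_crops) else
    data.frame(p_tumor = numeric(), p_wbc = numeric(),
               predicted = factor(character(), levels = model$levels))
  flow_run <- flow
  flow_run$n_frames <- n_frames
  result <- enumerate_cells(scores, alpha, n_frames, flow_run)
  manifest <- list(
    n_frames = n_frames, n_frames_processed = n_processed,
    n_detections = n_det, n_unique = nrow(unique_det),
    n_positives = result$detected_count,
    alpha = alpha, seed = stack$seed,
    optics_hash = object_hash(optics), flow_hash = object_hash(flow_run),
    model_hash = object_hash(model$params), dedup_hash = object_hash(dedup))
  structure(list(result = result, detections = detections,
                 unique_detections = unique_det, scores = scores,
                 crops = unique_crops, background = bg, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Holographic enumeration pipeline\n")
  cat(sprintf("  frames: %d (%d reconstructed) -> detections: %d -> unique: %d -> gated: %d\n",
              m$n_frames, m$n_frames_processed, m$n_detections, m$n_unique,
              m$n_positives))
  print(x$result)
  invisible(x)
}
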