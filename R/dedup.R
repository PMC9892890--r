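#' Remove multiple counts of cells spanning consecutive frames
#'
#' In laminar flow the cross-stream (y) and axial (z) positions of a cell are
#' conserved between frames while it traverses the field of view streamwise,
#' so a detection in frame i+1 that lies within `dy_max` cross-stream and
#' `dz_max` axially of a detection in frame i is the same cell seen again.
#' Such repeats are eliminated; when several frame-i detections satisfy both
#' criteria the nearest in (y, z) Euclidean distance claims the repeat.
#' Matching is transitive across chained frames (i, i+1, i+2, ...), so a slow
#' cell spanning several frames collapses to its earliest detection, which is
#' the instance kept.
#'
#' @param detections Data frame with at least `frame`, `y_um`, `z_um`.
#' @param cfg A [dedup_config()].
#' @return The surviving detections (first-frame instances), original order
#'   preserved, with a `duplicate_of` attribute column removed; the input row
#'   count is never increased and the operation is idempotent.
#' @examples
#' d <- data.frame(frame = c(1, 2), x_um = c(10, 600),
#'                 y_um = c(100, 101), z_um = c(150, 170))
#' remove_multiple_counts(d, dedup_config())  # second row removed
#' @export
remove_multiple_counts <- function(detections, cfg = dedup_config()) {
  if (!nrow(detections)) return(detections)
  if (is.unsorted(detections$frame))
    detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- detections$frame
  dup <- logical(nrow(detections))
  for (i in seq_len(nrow(detections))) {
    prev <- which(frames >= frames[i] - cfg$max_frame_gap & frames < frames[i])
    if (!length(prev)) next
    dy <- abs(detections$y_um[prev] - detections$y_um[i])
    dz <- abs(detections$z_um[prev] - detections$z_um[i])
    ok <- dy <= cfg$dy_max & dz <= cfg$dz_max
    if (any(ok)) dup[i] <- TRUE
  }
  out <- detections[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}
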