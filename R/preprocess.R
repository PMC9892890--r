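#' Estimate the object-free background of a hologram stack
#'
#' The background is the pixelwise arithmetic mean over all frames of the
#' acquisition. Cells are sparse and move between frames, so averaging the
#' full stack leaves essentially the static illumination pattern.
#'
#' @param stack A `hologram_stack` or a ny x nx x n_frames array.
#' @return Object of class `background_model`: list with `mean_frame` and
#'   `n_frames_used`.
#' @export
estimate_background <- function(stack) {
  frames <- if (inherits(stack, "hologram_stack")) stack$frames else stack
  if (is.null(frames)) stop("stack has no rendered frames")
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  nf <- dim(frames)[3]
  if (nf < 1L) stop("background estimation needs at least one frame")
  acc <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (f in seq_len(nf)) acc <- acc + frames[, , f]
  structure(list(mean_frame = acc / nf, n_frames_used = nf),
            class = "background_model")
}

#' Subtract the object-free background from a raw hologram
#'
#' Returns the signed residual `frame - background`. Downstream reconstruction
#' consumes the normalized contrast field `1 + cleaned / background` (see
#' [contrast_field()]).
#'
#' @param frame Raw hologram matrix.
#' @param bg A `background_model` from [estimate_background()] (or a matrix).
#' @return Cleaned (signed) hologram matrix.
#' @export
subtract_background <- function(frame, bg) {
  mean_frame <- if (inherits(bg, "background_model")) bg$mean_frame else bg
  if (!all(dim(frame) == dim(mean_frame)))
    stop("frame and background shapes differ")
  frame - mean_frame
}

#' Normalized contrast field for reconstruction
#'
#' Flat-field normalization of a cleaned hologram: `1 + cleaned / background`,
#' i.e. the raw frame divided by the background. Pixels where the background
#' falls below 1 percent of its median are clamped to that floor to prevent
#' division blow-ups at dead sensor regions.
#'
#' @param cleaned Background-subtracted hologram ([subtract_background()]).
#' @param bg A `background_model` (or background matrix).
#' @return Real matrix around unity, used as the amplitude of the optical
#'   field handed to [reconstruct_volume()].
#' @export
contrast_field <- function(cleaned, bg) {
  mean_frame <- if (inherits(bg, "background_model")) bg$mean_frame else bg
  if (!all(dim(cleaned) == dim(mean_frame)))
    stop("frame and background shapes differ")
  floor_val <- 0.01 * median(mean_frame)
  1 + cleaned / pmax(mean_frame, floor_val)
}
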