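#' Write a hologram stack as multi-page 16-bit TIFF
#'
#' Frames are stored as grayscale 16-bit pages; the ground truth (when
#' present) is written next to it as a CSV with columns `frame`, `cell_id`,
#' `class`, `x_um`, `y_um`, `z_um`, `diameter_um`.
#'
#' @param stack A `hologram_stack` (or ny x nx x n array of counts).
#' @param path Output TIFF path.
#' @param truth_path Optional CSV path for the ground-truth table.
#' @param max_count Count value mapped to the 16-bit ceiling.
#' @return `path`, invisibly.
#' @export
write_hologram_stack <- function(stack, path, truth_path = NULL,
                                 max_count = 65535) {
  frames <- if (inherits(stack, "hologram_stack")) stack$frames else stack
  if (is.null(frames)) stop("stack has no rendered frames")
  pages <- lapply(seq_len(dim(frames)[3]), function(f)
    pmin(pmax(frames[, , f] / max_count, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(truth_path) && inherits(stack, "hologram_stack"))
    write.csv(stack$truth, truth_path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF hologram stack
#'
#' @param path TIFF file written by [write_hologram_stack()] or any grayscale
#'   multi-page TIFF.
#' @param frame_rate Frame rate to attach, frames/s.
#' @param max_count Count value of the 16-bit ceiling (inverse of the scaling
#'   applied when writing).
#' @return A `hologram_stack` with integer count frames and no ground truth.
#' @export
read_hologram_stack <- function(path, frame_rate = 420, max_count = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  frames <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    frames[, , f] <- as.integer(round(pages[[f]] * max_count))
  structure(list(frames = frames, frame_rate = frame_rate, truth = NULL,
                 cells = NULL, illumination = NULL, noise_sd = NA_real_,
                 optics = NULL, flow = NULL, seed = NA_integer_),
            class = "hologram_stack")
}

#' Write / read a detection table
#'
#' Plain-CSV exchange format for detection tables produced by
#' [localize_frame()] and filtered by [remove_multiple_counts()].
#' @param detections Detection data frame.
#' @param path CSV path.
#' @return The path (write) or the detection data frame (read).
#' @export
write_detections <- function(detections, path) {
  write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) read.csv(path)

object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}
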