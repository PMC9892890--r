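#' Detect cell centers in a reconstructed volume
#'
#' Cells are absorbing objects, so each one produces a dark focus somewhere in
#' the reconstruction stack. The detector takes the minimum-intensity
#' projection over all planes, thresholds it at `median - k * MAD`, labels
#' connected components, filters them by area and returns the
#' intensity-weighted centroid of each component (weighted by the depth of the
#' intensity dip).
#'
#' Components whose darkest pixel stays above `max_min_intensity` are twin
#' image or diffraction side lobes (a true refocused cell dims the background
#' far more strongly) and are rejected; components closer together than
#' `min_separation_um` are merged, keeping the deepest.
#'
#' @param recon A `recon_stack` from [reconstruct_volume()].
#' @param k Threshold in robust standard deviations below the median.
#' @param area_min,area_max Accepted component area range, px.
#' @param max_min_intensity Maximum allowed darkest normalized intensity of a
#'   component (background is 1): a focused cell dims the reconstruction well
#'   below this even when its best plane falls between reconstruction planes,
#'   while side lobes stay above it.
#' @param min_separation_um Merge radius for nearby components, um.
#' @return Data frame with one row per detection: `x_um`, `y_um`, `x_px`,
#'   `y_px` (sub-pixel, 1-based), `area_px`, `min_intensity`.
#' @export
detect_2d <- function(recon, k = 6, area_min = 9, area_max = 2000,
                      max_min_intensity = 0.65, min_separation_um = 20) {
  planes <- recon$planes
  minproj <- planes[, , 1]
  for (p in seq_len(dim(planes)[3])[-1]) minproj <- pmin(minproj, planes[, , p])
  med <- median(minproj)
  s <- mad(minproj)
  thr <- med - k * s
  mask <- minproj < thr
  empty <- data.frame(x_um = numeric(), y_um = numeric(), x_px = numeric(),
                      y_px = numeric(), area_px = integer(),
                      min_intensity = numeric())
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  n_comp <- max(lab)
  depth <- pmax(med - minproj, 0)
  pitch <- recon$optics$pixel_pitch
  out <- vector("list", n_comp)
  for (cc in seq_len(n_comp)) {
    px <- which(lab == cc, arr.ind = TRUE)
    a <- nrow(px)
    if (a < area_min || a > area_max) next
    if (min(minproj[px]) > max_min_intensity) next
    w <- depth[px]
    ci <- sum(px[, 1] * w) / sum(w)
    cj <- sum(px[, 2] * w) / sum(w)
    out[[cc]] <- data.frame(
      x_um = (cj - 0.5) * pitch, y_um = (ci - 0.5) * pitch,
      x_px = cj, y_px = ci, area_px = a,
      min_intensity = min(minproj[px]))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # merge fragments of the same cell: keep the deepest within the merge radius
  res <- res[order(res$min_intensity), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i < nrow(res)) {
      later <- (i + 1):nrow(res)
      d2 <- (res$x_um[later] - res$x_um[i])^2 +
            (res$y_um[later] - res$y_um[i])^2
      keep[later[d2 < min_separation_um^2]] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$y_um, res$x_um), , drop = FALSE]
  rownames(res) <- NULL
  res
}

crop_window <- function(center_px, n_side = 36L) {
  c0 <- round(center_px)
  (c0 - n_side / 2L + 1L):(c0 + n_side / 2L)
}

focus_metric_value <- function(w, metric) {
  switch(metric,
    tenengrad = {
      gx <- w[-1, ] - w[-nrow(w), ]
      gy <- w[, -1] - w[, -ncol(w)]
      sum(gx^2) + sum(gy^2)
    },
    tamura = sd(w) / mean(w),
    min_mean = mean(w))
}

focus_metric_maximizes <- function(metric) metric %in% c("tenengrad", "tamura")

#' Axial focus profile of a detected cell
#'
#' Computes a focus metric in a 36 x 36 window centered on the detected (x, y)
#' position, at every reconstruction plane. The default metric is windowed
#' gradient energy (Tenengrad, maximized at focus): the refocused cell has the
#' sharpest edges in its own plane, which holds for both faint and strongly
#' absorbing cells. Alternatives: `"tamura"` (sd/mean, maximized) and
#' `"min_mean"` (windowed mean intensity, minimized at the dark focus). The
#' dark-focus criterion is unreliable for large opaque cells, whose shadow
#' stays dark over an extended axial range.
#'
#' @param recon A `recon_stack`.
#' @param centroid_xy Numeric `c(x_um, y_um)` of the detection.
#' @param metric `"tenengrad"` (default), `"tamura"` or `"min_mean"`.
#' @param window Side of the square analysis window, px.
#' @return Object of class `axial_profile`: list with `distances`, `focus`
#'   (metric per plane), `metric`, the window row/col indices and the `recon`
#'   stack (kept by reference for crop extraction). Errors if the window does
#'   not fit inside the field of view.
#' @export
axial_profile <- function(recon, centroid_xy,
                          metric = c("tenengrad", "tamura", "min_mean"),
                          window = 36L) {
  metric <- match.arg(metric)
  pitch <- recon$optics$pixel_pitch
  dims <- dim(recon$planes)
  rows <- crop_window(centroid_xy[2] / pitch + 0.5, window)
  cols <- crop_window(centroid_xy[1] / pitch + 0.5, window)
  if (min(rows) < 1L || max(rows) > dims[1] ||
      min(cols) < 1L || max(cols) > dims[2])
    stop("detection too close to the field edge for a ", window, "px crop")
  np <- dims[3]
  foc <- numeric(np)
  for (p in seq_len(np))
    foc[p] <- focus_metric_value(recon$planes[rows, cols, p], metric)
  structure(list(distances = recon$distances, focus = foc, metric = metric,
                 rows = rows, cols = cols, recon = recon),
            class = "axial_profile")
}

#' Select the plane of best focus and extract the cell crop
#'
#' Picks the optimum of the focus curve (maximum for tenengrad/tamura,
#' minimum for min_mean); ties break toward the smaller propagation distance
#' (`which.min`/`which.max` return the first optimum). The axial position is
#' converted to channel coordinates by subtracting the recording distance,
#' and the 36 x 36 crop is taken from the selected plane and min-max scaled
#' to `[0, 1]`.
#'
#' @param profile An [axial_profile()].
#' @return List with `z_um` (height above channel floor), `distance_um`,
#'   `focus_score` and `crop` (36 x 36 matrix in `[0, 1]`).
#' @export
select_pobf <- function(profile) {
  if (!length(profile$focus)) stop("empty axial profile")
  best <- if (focus_metric_maximizes(profile$metric))
    which.max(profile$focus) else which.min(profile$focus)
  d <- profile$distances[best]
  optics <- profile$recon$optics
  z <- min(max(d - optics$recording_distance, 0), optics$channel_height)
  crop <- profile$recon$planes[profile$rows, profile$cols, best]
  rng <- range(crop)
  crop <- if (rng[2] > rng[1]) (crop - rng[1]) / (rng[2] - rng[1])
          else crop * 0
  list(z_um = z, distance_um = d, focus_score = profile$focus[best],
       crop = crop)
}

#' Detect, localize and crop every cell in one reconstructed frame
#'
#' Runs [detect_2d()], then [axial_profile()] and [select_pobf()] for each
#' detection. Detections too close to the field edge for a full 36 x 36 crop
#' are dropped (with a message when `verbose`).
#'
#' @param recon A `recon_stack`.
#' @param frame_index Frame number recorded in the output.
#' @param verbose Report dropped edge detections.
#' @inheritParams detect_2d
#' @inheritParams axial_profile
#' @return List with `detections` (data frame: `frame`, `x_um`, `y_um`,
#'   `z_um`, `focus_score`, `area_px`) and `crops` (36 x 36 x n array).
#' @export
localize_frame <- function(recon, frame_index = 1L, k = 6, area_min = 9,
                           area_max = 2000, metric = "tenengrad",
                           verbose = FALSE) {
  det <- detect_2d(recon, k = k, area_min = area_min, area_max = area_max)
  n <- nrow(det)
  keep <- logical(n)
  z <- fs <- numeric(n)
  crops <- array(0, dim = c(36, 36, n))
  for (i in seq_len(n)) {
    prof <- tryCatch(
      axial_profile(recon, c(det$x_um[i], det$y_um[i]), metric = metric),
      error = function(e) NULL)
    if (is.null(prof)) {
      if (verbose)
        message(sprintf("frame %d: dropped edge detection at (%.0f, %.0f) um",
                        frame_index, det$x_um[i], det$y_um[i]))
      next
    }
    sel <- select_pobf(prof)
    keep[i] <- TRUE
    z[i] <- sel$z_um; fs[i] <- sel$focus_score
    crops[, , i] <- sel$crop
  }
  detections <- data.frame(frame = rep(frame_index, sum(keep)),
                           x_um = det$x_um[keep],
                           y_um = det$y_um[keep], z_um = z[keep],
                           focus_score = fs[keep], area_px = det$area_px[keep])
  list(detections = detections,
       crops = crops[, , keep, drop = FALSE])
}

#' Match detections to simulator ground truth
#'
#' Assigns each detection the nearest ground-truth cell of the same frame
#' within a lateral tolerance, attaching `truth_id` and `truth_label` columns
#' (NA where unmatched). Used for validation studies on simulated stacks.
#'
#' @param detections Detection data frame (see [localize_frame()]).
#' @param truth Ground-truth table from [simulate_stack()].
#' @param tol_um Maximum lateral (x, y) distance for a match.
#' @return `detections` with `truth_id` and `truth_label` added.
#' @export
match_truth <- function(detections, truth, tol_um = 10) {
  detections$truth_id <- NA_integer_
  detections$truth_label <- NA_character_
  for (i in seq_len(nrow(detections))) {
    cand <- truth[truth$frame == detections$frame[i], , drop = FALSE]
    if (!nrow(cand)) next
    d2 <- (cand$x_um - detections$x_um[i])^2 +
          (cand$y_um - detections$y_um[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol_um^2) {
      detections$truth_id[i] <- cand$cell_id[j]
      detections$truth_label[i] <- cand$class[j]
    }
  }
  detections
}
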