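score_vector <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$p_tumor
  if (!is.numeric(scores)) stop("scores must be numeric or a score data frame")
  scores
}

positive_mask <- function(labels, positive) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[1]
  labels == positive
}

#' Confusion-matrix metrics at a decision threshold
#'
#' A crop is called positive (tumor) when its positive-class probability
#' exceeds the decision threshold `alpha`. Reports true/false positive and
#' negative counts along with accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `TP/(TP+FN)` (true positive rate), specificity `TN/(TN+FP)` and false
#' positive rate `FP/(FP+TN) = 1 - specificity`.
#'
#' @param scores Numeric vector of positive-class probabilities, or the score
#'   data frame from [predict.snet()].
#' @param labels True class labels; the positive class defaults to the first
#'   factor level.
#' @param alpha Decision threshold on the positive-class probability.
#' @param positive Label value treated as positive.
#' @return Object of class `confusion_metrics`.
#' @examples
#' confusion_metrics(c(0.9, 0.8, 0.3, 0.6), c("TUMOR", "TUMOR", "WBC", "WBC"))
#' @export
confusion_metrics <- function(scores, labels, alpha = 0.5, positive = NULL) {
  scores <- score_vector(scores)
  if (!length(scores)) stop("empty input")
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  pos <- positive_mask(labels, positive)
  called <- scores > alpha
  tp <- sum(called & pos); fn <- sum(!called & pos)
  fp <- sum(called & !pos); tn <- sum(!called & !pos)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn, alpha = alpha,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fpr = if (tn + fp > 0) fp / (fp + tn) else NA_real_
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion at alpha = %g: TP %d  FN %d  FP %d  TN %d\n",
              x$alpha, x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f  FPR %.3g\n",
              x$accuracy, x$sensitivity, x$specificity, x$fpr))
  invisible(x)
}

#' Decision-threshold grid for ROC analysis
#'
#' The default grid spans the plain 0.5 majority decision and progressively
#' stricter gates `1 - 10^-k` up to `0.9999999`, the strictest threshold
#' at which the false positive rate stops changing in rare-cell screening.
#' @param max_nines Largest k in `1 - 10^-k`.
#' @return Increasing numeric vector of thresholds in `[0.5, 1)`.
#' @export
alpha_grid <- function(max_nines = 7L) c(0.5, 1 - 10^-(1:max_nines))

#' ROC curve over a threshold grid
#'
#' Computes the true and false positive rates of gated decisions at each
#' threshold via [confusion_metrics()]. Both rates are non-increasing in the
#' threshold.
#'
#' @inheritParams confusion_metrics
#' @param thresholds Threshold grid (default [alpha_grid()]).
#' @return Object of class `roc_curve`: data frame with `threshold`, `tpr`,
#'   `fpr`.
#' @export
roc_curve <- function(scores, labels, thresholds = alpha_grid(),
                      positive = NULL) {
  scores <- score_vector(scores)
  pos <- positive_mask(labels, positive)
  if (!any(pos) || all(pos))
    stop("ROC analysis needs both classes present")
  rows <- lapply(sort(thresholds), function(a) {
    cm <- confusion_metrics(scores, labels, alpha = a, positive = positive)
    data.frame(threshold = a, tpr = cm$sensitivity, fpr = cm$fpr)
  })
  structure(do.call(rbind, rows), class = c("roc_curve", "data.frame"))
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "b", xlab = "false positive rate",
       ylab = "true positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Select the operating decision threshold from an ROC curve
#'
#' Returns the smallest grid threshold attaining the minimum false positive
#' rate: increasing the threshold beyond it does not change the FPR, while
#' smaller thresholds are more permissive.
#'
#' @param roc A [roc_curve()].
#' @return The selected threshold (numeric scalar).
#' @export
select_alpha <- function(roc) {
  if (!nrow(roc)) stop("empty ROC curve")
  roc$threshold[which(roc$fpr == min(roc$fpr))[1]]
}

#' Compose an in-silico mixture from pure-population crop pools
#'
#' Draws `n_tumor` and `n_wbc` crops at random (without replacement) from the
#' two pure-population pools and returns the mixed, labeled dataset. Pool
#' indices listed in `exclude` are never drawn, which lets several mixtures be
#' built with no overlap from the same pools.
#'
#' @param pool_tumor,pool_wbc 36 x 36 x n crop arrays (or lists with `crops`).
#' @param n_tumor,n_wbc Number of crops of each class to draw.
#' @param seed Integer seed.
#' @param exclude Optional list with integer vectors `tumor` and `wbc` of pool
#'   indices to exclude.
#' @return List with `crops`, `labels` (factor TUMOR/WBC), and the drawn pool
#'   indices `idx_tumor`, `idx_wbc`.
#' @export
make_mixture <- function(pool_tumor, pool_wbc, n_tumor, n_wbc, seed = 1L,
                         exclude = NULL) {
  if (is.list(pool_tumor)) pool_tumor <- pool_tumor$crops
  if (is.list(pool_wbc)) pool_wbc <- pool_wbc$crops
  if (n_tumor < 0 || n_wbc < 0) stop("counts must be nonnegative")
  set.seed(seed)
  avail_t <- setdiff(seq_len(dim(pool_tumor)[3]), exclude$tumor)
  avail_w <- setdiff(seq_len(dim(pool_wbc)[3]), exclude$wbc)
  if (length(avail_t) < n_tumor || length(avail_w) < n_wbc)
    stop("crop pool exhausted")
  idx_t <- if (n_tumor) sample(avail_t, n_tumor) else integer()
  idx_w <- if (n_wbc) sample(avail_w, n_wbc) else integer()
  crops <- array(0, c(36, 36, n_tumor + n_wbc))
  if (n_tumor) crops[, , seq_len(n_tumor)] <- pool_tumor[, , idx_t]
  if (n_wbc) crops[, , n_tumor + seq_len(n_wbc)] <- pool_wbc[, , idx_w]
  list(crops = crops,
       labels = factor(rep(c("TUMOR", "WBC"), c(n_tumor, n_wbc)),
                       levels = c("TUMOR", "WBC")),
       idx_tumor = idx_t, idx_wbc = idx_w)
}

#' Sample volume imaged by an acquisition
#'
#' Time-based accounting: the volume of sample interrogated by `n_frames`
#' frames is the acquisition time times the sample flow rate,
#' `n_frames / frame_rate * sample_flow_rate`. At the reference operating
#' point, 10100 frames at 420 fps cover about 24 s, i.e. 1 mL at 2.5 mL/min.
#' (The per-frame geometric volume, [frame_volume()], under-samples the
#' stream and is reported for reference only.)
#'
#' @param n_frames Number of frames.
#' @param flow A [flow_config()].
#' @return Imaged sample volume, mL.
#' @export
imaged_volume <- function(n_frames, flow) {
  if (n_frames < 0) stop("n_frames must be nonnegative")
  n_frames / flow$frame_rate * flow$sample_flow_rate / 60
}

#' Geometric sample volume of a single hologram
#'
#' The instantaneous image volume of one frame: field-of-view length times
#' sheath-core width times channel depth. The reference geometry gives
#' 800 x 500 x 330 um^3, about 0.13 uL.
#'
#' @param optics An [optical_config()].
#' @return Volume in uL.
#' @export
frame_volume <- function(optics) {
  optics$fov_px[2] * optics$pixel_pitch * optics$sample_core_width *
    optics$channel_height * 1e-9  # um^3 -> uL
}

#' Gate classifier scores and report the enumerated concentration
#'
#' Counts detections whose positive-class probability exceeds the decision
#' threshold and converts the count to a concentration using the time-based
#' imaged volume.
#'
#' @param scores Score data frame from [predict.snet()] or numeric vector of
#'   positive-class probabilities for the unique (deduplicated) detections.
#' @param alpha Decision threshold (see [select_alpha()]).
#' @param n_frames Number of frames in the acquisition.
#' @param flow A [flow_config()].
#' @return Object of class `enumeration_result`: list with `detected_count`,
#'   `imaged_volume_ml`, `concentration_per_ml`, `alpha_used`.
#' @export
enumerate_cells <- function(scores, alpha, n_frames, flow) {
  p <- score_vector(scores)
  count <- sum(p > alpha)
  vol <- imaged_volume(n_frames, flow)
  structure(list(detected_count = count, imaged_volume_ml = vol,
                 concentration_per_ml = if (vol > 0) count / vol else NA_real_,
                 alpha_used = alpha, n_scored = length(p)),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat(sprintf("Enumeration: %d of %d unique cells gated positive at alpha = %g\n",
              x$detected_count, x$n_scored, x$alpha_used))
  cat(sprintf("  imaged volume %.3f mL -> %.2f cells/mL\n",
              x$imaged_volume_ml, x$concentration_per_ml))
  invisible(x)
}

#' Limit of detection from negative-control trials
#'
#' The limit of detection of the enumeration assay is
#' `LoD = mu_NC + 2 sigma_NC`, where `mu_NC` and `sigma_NC` are the mean and
#' sample standard deviation (n - 1 denominator) of the concentrations
#' reported for negative-control trials (samples with background WBCs but no
#' tumor cells). Either the raw per-trial counts or pre-computed statistics
#' may be supplied.
#'
#' @param counts Numeric vector of negative-control concentrations (>= 2
#'   trials), or `NULL` when `mu` and `sigma` are given.
#' @param mu,sigma Pre-computed negative-control mean and standard deviation.
#' @return Object of class `lod_result`: list with `mu`, `sigma`, `lod`,
#'   `n_trials`.
#' @examples
#' limit_of_detection(c(1, 1, 2))$lod          # 2.49
#' limit_of_detection(mu = 2.33, sigma = 1)$lod  # 4.33
#' @export
limit_of_detection <- function(counts = NULL, mu = NULL, sigma = NULL) {
  if (!is.null(counts)) {
    if (length(counts) < 2) stop("need at least 2 negative-control trials")
    mu <- mean(counts)
    sigma <- sd(counts)
    n <- length(counts)
  } else {
    if (is.null(mu) || is.null(sigma))
      stop("supply counts, or both mu and sigma")
    n <- NA_integer_
  }
  structure(list(mu = mu, sigma = sigma, lod = mu + 2 * sigma, n_trials = n),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LoD = mu + 2 sigma = %.2f cells/mL (mu = %.2f, sigma = %.2f%s)\n",
              x$lod, x$mu, x$sigma,
              if (is.na(x$n_trials)) "" else sprintf(", %d trials", x$n_trials)))
  invisible(x)
}
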