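#' s-Net architecture description
#'
#' The shallow classification network for 36 x 36 in-focus cell images: three
#' 3 x 3, stride-1, same-padded convolutional layers with 8, 16 and 32 filters,
#' each followed by batch normalization and ReLU, with 2 x 2 max pooling
#' (stride 2) after the first and second convolutions. Spatial sizes run
#' 36 -> 36 -> 18 -> 18 -> 9, so the flattened feature vector entering the
#' fully connected softmax layer has 9 x 9 x 32 = 2592 nodes. With batch
#' normalization the network has 11186 learnable parameters (about 11 000).
#'
#' @param conv_filters Integer triple of filter counts.
#' @param kernel Convolution kernel side (3).
#' @param input_dim Input image size in pixels.
#' @param n_classes Number of output classes.
#' @param batch_norm Include batch normalization after each convolution.
#' @param flatten_dim Optional declared flatten size; an error is raised at
#'   build time if it disagrees with the size implied by the filter counts.
#' @return Object of class `snet_architecture`.
#' @examples
#' arch <- snet_architecture()
#' arch$flatten_dim            # 2592
#' count_learnables(arch)      # 11186
#' @export
snet_architecture <- function(conv_filters = c(8L, 16L, 32L), kernel = 3L,
                              input_dim = c(36L, 36L), n_classes = 2L,
                              batch_norm = TRUE, flatten_dim = NULL) {
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) != 3L || any(conv_filters < 1L))
    stop("conv_filters must be three positive filter counts")
  if (kernel != 3L) stop("only 3x3 kernels are supported")
  if (any(input_dim %% 4L != 0L))
    stop("input_dim must be divisible by 4 (two 2x2 poolings)")
  spatial <- list(input_dim, input_dim, input_dim %/% 2L,
                  input_dim %/% 2L, input_dim %/% 4L)
  computed <- prod(input_dim %/% 4L) * conv_filters[3]
  if (!is.null(flatten_dim) && flatten_dim != computed)
    stop(sprintf("declared flatten dimension %d does not match computed %d",
                 flatten_dim, computed))
  structure(list(conv_filters = conv_filters, kernel = kernel,
                 input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 batch_norm = isTRUE(batch_norm),
                 flatten_dim = as.integer(computed),
                 spatial = spatial),
            class = "snet_architecture")
}

#' @export
print.snet_architecture <- function(x, ...) {
  cat("s-Net architecture\n")
  cat(sprintf("  input %dx%dx1 -> conv(%d)-%sReLU-pool -> conv(%d)-%sReLU-pool -> conv(%d)-%sReLU\n",
              x$input_dim[1], x$input_dim[2], x$conv_filters[1],
              if (x$batch_norm) "BN-" else "", x$conv_filters[2],
              if (x$batch_norm) "BN-" else "", x$conv_filters[3],
              if (x$batch_norm) "BN-" else ""))
  cat(sprintf("  flatten(%d) -> FC(%d) -> softmax; %d learnables\n",
              x$flatten_dim, x$n_classes, count_learnables(x)))
  invisible(x)
}

#' Count learnable parameters of an s-Net architecture
#'
#' Closed-form sum of convolution weights and biases, batch-norm scales and
#' offsets (when present) and fully connected weights and biases. The default
#' architecture has 80 + 16 + 1168 + 32 + 4640 + 64 + 5186 = 11186 learnables
#' (11074 without batch normalization).
#'
#' @param arch A [snet_architecture()].
#' @param include_batch_norm Count batch-norm scale/offset pairs (only when
#'   the architecture has batch norm).
#' @return Integer parameter count.
#' @export
count_learnables <- function(arch, include_batch_norm = arch$batch_norm) {
  k2 <- arch$kernel^2
  cin <- c(1L, arch$conv_filters[1:2])
  conv <- sum(k2 * cin * arch$conv_filters + arch$conv_filters)
  bn <- if (include_batch_norm && arch$batch_norm)
    sum(2L * arch$conv_filters) else 0L
  fc <- arch$flatten_dim * arch$n_classes + arch$n_classes
  as.integer(conv + bn + fc)
}

#' Stratified random train/test split
#'
#' Randomly splits observations into disjoint, exhaustive train and test sets.
#' Given a factor of class labels the split is stratified per class; given a
#' single integer it splits `1:n` (one class). The training set size per class
#' is `round(n * train_fraction)`; the remainder is the test set, matching a
#' 70/30 split of 52340 per-class images into 36638 and 15702.
#'
#' @param labels Factor of class labels, or a single integer count.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed; identical seeds reproduce the split.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  set.seed(seed)
  if (length(labels) == 1L && is.numeric(labels)) {
    n <- as.integer(labels)
    if (n < 2L) stop("need at least 2 observations to split")
    tr <- sort(sample.int(n, round(n * train_fraction)))
    return(list(train = tr, test = setdiff(seq_len(n), tr)))
  }
  labels <- as.factor(labels)
  train <- integer()
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < 2L) stop("class ", lv, " too small to split")
    train <- c(train, sort(sample(idx, round(length(idx) * train_fraction))))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
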