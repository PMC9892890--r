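snet_init_params <- function(arch) {
  cf <- arch$conv_filters
  cin <- c(1L, cf[1], cf[2])
  p <- list()
  for (l in 1:3) {
    p[[paste0("w", l)]] <- he_uniform(c(3, 3, cin[l], cf[l]), 9 * cin[l])
    p[[paste0("b", l)]] <- numeric(cf[l])
    if (arch$batch_norm) {
      p[[paste0("g", l)]] <- rep(1, cf[l])
      p[[paste0("be", l)]] <- numeric(cf[l])
    }
  }
  p$wf <- he_uniform(c(arch$n_classes, arch$flatten_dim), arch$flatten_dim)
  p$bf <- numeric(arch$n_classes)
  p
}

snet_init_running <- function(arch) {
  lapply(arch$conv_filters,
         function(cf) list(mean = numeric(cf), var = rep(1, cf)))
}

snet_forward <- function(params, arch, x, running, training = FALSE) {
  caches <- list(x = x)
  h <- x
  for (l in 1:3) {
    cv <- conv_layer_fwd(h, params[[paste0("w", l)]], params[[paste0("b", l)]])
    a <- cv$y
    if (training) {
      caches[[paste0("conv_cols", l)]] <- cv$cols
      caches[[paste0("conv_dim", l)]] <- dim(h)
    }
    if (arch$batch_norm) {
      bn <- bn_fwd(a, params[[paste0("g", l)]], params[[paste0("be", l)]],
                   running[[l]], training)
      running[[l]] <- bn$running
      caches[[paste0("bn", l)]] <- bn$cache
      a <- bn$y
    }
    caches[[paste0("pre_relu", l)]] <- a
    h <- relu_fwd(a)
    if (l < 3) {
      pl <- pool_layer_fwd(h)
      caches[[paste0("pool", l)]] <- pl
      h <- pl$y
    }
  }
  n <- dim(h)[4]
  flat <- matrix(h, arch$flatten_dim, n)
  caches$flat <- flat
  logits <- params$wf %*% flat + params$bf
  probs <- softmax_cols(logits)
  list(probs = probs, caches = caches, running = running)
}

snet_backward <- function(params, arch, fwd, y_onehot) {
  n <- ncol(y_onehot)
  dlogits <- (fwd$probs - y_onehot) / n
  grads <- list(wf = dlogits %*% t(fwd$caches$flat), bf = rowSums(dlogits))
  dh <- array(t(params$wf) %*% dlogits,
              c(arch$spatial[[5]], arch$conv_filters[3], n))
  for (l in 3:1) {
    if (l < 3) dh <- pool_layer_bwd(dh, fwd$caches[[paste0("pool", l)]])
    dh <- relu_bwd(dh, fwd$caches[[paste0("pre_relu", l)]])
    if (arch$batch_norm) {
      bn <- bn_bwd(dh, fwd$caches[[paste0("bn", l)]],
                   params[[paste0("g", l)]])
      grads[[paste0("g", l)]] <- bn$dgamma
      grads[[paste0("be", l)]] <- bn$dbeta
      dh <- bn$dx
    }
    cv <- conv_layer_bwd(fwd$caches[[paste0("conv_cols", l)]], dh,
                         params[[paste0("w", l)]],
                         fwd$caches[[paste0("conv_dim", l)]])
    grads[[paste0("w", l)]] <- cv$dw
    grads[[paste0("b", l)]] <- cv$db
    dh <- cv$dx
  }
  grads
}

as_input_array <- function(x, arch) {
  if (is.list(x) && !is.null(x$crops)) x <- x$crops
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1L))
  d <- dim(x)
  if (length(d) == 3L) x <- array(x, c(d[1], d[2], 1L, d[3]))
  d <- dim(x)
  if (d[1] != arch$input_dim[1] || d[2] != arch$input_dim[2] || d[3] != 1L)
    stop(sprintf("crops must be %d x %d x 1; got %s",
                 arch$input_dim[1], arch$input_dim[2],
                 paste(d, collapse = " x ")))
  x
}

#' Fit the s-Net cell classifier
#'
#' Trains the shallow convolutional network of [snet_architecture()] on
#' labeled 36 x 36 plane-of-best-focus cell images by minimizing softmax
#' cross-entropy with the Adam optimizer (default learning rate 1e-3,
#' minibatch 32, 20 epochs). Weights are He-uniform initialized from the
#' seeded RNG and training is deterministic given the seed. Crops are expected
#' on the `[0, 1]` scale produced by [select_pobf()] / [simulate_pobf_crops()].
#'
#' @param x Crop array, 36 x 36 x n (or 36 x 36 x 1 x n), or a list with a
#'   `crops` element.
#' @param y Factor (or character) of class labels; the first factor level is
#'   the positive ("tumor") class.
#' @param arch A [snet_architecture()].
#' @param epochs,batch_size,lr Training-recipe hyperparameters.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param verbose Print per-epoch loss and accuracy.
#' @return Object of class `snet`: list with `params`, `running` (batch-norm
#'   inference statistics), `arch`, `levels`, `history` (per-epoch data frame
#'   with `loss` and `accuracy`) and the training configuration.
#' @seealso [predict.snet()], [confusion_metrics()], [roc_curve()]
#' @export
snet <- function(x, y, arch = snet_architecture(), epochs = 20L,
                 batch_size = 32L, lr = 1e-3, seed = 1L, verbose = FALSE) {
  y <- as.factor(y)
  if (nlevels(y) != arch$n_classes)
    stop("number of label levels must match arch$n_classes")
  x <- as_input_array(x, arch)
  n <- dim(x)[4]
  if (length(y) != n) stop("length(y) must match the number of crops")
  set.seed(seed)
  params <- snet_init_params(arch)
  running <- snet_init_running(arch)
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  ycode <- as.integer(y)
  momentum <- 0.1
  hist_loss <- hist_acc <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      res <- snet_batch(params, as.numeric(xb),
                        c(arch$input_dim, length(idx)), ycode[idx],
                        lapply(running, `[[`, "mean"),
                        lapply(running, `[[`, "var"),
                        arch$batch_norm, TRUE)
      if (!is.finite(res$loss))
        stop(sprintf("non-finite loss at epoch %d; training aborted", ep))
      if (arch$batch_norm) {
        for (l in 1:3) {
          running[[l]]$mean <- (1 - momentum) * running[[l]]$mean +
            momentum * res$bn_mean[[l]]
          running[[l]]$var <- (1 - momentum) * running[[l]]$var +
            momentum * res$bn_var[[l]]
        }
      }
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(t(res$probs)) == ycode[idx])
      upd <- adam_step(params, res$grads, state, lr)
      params <- upd$params; state <- upd$state
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  acc %.4f",
                      ep, hist_loss[ep], hist_acc[ep]))
  }
  structure(list(params = params, running = running, arch = arch,
                 levels = levels(y),
                 history = data.frame(epoch = seq_len(epochs),
                                      loss = hist_loss, accuracy = hist_acc),
                 control = list(epochs = epochs, batch_size = batch_size,
                                lr = lr, seed = seed, n_train = n)),
            class = "snet")
}

#' Predict class probabilities for cell crops
#'
#' Runs crops through a trained s-Net in inference mode (batch-norm statistics
#' frozen at their running values) and returns per-crop softmax probabilities.
#' The default decision assigns the class with probability above 0.5; rare-cell
#' calling applies a stricter gate via [enumerate_cells()].
#'
#' @param object A fitted [snet()].
#' @param newdata Crop array (36 x 36 x n) or list with `crops`.
#' @param type `"score"` (data frame of probabilities and decision, default),
#'   `"prob"` (matrix of probabilities) or `"class"` (factor).
#' @param chunk Number of crops per forward pass.
#' @param ... Unused.
#' @return See `type`. For `"score"`: data frame with `p_tumor` (probability
#'   of the first, positive class), `p_wbc` and `predicted`.
#' @export
predict.snet <- function(object, newdata, type = c("score", "prob", "class"),
                         chunk = 512L, ...) {
  type <- match.arg(type)
  x <- as_input_array(newdata, object$arch)
  n <- dim(x)[4]
  probs <- matrix(0, object$arch$n_classes, n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs[, idx] <- snet_infer(object$params,
                               as.numeric(x[, , , idx, drop = FALSE]),
                               c(object$arch$input_dim, length(idx)),
                               lapply(object$running, `[[`, "mean"),
                               lapply(object$running, `[[`, "var"),
                               object$arch$batch_norm)
  }
  cls <- factor(object$levels[max.col(t(probs))], levels = object$levels)
  switch(type,
    prob = {
      out <- t(probs)
      colnames(out) <- object$levels
      out
    },
    class = cls,
    score = data.frame(p_tumor = probs[1, ], p_wbc = probs[2, ],
                       predicted = cls))
}

#' @export
print.snet <- function(x, ...) {
  cat(sprintf("s-Net classifier (%d learnables), classes: %s\n",
              count_learnables(x$arch), paste(x$levels, collapse = " vs ")))
  cat(sprintf("  trained %d epochs on %d crops (batch %d, Adam lr %g, seed %d)\n",
              x$control$epochs, x$control$n_train, x$control$batch_size,
              x$control$lr, x$control$seed))
  last <- nrow(x$history)
  cat(sprintf("  final training loss %.4f, accuracy %.4f\n",
              x$history$loss[last], x$history$accuracy[last]))
  invisible(x)
}

#' @export
summary.snet <- function(object, ...) {
  print(object)
  print(object$arch)
  invisible(object)
}

#' Plot the s-Net training history
#' @param x A fitted [snet()].
#' @param ... Passed to [plot()].
#' @export
plot.snet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "b", xlab = "epoch",
       ylab = "training loss", ...)
  plot(x$history$epoch, x$history$accuracy, type = "b", xlab = "epoch",
       ylab = "training accuracy", ...)
  invisible(x)
}

#' Serialize / restore a trained s-Net
#'
#' Saves architecture, weights, batch-norm statistics and training
#' configuration to an RDS file, with a content hash for provenance.
#' @param object A fitted [snet()].
#' @param path Output file.
#' @return `save_snet` invisibly returns the hash; `load_snet` returns the
#'   model.
#' @export
save_snet <- function(object, path) {
  saveRDS(object, path)
  invisible(unname(tools::md5sum(path)))
}

#' @rdname save_snet
#' @export
load_snet <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "snet"))
  obj
}
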