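test_that("architecture bookkeeping matches the closed-form counts", {
  arch <- snet_architecture()
  expect_equal(arch$flatten_dim, 2592L)
  expect_equal(count_learnables(arch),
               (3 * 3 * 1 * 8 + 8) + 16 + (3 * 3 * 8 * 16 + 16) + 32 +
                 (3 * 3 * 16 * 32 + 32) + 64 + (2592 * 2 + 2))
  expect_equal(count_learnables(arch), 11186L)
  expect_equal(count_learnables(arch, include_batch_norm = FALSE), 11074L)
  expect_equal(count_learnables(snet_architecture(batch_norm = FALSE)), 11074L)
  # declaring an inconsistent flatten size is a build-time error
  expect_error(snet_architecture(conv_filters = c(8, 16, 64),
                                 flatten_dim = 2592), "flatten")
  expect_equal(snet_architecture(conv_filters = c(8, 16, 64))$flatten_dim,
               5184L)
})

test_that("the stratified split is exact, disjoint and seeded", {
  sp <- split_dataset(52340, 0.7, seed = 3)
  expect_length(sp$train, 36638)
  expect_length(sp$test, 15702)
  expect_length(intersect(sp$train, sp$test), 0)
  sp10 <- split_dataset(10, 0.7, seed = 1)
  expect_length(sp10$train, 7)
  expect_length(sp10$test, 3)
  labs <- factor(rep(c("TUMOR", "WBC"), each = 40))
  spl <- split_dataset(labs, 0.7, seed = 5)
  expect_equal(sum(labs[spl$train] == "TUMOR"), 28)
  expect_equal(sort(c(spl$train, spl$test)), 1:80)
  expect_identical(split_dataset(labs, 0.7, seed = 5), spl)
  expect_false(identical(split_dataset(labs, 0.7, seed = 6)$train, spl$train))
})

test_that("the fused C++ training step reproduces the reference R layers", {
  arch <- snet_architecture()
  set.seed(14)
  params <- holocount:::snet_init_params(arch)
  running <- holocount:::snet_init_running(arch)
  x <- array(runif(36 * 36 * 12), c(36, 36, 1, 12))
  yc <- rep(1:2, 6)
  fwdR <- holocount:::snet_forward(params, arch, x, running, training = TRUE)
  onehot <- matrix(0, 2, 12); onehot[cbind(yc, 1:12)] <- 1
  grR <- holocount:::snet_backward(params, arch, fwdR, onehot)
  res <- holocount:::snet_batch(params, as.numeric(x), c(36L, 36L, 12L), yc,
                                lapply(running, `[[`, "mean"),
                                lapply(running, `[[`, "var"), TRUE, TRUE)
  expect_lt(max(abs(res$probs - fwdR$probs)), 1e-12)
  for (nm in names(grR))
    expect_lt(max(abs(as.numeric(res$grads[[nm]]) - as.numeric(grR[[nm]]))),
              1e-12)
  # inference path agrees with the reference in eval mode too
  fwdI <- holocount:::snet_forward(params, arch, x, running, training = FALSE)
  pI <- holocount:::snet_infer(params, as.numeric(x), c(36L, 36L, 12L),
                               lapply(running, `[[`, "mean"),
                               lapply(running, `[[`, "var"), TRUE)
  expect_lt(max(abs(pI - fwdI$probs)), 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  arch <- snet_architecture(input_dim = c(8L, 8L),
                            conv_filters = c(2L, 3L, 4L))
  set.seed(3)
  params <- holocount:::snet_init_params(arch)
  running <- holocount:::snet_init_running(arch)
  x <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
  yc <- c(1L, 2L, 1L, 2L)
  lossf <- function(p) {
    f <- holocount:::snet_batch(p, as.numeric(x), c(8L, 8L, 4L), yc,
                                lapply(running, `[[`, "mean"),
                                lapply(running, `[[`, "var"), TRUE, TRUE)
    f$loss
  }
  base <- holocount:::snet_batch(params, as.numeric(x), c(8L, 8L, 4L), yc,
                                 lapply(running, `[[`, "mean"),
                                 lapply(running, `[[`, "var"), TRUE, TRUE)
  eps <- 1e-5
  set.seed(8)
  for (nm in c("w1", "g2", "be1", "w3", "wf", "bf")) {
    for (ii in sample(seq_along(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- params; p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (lossf(p2) - lossf(p3)) / (2 * eps)
      expect_lt(abs(num - as.numeric(base$grads[[nm]])[ii]), 1e-6)
    }
  }
})

test_that("training is deterministic and learns separable classes", {
  pool <- quick_pool()
  m <- quick_model()
  sc <- predict(m, pool$crops)
  expect_gt(mean(sc$predicted == pool$labels), 0.98)
  # probabilities are a valid softmax and identical crops score identically
  expect_lt(max(abs(sc$p_tumor + sc$p_wbc - 1)), 1e-6)
  expect_true(all(sc$p_tumor >= 0 & sc$p_tumor <= 1))
  dup <- predict(m, pool$crops[, , c(1, 1)])
  expect_equal(dup$p_tumor[1], dup$p_tumor[2])
  # tumor crops score higher than WBC crops on average
  expect_gt(mean(sc$p_tumor[pool$labels == "TUMOR"]),
            mean(sc$p_tumor[pool$labels == "WBC"]))
  # retraining with the same seed reproduces identical weights
  m2 <- snet(pool$crops, pool$labels, epochs = 2, seed = 11)
  m3 <- snet(pool$crops, pool$labels, epochs = 2, seed = 11)
  expect_identical(m2$params, m3$params)
  expect_identical(m2$running, m3$running)
})

test_that("a serialized model survives a save/load round trip", {
  m <- quick_model()
  f <- tempfile(fileext = ".rds")
  save_snet(m, f)
  m2 <- load_snet(f)
  pool <- quick_pool()
  expect_identical(predict(m, pool$crops[, , 1:5]),
                   predict(m2, pool$crops[, , 1:5]))
  unlink(f)
})

test_that("the same architecture retrains onto a second tumor cell line", {
  # emulates transferring the classifier to a different (ovarian-like) cancer
  # cell class: same network, new positive-class size/contrast distribution
  pool1 <- fixture("retrain_pool1", function()
    simulate_pobf_crops(400, seed = 404, optics = crop_optics()))
  pool2 <- fixture("skov_pool", function()
    simulate_pobf_crops(400, seed = 405, optics = crop_optics(),
                        params = cell_params(
                          tumor = list(diameter_mean = 15, diameter_sd = 2,
                                       amplitude = 0.65, phase = 0))))
  acc <- function(pool) {
    sp <- split_dataset(pool$labels, 0.7, seed = 21)
    m <- snet(pool$crops[, , sp$train], pool$labels[sp$train],
              epochs = 6, seed = 402)
    mean(predict(m, pool$crops[, , sp$test])$predicted ==
           pool$labels[sp$test])
  }
  a1 <- acc(pool1); a2 <- acc(pool2)
  expect_gt(a1, 0.9)
  expect_lt(abs(a1 - a2), 0.05)
})

test_that("confusion metrics follow their defining identities", {
  lab <- rep(c("TUMOR", "WBC"), c(50, 50))
  cm <- confusion_metrics(c(rep(0.9, 50), rep(0.1, 50)), lab)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$fpr, 0)
  lab2 <- rep(c("TUMOR", "WBC"), c(100, 1000))
  sc2 <- c(rep(0.9, 90), rep(0.1, 10), rep(0.9, 20), rep(0.1, 980))
  cm2 <- confusion_metrics(sc2, lab2)
  expect_equal(cm2$sensitivity, 0.9)
  expect_equal(cm2$fpr, 0.02)
  expect_equal(cm2$fpr, 1 - cm2$specificity)
  expect_equal(cm2$accuracy, (90 + 980) / 1100)
  # a maximal gate with scores below 1 yields no calls at all
  cm3 <- confusion_metrics(sc2, lab2, alpha = 1 - 1e-12)
  expect_equal(cm3$sensitivity, 0)
  expect_equal(cm3$fpr, 0)
  expect_error(confusion_metrics(numeric(), character()), "empty")
})
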