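test_that("the ROC curve agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  lab <- factor(rep(c("TUMOR", "WBC"), each = 300), levels = c("TUMOR", "WBC"))
  sc <- c(rbeta(300, 4, 2), rbeta(300, 2, 4))
  roc <- roc_curve(sc, lab, thresholds = c(0.3, 0.5, 0.7))
  ref <- pROC::roc(response = lab, predictor = sc, levels = c("WBC", "TUMOR"),
                   direction = "<", quiet = TRUE)
  for (i in seq_len(nrow(roc))) {
    cc <- pROC::coords(ref, x = roc$threshold[i], input = "threshold",
                       ret = c("sensitivity", "specificity"))
    expect_equal(roc$tpr[i], as.numeric(cc["sensitivity"]), tolerance = 1e-12)
    expect_equal(roc$fpr[i], 1 - as.numeric(cc["specificity"]),
                 tolerance = 1e-12)
  }
  # uninformative scores give a near-diagonal curve
  set.seed(34)
  sc0 <- runif(600)
  auc0 <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc0,
                                         levels = c("WBC", "TUMOR"),
                                         direction = "<", quiet = TRUE)))
  expect_lt(abs(auc0 - 0.5), 0.05)
})

test_that("gated rates are monotone in the decision threshold", {
  set.seed(35)
  lab <- rep(c("TUMOR", "WBC"), each = 200)
  sc <- c(rbeta(200, 8, 2), rbeta(200, 2, 8))
  roc <- roc_curve(sc, lab)
  expect_true(all(diff(roc$tpr) <= 1e-12))
  expect_true(all(diff(roc$fpr) <= 1e-12))
  # perfectly separated scores saturate the curve
  perfect <- roc_curve(c(rep(1, 5), rep(0, 5)), rep(c("TUMOR", "WBC"), each = 5))
  expect_true(all(perfect$tpr == 1))
  expect_true(all(perfect$fpr == 0))
  expect_error(roc_curve(rep(0.5, 4), rep("TUMOR", 4)), "both classes")
})

test_that("threshold selection takes the first minimum-FPR grid point", {
  roc <- structure(data.frame(threshold = c(0.5, 0.9, 0.99, 0.999),
                              tpr = c(1, 0.9, 0.8, 0.8),
                              fpr = c(0.01, 0.001, 3e-4, 3e-4)),
                   class = c("roc_curve", "data.frame"))
  expect_equal(select_alpha(roc), 0.99)
  roc$fpr <- rep(0, 4)
  expect_equal(select_alpha(roc), 0.5)
  expect_equal(alpha_grid()[length(alpha_grid())], 0.9999999)
  expect_true(all(c(0.5, 0.9, 0.999, 0.9999999) %in% alpha_grid()))
})

test_that("in-silico mixtures sample pools disjointly", {
  pool <- quick_pool()
  pt <- pool$crops[, , pool$labels == "TUMOR"]
  pw <- pool$crops[, , pool$labels == "WBC"]
  mix <- make_mixture(pt, pw, 20, 80, seed = 5)
  expect_equal(dim(mix$crops)[3], 100)
  expect_equal(sum(mix$labels == "TUMOR"), 20)
  # several mixtures with accumulated exclusions never reuse a crop
  excl <- list(tumor = integer(), wbc = integer())
  seen_t <- seen_w <- integer()
  for (k in 1:3) {
    mk <- make_mixture(pt, pw, 10, 25, seed = k, exclude = excl)
    expect_length(intersect(mk$idx_tumor, seen_t), 0)
    expect_length(intersect(mk$idx_wbc, seen_w), 0)
    seen_t <- c(seen_t, mk$idx_tumor); seen_w <- c(seen_w, mk$idx_wbc)
    excl <- list(tumor = seen_t, wbc = seen_w)
  }
  # the single-cell mixture holds exactly one tumor crop
  m1 <- make_mixture(pt, pw, 1, 50, seed = 9)
  expect_equal(sum(m1$labels == "TUMOR"), 1)
  expect_error(make_mixture(pt, pw, 1e6, 1, seed = 1), "exhausted")
})

test_that("imaged volume follows time-based flow accounting", {
  fl <- flow_config()
  v <- imaged_volume(10100, fl)
  expect_equal(v, 10100 / 420 * 2.5 / 60)
  expect_lt(abs(v - 1), 0.01)
  expect_equal(imaged_volume(0, fl), 0)
  expect_equal(imaged_volume(2020, fl) * 2, imaged_volume(4040, fl))
  # geometric per-frame volume of the reference geometry is about 0.13 uL
  expect_equal(frame_volume(optical_config()), 800 * 500 * 330 * 1e-9)
})

test_that("enumeration converts gated counts to concentrations", {
  fl <- flow_config()
  sc <- c(rep(0.999999, 100), rep(0.2, 400))
  res <- enumerate_cells(sc, 0.99, 10100, fl)
  expect_equal(res$detected_count, 100)
  expect_equal(res$concentration_per_ml, 100 / imaged_volume(10100, fl))
  expect_equal(enumerate_cells(sc, 1, 10100, fl)$detected_count, 0)
  counts <- vapply(alpha_grid(),
                   function(a) enumerate_cells(sc, a, 10100, fl)$detected_count,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("limit of detection is mean plus two sample deviations", {
  lod <- limit_of_detection(c(1, 1, 2))
  expect_equal(lod$mu, 4 / 3)
  expect_equal(round(lod$lod, 2), 2.49)
  expect_equal(limit_of_detection(c(1, 1, 1))$lod, 1)
  expect_equal(limit_of_detection(mu = 2.33, sigma = 1)$lod, 4.33)
  expect_error(limit_of_detection(3), "at least 2")
  expect_error(limit_of_detection(), "supply")
})

test_that("false positives scale linearly with the WBC load", {
  # with a fixed per-crop FPR, FP counts across mixtures of increasing WBC
  # number are draws with a common rate: test homogeneity of proportions.
  # A borderline WBC population (size/contrast overlapping the tumor class)
  # gives the trained model a substantial, stable per-crop FPR.
  m <- quick_model()
  hard <- fixture("hard_wbc_pool", function()
    simulate_pobf_crops(120, seed = 409, optics = crop_optics(),
                        params = cell_params(
                          wbc = list(diameter_mean = 15, diameter_sd = 2,
                                     amplitude = 0.7, phase = 0))))
  pw <- hard$crops[, , hard$labels == "WBC"]
  pt <- hard$crops[, , hard$labels == "TUMOR"]
  n_wbc <- c(40, 80, 120)
  fp <- tn <- numeric(3)
  for (i in seq_along(n_wbc)) {
    mk <- make_mixture(pt, pw, 0, n_wbc[i], seed = 30 + i)
    p <- predict(m, mk$crops)$p_tumor
    fp[i] <- sum(p > 0.5); tn[i] <- sum(p <= 0.5)
  }
  expect_true(all(fp > 0))
  expect_true(all(tn > 0))
  ht <- suppressWarnings(stats::chisq.test(cbind(fp, tn)))
  expect_gt(ht$p.value, 0.05)
})
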