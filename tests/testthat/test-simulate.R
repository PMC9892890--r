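test_that("channel velocity profile has no-slip walls and conserves flow", {
  opt <- optical_config()
  fl <- flow_config()
  expect_equal(poiseuille_velocity(0, 165, fl, opt), 0)
  expect_equal(poiseuille_velocity(400, 0, fl, opt), 0)
  u_center <- poiseuille_velocity(400, 165, fl, opt)
  set.seed(1)
  ys <- runif(200, 0, 800); zs <- runif(200, 0, 330)
  expect_true(all(poiseuille_velocity(ys, zs, fl, opt) <= u_center))

  # cross-section quadrature reproduces the volumetric flow rate within 1%
  ny <- 200; nz <- 120
  yg <- (seq_len(ny) - 0.5) * 800 / ny
  zg <- (seq_len(nz) - 0.5) * 330 / nz
  u <- outer(yg, zg, function(y, z) poiseuille_velocity(y, z, fl, opt))
  q_num <- sum(u) * (800 / ny) * (330 / nz)        # um^3/s
  q_true <- fl$total_flow_rate * 1e12 / 60
  expect_lt(abs(q_num - q_true) / q_true, 0.01)

  # mean speed Q / (W H) is about 221 mm/s at the reference operating point
  expect_equal(q_true / (800 * 330) / 1e3, 221, tolerance = 0.005)
  expect_error(poiseuille_velocity(-5, 100, fl, opt), "outside")
})

test_that("the fastest cell crosses the field of view within one frame", {
  opt <- optical_config()
  fl <- flow_config()
  u_max <- poiseuille_velocity(400, 165, fl, opt)
  expect_gt(u_max / fl$frame_rate, opt$fov_px[2] * opt$pixel_pitch)
})

test_that("hologram projection reduces to the reference wave without cells", {
  opt <- test_optics_256()
  holo <- project_hologram(data.frame(), opt)
  expect_equal(holo, matrix(1, 256, 256))
})

test_that("a single cell's fringe pattern is centered on the cell", {
  opt <- test_optics_256()
  cell <- data.frame(x_um = 100.2, y_um = 140.8, z_um = 50, diameter_um = 16,
                     amplitude = 1, phase = 0)
  holo <- project_hologram(cell, opt)
  w <- abs(1 - holo)
  ci <- sum(row(w) * w) / sum(w)
  cj <- sum(col(w) * w) / sum(w)
  expect_lt(abs((cj - 0.5) - cell$x_um), 2)
  expect_lt(abs((ci - 0.5) - cell$y_um), 2)
})

test_that("fringe extent grows with propagation distance", {
  opt <- test_optics_256()
  rad_q90 <- function(z) {
    cell <- data.frame(x_um = 128, y_um = 128, z_um = z, diameter_um = 16,
                       amplitude = 1, phase = 0)
    w <- abs(1 - project_hologram(cell, opt))
    r <- sqrt((row(w) - 128.5)^2 + (col(w) - 128.5)^2)
    # radius enclosing 90% of the perturbation energy
    ord <- order(r)
    cs <- cumsum(w[ord]^2)
    r[ord][which(cs >= 0.9 * cs[length(cs)])[1]]
  }
  expect_gt(rad_q90(250), rad_q90(50))
})

test_that("projection rejects impossible cells", {
  opt <- crop_optics()
  expect_error(project_hologram(
    data.frame(x_um = 32, y_um = 32, z_um = 10, diameter_um = 100,
               amplitude = 0.5, phase = 0), opt), "larger than")
  expect_error(project_hologram(
    data.frame(x_um = 32, y_um = 32, z_um = 10, diameter_um = 0,
               amplitude = 0.5, phase = 0), opt), "diameters")
})

test_that("zero-contrast cells leave the background untouched", {
  opt <- optical_config(fov_px = c(64L, 64L))
  fl <- flow_config(n_frames = 8L)
  prm <- cell_params(tumor = list(diameter_mean = 18, diameter_sd = 2,
                                  amplitude = 0, phase = 0),
                     wbc = list(diameter_mean = 10, diameter_sd = 1.5,
                                amplitude = 0, phase = 0))
  stk <- simulate_stack(opt, fl, c(TUMOR = 1e6, WBC = 1e6), seed = 9,
                        params = prm, noise_frac = 0, quantize = FALSE)
  expect_gt(nrow(stk$cells), 0)
  for (f in seq_len(8))
    expect_equal(stk$frames[, , f], stk$illumination)
})

test_that("identical seeds give bit-identical stacks", {
  opt <- optical_config(fov_px = c(64L, 64L))
  fl <- flow_config(n_frames = 5L)
  s1 <- simulate_stack(opt, fl, c(TUMOR = 5e5, WBC = 5e5), seed = 31)
  s2 <- simulate_stack(opt, fl, c(TUMOR = 5e5, WBC = 5e5), seed = 31)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_stack(opt, fl, c(TUMOR = 5e5, WBC = 5e5), seed = 32)
  expect_false(identical(s1$frames, s3$frames))
})

test_that("ground truth logs every visible cell once per visible frame", {
  opt <- optical_config()
  fl <- flow_config(n_frames = 840L)  # 2 s of acquisition
  stk <- simulate_stack(opt, fl, c(TUMOR = 300, WBC = 700), seed = 77,
                        render = FALSE)
  fov_x <- opt$fov_px[2] * opt$pixel_pitch
  for (i in seq_len(nrow(stk$cells))) {
    cl <- stk$cells[i, ]
    k <- sum(stk$truth$cell_id == cl$cell_id)
    dx_frame <- cl$u_um_s / fl$frame_rate
    expected <- fov_x / dx_frame  # frames whose sample time falls in the FOV
    expect_true(abs(k - expected) <= 1)
  }
  # slow near-interface cells entering early enough are seen in more than
  # one consecutive frame
  early <- stk$cells$t0 < (fl$n_frames - 5) / fl$frame_rate
  slow <- stk$cells$cell_id[early &
                              stk$cells$u_um_s / fl$frame_rate < 0.5 * fov_x]
  if (length(slow)) {
    spans <- table(stk$truth$cell_id)[as.character(slow)]
    expect_true(all(spans >= 2))
    frames_of_first <- sort(stk$truth$frame[stk$truth$cell_id == slow[1]])
    expect_true(all(diff(frames_of_first) == 1))
  }
})

test_that("simulated arrival counts follow the Poisson spiking model", {
  opt <- optical_config()
  fl <- flow_config(n_frames = 2020L)  # 0.2 mL imaged
  lambda <- 100 * imaged_volume(fl$n_frames, fl)
  counts <- vapply(1:20, function(s)
    nrow(simulate_stack(opt, fl, c(TUMOR = 100), seed = 500 + s,
                        render = FALSE)$cells), numeric(1))
  expect_gt(mean(counts), 0.8 * lambda)
  expect_lt(mean(counts), 1.2 * lambda)
})

test_that("crop simulation produces labeled, normalized, in-focus images", {
  pool <- quick_pool()
  expect_equal(dim(pool$crops), c(36, 36, 240))
  expect_true(all(pool$crops >= 0 & pool$crops <= 1))
  expect_equal(as.vector(table(pool$labels)), c(120, 120))
  # PoBF selection recovers the true axial position of most crops
  expect_gt(mean(abs(pool$truth$z_um - pool$truth$z_est_um) <= 5), 0.9)
})
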