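test_that("uniform reconstructions yield no detections", {
  opt <- optical_config(fov_px = c(64L, 64L))
  rec <- reconstruct_volume(matrix(1, 64, 64), opt)
  expect_equal(nrow(detect_2d(rec)), 0)
  set.seed(2)
  noisy <- matrix(1 + rnorm(64^2, sd = 0.01), 64, 64)
  expect_equal(nrow(detect_2d(reconstruct_volume(noisy, opt))), 0)
})

test_that("single and well-separated cells are each detected once", {
  sc <- single_cell_recon()
  det <- detect_2d(sc$recon)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - sc$cell$x_um), 2)
  expect_lt(abs(det$y_um - sc$cell$y_um), 2)

  opt <- sc$optics
  cells <- data.frame(x_um = c(80, 180), y_um = c(128, 128),
                      z_um = c(100, 250), diameter_um = c(18, 10),
                      amplitude = c(0.8, 0.5), phase = 0)
  set.seed(9)
  holo <- project_hologram(cells, opt) +
    matrix(rnorm(256^2, sd = 0.01), 256, 256)
  det2 <- detect_2d(reconstruct_volume(holo, opt))
  expect_equal(nrow(det2), 2)
})

test_that("axial profiles respect margins and flatness off cells", {
  sc <- single_cell_recon()
  expect_error(axial_profile(sc$recon, c(5, 5)), "edge")
  prof_cell <- axial_profile(sc$recon, c(sc$cell$x_um, sc$cell$y_um))
  prof_empty <- axial_profile(sc$recon, c(210, 210))
  expect_length(prof_empty$focus, length(sc$recon$distances))
  # an empty window carries only noise: its focus curve stays far below the
  # cell's focus peak
  expect_lt(max(prof_empty$focus), 0.1 * max(prof_cell$focus))
})

test_that("plane selection takes the first optimum and a valid crop", {
  sc <- single_cell_recon()
  prof <- axial_profile(sc$recon, c(sc$cell$x_um, sc$cell$y_um))
  sel <- select_pobf(prof)
  expect_equal(dim(sel$crop), c(36, 36))
  expect_true(all(sel$crop >= 0 & sel$crop <= 1))
  expect_gte(sel$z_um, 0)
  expect_lte(sel$z_um, sc$optics$channel_height)
  # the focused crop is darker at the cell than the same window 50 um away
  off <- which.min(abs(prof$distances - (sel$distance_um + 50)))
  ctr <- 14:23
  crop_off <- sc$recon$planes[prof$rows, prof$cols, off]
  expect_lt(mean(sc$recon$planes[prof$rows, prof$cols,
                                 which(prof$distances == sel$distance_um)][ctr, ctr]),
            mean(crop_off[ctr, ctr]))
  # a monotone profile selects the endpoint
  fake <- structure(list(distances = prof$distances,
                         focus = seq_along(prof$distances),
                         metric = "tenengrad", rows = prof$rows,
                         cols = prof$cols, recon = sc$recon),
                    class = "axial_profile")
  expect_equal(select_pobf(fake)$distance_um, max(prof$distances))
  # ties break toward the smaller distance
  fake$focus <- rep(1, length(prof$distances))
  expect_equal(select_pobf(fake)$distance_um, min(prof$distances))
})

test_that("frame localization drops undroppable edge cells gracefully", {
  opt <- test_optics_256()
  cell <- data.frame(x_um = 10, y_um = 128, z_um = 100, diameter_um = 10,
                     amplitude = 0.5, phase = 0)  # too close to the edge
  set.seed(4)
  holo <- project_hologram(cell, opt) +
    matrix(rnorm(256^2, sd = 0.01), 256, 256)
  loc <- localize_frame(reconstruct_volume(holo, opt), frame_index = 3L)
  expect_equal(nrow(loc$detections), dim(loc$crops)[3])
  expect_true(all(loc$detections$frame == 3L))
})

test_that("detections match simulator ground truth by proximity", {
  truth <- data.frame(frame = c(1L, 1L), cell_id = c(7L, 9L),
                      class = c("TUMOR", "WBC"), x_um = c(50, 150),
                      y_um = c(60, 160), z_um = c(100, 200),
                      diameter_um = c(18, 10))
  det <- data.frame(frame = 1L, x_um = c(151, 400), y_um = c(159, 400),
                    z_um = c(195, 10))
  out <- match_truth(det, truth)
  expect_equal(out$truth_id, c(9L, NA_integer_))
  expect_equal(out$truth_label, c("WBC", NA_character_))
})
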