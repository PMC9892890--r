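# Shared fixtures, built lazily once per test session. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small-field optics used for single-cell imaging tests
test_optics_256 <- function(...) optical_config(fov_px = c(256L, 256L), ...)

crop_optics <- function(pixel_pitch = 1, plane_spacing = 5)
  optical_config(fov_px = c(64L, 64L), pixel_pitch = pixel_pitch,
                 plane_spacing = plane_spacing)

# 120 crops/class at reference optics; enough for quick classifier tests
quick_pool <- function() fixture("quick_pool", function()
  simulate_pobf_crops(120, seed = 401, optics = crop_optics()))

quick_model <- function() fixture("quick_model", function() {
  pool <- quick_pool()
  snet(pool$crops, pool$labels, epochs = 6, seed = 402)
})

# classifier matched to the scaled 2 um/px pipeline fixtures
quick_model_p2 <- function() fixture("quick_model_p2", function() {
  pool <- simulate_pobf_crops(120, seed = 406,
                              optics = crop_optics(pixel_pitch = 2,
                                                   plane_spacing = 30))
  snet(pool$crops, pool$labels, epochs = 6, seed = 402)
})

# single simulated cell imaged end-to-end at 256 px
single_cell_recon <- function() fixture("single_cell_recon", function() {
  opt <- test_optics_256()
  cell <- data.frame(x_um = 130.3, y_um = 120.7, z_um = 150,
                     diameter_um = 18, amplitude = 0.8, phase = 0)
  set.seed(403)
  holo <- project_hologram(cell, opt) +
    matrix(rnorm(256^2, sd = 0.01), 256, 256)
  list(optics = opt, cell = cell, holo = holo,
       recon = reconstruct_volume(holo, opt))
})
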