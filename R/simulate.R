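#' Default optical properties of the simulated cell classes
#'
#' Size and contrast parameters used by [simulate_stack()] and
#' [simulate_pobf_crops()] for the two cell classes: large, strongly scattering
#' tumor-like cells and smaller, fainter WBC-like cells. Diameters are drawn
#' from truncated normal distributions (truncated at 2.5 sd and at 2 um).
#' The published study does not report optical contrasts or size distributions
#' for its cell lines, so these are stand-in literature-typical values; they
#' are configurable and only need to yield class-separable in-focus images.
#'
#' @param tumor,wbc Lists with entries `diameter_mean`, `diameter_sd` (um),
#'   `amplitude` (fractional amplitude attenuation in `[0, 1]`) and `phase`
#'   (radians of phase delay inside the cell).
#' @return List of per-class parameter lists, class `cell_params`.
#' @export
cell_params <- function(tumor = list(diameter_mean = 18, diameter_sd = 2,
                                     amplitude = 0.8, phase = 0),
                        wbc = list(diameter_mean = 10, diameter_sd = 1.5,
                                   amplitude = 0.5, phase = 0)) {
  structure(list(TUMOR = tumor, WBC = wbc), class = "cell_params")
}

rtrunc_norm <- function(n, mean, sd, lower = max(2, mean - 2.5 * sd),
                        upper = mean + 2.5 * sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Streamwise velocity in the rectangular channel
#'
#' Laminar product-of-parabolas profile
#' `u(y, z) = u_max (1 - (2y/W - 1)^2)(1 - (2z/H - 1)^2)` with no-slip walls,
#' scaled so that the integral over the cross-section equals the total
#' volumetric flow rate, i.e. `u_max = (9/4) Q / (W H)`.
#'
#' @param y Cross-stream position(s), um, in `[0, channel_width]`.
#' @param z Axial position(s), um, in `[0, channel_height]`.
#' @param flow A [flow_config()] (total flow rate is used).
#' @param optics An [optical_config()] (channel geometry).
#' @return Streamwise speed(s), um/s.
#' @examples
#' opt <- optical_config(); fl <- flow_config()
#' poiseuille_velocity(0, 165, fl, opt)          # wall: 0
#' poiseuille_velocity(400, 165, fl, opt) / 1e3  # centerline, mm/s
#' @export
poiseuille_velocity <- function(y, z, flow, optics) {
  W <- optics$channel_width; H <- optics$channel_height
  if (any(y < 0 | y > W | z < 0 | z > H))
    stop("position outside channel cross-section")
  q_um3_s <- flow$total_flow_rate * 1e12 / 60  # mL/min -> um^3/s
  u_max <- 9 / 4 * q_um3_s / (W * H)
  u_max * (1 - (2 * y / W - 1)^2) * (1 - (2 * z / H - 1)^2)
}

#' Smooth illumination profile for the simulator
#'
#' A constant level modulated by a centered 2D Gaussian vignette, emulating the
#' non-uniform beam profile that background subtraction must remove.
#' @param optics An [optical_config()].
#' @param level Mean sensor counts of the illumination.
#' @param vignette Fractional peak-to-edge modulation depth.
#' @return Matrix of per-pixel illumination intensities.
#' @export
illumination_profile <- function(optics, level = 1000, vignette = 0.15) {
  ny <- optics$fov_px[1]; nx <- optics$fov_px[2]
  yy <- ((seq_len(ny) - 0.5) - ny / 2) / ny
  xx <- ((seq_len(nx) - 0.5) - nx / 2) / nx
  g <- exp(-outer(yy^2, xx^2, "+") / (2 * 0.35^2))
  level * ((1 - vignette) + vignette * g)
}

#' Forward-model an in-line hologram of a set of cells
#'
#' Each cell is an anti-aliased disk of the given diameter placed in its own
#' object plane with complex transmission `(1 - amplitude) exp(i phase)` inside
#' the disk and 1 outside. The single-scattering perturbation `t - 1` of every
#' cell is propagated to the hologram plane over its distance
#' `recording_distance + z` by the same angular-spectrum operator used for
#' reconstruction; perturbations from all cells are superposed on the
#' unit-amplitude reference wave before squaring to intensity.
#'
#' @param cells Data frame with columns `x_um`, `y_um`, `z_um`, `diameter_um`
#'   and optionally `amplitude` (default 0.8) and `phase` (default 0).
#' @param optics An [optical_config()].
#' @return Matrix of hologram intensities (unit background).
#' @export
project_hologram <- function(cells, optics) {
  ny <- optics$fov_px[1]; nx <- optics$fov_px[2]; pitch <- optics$pixel_pitch
  if (is.null(cells) || nrow(cells) == 0) return(matrix(1, ny, nx))
  if (is.null(cells$amplitude)) cells$amplitude <- 0.8
  if (is.null(cells$phase)) cells$phase <- 0
  if (any(cells$diameter_um <= 0)) stop("cell diameters must be > 0")
  if (any(cells$diameter_um >= min(ny, nx) * pitch))
    stop("cell larger than the field of view")
  if (any(cells$z_um < 0)) stop("cell z must be >= 0 (above channel floor)")
  pert_total <- matrix(0 + 0i, ny, nx)
  for (i in seq_len(nrow(cells))) {
    pert <- matrix(0 + 0i, ny, nx)
    r_px <- cells$diameter_um[i] / 2 / pitch
    ci <- cells$y_um[i] / pitch + 0.5  # row coordinate of center, px
    cj <- cells$x_um[i] / pitch + 0.5
    rlo <- max(1, floor(ci - r_px - 2)); rhi <- min(ny, ceiling(ci + r_px + 2))
    clo <- max(1, floor(cj - r_px - 2)); chi <- min(nx, ceiling(cj + r_px + 2))
    if (rlo > rhi || clo > chi) next  # cell entirely outside the field
    rows <- rlo:rhi
    cols <- clo:chi
    d <- sqrt(outer((rows - ci)^2, (cols - cj)^2, "+"))
    cover <- pmin(1, pmax(0, r_px + 0.5 - d))
    tin <- (1 - cells$amplitude[i]) * exp(1i * cells$phase[i])
    pert[rows, cols] <- (tin - 1) * cover
    dist <- optics$recording_distance + cells$z_um[i]
    pert_total <- pert_total +
      angular_spectrum_propagate(pert, dist, optics)
  }
  Mod(1 + pert_total)^2
}

sample_cells <- function(optics, flow, class_mix, params) {
  duration <- flow$n_frames / flow$frame_rate
  q_sample_mL_s <- flow$sample_flow_rate / 60
  core_lo <- (optics$channel_width - optics$sample_core_width) / 2
  core_hi <- core_lo + optics$sample_core_width
  out <- list()
  for (cls in names(class_mix)) {
    conc <- class_mix[[cls]]
    if (conc < 0) stop("concentrations must be nonnegative")
    if (conc == 0) next
    n <- rpois(1, conc * q_sample_mL_s * duration)
    if (n == 0) next
    p <- params[[cls]]
    diam <- rtrunc_norm(n, p$diameter_mean, p$diameter_sd)
    out[[cls]] <- data.frame(
      class = cls,
      t0 = runif(n, 0, duration),
      y_um = runif(n, core_lo, core_hi),
      z_um = runif(n, pmin(diam / 2 + 1, optics$channel_height / 2),
                   pmax(optics$channel_height - diam / 2 - 1,
                        optics$channel_height / 2)),
      diameter_um = diam,
      amplitude = p$amplitude,
      phase = p$phase)
  }
  cells <- if (length(out)) do.call(rbind, out) else
    data.frame(class = character(), t0 = numeric(), y_um = numeric(),
               z_um = numeric(), diameter_um = numeric(),
               amplitude = numeric(), phase = numeric())
  rownames(cells) <- NULL
  if (nrow(cells)) {
    cells <- cells[order(cells$t0), , drop = FALSE]
    cells$cell_id <- seq_len(nrow(cells))
    cells$u_um_s <- poiseuille_velocity(cells$y_um, cells$z_um, flow, optics)
  } else {
    cells$cell_id <- integer()
    cells$u_um_s <- numeric()
  }
  cells
}

#' Simulate a hologram stack of cells advected through the channel
#'
#' Generates a multi-frame in-line hologram acquisition: cells of each class
#' arrive as a Poisson process at rate `concentration x sample flow rate`, are
#' placed uniformly in the sheath-confined sample core, advected streamwise at
#' their local laminar flow speed, and imaged by [project_hologram()] under a
#' smooth illumination profile with additive Gaussian sensor noise. The ground
#' truth logs every cell once per frame in which its center lies inside the
#' field of view, so a slow cell spanning k consecutive frames contributes k
#' ground-truth rows (exercising multiple-count removal downstream).
#'
#' @param optics An [optical_config()].
#' @param flow A [flow_config()]; `flow$n_frames` frames are generated.
#' @param class_mix Named concentrations in cells/mL, e.g.
#'   `c(TUMOR = 100, WBC = 1000)`.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param params A [cell_params()] object.
#' @param level Mean illumination, sensor counts.
#' @param vignette Illumination modulation depth (see [illumination_profile()]).
#' @param noise_frac Gaussian sensor noise sd as a fraction of `level`.
#' @param render If `FALSE`, only the ground-truth tables are generated and
#'   `frames` is `NULL` (fast path for tracking/dedup studies).
#' @param quantize If `TRUE` (default), frames are rounded to nonnegative
#'   integer counts as a real sensor would record.
#' @param motion_blur If `TRUE`, each cell is averaged over three positions
#'   spanning its motion during `exposure_time` (off by default: the blur is
#'   about 15 um at the centerline speed and is neglected).
#' @param exposure_time Exposure time in seconds used when `motion_blur = TRUE`.
#' @return An object of class `hologram_stack`: list with `frames` (ny x nx x
#'   n_frames array or `NULL`), `frame_rate`, `truth` (per-frame ground-truth
#'   data frame), `cells` (per-cell table), `illumination`, `noise_sd`,
#'   `optics`, `flow`, `seed`.
#' @export
simulate_stack <- function(optics, flow, class_mix = c(TUMOR = 0, WBC = 0),
                           seed = 1L, params = cell_params(),
                           level = 1000, vignette = 0.15, noise_frac = 0.01,
                           render = TRUE, quantize = TRUE,
                           motion_blur = FALSE, exposure_time = 35e-6) {
  set.seed(seed)
  cells <- sample_cells(optics, flow, as.list(class_mix), params)
  ny <- optics$fov_px[1]; nx <- optics$fov_px[2]
  fov_x <- nx * optics$pixel_pitch
  n_frames <- flow$n_frames
  t_frame <- (seq_len(n_frames) - 1) / flow$frame_rate

  # ground truth: frame-by-frame positions of cells whose center is in the FOV
  truth <- list()
  if (nrow(cells)) {
    fov_y <- ny * optics$pixel_pitch
    for (i in seq_len(nrow(cells))) {
      if (cells$y_um[i] < 0 || cells$y_um[i] > fov_y) next
      x_f <- cells$u_um_s[i] * (t_frame - cells$t0[i])
      vis <- which(x_f >= 0 & x_f <= fov_x)
      if (length(vis))
        truth[[length(truth) + 1L]] <- data.frame(
          frame = vis, cell_id = cells$cell_id[i], class = cells$class[i],
          x_um = x_f[vis], y_um = cells$y_um[i], z_um = cells$z_um[i],
          diameter_um = cells$diameter_um[i])
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(), cell_id = integer(), class = character(),
               x_um = numeric(), y_um = numeric(), z_um = numeric(),
               diameter_um = numeric())
  truth <- truth[order(truth$frame, truth$cell_id), , drop = FALSE]
  rownames(truth) <- NULL

  illum <- illumination_profile(optics, level, vignette)
  noise_sd <- noise_frac * level
  frames <- NULL
  if (render) {
    frames <- array(if (quantize) 0L else 0, dim = c(ny, nx, n_frames))
    margin <- max(c(cells$diameter_um / 2, 0))
    for (f in seq_len(n_frames)) {
      holo <- 1
      if (nrow(cells)) {
        x_f <- cells$u_um_s * (t_frame[f] - cells$t0)
        vis <- which(x_f > -margin & x_f < fov_x + margin)
        if (length(vis)) {
          cf <- cells[vis, , drop = FALSE]
          cf$x_um <- x_f[vis]
          if (motion_blur) {
            dt <- exposure_time * c(-0.5, 0, 0.5)
            acc <- 0
            for (d in dt) {
              cfd <- cf; cfd$x_um <- cf$x_um + cf$u_um_s * d
              acc <- acc + project_hologram(cfd, optics)
            }
            holo <- acc / 3
          } else {
            holo <- project_hologram(cf, optics)
          }
        }
      }
      img <- illum * holo + rnorm(ny * nx, sd = noise_sd)
      if (quantize) {
        frames[, , f] <- as.integer(pmax(0, round(img)))
      } else {
        frames[, , f] <- img
      }
    }
  }
  structure(list(frames = frames, frame_rate = flow$frame_rate, truth = truth,
                 cells = cells, illumination = illum, noise_sd = noise_sd,
                 optics = optics, flow = flow, seed = seed),
            class = "hologram_stack")
}

#' @export
print.hologram_stack <- function(x, ...) {
  nf <- if (is.null(x$frames)) x$flow$n_frames else dim(x$frames)[3]
  cat(sprintf("Hologram stack: %d frames of %d x %d px at %g fps%s\n",
              nf, x$optics$fov_px[1], x$optics$fov_px[2], x$frame_rate,
              if (is.null(x$frames)) " (ground truth only)" else ""))
  cat(sprintf("  %d simulated cells (%s), %d ground-truth detections\n",
              nrow(x$cells),
              paste(sprintf("%s: %d", names(table(x$cells$class)),
                            as.integer(table(x$cells$class))), collapse = ", "),
              nrow(x$truth)))
  invisible(x)
}

#' Simulate labeled plane-of-best-focus training crops
#'
#' Generates pure-population 36 x 36 in-focus cell images by running single
#' simulated cells through the package's own imaging chain: forward hologram
#' projection at a random axial height, sensor noise, volume reconstruction
#' over the full channel depth and plane-of-best-focus selection via the axial
#' focus profile. The result is the synthetic counterpart of the pure
#' population crop libraries used for classifier training and in-silico
#' mixtures.
#'
#' @param n_per_class Number of crops per class.
#' @param seed Integer seed.
#' @param params A [cell_params()] object.
#' @param optics Small-field optical configuration used per crop; default is a
#'   64 x 64 px field with otherwise reference geometry.
#' @param noise_frac Additive Gaussian noise sd relative to unit background.
#' @return List with `crops` (36 x 36 x 2 n array, each min-max scaled to
#'   `[0, 1]`), `labels` (factor, levels `TUMOR`, `WBC`), and per-crop truth
#'   (`z_um`, `z_est_um`, `diameter_um`).
#' @export
simulate_pobf_crops <- function(n_per_class, seed = 1L,
                                params = cell_params(),
                                optics = optical_config(fov_px = c(64L, 64L)),
                                noise_frac = 0.01) {
  set.seed(seed)
  classes <- rep(c("TUMOR", "WBC"), each = n_per_class)
  n <- length(classes)
  crops <- array(0, dim = c(36, 36, n))
  z_true <- z_est <- diam <- numeric(n)
  ny <- optics$fov_px[1]; nx <- optics$fov_px[2]
  cx <- nx / 2 * optics$pixel_pitch; cy <- ny / 2 * optics$pixel_pitch
  for (i in seq_len(n)) {
    p <- params[[classes[i]]]
    d <- rtrunc_norm(1, p$diameter_mean, p$diameter_sd)
    z <- runif(1, d / 2 + 5, optics$channel_height - d / 2 - 5)
    cell <- data.frame(x_um = cx + runif(1, -1, 1),
                       y_um = cy + runif(1, -1, 1),
                       z_um = z, diameter_um = d,
                       amplitude = p$amplitude, phase = p$phase)
    holo <- project_hologram(cell, optics) + rnorm(ny * nx, sd = noise_frac)
    recon <- reconstruct_volume(holo, optics)
    prof <- axial_profile(recon, c(cell$x_um, cell$y_um))
    sel <- select_pobf(prof)
    crops[, , i] <- sel$crop
    z_true[i] <- z; z_est[i] <- sel$z_um; diam[i] <- d
  }
  list(crops = crops, labels = factor(classes, levels = c("TUMOR", "WBC")),
       truth = data.frame(class = classes, z_um = z_true, z_est_um = z_est,
                          diameter_um = diam))
}
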