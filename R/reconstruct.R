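fft_freqs <- function(n, pitch) {
  f <- ((seq_len(n) - 1L + floor(n / 2)) %% n) - floor(n / 2)
  f / (n * pitch)
}

as_transfer <- function(dims, distance, optics) {
  lam <- optics$wavelength / optics$medium_refractive_index
  fy <- fft_freqs(dims[1], optics$pixel_pitch)
  fx <- fft_freqs(dims[2], optics$pixel_pitch)
  kz2 <- 1 / lam^2 - outer(fy^2, fx^2, "+")
  H <- matrix(0 + 0i, dims[1], dims[2])
  prop <- kz2 > 0
  # The plane-wave carrier phase exp(i k d) is factored out so that the DC
  # component is invariant: perturbation fields then interfere with the
  # (unpropagated) unit reference at the correct relative phase, and a
  # refocused absorbing object is dark against the background.
  H[prop] <- exp(2i * pi * distance * (sqrt(kz2[prop]) - 1 / lam))
  H
}

#' Angular-spectrum propagation of a complex optical field
#'
#' Propagates a sampled scalar field over a signed distance using the exact
#' transfer function of free-space (in-medium) propagation,
#' `H(fx, fy; d) = exp(i 2 pi d sqrt((n/lambda)^2 - fx^2 - fy^2))`,
#' applied in the Fourier domain. Evanescent components (negative radicand)
#' are suppressed, which makes forward-then-backward propagation the identity
#' on all propagating modes. Positive distances propagate away from the
#' source toward the hologram plane; negative distances back-propagate.
#'
#' @param field Complex (or real) matrix.
#' @param distance Signed propagation distance, um.
#' @param optics An [optical_config()].
#' @return Complex matrix of the propagated field.
#' @export
angular_spectrum_propagate <- function(field, distance, optics) {
  if (!all(is.finite(Mod(field)))) stop("field contains non-finite values")
  if (abs(distance) > 1e6) stop("distance out of range")
  if (distance == 0) return(field + 0i)
  H <- as_transfer(dim(field), distance, optics)
  fft(fft(field) * H, inverse = TRUE) / length(field)
}

# The per-plane transfer functions depend only on the field size and the
# optical configuration, so they are cached across frames (reconstruction of
# a stack reuses one transfer stack for every frame). Small LRU: 4 entries.
.transfer_cache <- new.env(parent = emptyenv())

transfer_stack <- function(dims, dists, optics) {
  key <- paste(c(dims, dists, optics$wavelength, optics$pixel_pitch,
                 optics$medium_refractive_index), collapse = "|")
  hit <- .transfer_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hs <- lapply(dists, function(d) as_transfer(dims, -d, optics))
  keys <- ls(.transfer_cache)
  if (length(keys) >= 4) rm(list = keys[1], envir = .transfer_cache)
  assign(key, Hs, envir = .transfer_cache)
  Hs
}

#' Reconstruct the full channel volume from one cleaned hologram
#'
#' Back-propagates the normalized contrast field to every reconstruction plane
#' between the channel floor (at the recording distance) and the channel
#' ceiling, in steps of the configured plane spacing, and stores the
#' reconstructed intensity of each plane. In-line acquisition retains the
#' twin image, so reconstruction uses amplitude only: the real-valued contrast
#' is taken as the field amplitude with zero phase.
#'
#' @param contrast Real matrix from [contrast_field()] (or a hologram with
#'   unit background).
#' @param optics An [optical_config()].
#' @return Object of class `recon_stack`: list with `planes` (ny x nx x
#'   n_planes intensity array), `distances` (um) and `optics`.
#' @export
reconstruct_volume <- function(contrast, optics) {
  dists <- plane_distances(optics)
  dims <- dim(contrast)
  planes <- array(0, dim = c(dims, length(dists)))
  spec <- fft(contrast + 0i)
  npx <- prod(dims)
  Hs <- transfer_stack(dims, dists, optics)
  for (k in seq_along(dists)) {
    f <- fft(spec * Hs[[k]], inverse = TRUE)
    planes[, , k] <- (Re(f)^2 + Im(f)^2) / npx^2
  }
  structure(list(planes = planes, distances = dists, optics = optics),
            class = "recon_stack")
}

#' @export
print.recon_stack <- function(x, ...) {
  cat(sprintf("Reconstructed volume: %d planes (%g..%g um) of %d x %d px\n",
              length(x$distances), min(x$distances), max(x$distances),
              dim(x$planes)[1], dim(x$planes)[2]))
  invisible(x)
}
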