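#' Camera and PSF configuration for single-molecule rendering
#'
#' @param psf_sigma_nm Gaussian point-spread-function sigma (default
#'   120 nm).
#' @param pixel_size_nm Camera pixel size (default 100 nm).
#' @param photons_per_frame Expected photons emitted per molecule per
#'   frame (> 0).
#' @param readout_sigma_e Gaussian readout noise sd in electrons (camera
#'   gain fixed at 1 e-/count, so this maps directly to counts; default
#'   1.1 e-).
#' @param exposure_s Exposure time per frame, s.
#' @param n_substeps Sub-exposure sampling points used to integrate the
#'   motion of a molecule within one frame (motion blur); default 10.
#' @param background_photons Mean background (autofluorescence) photons
#'   per pixel per frame, subject to shot noise (default 0).
#' @param fov_px Field of view in pixels `c(rows, cols)`.
#' @return List of class `imaging_config`.
#' @export
imaging_config <- function(psf_sigma_nm = 120, pixel_size_nm = 100,
                           photons_per_frame = 500, readout_sigma_e = 1.1,
                           exposure_s = 0.01, n_substeps = 10,
                           background_photons = 0,
                           fov_px = c(64, 64)) {
  if (psf_sigma_nm <= 0) stopf("psf_sigma_nm must be > 0")
  if (readout_sigma_e < 0) stopf("readout_sigma_e must be >= 0")
  if (exposure_s <= 0) stopf("exposure_s must be > 0")
  if (photons_per_frame <= 0) stopf("photons_per_frame must be > 0")
  if (background_photons < 0) stopf("background_photons must be >= 0")
  structure(list(psf_sigma_nm = psf_sigma_nm, pixel_size_nm = pixel_size_nm,
                 photons_per_frame = photons_per_frame,
                 readout_sigma_e = readout_sigma_e,
                 exposure_s = exposure_s, n_substeps = n_substeps,
                 background_photons = background_photons,
                 fov_px = fov_px),
            class = "imaging_config")
}

# Add one Gaussian PSF (truncated at 4 sigma) to an image, in place.
add_psf <- function(img, x_px, y_px, photons, sigma_px) {
  r <- ceiling(4 * sigma_px)
  nr <- nrow(img); nc <- ncol(img)
  i0 <- max(1L, floor(y_px - r)); i1 <- min(nr, ceiling(y_px + r))
  j0 <- max(1L, floor(x_px - r)); j1 <- min(nc, ceiling(x_px + r))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  gy <- exp(-((ii - 0.5) - y_px)^2 / (2 * sigma_px^2))
  gx <- exp(-((jj - 0.5) - x_px)^2 / (2 * sigma_px^2))
  g <- outer(gy, gx)
  img[ii, jj] <- img[ii, jj] + photons * g / (2 * pi * sigma_px^2)
  img
}

#' Render camera frames from single-molecule trajectories
#'
#' Each molecule active in a frame deposits its photons along its path:
#' the exposure is divided into `n_substeps`, the position is linearly
#' interpolated towards the next frame's position at each sub-step
#' (producing motion blur for fast molecules), and a 2D Gaussian PSF is
#' accumulated at each sub-position. Poisson shot noise is then applied
#' per pixel, followed by additive Gaussian readout noise.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`) as
#'   produced by [simulate_tracks()].
#' @param config An [imaging_config()].
#' @param noise Apply shot and readout noise (`TRUE`) or return the
#'   noiseless photon image (`FALSE`).
#' @param seed Integer seed for the noise.
#' @return List of frames (matrices, photon counts); the noiseless stack
#'   is attached as attribute `clean` when `noise = TRUE`.
#' @export
render_smt_frames <- function(tracks, config = imaging_config(),
                              noise = TRUE, seed = NULL) {
  stopifnot(inherits(config, "imaging_config"))
  px_um <- config$pixel_size_nm / 1000
  sigma_px <- config$psf_sigma_nm / config$pixel_size_nm
  nr <- config$fov_px[1]; nc <- config$fov_px[2]
  nframes <- max(tracks$frame) + 1L
  nsub <- max(1L, config$n_substeps)
  bg <- config$background_photons %||% 0

  tracks <- arrange(tracks, .data$track_id, .data$frame)
  clean <- replicate(nframes, matrix(bg, nr, nc), simplify = FALSE)
  ids <- tracks$track_id
  for (tr in unique(ids)) {
    sub <- tracks[ids == tr, ]
    n <- nrow(sub)
    for (s in seq_len(n)) {
      f <- sub$frame[s] + 1L
      x0 <- sub$x_um[s] / px_um; y0 <- sub$y_um[s] / px_um
      if (s < n) {
        x1 <- sub$x_um[s + 1] / px_um; y1 <- sub$y_um[s + 1] / px_um
      } else {
        x1 <- x0; y1 <- y0
      }
      frac <- (seq_len(nsub) - 1) / nsub
      per <- config$photons_per_frame / nsub
      img <- clean[[f]]
      for (q in seq_len(nsub)) {
        img <- add_psf(img, x0 + frac[q] * (x1 - x0),
                       y0 + frac[q] * (y1 - y0), per, sigma_px)
      }
      clean[[f]] <- img
    }
  }
  if (!noise) return(clean)
  noisy <- with_seed(seed, lapply(clean, function(img) {
    shot <- matrix(rpois(length(img), img), nrow(img))
    shot + matrix(rnorm(length(img), 0, config$readout_sigma_e), nrow(img))
  }))
  attr(noisy, "clean") <- clean
  noisy
}

#' Peak signal-to-noise ratio of a rendered frame
#'
#' `20 * log10(peak / sd(noise))`, where the peak is the maximum of the
#' clean image and the noise sd is that of the residual.
#'
#' @param clean,noisy Same-shaped matrices.
#' @return PSNR in dB; `Inf` when the residual is exactly zero.
#' @export
psnr <- function(clean, noisy) {
  stopifnot(all(dim(clean) == dim(noisy)))
  peak <- max(clean)
  if (peak <= 0) stopf("clean image must have a positive peak")
  s <- sd(as.vector(noisy - clean))
  if (s == 0) return(Inf)
  20 * log10(peak / s)
}
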