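#' Generate a synthetic nucleus mask
#'
#' Builds a binary elliptical nucleus on a pixel grid, optionally with a
#' chromosomal band sub-ROI (a vertical stripe, emulating a polytene band)
#' and a circular locus ROI centred on the band. The mask is the geometry
#' on which FRAP movies are simulated and single-molecule trajectories are
#' confined.
#'
#' @param nrow,ncol Grid size in pixels (each at least 16).
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param semiaxes Ellipse semi-axes in pixels `c(row, col)`; defaults to
#'   45% of each grid dimension.
#' @param band_center_col,band_width_px Column centre and width (pixels) of
#'   an optional band ROI; `NULL` for none.
#' @param locus_radius_px Radius (pixels) of an optional circular locus ROI
#'   at the band centre; `NULL` for none.
#' @param irregularity Amplitude (0-0.5) of a smooth random radial
#'   perturbation of the ellipse boundary; 0 gives a deterministic ellipse.
#' @param seed Integer seed used only when `irregularity > 0`.
#'
#' @return An object of class `nucleus_mask`: a list with `mask` (logical
#'   matrix), `pixel_size_um`, and optional logical matrices `band` and
#'   `locus` (always subsets of `mask`).
#' @export
make_nucleus <- function(nrow, ncol, pixel_size_um = 0.25,
                         semiaxes = NULL,
                         band_center_col = NULL, band_width_px = NULL,
                         locus_radius_px = NULL,
                         irregularity = 0, seed = NULL) {
  if (nrow < 16 || ncol < 16) stopf("grid must be at least 16x16 pixels")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  semiaxes <- semiaxes %||% c(0.45 * nrow, 0.45 * ncol)
  if (any(semiaxes <= 0)) stopf("degenerate geometry: ellipse semi-axes must be > 0")

  ci <- (nrow + 1) / 2
  cj <- (ncol + 1) / 2
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  u <- (rows - ci) / semiaxes[1]
  v <- (cols - cj) / semiaxes[2]
  rr <- sqrt(u^2 + v^2)

  rlim <- matrix(1, nrow, ncol)
  if (irregularity > 0) {
    # low-order Fourier perturbation of the boundary radius
    ang <- atan2(u, v)
    coef <- with_seed(seed, rnorm(6, sd = irregularity / 2))
    pert <- coef[1] * cos(ang) + coef[2] * sin(ang) +
      coef[3] * cos(2 * ang) + coef[4] * sin(2 * ang) +
      coef[5] * cos(3 * ang) + coef[6] * sin(3 * ang)
    rlim <- 1 + pmax(pmin(pert, 0.5), -0.5)
  }
  mask <- rr <= rlim
  if (!any(mask)) stopf("degenerate geometry: empty mask")

  band <- locus <- NULL
  if (!is.null(band_center_col)) {
    band_width_px <- band_width_px %||% max(2L, round(ncol / 12))
    band <- mask & abs(cols - band_center_col) <= band_width_px / 2
    if (!any(band)) stopf("band ROI does not intersect the mask")
  }
  if (!is.null(locus_radius_px)) {
    if (is.null(band_center_col)) band_center_col <- cj
    locus <- mask &
      (rows - ci)^2 + (cols - band_center_col)^2 <= locus_radius_px^2
    if (!any(locus)) stopf("locus ROI does not intersect the mask")
  }

  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 band = band, locus = locus),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d x %d px (%.3g um/px), area %d px",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um, sum(x$mask)))
  if (!is.null(x$band)) cat(sprintf(", band %d px", sum(x$band)))
  if (!is.null(x$locus)) cat(sprintf(", locus %d px", sum(x$locus)))
  cat("\n")
  invisible(x)
}

#' Steady-state intensity map of a partially bound factor
#'
#' Constructs the equilibrium fluorescence image of a nucleus in which a
#' fraction of molecules is DNA-bound. The free pool is spatially uniform;
#' the bound pool is uniform except inside the band ROI, where its density
#' is multiplied by `enrichment`. Intensities are normalized so the mean
#' over the mask is 1.
#'
#' @param nucleus A [make_nucleus()] object.
#' @param bound_fraction Percentage of molecules bound at equilibrium
#'   (0 <= bf < 100).
#' @param enrichment Multiplicative enrichment of the bound pool inside the
#'   band ROI (>= 1); ignored when the nucleus has no band.
#' @return A list with `i_st` (intensity matrix, zero off-mask), `i_avg_st`
#'   (its mask mean, 1 by construction), and `free_level` (the uniform free
#'   intensity, `1 - bound_fraction/100`).
#' @export
make_steady_intensity <- function(nucleus, bound_fraction, enrichment = 1) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  if (bound_fraction < 0 || bound_fraction >= 100)
    stopf("bound_fraction must be in [0, 100); 100%% bound leaves no free pool")
  if (enrichment < 1) stopf("enrichment must be >= 1")
  mask <- nucleus$mask
  free <- 1 - bound_fraction / 100
  w <- matrix(1, nrow(mask), ncol(mask))
  if (!is.null(nucleus$band) && enrichment > 1) w[nucleus$band] <- enrichment
  w_mean <- mean(w[mask])
  bound <- (bound_fraction / 100) * w / w_mean
  i_st <- matrix(0, nrow(mask), ncol(mask))
  i_st[mask] <- free + bound[mask]
  list(i_st = i_st, i_avg_st = mean(i_st[mask]), free_level = free)
}
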