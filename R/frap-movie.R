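#' Bleach geometry descriptor
#'
#' Describes the photobleach applied between the pre- and post-bleach
#' frames as a multiplicative depletion profile on the nucleus grid.
#' `"column"` emulates a confocal point bleach that depletes a cylindrical
#' column through the nucleus (a uniform disk in the imaged plane),
#' `"point"` a Gaussian-edged spot, and `"half"` bleaching of one half of
#' the nucleus.
#'
#' @param type One of `"column"`, `"point"`, `"half"`.
#' @param center Bleach centre `c(row, col)` in pixels (ignored for
#'   `"half"`, which bleaches columns left of `center[2]`, defaulting to
#'   the mask centroid).
#' @param radius_px Bleach radius in pixels (disk radius, or Gaussian
#'   sigma for `"point"`).
#' @param depth Fraction of fluorescence removed at the bleach centre, in
#'   \[0, 1\]; 0 means no bleach.
#' @return An object of class `bleach_geometry`.
#' @export
bleach_geometry <- function(type = c("column", "point", "half"),
                            center = NULL, radius_px = 4, depth = 0.6) {
  type <- match.arg(type)
  if (depth < 0 || depth > 1) stopf("bleach depth must be in [0, 1]")
  structure(list(type = type, center = center, radius_px = radius_px,
                 depth = depth),
            class = "bleach_geometry")
}

# Multiplicative depletion matrix in (0, 1] for a bleach geometry.
bleach_profile <- function(bleach, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  center <- bleach$center
  if (is.null(center)) {
    center <- c(mean(rows[mask]), mean(cols[mask]))
  }
  prof <- matrix(1, nr, nc)
  if (bleach$type == "column") {
    inside <- (rows - center[1])^2 + (cols - center[2])^2 <= bleach$radius_px^2
    prof[inside] <- 1 - bleach$depth
  } else if (bleach$type == "point") {
    r2 <- (rows - center[1])^2 + (cols - center[2])^2
    prof <- 1 - bleach$depth * exp(-r2 / (2 * bleach$radius_px^2))
  } else {  # half
    prof[cols <= center[2]] <- 1 - bleach$depth
  }
  if (!any(prof[mask] < 1) && bleach$depth > 0)
    stopf("bleach geometry does not intersect the mask")
  prof
}

#' FRAP acquisition schedule
#'
#' The standard protocols: `"point"` = 10 pre-bleach frames and 300
#' post-bleach frames at 0.098 s intervals followed by 100 frames at 1 s
#' intervals; `"band"` = the same pre-bleach block with 300 post-bleach
#' frames at 0.115 s then 100 at 2 s.
#'
#' @param protocol `"point"`, `"band"`, or `"custom"`.
#' @param n_prebleach,post_times For `"custom"`: pre-bleach frame count
#'   and the post-bleach times (s, from the first post-bleach frame at 0).
#' @return List with `n_prebleach`, `pre_times` (s, negative), and
#'   `post_times` (s, starting at 0).
#' @export
frap_schedule <- function(protocol = c("point", "band", "custom"),
                          n_prebleach = 10, post_times = NULL) {
  protocol <- match.arg(protocol)
  if (protocol == "point") {
    post_times <- c(seq(0, by = 0.098, length.out = 300),
                    seq(0.098 * 300, by = 1, length.out = 100))
  } else if (protocol == "band") {
    post_times <- c(seq(0, by = 0.115, length.out = 300),
                    seq(0.115 * 300, by = 2, length.out = 100))
  } else if (is.null(post_times)) {
    stopf("custom schedule requires post_times")
  }
  if (is.unsorted(post_times, strictly = TRUE) && length(post_times) > 1)
    stopf("schedule times must be strictly increasing")
  list(n_prebleach = n_prebleach,
       pre_times = -rev(seq_len(n_prebleach)) * 0.098,
       post_times = as.numeric(post_times))
}

#' Render a synthetic FRAP movie with known ground truth
#'
#' Simulates the full imaging experiment: equilibrium pre-bleach frames of
#' the steady-state intensity map, a multiplicative bleach, and
#' post-bleach frames obtained by integrating the reaction-diffusion
#' model on the nucleus grid. Optional Poisson shot noise is applied per
#' pixel at a configurable photon scale.
#'
#' @param nucleus A [make_nucleus()] object (the movie is rendered at this
#'   grid's resolution).
#' @param D Diffusion constant, um^2/s.
#' @param koff Unbinding rate 1/s (residence time = 1/koff).
#' @param bound_fraction Percent bound at equilibrium.
#' @param bleach A [bleach_geometry()].
#' @param schedule A [frap_schedule()].
#' @param enrichment Band enrichment factor passed to
#'   [make_steady_intensity()].
#' @param photon_scale Expected photons per unit normalized intensity per
#'   pixel; `Inf` renders a noiseless movie.
#' @param seed Seed for the Poisson noise (ignored when noiseless).
#' @return Object of class `frap_movie`: list with `frames` (list of
#'   matrices, pre-bleach then post-bleach), `times` (s, bleach at 0),
#'   `is_prebleach` (logical), `nucleus`, and `ground_truth` (list of the
#'   generating parameters and the depletion profile).
#' @export
render_frap_movie <- function(nucleus, D, koff, bound_fraction,
                              bleach = bleach_geometry(),
                              schedule = frap_schedule("point"),
                              enrichment = 1,
                              photon_scale = Inf, seed = NULL) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  if (koff < 0 || D < 0) stopf("D and koff must be non-negative")
  mask <- nucleus$mask
  steady <- make_steady_intensity(nucleus, bound_fraction, enrichment)
  prof <- bleach_profile(bleach, mask)

  pre <- replicate(schedule$n_prebleach, steady$i_st, simplify = FALSE)

  if (koff == 0 && bound_fraction > 0)
    stopf("koff = 0 with a bound pool leaves bleached molecules immobile forever; use bound_fraction = 0 for pure diffusion")
  koff_eff <- if (bound_fraction == 0) 1 else koff  # k1 is 0; koff inert
  fields <- frap_fields(steady, mask, nucleus$pixel_size_um, D, koff_eff,
                        depletion = prof)
  sim <- simulate_recovery(fields, schedule$post_times,
                           rois = list(which(mask)),
                           return_frames = TRUE)
  post <- attr(sim, "frames")

  frames <- c(pre, post)
  if (is.finite(photon_scale)) {
    frames <- with_seed(seed, lapply(frames, function(f) {
      noisy <- f
      noisy[mask] <- rpois(sum(mask), photon_scale * f[mask]) / photon_scale
      noisy
    }))
  }
  structure(list(
    frames = frames,
    times = c(schedule$pre_times, schedule$post_times),
    is_prebleach = c(rep(TRUE, schedule$n_prebleach),
                     rep(FALSE, length(schedule$post_times))),
    nucleus = nucleus,
    ground_truth = list(D = D, koff = koff, bound_fraction = bound_fraction,
                        residence_s = if (koff > 0) 1 / koff else Inf,
                        enrichment = enrichment, bleach = bleach,
                        depletion = prof, photon_scale = photon_scale)
  ), class = "frap_movie")
}

#' @export
print.frap_movie <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "<frap_movie> %d frames (%d pre-bleach), %dx%d px\n  truth: D=%.3g um^2/s, bound=%.3g%%, residence=%.3g s\n",
    length(x$frames), sum(x$is_prebleach),
    nrow(x$frames[[1]]), ncol(x$frames[[1]]),
    gt$D, gt$bound_fraction, gt$residence_s))
  invisible(x)
}
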