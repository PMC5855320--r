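#' Image-derived initialization of the reaction-diffusion simulation
#'
#' Builds the binned steady-state intensity map and post-bleach initial
#' condition from movie frames, following the standard pipeline: Gaussian
#' smoothing, block binning (10x10 by default, 5x5 supported), averaging
#' of the first three post-bleach frames, and a rescale of the binned
#' fluorescence inside the bleached area by a factor close to 1 so it
#' exactly matches the full-resolution bleach-area fluorescence.
#'
#' @param prebleach List of pre-bleach frames (matrices).
#' @param postbleach List of post-bleach frames (>= 3; only the first
#'   three are used for initialization).
#' @param mask Logical nucleus mask at full resolution.
#' @param pixel_size_um Full-resolution pixel size (um).
#' @param bin_factor Binning factor; 10 or 5 are the tested settings, any
#'   other value emits a warning and proceeds.
#' @param smooth_sigma_px Gaussian smoothing sigma in pixels (default 5).
#' @param bleach_threshold Relative depletion defining the bleached area:
#'   pixels whose post/pre ratio is below
#'   `1 - bleach_threshold * max_depletion` belong to the bleach area
#'   (default 0.5, the half-depth contour).
#' @return Object of class `frap_init` with the binned steady map
#'   (mask-mean normalized to 1), binned initial total, local bleach-depth
#'   map, binned mask and spacing, the bleach-area scale factor, the
#'   estimated bleach centre/radius, and the two measurement ROIs (bleach
#'   spot and the farthest "opposite end" circle of the same radius).
#' @export
initialize_fields <- function(prebleach, postbleach, mask, pixel_size_um,
                              bin_factor = 10, smooth_sigma_px = 5,
                              bleach_threshold = 0.5) {
  if (length(prebleach) < 1) stopf("at least one pre-bleach frame required")
  if (length(postbleach) < 3) stopf("at least three post-bleach frames required")
  if (!(bin_factor %in% c(5, 10)))
    warn(sprintf("bin_factor %d is outside the tested settings {5, 10}; proceeding",
                 as.integer(bin_factor)))

  pre_mean <- Reduce(`+`, prebleach) / length(prebleach)
  post_mean <- Reduce(`+`, postbleach[1:3]) / 3

  # mask-normalized smoothing: convolving the masked image and the mask
  # indicator separately and taking their ratio avoids the edge darkening
  # a plain Gaussian blur causes at the nucleus boundary
  msm <- gauss_smooth(mask + 0, smooth_sigma_px)
  nsmooth <- function(img) {
    out <- gauss_smooth(img * mask, smooth_sigma_px)
    out[mask] <- out[mask] / msm[mask]
    out[!mask] <- 0
    out
  }
  pre_s <- nsmooth(pre_mean)
  post_s <- nsmooth(post_mean)

  # full-resolution bleach area from the pre/post ratio
  ratio <- matrix(1, nrow(mask), ncol(mask))
  ok <- mask & pre_s > 0
  ratio[ok] <- post_s[ok] / pre_s[ok]
  max_depl <- 1 - min(ratio[mask])
  if (max_depl > 0.02) {
    bleach_area <- mask & ratio <= 1 - bleach_threshold * max_depl
  } else {
    bleach_area <- mask & FALSE  # no detectable bleach
  }

  # coverage-weighted binning: block mean over the in-mask pixels only
  coverage <- bin_matrix(mask + 0, bin_factor)
  mask_b <- coverage >= 0.5
  bin_in_mask <- function(img) {
    out <- bin_matrix(img, bin_factor)
    out[mask_b] <- out[mask_b] / coverage[mask_b]
    out[!mask_b] <- 0
    out
  }
  steady_b <- bin_in_mask(pre_s)
  total_b <- bin_in_mask(post_s)
  area_b <- bin_matrix(bleach_area + 0, bin_factor) >= 0.5

  # Rescale the binned bleach-area fluorescence so it matches the raw
  # full-resolution fluorescence over the same pixels: smoothing leaks
  # signal from bright surroundings into the dark bleach spot, and this
  # near-unity factor restores the true bleach depth.
  scale_factor <- 1
  if (any(area_b)) {
    area_full <- kronecker(area_b + 0, matrix(1, bin_factor, bin_factor)) > 0
    post_crop <- (post_mean * mask)[seq_len(nrow(area_full)),
                                    seq_len(ncol(area_full))]
    full_sum <- sum(post_crop[area_full])
    binned_sum <- sum(total_b[area_b] * coverage[area_b]) * bin_factor^2
    if (binned_sum > 0) scale_factor <- full_sum / binned_sum
    total_b[area_b] <- total_b[area_b] * scale_factor
  }

  # normalize so the mask mean of the steady map is 1
  norm <- mean(steady_b[mask_b])
  if (norm <= 0) stopf("empty or dark nucleus after binning")
  steady_b <- steady_b / norm
  total_b <- total_b / norm
  steady_b[!mask_b] <- 0
  total_b[!mask_b] <- 0

  depth <- matrix(1, nrow(mask_b), ncol(mask_b))
  pos <- mask_b & steady_b > 0
  depth[pos] <- pmin(pmax(total_b[pos] / steady_b[pos], 1e-6), 1)

  # bleach centre = depletion-weighted centroid; radius from the area
  w <- pmax(1 - depth, 0) * mask_b
  if (sum(w) > 0) {
    rows <- matrix(seq_len(nrow(mask_b)), nrow(mask_b), ncol(mask_b))
    cols <- matrix(seq_len(ncol(mask_b)), nrow(mask_b), ncol(mask_b), byrow = TRUE)
    center <- c(sum(rows * w), sum(cols * w)) / sum(w)
    radius <- max(1.5, sqrt(sum(area_b) / pi))
  } else {
    center <- dim(mask_b) / 2
    radius <- max(1.5, min(dim(mask_b)) / 8)
  }
  opp <- farthest_mask_point(mask_b, center)
  rois <- list(bleach = circle_roi(mask_b, center, radius),
               opposite = circle_roi(mask_b, opp, radius))

  structure(list(steady = steady_b, total0 = total_b, depth = depth,
                 mask = mask_b,
                 pixel_size_um = pixel_size_um * bin_factor,
                 bin_factor = bin_factor, scale_factor = scale_factor,
                 bleach_center = center, bleach_radius_px = radius,
                 rois = rois),
            class = "frap_init")
}

# Equilibrium-split fields for one parameter combination, from an
# image-derived initialization. The free pool is the uniform free level
# scaled by the local bleach depth; the bound pool is the remainder.
fields_from_init <- function(init, D, koff, bound_fraction) {
  free <- 1 - bound_fraction / 100
  if (free <= 0) stopf("bound_fraction must be < 100")
  k1 <- steady_state_binding_map(init$steady, 1, free, koff, mask = init$mask)
  F0 <- matrix(0, nrow(init$mask), ncol(init$mask))
  C0 <- F0
  F0[init$mask] <- free * init$depth[init$mask]
  C0[init$mask] <- pmax(init$total0[init$mask] - F0[init$mask], 0)
  structure(list(F = F0, C = C0, k1 = k1, koff = koff, D = D,
                 mask = init$mask,
                 pixel_size_um = rep(init$pixel_size_um, length.out = 2),
                 i_st = init$steady, i_avg_st = 1, free_level = free),
            class = "frap_fields")
}

#' Assemble a FRAP experiment from a movie
#'
#' Extracts the measured intensity series (total nucleus, bleach ROI,
#' opposite-end ROI, background), double-normalizes them, and computes the
#' simulation initialization, yielding the per-replicate object consumed
#' by [grid_fit()] and [fit_diffusion_only()].
#'
#' @param movie A [render_frap_movie()] object (or a compatible list with
#'   `frames`, `times`, `is_prebleach`, `nucleus`).
#' @inheritParams initialize_fields
#' @return Object of class `frap_experiment` with elements `init`
#'   ([initialize_fields()] output), `observed` (tibble `t_s`, `roi`,
#'   `normalized` for the post-bleach frames at both measurement
#'   locations), and `times` (post-bleach sample times).
#' @export
frap_experiment <- function(movie, bin_factor = 10, smooth_sigma_px = 5,
                            bleach_threshold = 0.5) {
  mask <- movie$nucleus$mask
  pre <- movie$frames[movie$is_prebleach]
  post <- movie$frames[!movie$is_prebleach]
  init <- initialize_fields(pre, post, mask, movie$nucleus$pixel_size_um,
                            bin_factor = bin_factor,
                            smooth_sigma_px = smooth_sigma_px,
                            bleach_threshold = bleach_threshold)

  # measurement ROIs at full resolution, congruent with the binned ROIs
  bf <- init$bin_factor
  center_full <- (init$bleach_center - 0.5) * bf + 0.5
  radius_full <- init$bleach_radius_px * bf
  roi_b_full <- circle_roi(mask, center_full, radius_full)
  opp_full <- (farthest_mask_point(init$mask, init$bleach_center) - 0.5) * bf + 0.5
  roi_o_full <- circle_roi(mask, opp_full, radius_full)

  mask_idx <- which(mask)
  bg_idx <- which(!mask)
  series <- function(roi_idx) {
    tibble(
      t_s = movie$times,
      total = vapply(movie$frames, function(f) mean(f[mask_idx]), numeric(1)),
      bleach = vapply(movie$frames, function(f) mean(f[roi_idx]), numeric(1)),
      background = vapply(movie$frames, function(f)
        if (length(bg_idx)) mean(f[bg_idx]) else 0, numeric(1)),
      is_prebleach = movie$is_prebleach
    )
  }
  obs <- purrr::map2_dfr(list(roi_b_full, roi_o_full), c(1L, 2L),
                         function(idx, lab) {
                           dn <- double_normalize(series(idx))
                           dn$roi <- lab
                           dn[!dn$is_prebleach, c("t_s", "roi", "normalized")]
                         })

  # The model is initialized from the average of the first three
  # post-bleach frames; because the dynamics are linear, the simulated
  # curve equals the average of the true curve over three frame offsets.
  # The comparable observable is therefore the forward three-frame
  # average of the measured curve (interpolated where frame spacing
  # changes), which aligns model and data exactly with no free shift.
  post_times <- movie$times[!movie$is_prebleach]
  d <- post_times[2] - post_times[1]
  fit_frames <- post_times + 2 * d <= max(post_times) + 1e-9
  obs <- obs %>%
    group_by(.data$roi) %>%
    mutate(fit_target = {
      f <- approxfun(.data$t_s, .data$normalized)
      ifelse(fit_frames,
             (f(.data$t_s) + f(pmin(.data$t_s + d, max(.data$t_s))) +
                f(pmin(.data$t_s + 2 * d, max(.data$t_s)))) / 3,
             NA_real_)
    }) %>%
    ungroup()
  structure(list(init = init, observed = obs, times = post_times,
                 fit_frames = fit_frames),
            class = "frap_experiment")
}
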