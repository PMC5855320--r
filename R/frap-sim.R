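#' Equilibrium binding-rate map from a steady-state image
#'
#' Under the equilibrium assumption, fluorescence is the sum of a uniform
#' free pool plus a spatially varying bound pool, so the local effective
#' binding rate follows directly from the steady-state image:
#' `k1 = (koff / Free) * (i_st / i_avg_st - Free)`, where `Free` is the
#' average free intensity on the same normalized scale. Negative values
#' arising from noise are clipped to zero (their count is reported as an
#' attribute).
#'
#' @param i_st Steady-state intensity matrix (zero off-mask is fine).
#' @param i_avg_st Mean of `i_st` over the nucleus mask.
#' @param free_level Average free intensity with the mask mean of
#'   `i_st / i_avg_st` normalized to 1; must satisfy `0 < free_level <= 1`.
#' @param koff Unbinding rate in 1/s (> 0).
#' @param mask Optional logical matrix; `k1` is zero off-mask.
#' @return Matrix of local binding rates `k1` (1/s) with attribute
#'   `n_clipped`, the number of negative pixels clipped to 0.
#' @export
steady_state_binding_map <- function(i_st, i_avg_st, free_level, koff,
                                     mask = NULL) {
  if (free_level <= 0) stopf("free_level must be > 0")
  if (koff <= 0) stopf("koff must be > 0")
  k1 <- (koff / free_level) * (i_st / i_avg_st - free_level)
  n_clipped <- sum(k1 < 0 & (if (is.null(mask)) TRUE else mask))
  k1[k1 < 0] <- 0
  if (!is.null(mask)) k1[!mask] <- 0
  attr(k1, "n_clipped") <- n_clipped
  k1
}

#' Construct reaction-diffusion fields at equilibrium
#'
#' Builds the free (`F`) and bound (`C`) concentration grids for a given
#' steady-state map and kinetic parameters, partitioned so that
#' `k1 * F = koff * C` pointwise (detailed balance at initialization).
#'
#' @param steady Output of [make_steady_intensity()] (or a compatible list
#'   with `i_st`, `i_avg_st`, `free_level`).
#' @param mask Logical nucleus mask.
#' @param pixel_size_um Grid spacing in micrometres (scalar or length-2
#'   `c(row, col)`).
#' @param D Diffusion constant of the free pool, um^2/s.
#' @param koff Unbinding rate, 1/s.
#' @param depletion Optional multiplicative bleach-depletion matrix in
#'   (0, 1] applied to both pools (1 = unbleached).
#' @return An object of class `frap_fields`.
#' @export
frap_fields <- function(steady, mask, pixel_size_um, D, koff,
                        depletion = NULL) {
  p <- rep(pixel_size_um, length.out = 2)
  i_norm <- steady$i_st / steady$i_avg_st
  free <- steady$free_level
  # koff = 0 switches binding off entirely (pure-diffusion limit)
  k1 <- if (koff > 0) {
    steady_state_binding_map(steady$i_st, steady$i_avg_st, free, koff,
                             mask = mask)
  } else matrix(0, nrow(mask), ncol(mask))
  Fg <- matrix(0, nrow(mask), ncol(mask))
  Cg <- matrix(0, nrow(mask), ncol(mask))
  Fg[mask] <- free
  Cg[mask] <- pmax(i_norm[mask] - free, 0)
  if (!is.null(depletion)) {
    Fg <- Fg * depletion
    Cg <- Cg * depletion
  }
  structure(list(F = Fg, C = Cg, k1 = k1, koff = koff, D = D,
                 mask = mask, pixel_size_um = p,
                 i_st = steady$i_st, i_avg_st = steady$i_avg_st,
                 free_level = free),
            class = "frap_fields")
}

# Stability bound for the explicit scheme: the diffusion bound
# p^2 / (4 D) on the tighter axis, and the reaction bound 1 / (k1 + koff)
# which matters for fast-exchange parameter combinations.
frap_stable_dt <- function(fields, safety = 0.8) {
  p2 <- min(fields$pixel_size_um)^2
  diff_dt <- if (fields$D > 0) p2 / (4 * fields$D) else Inf
  rate <- max(fields$k1) + fields$koff
  react_dt <- if (rate > 0) 1 / rate else Inf
  safety * min(diff_dt, react_dt)
}

#' Simulate FRAP recovery curves from initialized fields
#'
#' Integrates the reaction-diffusion system with an explicit
#' finite-difference scheme (forward Euler, 5-point Laplacian, no-flux at
#' the mask boundary) and reports the mean of `F + C` over each
#' measurement ROI at the requested times.
#'
#' @param fields A [frap_fields()] object (typically bleach-depleted).
#' @param times Sample times in seconds (non-decreasing, starting >= 0;
#'   time 0 is the initial state).
#' @param rois List of ROIs, each a vector of 1-based linear matrix
#'   indices (see [circle_roi()]); all must lie inside the mask.
#' @param dt Explicit time step; defaults to 0.8x the diffusion stability
#'   bound. Supplying a larger value is an error.
#' @param return_frames If `TRUE`, also return the full `F + C` frame at
#'   each sample time.
#' @return A tibble with columns `t_s`, `roi`, `signal`; frames (if
#'   requested) and the final fields are attached as attributes
#'   `frames` and `fields`.
#' @export
simulate_recovery <- function(fields, times, rois, dt = NULL,
                              return_frames = FALSE) {
  stopifnot(inherits(fields, "frap_fields"))
  dt_max <- frap_stable_dt(fields)
  if (is.null(dt)) dt <- dt_max
  if (dt > dt_max * (1 + 1e-12))
    stopf("time step %.3g s violates the stability bound; use dt <= %.3g s",
          dt, dt_max)
  for (r in rois) {
    if (any(!fields$mask[r])) stopf("measurement ROI extends outside the mask")
  }
  res <- frap_simulate_cpp(fields$F, fields$C, fields$k1, fields$koff,
                           fields$D, fields$pixel_size_um[1],
                           fields$pixel_size_um[2],
                           matrix(as.integer(fields$mask), nrow(fields$mask)),
                           dt, as.numeric(times), rois,
                           return_frames = return_frames)
  curves <- res$curves
  out <- tibble(
    t_s = rep(as.numeric(times), times = length(rois)),
    roi = rep(seq_along(rois), each = length(times)),
    signal = as.vector(curves)
  )
  if (return_frames) attr(out, "frames") <- res$frames
  attr(out, "fields") <- list(F = res$F, C = res$C)
  out
}

#' Circular measurement ROI
#'
#' @param mask Logical matrix defining the grid.
#' @param center Row/column centre in pixels, `c(row, col)`.
#' @param radius_px Radius in pixels.
#' @return Integer vector of 1-based linear indices restricted to the mask.
#' @export
circle_roi <- function(mask, center, radius_px) {
  idx <- circle_indices(nrow(mask), ncol(mask), center[1], center[2], radius_px)
  idx[mask[idx]]
}

# The mask pixel farthest from a point, used for the "opposite end"
# measurement location.
farthest_mask_point <- function(mask, from) {
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  d2 <- (rows - from[1])^2 + (cols - from[2])^2
  d2[!mask] <- -Inf
  i <- which.max(d2)
  c(rows[i], cols[i])
}
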