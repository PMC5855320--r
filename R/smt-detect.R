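# Undecimated a-trous wavelet smoothing with the B3-spline kernel
# [1, 4, 6, 4, 1] / 16, holes of 2^(scale-1) pixels, replicate boundary.
atrous_smooth <- function(img, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * as.integer(step)
  conv_axis <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- 0
    for (q in seq_along(off)) {
      idx <- pmin(pmax(seq_len(n) + off[q], 1L), n)
      out <- out + w[q] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  conv_axis(conv_axis(img, TRUE), FALSE)
}

# Wavelet detail planes w_s = c_{s-1} - c_s for s = 1..n_scales.
atrous_planes <- function(img, n_scales) {
  planes <- vector("list", n_scales)
  c_prev <- img
  for (s in seq_len(n_scales)) {
    c_s <- atrous_smooth(c_prev, 2^(s - 1))
    planes[[s]] <- c_prev - c_s
    c_prev <- c_s
  }
  list(planes = planes, residual = c_prev)
}

#' Detect fluorescent spots with an undecimated wavelet transform
#'
#' Decomposes the frame into a-trous B3-spline wavelet planes, hard
#' thresholds each plane at `k_sigma` times its robust (median absolute
#' deviation) noise sd, and detects spots as connected components of the
#' multiscale product of the thresholded planes. Sub-pixel positions are
#' intensity-weighted centroids on the background-subtracted frame; spots
#' touching the frame border are dropped.
#'
#' Detections whose
#' local intensity distribution is much broader than the point-spread
#' function (motion-blurred or overlapping molecules) can be rejected
#' with the width gate.
#'
#' @param frame Image matrix (>= 8 x 8 pixels).
#' @param pixel_size_um Pixel size used for the reported coordinates.
#' @param n_scales Number of wavelet scales (default 3).
#' @param k_sigma Threshold in robust noise sds per scale (default 3).
#' @param psf_sigma_um Nominal PSF sigma used by the width gate.
#' @param max_width_factor Reject detections whose largest second-moment
#'   width exceeds this multiple of `psf_sigma_um` (default `Inf`, no
#'   gating; motion-blur analysis uses 2).
#' @return Tibble with one row per spot: `x_px`, `y_px` (pixel-centre
#'   coordinates, 0.5 = centre of the first pixel), `x_um`, `y_um`,
#'   `intensity` (summed background-subtracted signal), `n_px`.
#' @export
detect_spots <- function(frame, pixel_size_um = 0.1, n_scales = 3,
                         k_sigma = 3, psf_sigma_um = 0.12,
                         max_width_factor = Inf) {
  if (nrow(frame) < 8 || ncol(frame) < 8) stopf("frame must be at least 8x8 px")
  if (sum(frame == max(frame)) >= 10)
    warn("frame looks saturated (>= 10 pixels at the maximum); proceeding")
  dec <- atrous_planes(frame, n_scales)
  support <- matrix(TRUE, nrow(frame), ncol(frame))
  for (wplane in dec$planes) {
    s <- mad(as.vector(wplane))
    if (s == 0) s <- sd(as.vector(wplane))
    support <- support & (wplane > k_sigma * s)
  }
  empty <- tibble(x_px = numeric(), y_px = numeric(), x_um = numeric(),
                  y_um = numeric(), intensity = numeric(), n_px = integer())
  if (!any(support)) return(empty)

  labels <- EBImage::bwlabel(support)
  signal <- pmax(frame - dec$residual, 0)
  nr <- nrow(frame); nc <- ncol(frame)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sigma_px <- psf_sigma_um / pixel_size_um
  win <- max(2L, ceiling(3 * sigma_px))
  out <- lapply(seq_len(max(labels)), function(lab) {
    idx <- which(labels == lab)
    if (any(rows[idx] == 1 | rows[idx] == nr |
            cols[idx] == 1 | cols[idx] == nc)) return(NULL)
    w <- signal[idx]
    if (sum(w) <= 0) return(NULL)
    cx <- sum((cols[idx] - 0.5) * w) / sum(w)
    cy <- sum((rows[idx] - 0.5) * w) / sum(w)
    if (is.finite(max_width_factor)) {
      # intensity-weighted second moments in a local window: a resolved
      # molecule has width ~ sigma_psf, a motion smear is much broader
      ci <- round(cy + 0.5); cj <- round(cx + 0.5)
      ii <- max(1, ci - win):min(nr, ci + win)
      jj <- max(1, cj - win):min(nc, cj + win)
      patch <- signal[ii, jj, drop = FALSE]
      # trim to the bright core so window noise cannot inflate the moments
      patch <- pmax(patch - 0.25 * max(patch), 0)
      if (sum(patch) > 0) {
        py <- rowSums(patch); px <- colSums(patch)
        my <- sum((ii - 0.5) * py) / sum(py)
        mx <- sum((jj - 0.5) * px) / sum(px)
        vyy <- sum(((ii - 0.5) - my)^2 * py) / sum(py)
        vxx <- sum(((jj - 0.5) - mx)^2 * px) / sum(px)
        pm <- patch * outer((ii - 0.5) - my, (jj - 0.5) - mx)
        vxy <- sum(pm) / sum(patch)
        lam_max <- (vxx + vyy) / 2 +
          sqrt(((vxx - vyy) / 2)^2 + vxy^2)
        if (sqrt(max(lam_max, 0)) > max_width_factor * sigma_px)
          return(NULL)
      }
    }
    tibble(x_px = cx, y_px = cy, intensity = sum(w), n_px = length(idx))
  })
  out <- bind_rows(out)
  if (!nrow(out)) return(empty)
  out$x_um <- out$x_px * pixel_size_um
  out$y_um <- out$y_px * pixel_size_um
  out[, c("x_px", "y_px", "x_um", "y_um", "intensity", "n_px")]
}

#' Detect localizations across a stack of frames
#'
#' @param stack List of frames (matrices).
#' @param dt Frame interval (s) used for the `t_s` column.
#' @inheritParams detect_spots
#' @return Tibble of localizations with `frame` (0-based) and `t_s`.
#' @export
localize_stack <- function(stack, dt = 0.01, pixel_size_um = 0.1,
                           n_scales = 3, k_sigma = 3,
                           psf_sigma_um = 0.12, max_width_factor = Inf) {
  out <- purrr::imap_dfr(stack, function(fr, i) {
    d <- detect_spots(fr, pixel_size_um = pixel_size_um,
                      n_scales = n_scales, k_sigma = k_sigma,
                      psf_sigma_um = psf_sigma_um,
                      max_width_factor = max_width_factor)
    if (nrow(d)) {
      d$frame <- as.integer(i) - 1L
      d$t_s <- d$frame * dt
    }
    d
  })
  if (!nrow(out)) {
    out$frame <- integer()
    out$t_s <- numeric()
  }
  out
}
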