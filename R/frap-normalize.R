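#' Double normalization of a FRAP recovery curve
#'
#' Normalizes the bleach-ROI signal to its pre-bleach mean while
#' correcting for the loss of total fluorescence caused by the bleach
#' pulse and by acquisition bleaching:
#' `(T_pre - BG) * (B_t - BG) / ((T_t - BG) * (B_pre - BG))`,
#' where `BG` is the experiment-wide mean background, and `T_pre`, `B_pre`
#' are pre-bleach means of the total-nucleus and bleach-ROI series.
#'
#' @param curve Data frame with columns `t_s`, `total`, `bleach`,
#'   `background` and a logical `is_prebleach` (at least one pre-bleach
#'   frame). An optional `unbleached` column is carried through.
#' @return The input tibble with an added `normalized` column; pre-bleach
#'   scalars are attached as attributes `T_pre`, `B_pre`, `BG`.
#' @export
double_normalize <- function(curve) {
  curve <- as_tibble(curve)
  need <- c("t_s", "total", "bleach", "background", "is_prebleach")
  miss <- setdiff(need, names(curve))
  if (length(miss)) stopf("curve is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!any(curve$is_prebleach)) stopf("at least one pre-bleach frame required")
  bg <- mean(curve$background)
  t_pre <- mean(curve$total[curve$is_prebleach])
  b_pre <- mean(curve$bleach[curve$is_prebleach])
  denom <- (curve$total - bg) * (b_pre - bg)
  bad <- which(denom <= 0)
  if (length(bad))
    stopf("non-positive normalization denominator at frame %d (t = %.3g s)",
          bad[1], curve$t_s[bad[1]])
  curve$normalized <- (t_pre - bg) * (curve$bleach - bg) / denom
  attr(curve, "T_pre") <- t_pre
  attr(curve, "B_pre") <- b_pre
  attr(curve, "BG") <- bg
  curve
}

#' Half-recovery time of a normalized FRAP curve
#'
#' The plateau is estimated as the mean of the final 10% of samples; the
#' half time is the first time the curve crosses halfway between its first
#' post-bleach value and the plateau, linearly interpolated between
#' samples.
#'
#' @param t_s Sample times (s), post-bleach, increasing.
#' @param value Normalized recovery values at `t_s`.
#' @return Half time in seconds, or `NA_real_` when the curve does not
#'   recover (plateau at or below the starting value).
#' @export
halftime <- function(t_s, value) {
  stopifnot(length(t_s) == length(value), length(t_s) >= 3)
  n_tail <- max(1L, ceiling(length(value) / 10))
  plateau <- mean(tail(value, n_tail))
  start <- value[1]
  if (plateau <= start) return(NA_real_)
  half <- (start + plateau) / 2
  above <- which(value >= half)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1) return(t_s[1])
  # linear interpolation across the crossing
  frac <- (half - value[i - 1]) / (value[i] - value[i - 1])
  t_s[i - 1] + frac * (t_s[i] - t_s[i - 1])
}
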