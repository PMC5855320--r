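#' Durations of uninterrupted visits to one state
#'
#' Run-length encodes the per-step state labels of each track and returns
#' the duration (in seconds) of every maximal run in the requested state.
#' Runs truncated by the start or end of a track are included; at the
#' short track lengths typical of single-molecule data this biases dwell
#' estimates down, which is part of why photobleaching correction exists.
#'
#' @param labels Tibble with `track_id` and a per-step state column.
#' @param state State value whose runs are measured.
#' @param dt Frame interval, s.
#' @param state_col Name of the state column (default `"state"`).
#' @return Numeric vector of segment durations (s).
#' @export
state_segment_durations <- function(labels, state, dt,
                                    state_col = "state") {
  labels <- as_tibble(labels)
  out <- lapply(split(labels[[state_col]], labels$track_id), function(s) {
    r <- rle(s == state)
    r$lengths[r$values]
  })
  unlist(out, use.names = FALSE) * dt
}

#' Mean dwell time from bound-segment durations
#'
#' Fits an exponential survival model to the durations of bound-classified
#' track segments (maximum likelihood, equivalent to fitting the
#' log-survival curve). If a photobleaching rate is supplied, the fitted
#' loss rate is corrected by subtracting it, since bleaching and unbinding
#' are competing exponential losses whose rates add.
#'
#' @param durations_s Segment durations, s (>= 20 required).
#' @param bleach_rate Photobleaching rate (1/s) to subtract from the
#'   fitted loss rate; default 0.
#' @return List with `dwell_s` (corrected mean dwell), `rate_fit` (raw
#'   loss rate), `n`, and `poor_fit` (`TRUE` when the duration
#'   distribution is clearly non-exponential: coefficient of variation
#'   outside \[0.5, 2\]).
#' @export
dwell_from_durations <- function(durations_s, bleach_rate = 0) {
  durations_s <- durations_s[is.finite(durations_s) & durations_s > 0]
  if (length(durations_s) < 20)
    stopf("need >= 20 bound segments, got %d", length(durations_s))
  rate_fit <- 1 / mean(durations_s)
  cv <- sd(durations_s) / mean(durations_s)
  rate_corr <- rate_fit - bleach_rate
  if (rate_corr <= 0)
    stopf("bleach rate exceeds the fitted loss rate; dwell time undefined")
  list(dwell_s = 1 / rate_corr, rate_fit = rate_fit,
       n = length(durations_s), poor_fit = cv < 0.5 || cv > 2)
}

#' State usage inside versus outside a nuclear region
#'
#' Assigns each track to a region by its mean position and reports, per
#' region, the fraction of tracks whose modal state label is the slowest
#' state — the signature of specific DNA binding concentrated at a target
#' locus.
#'
#' @param tracks Track tibble (`track_id`, `x_um`, `y_um`).
#' @param labels Per-step labels: tibble with `track_id` and a state
#'   column (e.g. the `annotation` of [vb_fit()] with `state_col =
#'   "map_state"`, or ground-truth tracks with `state_col = "state"`).
#' @param roi_mask Logical matrix marking the region.
#' @param pixel_size_um Pixel size of `roi_mask`.
#' @param slow_state State value counted as bound; defaults to the
#'   smallest label present.
#' @param state_col Name of the state column in `labels`.
#' @return Tibble with one row per region (`inside`, `outside`):
#'   `n_tracks`, `n_slow`, `fraction_slow` (`NA` when a region holds no
#'   tracks).
#' @export
stratify_by_roi <- function(tracks, labels, roi_mask, pixel_size_um,
                            slow_state = NULL, state_col = "map_state") {
  tracks <- as_tibble(tracks)
  labels <- as_tibble(labels)
  slow_state <- slow_state %||% min(labels[[state_col]])
  pos <- tracks %>%
    group_by(.data$track_id) %>%
    summarise(x = mean(.data$x_um), y = mean(.data$y_um), .groups = "drop")
  i <- pmin(pmax(ceiling(pos$y / pixel_size_um), 1L), nrow(roi_mask))
  j <- pmin(pmax(ceiling(pos$x / pixel_size_um), 1L), ncol(roi_mask))
  pos$inside <- roi_mask[cbind(i, j)]

  modal <- labels %>%
    group_by(.data$track_id) %>%
    summarise(slow = mean(.data[[state_col]] == slow_state) >= 0.5,
              .groups = "drop")
  pos <- left_join(pos, modal, by = "track_id")
  pos <- pos[!is.na(pos$slow), ]
  purrr::map_dfr(c(inside = TRUE, outside = FALSE), function(region) {
    sub <- pos[pos$inside == region, ]
    tibble(n_tracks = nrow(sub), n_slow = sum(sub$slow),
           fraction_slow = if (nrow(sub)) mean(sub$slow) else NA_real_)
  }, .id = "region")
}
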