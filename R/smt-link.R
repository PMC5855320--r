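# One frame-pair assignment: globally optimal linear assignment on squared
# displacement with a gating radius. Unmatched detections are handled by
# augmenting the cost matrix with per-detection "no link" alternatives
# priced at r_max^2, so a link is only made when it beats termination.
assign_pair <- function(prev, curr, r_max) {
  n <- nrow(prev); m <- nrow(curr)
  if (n == 0 || m == 0) return(integer(0))
  big <- 4 * r_max^2 + 1
  d2 <- outer(prev$x_um, curr$x_um, `-`)^2 + outer(prev$y_um, curr$y_um, `-`)^2
  d2[d2 > r_max^2] <- big
  cost <- matrix(big, n + m, n + m)
  cost[seq_len(n), seq_len(m)] <- d2
  for (i in seq_len(n)) cost[i, m + i] <- r_max^2         # track ends
  for (j in seq_len(m)) cost[n + j, j] <- r_max^2         # track starts
  cost[n + seq_len(m), m + seq_len(n)] <- 0               # dummy-dummy
  sol <- clue::solve_LSAP(cost)
  link <- integer(n)
  for (i in seq_len(n)) {
    j <- sol[i]
    link[i] <- if (j <= m && d2[i, j] <= r_max^2) j else 0L
  }
  link
}

#' Link localizations into gap-free tracks
#'
#' Performs frame-to-frame global nearest-neighbour linking (optimal
#' linear assignment on squared displacement) with a hard gating radius.
#' No gap closing is attempted: a molecule missing in one frame terminates
#' its track and any later reappearance starts a new one. Tracks shorter
#' than `min_points` localizations are discarded (the default keeps tracks
#' longer than three time points).
#'
#' @param locs Localization tibble with columns `frame` (0-based
#'   consecutive integers), `x_um`, `y_um` (as from [localize_stack()]).
#' @param r_max_um Gating radius (um); defaults to
#'   `3 * sqrt(4 * D_max * dt)` with `D_max` = 2 um^2/s, capturing
#'   essentially all true steps of the fastest state.
#' @param dt Frame interval, s.
#' @param min_points Minimum localizations per retained track (default 4).
#' @return Track tibble: `track_id`, `frame`, `t_s`, `x_um`, `y_um`
#'   (plus `intensity` when present in `locs`).
#' @export
link_tracks <- function(locs, r_max_um = NULL, dt = 0.01, min_points = 4) {
  if (!is.null(r_max_um) && r_max_um <= 0) stopf("r_max_um must be > 0")
  r_max <- r_max_um %||% (3 * sqrt(4 * 2 * dt))
  locs <- arrange(as_tibble(locs), .data$frame)
  if (!nrow(locs)) {
    return(tibble(track_id = integer(), frame = integer(), t_s = numeric(),
                  x_um = numeric(), y_um = numeric()))
  }
  frames <- sort(unique(locs$frame))
  by_frame <- split(locs, locs$frame)

  next_id <- 0L
  new_ids <- function(k) {
    ids <- next_id + seq_len(k)
    next_id <<- next_id + k
    ids
  }
  cur <- by_frame[[as.character(frames[1])]]
  cur$track_id <- new_ids(nrow(cur))
  done <- list(cur)
  for (fi in seq_along(frames)[-1]) {
    nxt <- by_frame[[as.character(frames[fi])]]
    gap <- frames[fi] - frames[fi - 1]
    if (gap == 1L && nrow(cur) && nrow(nxt)) {
      link <- assign_pair(cur, nxt, r_max)
      nxt$track_id <- NA_integer_
      nxt$track_id[link[link > 0]] <- cur$track_id[link > 0]
      un <- is.na(nxt$track_id)
      nxt$track_id[un] <- new_ids(sum(un))
    } else {
      nxt$track_id <- new_ids(nrow(nxt))
    }
    done[[length(done) + 1]] <- nxt
    cur <- nxt
  }
  tracks <- bind_rows(done)
  keep <- names(which(table(tracks$track_id) >= min_points))
  tracks <- tracks[tracks$track_id %in% as.integer(keep), ]
  tracks <- arrange(tracks, .data$track_id, .data$frame)
  # compact ids
  tracks$track_id <- match(tracks$track_id, unique(tracks$track_id))
  tracks$t_s <- tracks$frame * dt
  cols <- c("track_id", "frame", "t_s", "x_um", "y_um",
            intersect("intensity", names(tracks)))
  tracks[, cols]
}
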