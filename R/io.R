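#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @return List of frames (numeric matrices, native intensity scale); a
#'   single-page file yields a list of length 1.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("inconsistent frame shapes in %s", path)
  lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
}

#' Write a multi-page 16-bit TIFF stack
#'
#' Intensities are clipped to `[0, 65535]` and rounded; masks (logical
#' matrices) are written as 0/255.
#'
#' @param frames A matrix or list of matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (is.logical(f)) f <- f * 255
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write tracks to CSV
#'
#' @param tracks Track tibble (`track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, optional `state`).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("track_id", "frame", "t_s", "x_um", "y_um", "state"),
                    names(tracks))
  utils::write.csv(as.data.frame(tracks)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV, enforcing the gap-free contract
#'
#' @param path CSV with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um` (optional `state`). Within each track, frame indices must
#'   increase by exactly 1.
#' @return Track tibble; an empty file yields an empty track set.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  empty <- tibble(track_id = integer(), frame = integer(), t_s = numeric(),
                  x_um = numeric(), y_um = numeric())
  raw <- tryCatch(utils::read.csv(path), error = function(e) NULL)
  if (is.null(raw) || !nrow(raw)) return(empty)
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("track file missing columns: %s",
                          paste(miss, collapse = ", "))
  tracks <- arrange(as_tibble(raw), .data$track_id, .data$frame)
  gaps <- tracks %>%
    group_by(.data$track_id) %>%
    summarise(ok = all(diff(.data$frame) == 1), .groups = "drop")
  if (any(!gaps$ok))
    stopf("track %s contains a frame gap; tracks must be gap-free",
          gaps$track_id[!gaps$ok][1])
  tracks
}
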