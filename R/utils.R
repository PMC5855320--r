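# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; a NULL
# seed leaves the global RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic derived seeds for sub-tasks, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 101L + as.integer(offset)) %% 2147483629L
}

stopf <- function(...) abort(sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pixel-centre physical coordinates (matrix row i -> y, column j -> x).
px_center <- function(idx, pixel_size) (idx - 0.5) * pixel_size

# Separable Gaussian smoothing that preserves constants on the full frame.
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma, boundary = "replicate")
}

# Block-average binning by an integer factor; trailing rows/cols that do
# not fill a complete block are dropped.
bin_matrix <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  nr <- nrow(img) %/% factor
  nc <- ncol(img) %/% factor
  img <- img[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  x <- array(img, dim = c(factor, nr, factor, nc))
  out <- apply(x, c(2, 4), mean)
  out
}

# Linear matrix indices of a filled circle (centre in pixel units).
circle_indices <- function(nr, nc, center_row, center_col, radius_px) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  which((rows - center_row)^2 + (cols - center_col)^2 <= radius_px^2)
}
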