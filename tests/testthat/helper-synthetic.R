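# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small nucleus and noiseless pure-diffusion movie on a short schedule:
# cheap enough for unit tests, sharp enough to carry real signal.
small_diffusion_movie <- function() {
  fixture("small_diffusion_movie", function() {
    nuc <- make_nucleus(60, 100, pixel_size_um = 0.2)
    sch <- frap_schedule("custom", n_prebleach = 4,
                         post_times = seq(0, by = 0.098, length.out = 80))
    render_frap_movie(nuc, D = 2.2, koff = 1, bound_fraction = 0,
                      bleach = bleach_geometry("column", radius_px = 8,
                                               depth = 0.6),
                      schedule = sch, photon_scale = Inf)
  })
}

# Rendered single-emitter frame at high SNR (no noise).
single_emitter_frame <- function(x_um = 3.2, y_um = 3.2, photons = 2000) {
  cfg <- imaging_config(photons_per_frame = photons, fov_px = c(64, 64))
  tr <- tibble::tibble(track_id = 1L, frame = 0L, t_s = 0,
                       x_um = x_um, y_um = y_um)
  render_smt_frames(tr, cfg, noise = FALSE)[[1]]
}

# Brute-force minimal-cost frame-pair matching by enumerating all
# one-to-one assignments under the gating radius (oracle for the linker).
brute_force_pairing <- function(prev, curr, r_max) {
  n <- nrow(prev); m <- nrow(curr)
  d2 <- outer(prev$x_um, curr$x_um, `-`)^2 + outer(prev$y_um, curr$y_um, `-`)^2
  best_cost <- Inf
  best_link <- integer(n)
  assign_next <- function(i, link, used, cost) {
    if (i > n) {
      # unmatched detections cost r_max^2 each (termination / new track)
      total <- cost + (sum(link == 0) + sum(!used)) * r_max^2
      if (total < best_cost) {
        best_cost <<- total
        best_link <<- link
      }
      return(invisible())
    }
    assign_next(i + 1, {
      l <- link
      l[i] <- 0L
      l
    }, used, cost)
    for (j in seq_len(m)) {
      if (!used[j] && d2[i, j] <= r_max^2) {
        u <- used
        u[j] <- TRUE
        l <- link
        l[i] <- j
        assign_next(i + 1, l, u, cost + d2[i, j])
      }
    }
  }
  assign_next(1L, integer(n), rep(FALSE, m), 0)
  list(link = best_link, cost = best_cost)
}

one_state_tracks <- function() {
  fixture("one_state_tracks", function() {
    m <- diffusion_state_model(D = 1.0, pi = 1, A = matrix(1, 1, 1))
    simulate_tracks(m, dt = 0.01, n_tracks = 800, mean_length = 14,
                    fov_um = c(100, 100), resolution_nm = 15,
                    loc_error_nm = 33, seed = 61)
  })
}

two_state_tracks <- function() {
  fixture("two_state_tracks", function() {
    A2 <- 0.9 * diag(2) + 0.1 * matrix(0.5, 2, 2)
    m <- diffusion_state_model(D = c(0.09, 1.89), pi = c(0.5, 0.5), A = A2)
    simulate_tracks(m, dt = 0.01, n_tracks = 2500, mean_length = 10,
                    fov_um = c(60, 60), resolution_nm = 15,
                    loc_error_nm = 33, seed = 62)
  })
}
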