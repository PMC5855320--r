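# Canonical synthetic benchmark experiments. Each function encodes one
# study condition used throughout the package's validation: the same
# definitions drive the test suite and the reproduction script, so the
# conditions are stated in exactly one place.

#' Diffusion-only FRAP benchmark
#'
#' Renders a noiseless FRAP movie of a non-binding factor (bound fraction
#' 0) on an elliptical nucleus, assembles the experiment, and refits the
#' diffusion constant over a grid. Default truth is the free-diffusion
#' constant of 2.2 um^2/s with a 60%-deep column bleach and the standard
#' 0.098 s x 300 frame schedule.
#'
#' @param seed Integer seed (threaded to every stochastic step; the
#'   default conditions are noiseless, so it only fixes the geometry).
#' @param D_true Generating diffusion constant, um^2/s.
#' @param D_grid Grid of candidate diffusion constants.
#' @param pixel_size_um Rendering pixel size; the movie is binned by
#'   `bin_factor` for fitting.
#' @param n_px Rendered grid size `c(rows, cols)`.
#' @param bin_factor Binning factor for initialization.
#' @return List with `fit` (a `frap_fit`), `D_best`, and `truth`.
#' @export
frap_benchmark_diffusion <- function(seed = 1, D_true = 2.2,
                                     D_grid = seq(0.5, 5, by = 0.1),
                                     pixel_size_um = 0.05,
                                     n_px = c(240, 400),
                                     bin_factor = 5) {
  nuc <- make_nucleus(n_px[1], n_px[2], pixel_size_um = pixel_size_um)
  radius_px <- 1.5 / pixel_size_um
  sch <- frap_schedule("custom", n_prebleach = 10,
                       post_times = seq(0, by = 0.098, length.out = 300))
  movie <- render_frap_movie(nuc, D = D_true, koff = 1, bound_fraction = 0,
                             bleach = bleach_geometry("column",
                                                     radius_px = radius_px,
                                                     depth = 0.6),
                             schedule = sch, photon_scale = Inf,
                             seed = derive_seed(seed, 1))
  ex <- frap_experiment(movie, bin_factor = bin_factor)
  fit <- fit_diffusion_only(list(ex), D_grid = D_grid)
  list(fit = fit, D_best = glance(fit)$D_best,
       truth = list(D = D_true))
}

#' Reaction-diffusion FRAP benchmark with binding
#'
#' Renders noiseless replicate movies at a given bound fraction and
#' residence time (D = 2.2 um^2/s), and grid-fits residence time and
#' bound fraction with D fixed at its true value. The defaults reproduce
#' a transiently binding factor (30% bound, 1 s); `bound_fraction = 80`,
#' `residence_s = 45` gives the stably bound regime.
#'
#' @param seed Integer seed.
#' @param bound_fraction,residence_s Generating parameters.
#' @param D Diffusion constant (generating and fitting).
#' @param n_replicates Number of replicate nuclei (default 3).
#' @param residence_grid,bound_grid Fitting grids (defaults as in
#'   [grid_fit()]).
#' @param pixel_size_um,n_px,bin_factor Rendering geometry.
#' @return List with `fit`, `best` (one-row tibble), and `truth`.
#' @export
frap_benchmark_binding <- function(seed = 1, bound_fraction = 30,
                                   residence_s = 1, D = 2.2,
                                   n_replicates = 3,
                                   residence_grid = default_residence_grid(),
                                   bound_grid = default_bound_grid(),
                                   pixel_size_um = 0.1,
                                   n_px = c(120, 200),
                                   bin_factor = 5) {
  radius_px <- 1.5 / pixel_size_um
  sch <- frap_schedule("point")
  exs <- lapply(seq_len(n_replicates), function(i) {
    nuc <- make_nucleus(n_px[1], n_px[2], pixel_size_um = pixel_size_um,
                        irregularity = 0.08, seed = derive_seed(seed, 10 + i))
    movie <- render_frap_movie(nuc, D = D, koff = 1 / residence_s,
                               bound_fraction = bound_fraction,
                               bleach = bleach_geometry("column",
                                                       radius_px = radius_px,
                                                       depth = 0.6),
                               schedule = sch, photon_scale = Inf,
                               seed = derive_seed(seed, 20 + i))
    frap_experiment(movie, bin_factor = bin_factor)
  })
  fit <- grid_fit(exs, D = D, residence_grid = residence_grid,
                  bound_grid = bound_grid)
  list(fit = fit, best = glance(fit),
       truth = list(bound_fraction = bound_fraction,
                    residence_s = residence_s, D = D))
}

#' Locus-ROI FRAP benchmark (band-enriched nucleus)
#'
#' Emulates focused bleaching of a target locus in an activated nucleus:
#' the steady-state map carries a 2x band enrichment, the bleach is a
#' Gaussian point spot centred on the band, and frames follow the band
#' schedule (0.115 s x 300 then 2 s x 100). Defaults generate a 12 s
#' residence time with 30% bound.
#'
#' @inheritParams frap_benchmark_binding
#' @param enrichment Band enrichment factor of the bound pool.
#' @return List with `fit`, `best`, and `truth`.
#' @export
frap_benchmark_locus <- function(seed = 1, bound_fraction = 30,
                                 residence_s = 12, D = 2.2,
                                 enrichment = 2, n_replicates = 3,
                                 residence_grid = default_residence_grid(),
                                 bound_grid = default_bound_grid(),
                                 pixel_size_um = 0.1,
                                 n_px = c(120, 200),
                                 bin_factor = 5) {
  radius_px <- 1.5 / pixel_size_um
  sch <- frap_schedule("band")
  exs <- lapply(seq_len(n_replicates), function(i) {
    nuc <- make_nucleus(n_px[1], n_px[2], pixel_size_um = pixel_size_um,
                        band_center_col = round(n_px[2] / 2),
                        band_width_px = round(n_px[2] / 12))
    movie <- render_frap_movie(nuc, D = D, koff = 1 / residence_s,
                               bound_fraction = bound_fraction,
                               enrichment = enrichment,
                               bleach = bleach_geometry("point",
                                                       center = c(n_px[1] / 2,
                                                                  n_px[2] / 2),
                                                       radius_px = radius_px,
                                                       depth = 0.6),
                               schedule = sch, photon_scale = Inf,
                               seed = derive_seed(seed, 30 + i))
    frap_experiment(movie, bin_factor = bin_factor)
  })
  fit <- grid_fit(exs, D = D, residence_grid = residence_grid,
                  bound_grid = bound_grid)
  list(fit = fit, best = glance(fit),
       truth = list(bound_fraction = bound_fraction,
                    residence_s = residence_s, D = D,
                    enrichment = enrichment))
}

#' Four-state single-molecule tracking benchmark
#'
#' Simulates tracks from the canonical four-state model
#' ([su_h_four_state_model()]) at 10 ms frames with 33 nm localization
#' error, then fits a K = 4 variational-Bayes HMM with the same
#' localization-error term in the emissions.
#'
#' @param seed Integer seed.
#' @param n_tracks Number of tracks (default 2e4, geometric mean length
#'   10).
#' @param mean_length Mean track length (positions).
#' @param dt Frame interval, s.
#' @param loc_error_nm Localization error (generator and emission model).
#' @param n_restarts Restarts for [vb_fit()].
#' @return List with `fit` (an `sm_diffusion_fit`), `states` (its
#'   [tidy()] table), and `truth` (the generating model).
#' @export
smt_benchmark_four_state <- function(seed = 1, n_tracks = 20000,
                                     mean_length = 10, dt = 0.01,
                                     loc_error_nm = 33, n_restarts = 10) {
  model <- su_h_four_state_model()
  tracks <- simulate_tracks(model, dt = dt, n_tracks = n_tracks,
                            mean_length = mean_length, fov_um = c(50, 50),
                            resolution_nm = 15,
                            loc_error_nm = loc_error_nm,
                            seed = derive_seed(seed, 41))
  fit <- vb_fit(tracks, K = 4, dt = dt, loc_error_nm = loc_error_nm,
                n_restarts = n_restarts, seed = derive_seed(seed, 42))
  list(fit = fit, states = tidy(fit), truth = model)
}
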