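test_that("nucleus masks match a brute-force pixel-in-ellipse count", {
  nuc <- make_nucleus(40, 24, pixel_size_um = 0.5,
                      semiaxes = c(18, 10))
  # independent exhaustive pixel test of the same ellipse
  ci <- (40 + 1) / 2
  cj <- (24 + 1) / 2
  count <- 0L
  for (i in 1:40) for (j in 1:24) {
    if (((i - ci) / 18)^2 + ((j - cj) / 10)^2 <= 1) count <- count + 1L
  }
  expect_equal(sum(nuc$mask), count)
})

test_that("degenerate nucleus geometry is rejected", {
  expect_error(make_nucleus(32, 32, semiaxes = c(0, 5)), "degenerate")
  expect_error(make_nucleus(8, 8), "16x16")
})

test_that("irregular nuclei are reproducible under a fixed seed", {
  a <- make_nucleus(48, 48, irregularity = 0.2, seed = 7)
  b <- make_nucleus(48, 48, irregularity = 0.2, seed = 7)
  c <- make_nucleus(48, 48, irregularity = 0.2, seed = 8)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$mask, c$mask))
})

test_that("band and locus ROIs are subsets of the mask", {
  nuc <- make_nucleus(48, 80, band_center_col = 40, band_width_px = 8,
                      locus_radius_px = 4)
  expect_true(all(nuc$mask[nuc$band]))
  expect_true(all(nuc$mask[nuc$locus]))
})

test_that("steady-state intensity reflects binding and enrichment", {
  nuc <- make_nucleus(48, 80, band_center_col = 40, band_width_px = 8)
  # no binding: uniform map equal to its average
  st0 <- make_steady_intensity(nuc, 0)
  expect_true(all(abs(st0$i_st[nuc$mask] - st0$i_avg_st) < 1e-12))
  # enrichment 1: uniform even with binding, free level 0.7
  st1 <- make_steady_intensity(nuc, 30, enrichment = 1)
  expect_equal(st1$free_level, 0.7)
  expect_lt(diff(range(st1$i_st[nuc$mask])), 1e-12)
  # with enrichment 1 the implied binding-rate map is uniform
  k1 <- steady_state_binding_map(st1$i_st, st1$i_avg_st, st1$free_level,
                                 koff = 2, mask = nuc$mask)
  expect_true(all(abs(k1[nuc$mask] - 2 * 0.3 / 0.7) < 1e-9))
  # band pixels carry twice the bound signal of non-band pixels
  st2 <- make_steady_intensity(nuc, 30, enrichment = 2)
  bound_band <- mean(st2$i_st[nuc$band]) - st2$free_level
  bound_out <- mean(st2$i_st[nuc$mask & !nuc$band]) - st2$free_level
  expect_equal(bound_band / bound_out, 2, tolerance = 1e-9)
  # no free pool is undefined
  expect_error(make_steady_intensity(nuc, 100), "free pool")
})

test_that("movie rendering honours the no-bleach and seeding contracts", {
  nuc <- make_nucleus(32, 48, pixel_size_um = 0.25)
  sch <- frap_schedule("custom", n_prebleach = 2,
                       post_times = seq(0, by = 0.1, length.out = 6))
  no_bleach <- render_frap_movie(nuc, D = 1, koff = 1, bound_fraction = 20,
                                 bleach = bleach_geometry("column", depth = 0),
                                 schedule = sch, photon_scale = Inf)
  st <- make_steady_intensity(nuc, 20)
  for (f in no_bleach$frames)
    expect_true(max(abs(f - st$i_st)) < 1e-9)

  noisy1 <- render_frap_movie(nuc, D = 1, koff = 1, bound_fraction = 0,
                              schedule = sch, photon_scale = 500, seed = 1)
  noisy1b <- render_frap_movie(nuc, D = 1, koff = 1, bound_fraction = 0,
                               schedule = sch, photon_scale = 500, seed = 1)
  noisy2 <- render_frap_movie(nuc, D = 1, koff = 1, bound_fraction = 0,
                              schedule = sch, photon_scale = 500, seed = 2)
  expect_identical(noisy1$frames, noisy1b$frames)
  expect_false(identical(noisy1$frames, noisy2$frames))
})

test_that("noiseless movie extraction matches the forward model", {
  mov <- small_diffusion_movie()
  mask <- mov$nucleus$mask
  # re-simulate the post-bleach phase directly and compare whole frames
  st <- make_steady_intensity(mov$nucleus, 0)
  fields <- frap_fields(st, mask, mov$nucleus$pixel_size_um, D = 2.2,
                        koff = 1, depletion = mov$ground_truth$depletion)
  post_times <- mov$times[!mov$is_prebleach]
  sim <- simulate_recovery(fields, post_times, list(which(mask)),
                           return_frames = TRUE)
  frames <- attr(sim, "frames")
  post <- mov$frames[!mov$is_prebleach]
  for (i in c(1, 10, 40, 80))
    expect_lt(max(abs(frames[[i]] - post[[i]])), 1e-9)
})

test_that("single-state displacements calibrate to 2 D dt per axis", {
  m1 <- diffusion_state_model(D = 1.0, pi = 1, A = matrix(1, 1, 1))
  tr <- simulate_tracks(m1, dt = 0.01, n_tracks = 120, mean_length = 100,
                        fov_um = c(300, 300), resolution_nm = 1e-6,
                        seed = 4)
  d <- tr %>% dplyr::group_by(track_id) %>%
    dplyr::reframe(dx = diff(x_um), dy = diff(y_um))
  n <- nrow(d)
  expect_gt(n, 1e4)
  se <- sqrt(2) * 0.02 / sqrt(n)  # se of a variance estimate, var = 0.02
  expect_lt(abs(var(d$dx) - 0.02), 3 * se)
  expect_lt(abs(var(d$dy) - 0.02), 3 * se)
  expect_lt(abs(mean(d$dx^2 + d$dy^2) - 0.04), 6 * se)
})

test_that("identity transition matrix produces no state switches", {
  m <- diffusion_state_model(D = c(0.1, 1), pi = c(0.5, 0.5), A = diag(2))
  tr <- simulate_tracks(m, dt = 0.01, n_tracks = 50, mean_length = 20,
                        seed = 5)
  switches <- tr %>% dplyr::group_by(track_id) %>%
    dplyr::summarise(s = dplyr::n_distinct(state))
  expect_true(all(switches$s == 1))
})

test_that("state occupancy and transition frequencies follow the chain law", {
  model <- su_h_four_state_model()
  tr <- simulate_tracks(model, dt = 0.01, n_tracks = 12000,
                        mean_length = 12, fov_um = c(100, 100), seed = 6)
  # steps, not positions: drop each track's duplicated final state
  steps <- tr %>% dplyr::group_by(track_id) %>%
    dplyr::slice(-dplyr::n()) %>% dplyr::ungroup()
  occ <- as.vector(table(factor(steps$state, levels = 1:4))) / nrow(steps)
  expect_true(all(abs(occ - model$pi) < 0.015))

  trans <- steps %>% dplyr::group_by(track_id) %>%
    dplyr::reframe(from = head(state, -1), to = tail(state, -1))
  A_emp <- prop.table(table(factor(trans$from, levels = 1:4),
                            factor(trans$to, levels = 1:4)), margin = 1)
  tv <- max(rowSums(abs(A_emp - model$A)) / 2)
  expect_lt(tv, 0.02)
})

test_that("invalid state models are rejected", {
  expect_error(diffusion_state_model(c(1, 2), c(0.6, 0.6), diag(2)),
               "sum to 1")
  expect_error(diffusion_state_model(c(1, 2), c(0.5, 0.5),
                                     matrix(c(0.5, 0.6, 0.4, 0.4), 2)),
               "sum to 1")
  expect_error(simulate_tracks(su_h_four_state_model(), dt = -1,
                               n_tracks = 1), "dt")
})

test_that("confined trajectories stay inside the nucleus mask", {
  nuc <- make_nucleus(40, 40, pixel_size_um = 0.25)
  m <- diffusion_state_model(D = 2, pi = 1, A = matrix(1, 1, 1))
  tr <- simulate_tracks(m, dt = 0.02, n_tracks = 60, mean_length = 30,
                        geometry = nuc, seed = 9)
  i <- pmin(pmax(ceiling(tr$y_um / 0.25), 1), 40)
  j <- pmin(pmax(ceiling(tr$x_um / 0.25), 1), 40)
  expect_true(all(nuc$mask[cbind(i, j)]))
})

test_that("rendered emitters conserve photons and localize correctly", {
  frame <- single_emitter_frame(x_um = 3.17, y_um = 2.83, photons = 1000)
  # photon conservation before noise (PSF truncation loss < 0.5%)
  expect_lt(abs(sum(frame) - 1000) / 1000, 0.005)
  # peak at the emitter pixel, centroid within half a pixel
  peak <- which(frame == max(frame), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(ceiling(2.83 / 0.1), ceiling(3.17 / 0.1)))
  w <- frame / sum(frame)
  cx <- sum(t(w) * (seq_len(64) - 0.5)) * 0.1
  cy <- sum(w * (seq_len(64) - 0.5)) * 0.1
  expect_lt(abs(cx - 3.17), 0.05)
  expect_lt(abs(cy - 2.83), 0.05)
})

test_that("motion blur lowers the peak of fast molecules at long exposure", {
  m <- diffusion_state_model(D = 1.89, pi = 1, A = matrix(1, 1, 1))
  peaks <- vapply(c(0.01, 0.1), function(expo) {
    tr <- simulate_tracks(m, dt = expo, n_tracks = 1, mean_length = 2,
                          fov_um = c(6.4, 6.4), seed = 21)
    tr <- tr[tr$frame == 0 | tr$frame == 1, ]
    cfg <- imaging_config(exposure_s = expo, photons_per_frame = 1000,
                          fov_px = c(64, 64))
    max(render_smt_frames(tr, cfg, noise = FALSE)[[1]])
  }, numeric(1))
  expect_lt(peaks[2], peaks[1])
})

test_that("repeated noisy renders of a fixed emitter scatter as configured", {
  cfg <- imaging_config(photons_per_frame = 1000, fov_px = c(32, 32))
  tr <- tibble::tibble(track_id = 1L, frame = 0L, t_s = 0,
                       x_um = 1.6, y_um = 1.6)
  locs <- purrr::map_dfr(1:60, function(s) {
    fr <- render_smt_frames(tr, cfg, noise = TRUE, seed = 100 + s)[[1]]
    detect_spots(fr, pixel_size_um = 0.1)
  })
  expect_gt(nrow(locs), 50)
  scatter_nm <- sqrt((var(locs$x_um) + var(locs$y_um)) / 2) * 1000
  # theoretical limit sigma_psf / sqrt(N) ~ 6 nm; centroid localization
  # on a thresholded support is a few-fold worse but well under a pixel
  expect_lt(scatter_nm, 60)
  expect_gt(scatter_nm, 1)
})

test_that("psnr follows its defining formula", {
  clean <- matrix(0, 16, 16)
  clean[8, 8] <- 100
  noise <- matrix(rnorm(256), 16, 16)
  noise <- (noise - mean(noise)) / sd(noise)  # unit sd residual
  expect_equal(psnr(clean, clean + noise), 40, tolerance = 1e-9)
  clean2 <- clean / 10
  expect_equal(psnr(clean2, clean2 + noise), 20, tolerance = 1e-9)
  expect_identical(psnr(clean, clean), Inf)
})
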