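test_that("null frames produce almost no false positives", {
  set.seed(101)
  fp <- 0L
  npix <- 0L
  for (i in 1:60) {
    frame <- matrix(rnorm(64 * 64, mean = 10, sd = 1.1), 64, 64)
    fp <- fp + nrow(detect_spots(frame, k_sigma = 3))
    npix <- npix + 64L * 64L
  }
  expect_lte(fp / npix, 1e-4)
})

test_that("bright emitters are detected at their positions", {
  frame <- single_emitter_frame(x_um = 3.2, y_um = 3.2)
  d <- detect_spots(frame, pixel_size_um = 0.1)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x_um - 3.2), 0.1)
  expect_lt(abs(d$y_um - 3.2), 0.1)

  # two emitters 10 sigma_psf apart resolve as two spots
  cfg <- imaging_config(photons_per_frame = 2000, fov_px = c(64, 64))
  tr <- tibble::tibble(track_id = c(1L, 2L), frame = 0L, t_s = 0,
                       x_um = c(2.0, 3.2), y_um = c(2.0, 2.0))
  fr <- render_smt_frames(tr, cfg, noise = FALSE)[[1]]
  expect_equal(nrow(detect_spots(fr, pixel_size_um = 0.1)), 2)

  expect_error(detect_spots(matrix(0, 4, 4)), "8x8")
})

test_that("linking produces gap-free tracks with the length filter", {
  # one stationary spot in all 50 frames -> one 50-point track
  locs <- tibble::tibble(frame = 0:49, x_um = 2, y_um = 2)
  tr <- link_tracks(locs, r_max_um = 0.5, dt = 0.01)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 50)
  expect_true(all(diff(tr$frame) == 1))

  # a missing detection splits the track; no gap closing
  locs2 <- locs[locs$frame != 25, ]
  tr2 <- link_tracks(locs2, r_max_um = 0.5, dt = 0.01)
  expect_equal(length(unique(tr2$track_id)), 2)
  per <- tr2 %>% dplyr::group_by(track_id) %>%
    dplyr::summarise(ok = all(diff(frame) == 1))
  expect_true(all(per$ok))

  # a 3-point track is removed by the >3-time-points filter
  locs3 <- tibble::tibble(frame = 0:2, x_um = 1, y_um = 1)
  expect_equal(nrow(link_tracks(locs3, r_max_um = 0.5, dt = 0.01)), 0)

  expect_error(link_tracks(locs, r_max_um = -1), "r_max")
})

test_that("no linked displacement ever exceeds the gating radius", {
  set.seed(7)
  locs <- purrr::map_dfr(0:29, function(f) {
    n <- sample(2:6, 1)
    tibble::tibble(frame = f, x_um = runif(n, 0, 5), y_um = runif(n, 0, 5))
  })
  tr <- link_tracks(locs, r_max_um = 0.6, dt = 0.01, min_points = 2)
  steps <- tr %>% dplyr::group_by(track_id) %>%
    dplyr::reframe(d = sqrt(diff(x_um)^2 + diff(y_um)^2),
                   gap = diff(frame))
  expect_true(all(steps$d <= 0.6 + 1e-12))
  expect_true(all(steps$gap == 1))
})

test_that("linking is permutation-invariant and matches brute force", {
  set.seed(42)
  for (rep in 1:15) {
    prev <- tibble::tibble(x_um = runif(4, 0, 3), y_um = runif(4, 0, 3))
    curr <- tibble::tibble(x_um = runif(5, 0, 3), y_um = runif(5, 0, 3))
    link <- nucdyn:::assign_pair(prev, curr, r_max = 1)
    oracle <- brute_force_pairing(prev, curr, r_max = 1)
    d2 <- outer(prev$x_um, curr$x_um, `-`)^2 +
      outer(prev$y_um, curr$y_um, `-`)^2
    cost <- function(l) sum(d2[cbind(which(l > 0), l[l > 0])]) +
      (sum(l == 0) + nrow(curr) - sum(l > 0)) * 1
    expect_equal(cost(link), oracle$cost, tolerance = 1e-9)
  }

  # shuffling the localizations within frames leaves track sets identical
  locs <- purrr::map_dfr(0:19, function(f) {
    tibble::tibble(frame = f,
                   x_um = c(1, 2.5, 4) + f * 0.03,
                   y_um = c(1, 1.2, 0.8))
  })
  set.seed(9)
  shuffled <- locs[sample(nrow(locs)), ]
  t1 <- link_tracks(locs, r_max_um = 0.5, dt = 0.01)
  t2 <- link_tracks(shuffled, r_max_um = 0.5, dt = 0.01)
  # compare the track partition itself (ids are arbitrary labels)
  sig <- function(x) sort(vapply(split(x, x$track_id), function(tr)
    paste(tr$frame, round(tr$x_um, 9), round(tr$y_um, 9), collapse = ";"),
    character(1)))
  expect_identical(unname(sig(t1)), unname(sig(t2)))
})

test_that("localization precision recovers known jitter", {
  # zero jitter -> zero precision
  still <- purrr::map_dfr(1:5, function(id)
    tibble::tibble(track_id = id, frame = 0:19, x_um = id, y_um = id))
  expect_equal(suppressMessages(localization_precision(still)), 0,
               tolerance = 1e-12, ignore_attr = TRUE)

  # anisotropic closed form: sd (20, 40) nm -> sqrt((400+1600)/2)
  set.seed(11)
  jit <- purrr::map_dfr(1:100, function(id)
    tibble::tibble(track_id = id, frame = 0:49,
                   x_um = 1 + rnorm(50, 0, 0.020),
                   y_um = 1 + rnorm(50, 0, 0.040)))
  p <- localization_precision(jit)
  expect_equal(as.numeric(p), sqrt((400 + 1600) / 2), tolerance = 0.08)

  # isotropic 33 nm within 10%
  set.seed(12)
  iso <- purrr::map_dfr(1:100, function(id)
    tibble::tibble(track_id = id, frame = 0:49,
                   x_um = rnorm(50, 0, 0.033), y_um = rnorm(50, 0, 0.033)))
  expect_equal(as.numeric(localization_precision(iso)), 33,
               tolerance = 0.10)

  # short tracks are excluded with a message
  expect_message(
    localization_precision(dplyr::bind_rows(
      jit, tibble::tibble(track_id = 999, frame = 0:3,
                          x_um = 0, y_um = 0))),
    "excluded")
})

test_that("motion blur analysis separates immobile from fast molecules", {
  # fixed per-frame photon budget over a constant autofluorescence
  # background: an immobile molecule keeps its contrast at any exposure,
  # while a diffusing one smears its photons along its path
  series <- function(model, n_tracks, seed, expos = c(10, 50, 100)) {
    out <- list()
    for (expo in expos) {
      tr <- simulate_tracks(model, dt = expo / 1000, n_tracks = n_tracks,
                            mean_length = 60, fov_um = c(6.4, 6.4),
                            seed = seed + expo)
      tr <- tr[tr$frame < 12, ]
      cfg <- imaging_config(exposure_s = expo / 1000,
                            photons_per_frame = 150,
                            background_photons = 10, fov_px = c(64, 64))
      out[[as.character(expo)]] <-
        render_smt_frames(tr, cfg, noise = TRUE, seed = seed + expo + 1)
    }
    out
  }
  one <- function(D) diffusion_state_model(D = D, pi = 1,
                                           A = matrix(1, 1, 1))
  immobile <- motion_blur_analysis(series(one(1e-4), 10, 500))
  fast <- motion_blur_analysis(series(one(1.89), 10, 600))
  # immobile counts stay flat; fast counts fall monotonically and end
  # well below the immobile fraction
  expect_gt(immobile$unblurred_fraction, 0.8)
  expect_lt(fast$unblurred_fraction, immobile$unblurred_fraction - 0.3)
  expect_true(all(diff(fast$counts$loc_per_frame) < 0))

  # a 20/80 immobile/fast mixture behaves as the weighted combination of
  # its components (composition oracle from the single-population rates)
  mix <- diffusion_state_model(D = c(1e-4, 1.89), pi = c(0.2, 0.8),
                               A = diag(2))
  mx <- motion_blur_analysis(series(mix, 40, 700, expos = c(10, 100)))
  r_im <- immobile$counts$loc_per_frame
  r_fa <- fast$counts$loc_per_frame
  pred <- (0.2 * r_im[3] + 0.8 * r_fa[3]) / (0.2 * r_im[1] + 0.8 * r_fa[1])
  expect_lt(abs(mx$unblurred_fraction - pred), 0.12)
  expect_lt(mx$unblurred_fraction, immobile$unblurred_fraction)
  expect_gt(mx$unblurred_fraction, fast$unblurred_fraction)

  suppressWarnings(
    expect_error(motion_blur_analysis(list(a = list())), "exposure"))
})

test_that("detection recall and precision are high at benchmark SNR", {
  # bright emitters on a quiet background (PSNR ~29 dB regime)
  set.seed(55)
  truth <- tibble::tibble(track_id = 1:8, frame = 0L, t_s = 0,
                          x_um = runif(8, 1, 5.4),
                          y_um = runif(8, 1, 5.4))
  cfg <- imaging_config(photons_per_frame = 1500, fov_px = c(64, 64))
  hits <- 0L; dets <- 0L; matched <- 0L
  for (s in 1:20) {
    stack <- render_smt_frames(truth, cfg, noise = TRUE, seed = 900 + s)
    fr <- stack[[1]]
    expect_gte(psnr(attr(stack, "clean")[[1]], fr), 25)
    d <- detect_spots(fr, pixel_size_um = 0.1)
    dets <- dets + nrow(d)
    for (i in seq_len(nrow(truth))) {
      dd <- sqrt((d$x_um - truth$x_um[i])^2 + (d$y_um - truth$y_um[i])^2)
      if (any(dd < 0.2)) hits <- hits + 1L
    }
    if (nrow(d)) {
      dmin <- vapply(seq_len(nrow(d)), function(j)
        min(sqrt((d$x_um[j] - truth$x_um)^2 + (d$y_um[j] - truth$y_um)^2)),
        numeric(1))
      matched <- matched + sum(dmin < 0.2)
    }
  }
  expect_gte(hits / (20 * nrow(truth)), 0.95)   # recall
  expect_gte(matched / dets, 0.95)              # precision
})

test_that("the SMT round trip recovers immobile ground-truth segments", {
  # simulate -> render -> detect -> link on slow molecules
  m <- diffusion_state_model(D = 0.01, pi = 1, A = matrix(1, 1, 1))
  tracks <- simulate_tracks(m, dt = 0.01, n_tracks = 6, mean_length = 40,
                            fov_um = c(6.4, 6.4), resolution_nm = 15,
                            seed = 77)
  tracks <- tracks[tracks$frame < 25, ]
  cfg <- imaging_config(photons_per_frame = 1200, fov_px = c(64, 64))
  stack <- render_smt_frames(tracks, cfg, noise = TRUE, seed = 78)
  locs <- localize_stack(stack, dt = 0.01, pixel_size_um = 0.1)
  linked <- link_tracks(locs, dt = 0.01)
  # every interior ground-truth position should be covered by a linked
  # localization (border detections are dropped by design)
  tracks <- tracks[tracks$x_um > 0.5 & tracks$x_um < 5.9 &
                     tracks$y_um > 0.5 & tracks$y_um < 5.9, ]
  covered <- vapply(seq_len(nrow(tracks)), function(i) {
    sub <- linked[linked$frame == tracks$frame[i], ]
    nrow(sub) > 0 &&
      min(sqrt((sub$x_um - tracks$x_um[i])^2 +
                 (sub$y_um - tracks$y_um[i])^2)) < 0.2
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})
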