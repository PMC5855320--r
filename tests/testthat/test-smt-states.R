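test_that("step log-likelihood matches the isotropic Gaussian closed form", {
  # zero displacement, D = 1, dt = 0.01: log(1 / (4 pi D dt))
  expect_equal(step_loglik(0, 0, D = 1, dt = 0.01),
               log(1 / (4 * pi * 1 * 0.01)), tolerance = 1e-12)
  # doubling dt halves the density at zero displacement
  expect_equal(exp(step_loglik(0, 0, 1, 0.02)),
               exp(step_loglik(0, 0, 1, 0.01)) / 2, tolerance = 1e-12)
  # the density integrates to 1 over the plane (polar quadrature)
  r <- seq(0, 3, length.out = 6000)
  dens <- exp(step_loglik(r, 0, D = 0.5, dt = 0.05))
  integral <- sum(dens * 2 * pi * r) * (r[2] - r[1])
  expect_equal(integral, 1, tolerance = 1e-4)
  # degenerate state: zero variance
  expect_identical(step_loglik(0.1, 0, 0, 0.01, loc_error_nm = 0), -Inf)
  expect_identical(step_loglik(0, 0, 0, 0.01, loc_error_nm = 0), Inf)
})

test_that("single-state fits recover D within 5%", {
  fit <- vb_fit(one_state_tracks(), K = 1, dt = 0.01, loc_error_nm = 33,
                n_restarts = 3, seed = 63)
  expect_lt(abs(fit$D - 1.0) / 1.0, 0.05)
  expect_equal(fit$occupancy, 1)
})

test_that("two-state fits recover both coefficients within 20%", {
  fit <- vb_fit(two_state_tracks(), K = 2, dt = 0.01, loc_error_nm = 33,
                n_restarts = 5, seed = 64)
  expect_lt(abs(fit$D[1] - 0.09) / 0.09, 0.20)
  expect_lt(abs(fit$D[2] - 1.89) / 1.89, 0.20)
  expect_lt(abs(fit$occupancy[1] - 0.5), 0.05)
  # ELBO is non-decreasing across iterations
  expect_true(all(diff(fit$elbo_trace) > -1e-6 * abs(fit$elbo)))
  # posterior responsibilities sum to 1 per step and occupancies are
  # the responsibility-weighted step fractions
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-9)
  expect_equal(colSums(fit$posterior) / nrow(fit$posterior),
               fit$occupancy, tolerance = 1e-9)
})

test_that("restart seeds agree after sorting states by D", {
  fa <- vb_fit(two_state_tracks(), K = 2, dt = 0.01, loc_error_nm = 33,
               n_restarts = 4, seed = 101)
  fb <- vb_fit(two_state_tracks(), K = 2, dt = 0.01, loc_error_nm = 33,
               n_restarts = 4, seed = 202)
  expect_equal(fa$D, fb$D, tolerance = 1e-3)
  expect_equal(fa$occupancy, fb$occupancy, tolerance = 1e-3)
})

test_that("model selection finds one state in one-state data", {
  sel <- select_model(one_state_tracks(), K_max = 2, dt = 0.01,
                      loc_error_nm = 33, n_restarts = 3, seed = 65)
  expect_equal(sel$best_K, 1)
  expect_equal(nrow(sel$table), 2)
})

test_that("dwell times follow the geometric sojourn formula", {
  A <- matrix(c(0.9, 0.1, 0.01, 0.99), 2, 2, byrow = TRUE)
  tau <- mean_dwell_times(A, dt = 0.01)
  expect_equal(tau, c(0.1, 1), tolerance = 1e-12)
  expect_identical(mean_dwell_times(diag(2), 0.01), c(Inf, Inf))
  expect_error(mean_dwell_times(matrix(c(0.5, 0.2, 0.4, 0.8), 2), 0.01),
               "sum to 1")
})

test_that("dwell estimation from segment durations is calibrated", {
  set.seed(71)
  dur <- rexp(500, rate = 1 / 0.56)
  est <- dwell_from_durations(dur)
  expect_lt(abs(est$dwell_s - 0.56) / 0.56, 0.15)
  expect_false(est$poor_fit)

  # equal durations: estimate equals T but flagged as a poor fit
  est2 <- dwell_from_durations(rep(0.3, 50))
  expect_true(est2$dwell_s >= 0.15 && est2$dwell_s <= 0.6)
  expect_true(est2$poor_fit)

  # a bleach rate equal to the unbinding rate doubles the corrected dwell
  set.seed(72)
  k <- 1 / 0.5
  dur3 <- rexp(2000, rate = 2 * k)  # unbinding + equal bleaching
  raw <- dwell_from_durations(dur3)
  corr <- dwell_from_durations(dur3, bleach_rate = k)
  expect_equal(corr$dwell_s / raw$dwell_s, 2, tolerance = 0.15)

  expect_error(dwell_from_durations(rexp(5, 1)), ">= 20")
})

test_that("segment durations come from run-length encoding per track", {
  lab <- tibble::tibble(track_id = c(1, 1, 1, 1, 2, 2),
                        state = c(1, 1, 2, 1, 2, 2))
  d <- state_segment_durations(lab, state = 1, dt = 0.1)
  expect_equal(sort(d), c(0.1, 0.2))
  expect_equal(state_segment_durations(lab, state = 2, dt = 0.1),
               c(0.1, 0.2))
})

test_that("region stratification separates slow-state usage", {
  roi <- matrix(FALSE, 20, 20)
  roi[, 1:10] <- TRUE  # left half (x <= 5 um at 0.5 um/px)
  # slow tracks inside, fast outside
  tracks <- dplyr::bind_rows(
    purrr::map_dfr(1:30, function(i) tibble::tibble(
      track_id = i, frame = 0:5, x_um = 2.5, y_um = 5)),
    purrr::map_dfr(31:60, function(i) tibble::tibble(
      track_id = i, frame = 0:5, x_um = 7.5, y_um = 5)))
  labels <- tibble::tibble(
    track_id = rep(1:60, each = 5),
    map_state = rep(c(1, 2), each = 150))
  out <- stratify_by_roi(tracks, labels, roi, pixel_size_um = 0.5)
  expect_equal(out$fraction_slow[out$region == "inside"], 1)
  expect_equal(out$fraction_slow[out$region == "outside"], 0)

  # uniform mixing: inside and outside fractions agree within noise
  set.seed(81)
  tracks_u <- purrr::map_dfr(1:400, function(i) tibble::tibble(
    track_id = i, frame = 0:5, x_um = runif(1, 0, 10), y_um = 5))
  labels_u <- tibble::tibble(track_id = rep(1:400, each = 5),
                             map_state = rep(sample(1:2, 400, TRUE),
                                             each = 5))
  out_u <- stratify_by_roi(tracks_u, labels_u, roi, pixel_size_um = 0.5)
  d <- abs(diff(out_u$fraction_slow))
  expect_lt(d, 3 * sqrt(0.25 / 200 + 0.25 / 200))

  # an empty region yields the NA sentinel with a zero count
  far <- tracks[tracks$track_id <= 30, ]
  far_lab <- labels[labels$track_id <= 30, ]
  out_e <- stratify_by_roi(far, far_lab, roi, pixel_size_um = 0.5)
  expect_equal(out_e$n_tracks[out_e$region == "outside"], 0)
  expect_true(is.na(out_e$fraction_slow[out_e$region == "outside"]))
})

test_that("fit summaries expose the state table and fit metadata", {
  fit <- vb_fit(one_state_tracks(), K = 1, dt = 0.01, n_restarts = 2,
                seed = 66)
  expect_setequal(names(tidy(fit)),
                  c("state", "D_um2_s", "occupancy", "tau_s",
                    "self_transition"))
  g <- glance(fit)
  expect_equal(g$K, 1)
  expect_true(is.finite(g$elbo))
  expect_s3_class(autoplot(fit), "ggplot")
})
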