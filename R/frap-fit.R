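# Model recovery curves expressed on the double-normalized scale, so they
# are directly comparable to observed curves: the bleach pulse removes
# total mass M_post < M_pre, and the double normalization multiplies the
# relative ROI recovery by M_pre / M_post.
model_curves <- function(init, fields, times) {
  sim <- simulate_recovery(fields, times, init$rois)
  m_pre <- mean(init$steady[init$mask])       # = 1 by construction
  m_post <- mean((fields$F + fields$C)[init$mask])
  steady_roi <- vapply(init$rois, function(r) mean(init$steady[r]), numeric(1))
  sim$signal <- sim$signal / steady_roi[sim$roi] * (m_pre / m_post)
  sim
}

default_residence_grid <- function(n = 25) exp(seq(log(0.1), log(100), length.out = n))
default_bound_grid <- function() seq(0, 95, by = 5)

new_frap_fit <- function(surface, D = NA_real_, what = "reaction-diffusion",
                         n_experiments = NA_integer_) {
  valid <- surface[surface$valid, , drop = FALSE]
  if (!nrow(valid)) stopf("all parameter combinations failed to simulate")
  # deterministic tie-break: smallest residence time, then smallest bound
  ord <- order(valid$mse, valid$residence_s, valid$bound_pct)
  best <- valid[ord[1], , drop = FALSE]
  region <- valid[valid$mse <= 1.01 * best$mse, , drop = FALSE]
  structure(list(surface = surface, best = best, region = region,
                 D = D, model = what, n_experiments = n_experiments),
            class = "frap_fit")
}

#' Grid-search fit of residence time and bound fraction to FRAP data
#'
#' For every cell of a (residence time x bound fraction) grid the
#' reaction-diffusion model is re-initialized per replicate from that
#' replicate's own image-derived initialization (`koff = 1/residence`,
#' free level from the bound fraction, binding-rate map recomputed from
#' the steady-state image), simulated at the observed frame times, and
#' compared to the double-normalized recovery at both measurement
#' locations. Mean squared errors are summed over replicates; the best
#' cell and all cells within 1% of its error are reported.
#'
#' @param experiments List of [frap_experiment()] objects (>= 1), each
#'   with its own nucleus shape and bleach profile.
#' @param D Fixed diffusion constant (um^2/s), typically estimated from a
#'   non-binding control with [fit_diffusion_only()].
#' @param residence_grid Residence times (s) to scan; default 25 points
#'   log-spaced on 0.1-100 s.
#' @param bound_grid Bound fractions (%) to scan; default 0-95 step 5.
#' @return Object of class `frap_fit`; see [tidy.frap_fit()] and
#'   [glance.frap_fit()].
#' @export
grid_fit <- function(experiments, D,
                     residence_grid = default_residence_grid(),
                     bound_grid = default_bound_grid()) {
  stopifnot(length(experiments) >= 1,
            length(residence_grid) >= 1, length(bound_grid) >= 1)
  grid <- tidyr::expand_grid(residence_s = sort(residence_grid),
                             bound_pct = sort(bound_grid))
  mse <- numeric(nrow(grid))
  valid <- rep(TRUE, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    koff <- 1 / grid$residence_s[g]
    res <- try({
      total <- 0
      for (ex in experiments) {
        fields <- fields_from_init(ex$init, D, koff, grid$bound_pct[g])
        m <- model_curves(ex$init, fields, ex$times)
        keep <- rep(ex$fit_frames, 2)
        total <- total +
          mean((m$signal[keep] - ex$observed$fit_target[keep])^2)
      }
      total
    }, silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res)) {
      valid[g] <- FALSE
      mse[g] <- NA_real_
      inform(sprintf("grid cell (residence %.3g s, bound %.3g%%) failed; excluded",
                     grid$residence_s[g], grid$bound_pct[g]))
    } else mse[g] <- res
  }
  grid$mse <- mse
  grid$valid <- valid
  new_frap_fit(grid, D = D, what = "reaction-diffusion",
               n_experiments = length(experiments))
}

#' Diffusion-only fit of FRAP data
#'
#' Fits the pure-diffusion limit of the model (no bound pool: the whole
#' post-bleach signal diffuses with constant `D`) over a grid of diffusion
#' constants. Used to estimate `D` from a non-binding control construct.
#'
#' @param experiments List of [frap_experiment()] objects.
#' @param D_grid Diffusion constants (um^2/s) to scan.
#' @return Object of class `frap_fit` whose surface has a `D` column; the
#'   best-fit `D` is in `glance()$D_best`.
#' @export
fit_diffusion_only <- function(experiments, D_grid) {
  stopifnot(length(experiments) >= 1, length(D_grid) >= 1)
  D_grid <- sort(D_grid)
  mse <- numeric(length(D_grid))
  valid <- rep(TRUE, length(D_grid))
  for (g in seq_along(D_grid)) {
    res <- try({
      total <- 0
      for (ex in experiments) {
        init <- ex$init
        F0 <- init$total0
        fields <- structure(list(
          F = F0, C = matrix(0, nrow(F0), ncol(F0)),
          k1 = matrix(0, nrow(F0), ncol(F0)), koff = 0, D = D_grid[g],
          mask = init$mask,
          pixel_size_um = rep(init$pixel_size_um, length.out = 2),
          i_st = init$steady, i_avg_st = 1, free_level = 1),
          class = "frap_fields")
        m <- model_curves(init, fields, ex$times)
        keep <- rep(ex$fit_frames, 2)
        total <- total +
          mean((m$signal[keep] - ex$observed$fit_target[keep])^2)
      }
      total
    }, silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res)) {
      valid[g] <- FALSE
      mse[g] <- NA_real_
    } else mse[g] <- res
  }
  surface <- tibble(residence_s = NA_real_, bound_pct = 0,
                    D = D_grid, mse = mse, valid = valid)
  fit <- new_frap_fit(surface, D = NA_real_, what = "diffusion-only",
                      n_experiments = length(experiments))
  fit$D <- fit$best$D
  fit
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit: %s> %d grid cells (%d valid), %d replicate(s)\n",
              x$model, nrow(x$surface), sum(x$surface$valid),
              x$n_experiments))
  if (x$model == "diffusion-only") {
    cat(sprintf("  best D = %.3g um^2/s (mse %.3g)\n", x$best$D, x$best$mse))
  } else {
    cat(sprintf("  best: residence %.3g s, bound %.3g%% (mse %.3g); %d cells within 1%%\n",
                x$best$residence_s, x$best$bound_pct, x$best$mse,
                nrow(x$region)))
  }
  invisible(x)
}

#' Tidy the error surface of a FRAP grid fit
#'
#' @param x A `frap_fit` object.
#' @param ... Unused.
#' @return Tibble of grid cells with `mse`, `valid`, and logical
#'   `in_region` (within 1% of the best error).
#' @export
tidy.frap_fit <- function(x, ...) {
  s <- as_tibble(x$surface)
  key <- if (x$model == "diffusion-only") "D" else c("residence_s", "bound_pct")
  s$in_region <- FALSE
  s$in_region[s$valid][
    interaction(s[s$valid, key]) %in% interaction(x$region[, key])] <- TRUE
  s
}

#' One-row summary of a FRAP grid fit
#'
#' @param x A `frap_fit` object.
#' @param ... Unused.
#' @return Tibble with the best-fit parameters, the best mean squared
#'   error, the size of the 1% region, and the number of replicates.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(model = x$model,
         D_fixed = if (x$model == "diffusion-only") NA_real_ else x$D,
         D_best = if (x$model == "diffusion-only") x$best$D else x$D,
         residence_s = x$best$residence_s,
         bound_pct = x$best$bound_pct,
         mse = x$best$mse,
         n_region = nrow(x$region),
         n_experiments = x$n_experiments)
}

#' Plot the FRAP fit error surface
#'
#' @param object A `frap_fit` object.
#' @param ... Unused.
#' @return A ggplot: log10 error over the parameter grid with the 1%
#'   region highlighted, or the error-vs-D profile for diffusion-only
#'   fits.
#' @export
autoplot.frap_fit <- function(object, ...) {
  s <- tidy(object)
  if (object$model == "diffusion-only") {
    return(ggplot(s[s$valid, ], aes(x = .data$D, y = .data$mse)) +
             geom_line() + geom_point(aes(colour = .data$in_region)) +
             labs(x = "D (um²/s)", y = "summed MSE",
                  colour = "within 1%") +
             theme_minimal())
  }
  ggplot(s[s$valid, ],
         aes(x = .data$residence_s, y = .data$bound_pct,
             fill = log10(.data$mse))) +
    geom_tile() +
    geom_point(data = s[s$in_region, ], shape = 21, fill = "white",
               size = 1.2) +
    ggplot2::scale_x_log10() +
    scale_fill_viridis_c() +
    labs(x = "residence time (s)", y = "bound fraction (%)",
         fill = "log10 MSE") +
    theme_minimal()
}
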