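#' Log-likelihood of one displacement under a diffusive state
#'
#' Displacements of a molecule diffusing with coefficient `D` observed at
#' interval `dt` with localization error `loc_error_nm` are isotropic
#' Gaussian with per-axis variance `2 * D * dt + 2 * sigma_loc^2`.
#'
#' @param dx,dy Displacement components, um (vectorized).
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param dt Frame interval, s (> 0).
#' @param loc_error_nm Localization error sd, nm.
#' @return Log density (per displacement).
#' @export
step_loglik <- function(dx, dy, D, dt, loc_error_nm = 0) {
  if (D < 0 || dt <= 0) stopf("D must be >= 0 and dt > 0")
  s <- 2 * D * dt + 2 * (loc_error_nm / 1000)^2
  r2 <- dx^2 + dy^2
  if (s == 0) return(ifelse(r2 == 0, Inf, -Inf))
  -log(2 * pi * s) - r2 / (2 * s)
}

# Displacement table for HMM fitting: one row per step, tracks with fewer
# than `min_steps` displacements dropped (the track-length filter).
track_displacements <- function(tracks, min_steps = 3) {
  tracks <- arrange(as_tibble(tracks), .data$track_id, .data$frame)
  g <- split(seq_len(nrow(tracks)), tracks$track_id)
  keep <- vapply(g, length, integer(1)) >= min_steps + 1
  g <- g[keep]
  if (!length(g)) stopf("no tracks with >= %d displacements", min_steps)
  steps <- lapply(g, function(idx) {
    x <- tracks$x_um[idx]; y <- tracks$y_um[idx]
    tibble(track_id = tracks$track_id[idx[1]],
           step = seq_len(length(idx) - 1),
           dx = diff(x), dy = diff(y))
  })
  steps <- bind_rows(steps)
  steps$r2 <- steps$dx^2 + steps$dy^2
  steps
}

kl_dirichlet <- function(alpha_q, alpha_p) {
  a0q <- sum(alpha_q); a0p <- sum(alpha_p)
  lgamma(a0q) - sum(lgamma(alpha_q)) - lgamma(a0p) + sum(lgamma(alpha_p)) +
    sum((alpha_q - alpha_p) * (digamma(alpha_q) - digamma(a0q)))
}

kl_gamma <- function(aq, bq, ap, bp) {
  (aq - ap) * digamma(aq) - lgamma(aq) + lgamma(ap) +
    ap * (log(bq) - log(bp)) + aq * (bp - bq) / bq
}

# One VB run from a given initialization of the emission hyperparameters;
# `state` can carry the full hyperparameter set of an earlier run so a
# promising restart can be continued to convergence.
vb_run <- function(r2, track_start, track_len, K, dt, sig2_loc,
                   a_lam, b_lam, prior, max_iter, tol, state = NULL) {
  n <- length(r2)
  prior_A <- matrix(prior$alpha_A, K, K) +
    diag(prior$alpha_A_diag %||% 0, K)
  alpha_pi <- state$alpha_pi %||% rep(prior$alpha_pi, K)
  alpha_A <- state$alpha_A %||% prior_A
  if (!is.null(state)) {
    a_lam <- state$a_lam
    b_lam <- state$b_lam
  }
  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE

  estep <- function(want_gamma = FALSE) {
    vb_forward_backward_cpp(r2,
                            digamma(a_lam) - log(b_lam), a_lam / b_lam,
                            track_start, track_len,
                            digamma(alpha_pi) - digamma(sum(alpha_pi)),
                            digamma(alpha_A) - digamma(rowSums(alpha_A)),
                            want_gamma = want_gamma)
  }
  for (it in seq_len(max_iter)) {
    fb <- estep()

    elbo <- fb$loglik - kl_dirichlet(alpha_pi, rep(prior$alpha_pi, K))
    for (k in seq_len(K)) {
      elbo <- elbo - kl_dirichlet(alpha_A[k, ], prior_A[k, ]) -
        kl_gamma(a_lam[k], b_lam[k], prior$a0, prior$b0)
    }
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_prev) && abs(elbo - elbo_prev) <
        tol * (abs(elbo) + 1e-12)) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo

    alpha_pi <- prior$alpha_pi + fb$init
    alpha_A <- prior_A + fb$xi
    a_lam <- prior$a0 + fb$N_k
    b_lam <- prior$b0 + fb$S_k / 2
  }

  fb <- estep(want_gamma = TRUE)
  s_hat <- b_lam / pmax(a_lam - 1, 1e-9)   # posterior mean step variance
  D_hat <- pmax((s_hat - 2 * sig2_loc) / (2 * dt), 0)
  A_hat <- alpha_A / rowSums(alpha_A)
  list(elbo = elbo_trace[length(elbo_trace)], elbo_trace = elbo_trace,
       converged = converged, n_iter = length(elbo_trace),
       D = D_hat, occupancy = fb$N_k / sum(fb$N_k), A = A_hat,
       gamma = fb$gamma, a_lam = a_lam, b_lam = b_lam,
       alpha_pi = alpha_pi, alpha_A = alpha_A)
}

#' Variational-Bayes HMM fit of diffusion states to tracks
#'
#' Fits a K-state hidden Markov model to track displacements by
#' variational expectation-maximization: Dirichlet priors on the initial
#' distribution and on each transition-matrix row, a Gamma prior on each
#' state's step precision, forward-backward responsibilities in the
#' E-step, and conjugate hyperparameter updates in the M-step. The
#' evidence lower bound (ELBO) is monotone across iterations and is used
#' by [select_model()] to choose K. Multiple restarts guard against local
#' optima; states are reported sorted by diffusion coefficient.
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`); only
#'   tracks with more than three displacements are used.
#' @param K Number of states (>= 1).
#' @param dt Frame interval, s; defaults to the `dt` attribute of
#'   `tracks` when present.
#' @param loc_error_nm Localization error included in the emission
#'   variance (default 33 nm, the fixed-sample precision estimate).
#' @param n_restarts Random restarts (default 10). Each restart is run
#'   for `explore_iter` iterations and the most promising one is then
#'   continued to convergence, which is where VB spends its time.
#' @param explore_iter Exploration iterations per restart (default 50).
#' @param max_iter,tol Iteration cap and relative ELBO tolerance for the
#'   final convergence phase.
#' @param prior Prior hyperparameters: `alpha_pi` and `alpha_A`
#'   (Dirichlet weights), `alpha_A_diag` (extra pseudocount on the
#'   transition-matrix diagonal; the default 9 encodes the expectation
#'   that states persist for a few frames, which stops the model from
#'   splitting a slow state by step magnitude instead of by molecule),
#'   and `a0`, `b0` for the Gamma precision prior (`b0 = NULL` sets a
#'   weak prior centred on D = 0.5 um^2/s).
#' @param seed Integer seed controlling the restarts.
#' @return Object of class `sm_diffusion_fit` with per-state `D`
#'   (um^2/s), `occupancy`, transition matrix `A`, dwell times `tau_s`,
#'   the ELBO, the per-step state posteriors, and a convergence flag.
#' @export
vb_fit <- function(tracks, K, dt = NULL, loc_error_nm = 33,
                   n_restarts = 10, explore_iter = 50, max_iter = 1000,
                   tol = 1e-9,
                   prior = list(alpha_pi = 1, alpha_A = 1,
                                alpha_A_diag = 9, a0 = 1, b0 = NULL),
                   seed = NULL) {
  if (K < 1) stopf("K must be >= 1")
  dt <- dt %||% attr(tracks, "dt")
  if (is.null(dt)) stopf("dt must be given (or carried by the tracks)")
  steps <- track_displacements(tracks, min_steps = 3)
  sig2_loc <- (loc_error_nm / 1000)^2
  prior$b0 <- prior$b0 %||% (prior$a0 * (2 * 0.5 * dt + 2 * sig2_loc))

  lens <- as.integer(table(factor(steps$track_id,
                                  levels = unique(steps$track_id))))
  start <- c(0L, cumsum(lens)[-length(lens)])
  r2 <- steps$r2

  # restart initializations: emission variances seeded from the data's
  # squared-displacement quantiles, with the quantile span varied across
  # restarts (wide, low-heavy, high-heavy, ...) plus lognormal jitter, so
  # the restarts explore structurally different state layouts
  spans <- list(c(0.15, 0.90), c(0.05, 0.70), c(0.30, 0.95),
                c(0.05, 0.95), c(0.10, 0.60))
  seeds <- if (is.null(seed)) rep(list(NULL), n_restarts) else
    lapply(seq_len(n_restarts), function(i) derive_seed(seed, i))
  runs <- vector("list", n_restarts)
  for (rs in seq_len(n_restarts)) {
    span <- spans[[(rs - 1) %% length(spans) + 1]]
    qs <- quantile(r2[r2 > 0],
                   probs = seq(span[1], span[2], length.out = max(K, 2)))
    init_s <- with_seed(seeds[[rs]], {
      jit <- exp(rnorm(K, 0, 0.4))
      sort(pmax(qs[seq_len(K)] * jit / 2, 1e-8))
    })
    a_init <- rep(5, K)
    b_init <- a_init * init_s
    runs[[rs]] <- vb_run(r2, start, lens, K, dt, sig2_loc,
                         a_lam = a_init, b_lam = b_init, prior = prior,
                         max_iter = explore_iter, tol = tol)
  }
  # exploration-phase ELBO ranks restarts imperfectly (slow-state splits
  # emerge late), so promising runs get a medium budget before the best
  # few are continued all the way to convergence
  continue_runs <- function(idx, budget) {
    for (rs in idx) {
      run <- runs[[rs]]
      if (run$converged) next
      cont <- vb_run(r2, start, lens, K, dt, sig2_loc,
                     a_lam = run$a_lam, b_lam = run$b_lam, prior = prior,
                     max_iter = budget, tol = tol, state = run)
      cont$elbo_trace <- c(run$elbo_trace, cont$elbo_trace)
      runs[[rs]] <<- cont
    }
  }
  rank_runs <- function() order(vapply(runs, function(r) r$elbo,
                                       numeric(1)), decreasing = TRUE)
  continue_runs(rank_runs()[seq_len(min(5, n_restarts))], 250)
  continue_runs(rank_runs()[seq_len(min(3, n_restarts))], max_iter)
  best <- runs[[rank_runs()[1]]]

  ord <- order(best$D)
  gam <- best$gamma[, ord, drop = FALSE]
  ann <- steps[, c("track_id", "step")]
  ann$map_state <- max.col(gam)
  A <- best$A[ord, ord, drop = FALSE]
  structure(list(
    K = K, dt = dt, loc_error_nm = loc_error_nm,
    D = best$D[ord], occupancy = best$occupancy[ord], A = A,
    tau_s = mean_dwell_times(A, dt),
    elbo = best$elbo, elbo_trace = best$elbo_trace,
    converged = best$converged, n_iter = best$n_iter,
    posterior = gam, annotation = ann,
    n_tracks = length(lens), n_steps = length(r2)
  ), class = "sm_diffusion_fit")
}

#' @export
print.sm_diffusion_fit <- function(x, ...) {
  cat(sprintf("<sm_diffusion_fit> K=%d, %d tracks, %d steps, ELBO %.1f%s\n",
              x$K, x$n_tracks, x$n_steps, x$elbo,
              if (x$converged) "" else " (not converged)"))
  print(tidy(x))
  invisible(x)
}

#' Per-state summary of a diffusion-state fit
#'
#' @param x An `sm_diffusion_fit`.
#' @param ... Unused.
#' @return Tibble: `state` (1 = slowest), `D_um2_s`, `occupancy`,
#'   `tau_s` (mean dwell time), `self_transition`.
#' @export
tidy.sm_diffusion_fit <- function(x, ...) {
  tibble(state = seq_len(x$K), D_um2_s = x$D, occupancy = x$occupancy,
         tau_s = x$tau_s, self_transition = diag(x$A))
}

#' One-row summary of a diffusion-state fit
#' @param x An `sm_diffusion_fit`.
#' @param ... Unused.
#' @export
glance.sm_diffusion_fit <- function(x, ...) {
  tibble(K = x$K, elbo = x$elbo, n_tracks = x$n_tracks,
         n_steps = x$n_steps, n_iter = x$n_iter, converged = x$converged)
}

#' Plot a diffusion-state fit
#'
#' @param object An `sm_diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot of state occupancies against diffusion coefficients.
#' @export
autoplot.sm_diffusion_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$D_um2_s, y = .data$occupancy)) +
    ggplot2::geom_col(width = 0.05) +
    ggplot2::scale_x_log10() +
    labs(x = "D (um²/s)", y = "occupancy") +
    theme_minimal()
}

#' Select the number of diffusive states by the evidence lower bound
#'
#' Fits `K = 1 .. K_max` with [vb_fit()] and returns the fit maximizing
#' the ELBO together with the full model table.
#'
#' @param tracks Track tibble.
#' @param K_max Largest state count to consider.
#' @param ... Passed to [vb_fit()].
#' @return List with `best_K`, `best_fit`, `fits` (all fits), and
#'   `table` (tibble of K and ELBO).
#' @export
select_model <- function(tracks, K_max, ...) {
  stopifnot(K_max >= 1)
  fits <- lapply(seq_len(K_max), function(k) vb_fit(tracks, K = k, ...))
  tab <- bind_rows(lapply(fits, glance))
  best <- which.max(tab$elbo)
  list(best_K = tab$K[best], best_fit = fits[[best]], fits = fits,
       table = tab)
}
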