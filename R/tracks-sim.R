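#' Discrete diffusion-state model
#'
#' A K-state hidden Markov model of molecular motion: each state k has a
#' diffusion coefficient `D[k]` (um^2/s), the chain starts from the
#' occupancy vector `pi` and evolves with the per-step transition matrix
#' `A`. Mean dwell times follow as `dt / (1 - A[k, k])`.
#'
#' @param D Diffusion coefficients, um^2/s (non-negative; stored sorted
#'   ascending together with the matching rows of `pi` and `A`).
#' @param pi Occupancies (must sum to 1).
#' @param A K x K transition matrix (rows must sum to 1).
#' @return Object of class `diffusion_state_model`.
#' @export
diffusion_state_model <- function(D, pi, A) {
  K <- length(D)
  stopifnot(length(pi) == K, all(dim(A) == K))
  if (any(D < 0)) stopf("all diffusion coefficients must be >= 0")
  if (abs(sum(pi) - 1) > 1e-8) stopf("occupancies must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-8) || any(A < 0))
    stopf("transition matrix rows must be non-negative and sum to 1")
  ord <- order(D)
  structure(list(K = K, D = D[ord], pi = pi[ord],
                 A = A[ord, ord, drop = FALSE]),
            class = "diffusion_state_model")
}

#' Canonical four-state model of a transiently DNA-binding factor
#'
#' The benchmark parameter set used throughout the package: four diffusive
#' states ranging from specific DNA binding (B1, D = 0.09 um^2/s, 22% of
#' molecules) through non-specific chromatin interaction (B2,
#' D = 0.22 um^2/s) and obstructed diffusion (F2, D = 0.50 um^2/s) to free
#' diffusion (F1, D = 1.89 um^2/s, 21%). The occupancies of the two
#' intermediate states are split 27/30 so all four sum to one. Transitions
#' are sticky: `A = a * I + (1 - a) * 1 pi'`, which leaves `pi` exactly
#' stationary while giving every state a self-transition probability of at
#' least `a`; at `a = 0.9` and 10 ms steps the bound-state mean dwell time
#' is ~0.1 s.
#'
#' @param self_transition Baseline stickiness `a` in \[0, 1).
#' @return A [diffusion_state_model()].
#' @export
su_h_four_state_model <- function(self_transition = 0.9) {
  D <- c(B1 = 0.09, B2 = 0.22, F2 = 0.50, F1 = 1.89)
  pi <- c(B1 = 0.22, B2 = 0.27, F2 = 0.30, F1 = 0.21)
  a <- self_transition
  A <- a * diag(4) + (1 - a) * matrix(pi, 4, 4, byrow = TRUE)
  diffusion_state_model(unname(D), unname(pi), unname(A))
}

#' Mean dwell times of a transition matrix
#'
#' Geometric mean sojourn per state: `tau_k = dt / (1 - A[k, k])`, with an
#' infinite sentinel for absorbing states.
#'
#' @param A Transition matrix (rows summing to 1).
#' @param dt Frame interval, s.
#' @return Numeric vector of mean dwell times (s).
#' @export
mean_dwell_times <- function(A, dt) {
  if (any(abs(rowSums(A) - 1) > 1e-8)) stopf("rows of A must sum to 1")
  akk <- diag(A)
  ifelse(akk >= 1, Inf, dt / (1 - akk))
}

#' Simulate multi-state single-molecule trajectories
#'
#' Hidden states follow the Markov chain of `model`; given the state, each
#' displacement is isotropic Gaussian with per-axis variance
#' `2 * D_state * dt`. Trajectories can be confined to a nucleus mask with
#' reflecting boundaries, are snapped to a spatial discretization grid
#' (15 nm by default), and can carry iid Gaussian localization error.
#'
#' @param model A [diffusion_state_model()].
#' @param dt Frame interval, s.
#' @param n_tracks Number of tracks.
#' @param mean_length Mean number of positions per track (geometric
#'   length distribution, folding track termination and photobleaching
#'   into one per-frame survival probability); minimum length 2.
#' @param geometry Optional [make_nucleus()] mask to confine motion
#'   (reflecting boundary); `NULL` for unconfined motion in a nominal
#'   field of view.
#' @param fov_um Field of view (um) used when `geometry` is `NULL`.
#' @param resolution_nm Spatial discretization of the stored positions.
#' @param loc_error_nm Localization error sd added independently to every
#'   stored position (0 = perfect localization).
#' @param seed Integer seed.
#' @return Tibble with columns `track_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `state` (ground-truth state of the step starting at this position);
#'   the generating model is attached as attribute `model`.
#' @export
simulate_tracks <- function(model, dt, n_tracks, mean_length = 10,
                            geometry = NULL, fov_um = c(10, 10),
                            resolution_nm = 15, loc_error_nm = 0,
                            seed = NULL) {
  stopifnot(inherits(model, "diffusion_state_model"))
  if (dt <= 0) stopf("dt must be > 0")
  if (resolution_nm <= 0) stopf("resolution must be > 0")
  res_um <- resolution_nm / 1000
  sd_step <- sqrt(2 * model$D * dt)

  inside <- if (is.null(geometry)) {
    function(x, y) x >= 0 & x <= fov_um[1] & y >= 0 & y <= fov_um[2]
  } else {
    m <- geometry$mask
    p <- geometry$pixel_size_um
    function(x, y) {
      j <- ceiling(x / p); i <- ceiling(y / p)
      ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
      ok[ok] <- m[cbind(i[ok], j[ok])]
      ok
    }
  }
  start_point <- function() {
    repeat {
      if (is.null(geometry)) {
        x <- runif(1, 0, fov_um[1]); y <- runif(1, 0, fov_um[2])
      } else {
        idx <- sample(which(geometry$mask), 1)
        m <- geometry$mask
        y <- (row(m)[idx] - 0.5) * geometry$pixel_size_um
        x <- (col(m)[idx] - 0.5) * geometry$pixel_size_um
      }
      if (inside(x, y)) return(c(x, y))
    }
  }

  with_seed(seed, {
    lens <- pmax(2L, rgeom(n_tracks, prob = 1 / max(mean_length, 1.001)) + 1L)
    out <- vector("list", n_tracks)
    for (tr in seq_len(n_tracks)) {
      L <- lens[tr]
      states <- integer(L - 1)
      states[1] <- sample.int(model$K, 1, prob = model$pi)
      if (L > 2) for (s in 2:(L - 1))
        states[s] <- sample.int(model$K, 1, prob = model$A[states[s - 1], ])
      xs <- ys <- numeric(L)
      p0 <- start_point()
      xs[1] <- p0[1]; ys[1] <- p0[2]
      snap <- function(v) round(v / res_um) * res_um
      xs[1] <- snap(xs[1]); ys[1] <- snap(ys[1])
      if (!inside(xs[1], ys[1])) { xs[1] <- p0[1]; ys[1] <- p0[2] }
      for (s in seq_len(L - 1)) {
        sdv <- sd_step[states[s]]
        dx <- rnorm(1, 0, sdv); dy <- rnorm(1, 0, sdv)
        nx <- snap(xs[s] + dx); ny <- snap(ys[s] + dy)
        if (!inside(nx, ny)) {
          # reflect the step back across the starting point; if that also
          # leaves the domain, the molecule stays put for this frame
          nx <- snap(xs[s] - dx); ny <- snap(ys[s] - dy)
          if (!inside(nx, ny)) {
            nx <- xs[s]; ny <- ys[s]
          }
        }
        xs[s + 1] <- nx; ys[s + 1] <- ny
      }
      if (loc_error_nm > 0) {
        xs <- snap(xs + rnorm(L, 0, loc_error_nm / 1000))
        ys <- snap(ys + rnorm(L, 0, loc_error_nm / 1000))
      }
      out[[tr]] <- tibble(track_id = tr, frame = seq_len(L) - 1L,
                          t_s = (seq_len(L) - 1L) * dt,
                          x_um = xs, y_um = ys,
                          state = c(states, states[L - 1]))
    }
    tracks <- bind_rows(out)
    attr(tracks, "model") <- model
    attr(tracks, "dt") <- dt
    tracks
  })
}
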