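#' Diffusion-coefficient state grid for Bayesian state-array inference
#'
#' A fixed log-spaced grid of candidate diffusion coefficients over which
#' per-trajectory likelihoods are aggregated into posterior occupancies.
#' The likelihood is regular Brownian motion with localization error
#' (RBME); the bound fraction is the cumulative occupancy strictly below
#' \code{bound_threshold_um2s}.
#'
#' @param n_states Grid size (default 100).
#' @param D_min_um2s,D_max_um2s Grid range (um^2/s).
#' @param loc_error_um Localization error sigma (um), treated as known.
#' @param frame_interval_s Frame interval (s).
#' @param focal_depth_um Focal slab depth (um) for the defocalization
#'   correction.
#' @param bound_threshold_um2s Bound/free threshold (um^2/s); must lie
#'   inside the grid range.
#' @param infer_start_frame Trajectories beginning before this frame are
#'   excluded from inference.
#' @param max_sample At most this many trajectories enter the posterior
#'   (uniform random, seeded).
#' @return Object of class \code{state_grid} with element \code{D} (the
#'   grid values).
#' @export
state_grid <- function(n_states = 100L, D_min_um2s = 1e-2, D_max_um2s = 1e2,
                       loc_error_um = 0.035, frame_interval_s = 0.00748,
                       focal_depth_um = 0.7, bound_threshold_um2s = 0.1,
                       infer_start_frame = 1000L, max_sample = 1000000L) {
  stopifnot_scalar(n_states, "n_states", 2)
  stopifnot_scalar(D_min_um2s, "D_min_um2s", 1e-12)
  stopifnot_scalar(D_max_um2s, "D_max_um2s", D_min_um2s)
  stopifnot_scalar(loc_error_um, "loc_error_um", 0)
  stopifnot_scalar(frame_interval_s, "frame_interval_s", 1e-9)
  stopifnot_scalar(focal_depth_um, "focal_depth_um", 1e-6)
  if (bound_threshold_um2s <= D_min_um2s || bound_threshold_um2s >= D_max_um2s) {
    stop("bound_threshold_um2s must lie inside the grid range")
  }
  structure(list(
    D = exp(seq(log(D_min_um2s), log(D_max_um2s), length.out = n_states)),
    loc_error_um = loc_error_um, frame_interval_s = frame_interval_s,
    focal_depth_um = focal_depth_um,
    bound_threshold_um2s = bound_threshold_um2s,
    infer_start_frame = as.integer(infer_start_frame),
    max_sample = as.integer(max_sample)
  ), class = "state_grid")
}

# Split a trajectory table into per-trajectory lag-1 jump vectors.
# Frames must be consecutive within a trajectory (no blinking gaps).
trajectory_jumps <- function(tracks) {
  dt <- data.table::as.data.table(tracks)
  if (!all(is.finite(dt$x_um)) || !all(is.finite(dt$y_um))) {
    stop("non-finite coordinates in trajectory table")
  }
  data.table::setorderv(dt, c("movie_id", "trajectory_id", "frame"))
  dt[, `:=`(dx = c(diff(x_um), NA_real_), dy = c(diff(y_um), NA_real_),
            dfr = c(diff(frame), NA_integer_)),
     by = .(movie_id, trajectory_id)]
  jumps <- dt[!is.na(dt$dfr), ]
  if (!nrow(jumps)) stop("no trajectories with at least one jump")
  if (any(jumps$dfr != 1L)) {
    stop("trajectories must have consecutive frames (no gaps)")
  }
  jumps[, .(dx = list(dx), dy = list(dy), n_jumps = .N,
            start_frame = min(frame)),
        by = .(movie_id, trajectory_id)]
}

#' Per-trajectory RBME log-likelihoods over a state grid
#'
#' Under regular Brownian motion with localization error, the lag-1 jump
#' vector of a trajectory is zero-mean Gaussian per coordinate with
#' tridiagonal covariance: diagonal \code{2 D dt + 2 sigma^2}, first
#' off-diagonal \code{-sigma^2} (successive jumps share one noisy
#' endpoint). The density is evaluated exactly via the tridiagonal LDL
#' factorization, shared across all trajectories of equal length; x and y
#' contribute independently.
#'
#' @param tracks Trajectory table (\code{movie_id, trajectory_id, frame,
#'   x_um, y_um}); frames consecutive within trajectories.
#' @param grid A [state_grid()].
#' @return List: \code{loglik} (matrix, trajectory x grid state),
#'   \code{n_jumps} per trajectory, \code{keys} (movie/trajectory ids).
#' @export
trajectory_log_likelihoods <- function(tracks, grid) {
  stopifnot(inherits(grid, "state_grid"))
  jt <- trajectory_jumps(tracks)
  jt <- jt[jt$n_jumps >= 1L, ]
  if (!nrow(jt)) stop("no trajectories with at least one jump")
  dt <- grid$frame_interval_s
  s2 <- grid$loc_error_um^2
  nD <- length(grid$D)
  ll <- matrix(NA_real_, nrow(jt), nD)
  for (n in sort(unique(jt$n_jumps))) {
    rows <- which(jt$n_jumps == n)
    Vx <- matrix(unlist(jt$dx[rows]), nrow = n)  # n x m
    Vy <- matrix(unlist(jt$dy[rows]), nrow = n)
    for (j in seq_len(nD)) {
      a <- 2 * grid$D[j] * dt + 2 * s2
      b <- -s2
      d <- numeric(n)
      d[1] <- a
      Ux <- Vx; Uy <- Vy
      if (n > 1) {
        for (k in 2:n) {
          l <- b / d[k - 1]
          d[k] <- a - b * l
          Ux[k, ] <- Vx[k, ] - l * Ux[k - 1, ]
          Uy[k, ] <- Vy[k, ] - l * Uy[k - 1, ]
        }
      }
      quad <- colSums(Ux^2 / d) + colSums(Uy^2 / d)
      ll[rows, j] <- -0.5 * quad - sum(log(d)) - n * log(2 * pi)
    }
  }
  list(loglik = ll, n_jumps = jt$n_jumps,
       keys = jt[, c("movie_id", "trajectory_id")])
}

#' Defocalization survival weights
#'
#' Probability that a Brownian particle with diffusion coefficient D,
#' started uniformly inside an absorbing slab of depth L, remains inside
#' through \code{track_length} frames:
#' \code{S(t) = sum over odd k of (8 / (k^2 pi^2)) exp(-k^2 pi^2 D t / L^2)},
#' truncated when terms fall below 1e-10. Used to debias posterior
#' occupancies for the preferential loss of fast molecules from the focal
#' slab.
#'
#' @param grid A [state_grid()].
#' @param track_length Number of frames survived (>= 1).
#' @return Numeric vector of weights in (0, 1\], one per grid state.
#' @export
defocalization_weights <- function(grid, track_length = 1L) {
  stopifnot(inherits(grid, "state_grid"))
  stopifnot_scalar(track_length, "track_length", 1)
  t <- track_length * grid$frame_interval_s
  L <- grid$focal_depth_um
  vapply(grid$D, function(D) {
    if (D <= 0) return(1)
    s <- 0
    k <- 1
    repeat {
      term <- 8 / (k^2 * pi^2) * exp(-k^2 * pi^2 * D * t / L^2)
      s <- s + term
      if (term < 1e-10 || k > 1e5) break
      k <- k + 2
    }
    min(s, 1)
  }, numeric(1))
}

#' Bayesian state-array posterior over the diffusion grid
#'
#' Aggregates per-trajectory likelihoods into posterior occupancies by the
#' iterative responsibility update
#' \code{r_ij \%prop\% tau_j L_ij},
#' \code{tau_j <- (alpha - 1 + sum_i r_ij) / sum_j (...)},
#' run to a relative change below \code{tol} or \code{max_iter}
#' iterations, with a uniform Dirichlet prior (pseudocount 1). Final
#' occupancies are debiased by the one-frame defocalization survival
#' weight of each state and renormalized. At most \code{grid$max_sample}
#' trajectories are used (uniform random, seeded).
#'
#' @param ll Result of [trajectory_log_likelihoods()] (or a compatible
#'   list with \code{loglik} and \code{n_jumps}).
#' @param grid A [state_grid()].
#' @param prior_pseudocounts Dirichlet pseudocount alpha (default 1,
#'   uniform).
#' @param tol,max_iter Convergence controls.
#' @param seed Seed for the trajectory subsample.
#' @param defoc_correction Apply the defocalization debias.
#' @return Object of class \code{posterior_spectrum}: \code{D},
#'   \code{occupancy} (sums to 1), \code{occupancy_naive},
#'   \code{n_trajectories}, \code{n_jumps}, \code{iterations}.
#' @export
state_array_posterior <- function(ll, grid, prior_pseudocounts = 1,
                                  tol = 1e-6, max_iter = 250L, seed = 1L,
                                  defoc_correction = TRUE) {
  stopifnot(inherits(grid, "state_grid"))
  L <- ll$loglik
  if (is.null(L)) stop("ll must carry a 'loglik' matrix")
  if (!nrow(L)) stop("empty trajectory set")
  n_jumps <- ll$n_jumps
  if (nrow(L) > grid$max_sample) {
    pick <- with_seed(seed, sample.int(nrow(L), grid$max_sample))
    L <- L[pick, , drop = FALSE]
    n_jumps <- n_jumps[pick]
  }
  W <- exp(L - apply(L, 1, max))
  nD <- ncol(W)
  tau <- rep(1 / nD, nD)
  a0 <- prior_pseudocounts - 1
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.vector(W %*% tau)
    s <- tau * as.vector(crossprod(W, 1 / denom))
    tau_new <- (a0 + s) / sum(a0 + s)
    delta <- sum(abs(tau_new - tau))
    tau <- tau_new
    if (delta < tol || it >= max_iter) break
  }
  naive <- tau
  if (defoc_correction) {
    w <- defocalization_weights(grid, 1L)
    tau <- tau / w
    tau <- tau / sum(tau)
  }
  structure(list(D = grid$D, occupancy = tau, occupancy_naive = naive,
                 n_trajectories = nrow(W), n_jumps = sum(n_jumps),
                 iterations = it),
            class = "posterior_spectrum")
}

#' @export
print.posterior_spectrum <- function(x, ...) {
  cat(sprintf("<posterior_spectrum> %d states, %d trajectories, %d jumps\n",
              length(x$D), x$n_trajectories, x$n_jumps))
  cat(sprintf("  posterior mode at D = %.3g um^2/s; bound fraction (<0.1) = %.3f\n",
              x$D[which.max(x$occupancy)], bound_fraction(x)))
  invisible(x)
}

#' Bound fraction of a posterior spectrum
#'
#' Cumulative posterior occupancy at diffusion coefficients strictly below
#' the threshold (default 0.1 um^2/s); a proxy for the chromatin-engaged
#' share of the tracked molecules.
#'
#' @param spectrum A \code{posterior_spectrum}.
#' @param threshold_um2s Bound/free threshold.
#' @return Proportion in \[0, 1\].
#' @export
bound_fraction <- function(spectrum, threshold_um2s = 0.1) {
  stopifnot(inherits(spectrum, "posterior_spectrum"))
  sum(spectrum$occupancy[spectrum$D < threshold_um2s])
}

#' Diffusion spectrum from a trajectory table
#'
#' Applies the inference start-frame filter (trajectories beginning before
#' \code{grid$infer_start_frame} are excluded), computes RBME likelihoods
#' and runs the state-array posterior.
#'
#' @param tracks Trajectory table.
#' @param grid A [state_grid()].
#' @param seed Seed for the max-sample subsample.
#' @param apply_start_filter Set \code{FALSE} to use every trajectory.
#' @param ... Passed to [state_array_posterior()].
#' @return A \code{posterior_spectrum}.
#' @export
infer_spectrum <- function(tracks, grid, seed = 1L,
                           apply_start_filter = TRUE, ...) {
  dt <- data.table::as.data.table(tracks)
  if (apply_start_filter) {
    first <- dt[, .(f0 = min(frame)), by = .(movie_id, trajectory_id)]
    keep <- first[first$f0 >= grid$infer_start_frame, ]
    dt <- merge(dt, keep[, c("movie_id", "trajectory_id")],
                by = c("movie_id", "trajectory_id"))
  }
  if (!nrow(dt)) stop("no trajectories pass the start-frame filter")
  ll <- trajectory_log_likelihoods(dt, grid)
  state_array_posterior(ll, grid, seed = seed, ...)
}

#' Bound-fraction stability under trajectory subsampling
#'
#' Runs the state-array inference on the full trajectory set and on a
#' seeded uniform random subsample of \code{n_subsample} trajectories, and
#' returns the absolute bound-fraction difference in percentage points —
#' the control used to show that unequal trajectory counts between
#' conditions do not bias the comparison.
#'
#' @param tracks Trajectory table.
#' @param grid A [state_grid()].
#' @param n_subsample Trajectories in the subsample (default 20,000).
#' @param seed Seed for the subsample.
#' @param apply_start_filter Passed to [infer_spectrum()].
#' @return List: \code{diff_points}, \code{bound_full}, \code{bound_sub},
#'   \code{n_full}, \code{n_sub}.
#' @export
subsample_stability <- function(tracks, grid, n_subsample = 20000L,
                                seed = 1L, apply_start_filter = TRUE) {
  dt <- data.table::as.data.table(tracks)
  # restrict to the analyzed population (start filter, >= 1 jump) before
  # subsampling, so n_subsample counts trajectories that enter inference
  info <- dt[, .(f0 = min(frame), n = .N), by = .(movie_id, trajectory_id)]
  if (apply_start_filter) info <- info[info$f0 >= grid$infer_start_frame, ]
  info <- info[info$n >= 2L, ]
  dt <- merge(dt, info[, c("movie_id", "trajectory_id")],
              by = c("movie_id", "trajectory_id"))
  full <- infer_spectrum(dt, grid, seed = seed, apply_start_filter = FALSE)
  ids <- unique(dt[, c("movie_id", "trajectory_id")])
  n_sub <- min(n_subsample, nrow(ids))
  pick <- with_seed(seed, sample.int(nrow(ids), n_sub))
  sub <- merge(dt, ids[pick, ], by = c("movie_id", "trajectory_id"))
  subsp <- infer_spectrum(sub, grid, seed = seed, apply_start_filter = FALSE)
  bf_full <- bound_fraction(full, grid$bound_threshold_um2s)
  bf_sub <- bound_fraction(subsp, grid$bound_threshold_um2s)
  list(diff_points = abs(bf_full - bf_sub) * 100,
       bound_full = bf_full, bound_sub = bf_sub,
       n_full = full$n_trajectories, n_sub = subsp$n_trajectories,
       spectrum_full = full, spectrum_sub = subsp)
}
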