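#' Stroboscopic acquisition settings for single-molecule tracking
#'
#' Defaults match a HILO single-molecule acquisition: 160 nm pixels, 7.48 ms
#' frame interval, 8,000 frames over a 150 x 150 px nuclear ROI, and a
#' 0.7 um focal slab. \code{track_start_frame} discards the dense start of
#' the movie before linking; \code{infer_start_frame} additionally excludes
#' early trajectories from diffusion inference.
#'
#' @param pixel_size_um,frame_interval_s,n_frames,roi_px,focal_depth_um
#'   Acquisition geometry and timing.
#' @param track_start_frame,infer_start_frame Frame cutoffs (see above).
#' @return Object of class \code{acquisition_spec}.
#' @export
acquisition_spec <- function(pixel_size_um = 0.16, frame_interval_s = 0.00748,
                             n_frames = 8000L, roi_px = 150L,
                             focal_depth_um = 0.7,
                             track_start_frame = 100L,
                             infer_start_frame = 1000L) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um", 1e-6)
  stopifnot_scalar(frame_interval_s, "frame_interval_s", 1e-9)
  stopifnot_scalar(n_frames, "n_frames", 2)
  stopifnot_scalar(roi_px, "roi_px", 2)
  stopifnot_scalar(focal_depth_um, "focal_depth_um", 1e-6)
  stopifnot_scalar(track_start_frame, "track_start_frame", 0)
  stopifnot_scalar(infer_start_frame, "infer_start_frame", 0)
  if (infer_start_frame < track_start_frame) {
    stop("infer_start_frame must be >= track_start_frame")
  }
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames), roi_px = as.integer(roi_px),
                 focal_depth_um = focal_depth_um,
                 track_start_frame = as.integer(track_start_frame),
                 infer_start_frame = as.integer(infer_start_frame)),
            class = "acquisition_spec")
}

#' Ground-truth diffusive mixture model
#'
#' A static mixture of Brownian states: each molecule is assigned one
#' diffusion coefficient for its whole trajectory (the state-array model
#' assumption). Within-track switching is available behind
#' \code{allow_switching} for robustness experiments only.
#'
#' @param state_D_um2s Diffusion coefficients (um^2/s), >= 0.
#' @param state_occupancy State proportions, summing to 1.
#' @param loc_error_um Static localization error sigma (um), applied
#'   independently per coordinate per frame.
#' @param bleach_mean_frames Expected track lifetime in frames (geometric
#'   photobleaching).
#' @param allow_switching If \code{TRUE}, molecules re-draw their state each
#'   frame with probability \code{switch_prob}.
#' @param switch_prob Per-frame switching probability when enabled.
#' @return Object of class \code{diffusion_model}.
#' @export
diffusion_model <- function(state_D_um2s = c(0.01, 2.5),
                            state_occupancy = c(0.3, 0.7),
                            loc_error_um = 0.035,
                            bleach_mean_frames = 6,
                            allow_switching = FALSE,
                            switch_prob = 0.1) {
  if (length(state_D_um2s) != length(state_occupancy)) {
    stop("state_D_um2s and state_occupancy must have equal length")
  }
  if (any(state_D_um2s < 0)) stop("diffusion coefficients must be >= 0")
  if (any(state_occupancy < 0) || abs(sum(state_occupancy) - 1) > 1e-9) {
    stop("state_occupancy must be nonnegative and sum to 1")
  }
  stopifnot_scalar(loc_error_um, "loc_error_um", 0)
  stopifnot_scalar(bleach_mean_frames, "bleach_mean_frames", 1)
  structure(list(state_D_um2s = state_D_um2s,
                 state_occupancy = state_occupancy,
                 loc_error_um = loc_error_um,
                 bleach_mean_frames = bleach_mean_frames,
                 allow_switching = isTRUE(allow_switching),
                 switch_prob = switch_prob),
            class = "diffusion_model")
}

# Column-wise cumulative sum over the short (column) dimension of an
# n_tracks x len matrix, vectorized across tracks.
row_cumsum <- function(m) {
  if (ncol(m) > 1) for (k in 2:ncol(m)) m[, k] <- m[, k - 1] + m[, k]
  m
}

#' Simulate single-molecule trajectories from a diffusive mixture
#'
#' Each track draws one state by occupancy, then performs 2D Brownian
#' motion with per-coordinate jump variance 2 D dt. Observed positions add
#' independent Gaussian localization error per coordinate per frame. The
#' axial coordinate diffuses freely from a uniform start inside a slab of
#' depth \code{acq$focal_depth_um}; the track is truncated at its first
#' exit (defocalization). Photobleaching truncates tracks with a geometric
#' lifetime of mean \code{model$bleach_mean_frames}. Track start frames are
#' uniform over the usable movie, emulating continuous photoactivation.
#'
#' @param model A [diffusion_model()].
#' @param acq An [acquisition_spec()].
#' @param n_tracks Number of molecules to simulate (>= 1).
#' @param seed Integer seed.
#' @param movie_id Identifier stamped on all rows.
#' @return A list: \code{tracks}, a \code{data.table} with columns
#'   \code{movie_id, trajectory_id, frame, x_um, y_um, cell_id}; and
#'   \code{truth}, holding the per-track state assignment and realized
#'   state occupancies over all simulated tracks.
#' @export
simulate_trajectories <- function(model, acq, n_tracks, seed = 1L,
                                  movie_id = "sim") {
  stopifnot(inherits(model, "diffusion_model"),
            inherits(acq, "acquisition_spec"))
  stopifnot_scalar(n_tracks, "n_tracks", 1)
  n_tracks <- as.integer(n_tracks)
  dt <- acq$frame_interval_s
  L <- acq$focal_depth_um
  with_seed(seed, {
    state <- sample.int(length(model$state_D_um2s), n_tracks, replace = TRUE,
                        prob = model$state_occupancy)
    D <- model$state_D_um2s[state]
    # geometric lifetime on {1, 2, ...} with mean bleach_mean_frames
    p_bleach <- 1 / model$bleach_mean_frames
    n_bleach <- 1L + rgeom(n_tracks, p_bleach)
    start <- sample(acq$track_start_frame:(acq$n_frames - 2L), n_tracks,
                    replace = TRUE)
    n_bleach <- pmin(n_bleach, acq$n_frames - start)
    maxlen <- max(n_bleach)
    sdxy <- sqrt(2 * D * dt)
    if (model$allow_switching) {
      # per-frame state redraws; sdxy becomes a matrix of per-step sds
      st_mat <- matrix(state, n_tracks, maxlen)
      if (maxlen > 1) {
        for (k in 2:maxlen) {
          flip <- runif(n_tracks) < model$switch_prob
          st_mat[, k] <- ifelse(flip,
                                sample.int(length(model$state_D_um2s),
                                           n_tracks, replace = TRUE,
                                           prob = model$state_occupancy),
                                st_mat[, k - 1])
        }
      }
      sd_steps <- sqrt(2 * model$state_D_um2s[st_mat] * dt)
      dim(sd_steps) <- dim(st_mat)
    } else {
      sd_steps <- matrix(sdxy, n_tracks, maxlen)
    }
    zstep <- matrix(rnorm(n_tracks * maxlen), n_tracks) * sd_steps
    z <- row_cumsum(cbind(runif(n_tracks, 0, L), zstep[, -1, drop = FALSE]))
    # absorbing slab in continuous time: absorb when an endpoint leaves the
    # slab, or when the Brownian bridge between in-slab endpoints crosses a
    # boundary within the frame interval
    out <- z < 0 | z > L
    if (maxlen > 1) {
      for (k in 2:maxlen) {
        s2 <- sd_steps[, k]^2
        a <- z[, k - 1]; b <- z[, k]
        p_lo <- exp(-2 * pmax(a, 0) * pmax(b, 0) / pmax(s2, 1e-300))
        p_hi <- exp(-2 * pmax(L - a, 0) * pmax(L - b, 0) / pmax(s2, 1e-300))
        cross <- runif(n_tracks) < pmin(p_lo + p_hi, 1)
        out[, k] <- out[, k] | cross
      }
    }
    out <- cbind(out, TRUE)   # sentinel: exit at maxlen + 1
    first_exit <- max.col(out, ties.method = "first")
    n_obs <- pmin(n_bleach, first_exit - 1L)
    keep <- n_obs >= 1L
    roi_um <- acq$roi_px * acq$pixel_size_um
    xs <- row_cumsum(cbind(runif(n_tracks, 0, roi_um),
                           (matrix(rnorm(n_tracks * maxlen), n_tracks) *
                              sd_steps)[, -1, drop = FALSE]))
    ys <- row_cumsum(cbind(runif(n_tracks, 0, roi_um),
                           (matrix(rnorm(n_tracks * maxlen), n_tracks) *
                              sd_steps)[, -1, drop = FALSE]))
    rows <- rep(seq_len(n_tracks)[keep], n_obs[keep])
    cols <- sequence(n_obs[keep])
    ij <- cbind(rows, cols)
    sig <- model$loc_error_um
    nr <- length(rows)
    tracks <- data.table::data.table(
      movie_id = movie_id,
      trajectory_id = rows,
      frame = start[rows] + cols - 1L,
      x_um = xs[ij] + if (sig > 0) rnorm(nr, 0, sig) else 0,
      y_um = ys[ij] + if (sig > 0) rnorm(nr, 0, sig) else 0,
      cell_id = 1L
    )
    occ <- tabulate(state, nbins = length(model$state_D_um2s)) / n_tracks
    list(tracks = tracks,
         truth = list(state = state, n_obs = n_obs,
                      state_D_um2s = model$state_D_um2s,
                      occupancy = occ,
                      occupancy_nominal = model$state_occupancy))
  })
}

#' Render localizations into a synthetic movie
#'
#' Each localization becomes an integrated-Gaussian spot on a constant
#' background, with optional Poisson shot noise, so that detection and
#' localization can be tested end to end against known positions.
#'
#' @param localizations data.frame with \code{frame} (0-based),
#'   \code{x_um}, \code{y_um}.
#' @param acq An [acquisition_spec()]; sets pixel size and ROI.
#' @param psf_sd_px Gaussian PSF standard deviation (pixels).
#' @param intensity Integrated photons per spot.
#' @param background Background counts per pixel.
#' @param n_frames Number of frames to render (default: up to max frame).
#' @param poisson_noise Add Poisson noise when \code{TRUE}.
#' @param seed Seed for the noise.
#' @return Numeric array \code{[row, col, frame]}.
#' @export
render_movie <- function(localizations, acq, psf_sd_px = 1.0,
                         intensity = 500, background = 10,
                         n_frames = NULL, poisson_noise = TRUE, seed = 1L) {
  stopifnot(inherits(acq, "acquisition_spec"))
  np <- acq$roi_px
  if (is.null(n_frames)) {
    n_frames <- if (nrow(localizations)) max(localizations$frame) + 1L else 1L
  }
  stack <- array(background, dim = c(np, np, n_frames))
  ps <- acq$pixel_size_um
  if (nrow(localizations)) {
    for (i in seq_len(nrow(localizations))) {
      f <- localizations$frame[i] + 1L
      if (f < 1L || f > n_frames) next
      cx <- localizations$x_um[i] / ps   # pixel units, 0 = left edge
      cy <- localizations$y_um[i] / ps
      x0 <- max(1L, floor(cx - 4 * psf_sd_px)); x1 <- min(np, ceiling(cx + 4 * psf_sd_px))
      y0 <- max(1L, floor(cy - 4 * psf_sd_px)); y1 <- min(np, ceiling(cy + 4 * psf_sd_px))
      if (x0 > x1 || y0 > y1) next
      fx <- pnorm(x0:x1, cx, psf_sd_px) - pnorm((x0:x1) - 1, cx, psf_sd_px)
      fy <- pnorm(y0:y1, cy, psf_sd_px) - pnorm((y0:y1) - 1, cy, psf_sd_px)
      stack[y0:y1, x0:x1, f] <- stack[y0:y1, x0:x1, f] +
        intensity * outer(fy, fx)
    }
  }
  if (poisson_noise) {
    with_seed(seed, {
      stack[] <- rpois(length(stack), lambda = stack)
    })
  }
  stack
}
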