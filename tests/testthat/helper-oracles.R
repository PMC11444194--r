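# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths.

# Dense multivariate-Gaussian log-density for a per-coordinate jump vector
# under Brownian motion with localization error: full covariance matrix,
# Cholesky solve. Oracle for the tridiagonal likelihood engine.
dense_rbme_loglik <- function(dx, dy, D, dt, sigma) {
  n <- length(dx)
  S <- diag(2 * D * dt + 2 * sigma^2, n)
  if (n > 1) {
    for (k in 1:(n - 1)) S[k, k + 1] <- S[k + 1, k] <- -sigma^2
  }
  R <- chol(S)
  ld <- 2 * sum(log(diag(R)))
  quad <- function(v) sum(backsolve(R, v, transpose = TRUE)^2)
  -0.5 * (quad(dx) + quad(dy)) - ld - n * log(2 * pi)
}

# Exhaustive optimal frame-to-frame assignment tracker: at each consecutive
# frame pair, enumerate every injective assignment of previous-frame heads
# to current detections within the search radius; keep the assignment with
# the most links, breaking ties by the smallest total squared distance.
# Returns a trajectory id per localization row.
oracle_link <- function(locs, radius) {
  locs <- locs[order(locs$frame), ]
  frames <- sort(unique(locs$frame))
  byf <- split(seq_len(nrow(locs)), locs$frame)
  traj <- integer(nrow(locs))
  next_id <- 1L
  prev <- integer(0); prev_frame <- -2L
  best_assign <- function(d2, r2) {
    np <- nrow(d2); nc <- ncol(d2)
    best <- list(links = -1L, cost = Inf, map = rep(0L, np))
    recurse <- function(i, used, map, links, cost) {
      if (i > np) {
        if (links > best$links ||
            (links == best$links && cost < best$cost)) {
          best <<- list(links = links, cost = cost, map = map)
        }
        return(invisible())
      }
      recurse(i + 1L, used, map, links, cost)   # leave head i unlinked
      for (j in seq_len(nc)) {
        if (!used[j] && d2[i, j] <= r2) {
          used[j] <- TRUE; map[i] <- j
          recurse(i + 1L, used, map, links + 1L, cost + d2[i, j])
          used[j] <- FALSE; map[i] <- 0L
        }
      }
    }
    recurse(1L, rep(FALSE, nc), rep(0L, np), 0L, 0)
    best$map
  }
  for (f in frames) {
    cur <- byf[[as.character(f)]]
    if (f == prev_frame + 1L && length(prev)) {
      d2 <- outer(locs$x_um[prev], locs$x_um[cur], `-`)^2 +
        outer(locs$y_um[prev], locs$y_um[cur], `-`)^2
      map <- best_assign(d2, radius^2)
      for (i in seq_along(prev)) {
        if (map[i] > 0L) traj[cur[map[i]]] <- traj[prev[i]]
      }
    }
    new <- cur[traj[cur] == 0L]
    if (length(new)) {
      traj[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    prev <- cur; prev_frame <- f
  }
  traj
}

# Canonical partition of localizations into trajectories, for comparing two
# linkers independent of id numbering.
partition_signature <- function(frame, x, y, traj) {
  key <- paste(frame, round(x, 9), round(y, 9), sep = "|")
  groups <- split(key, traj)
  sort(vapply(groups, function(g) paste(sort(g), collapse = ";"),
              character(1)), method = "radix")
}

# Three well-separated slow molecules over consecutive frames: a sparse
# movie on which conservative linking must agree with optimal assignment.
sparse_movie_locs <- function(seed, n_frames = 200) {
  acq <- acquisition_spec(n_frames = n_frames, track_start_frame = 0,
                          infer_start_frame = 0, focal_depth_um = 1e6)
  mod <- diffusion_model(0.05, 1, loc_error_um = 0.02,
                         bleach_mean_frames = 1e9)
  parts <- lapply(1:3, function(i) {
    tr <- simulate_trajectories(mod, acq, 1, seed = seed * 10 + i)$tracks
    tr <- tr[tr$frame < n_frames, ]
    tr$x_um <- tr$x_um - min(tr$x_um) + (i - 1) * 40
    tr$y_um <- tr$y_um - min(tr$y_um)
    tr$frame <- tr$frame - min(tr$frame)
    tr
  })
  out <- data.table::rbindlist(parts)
  data.frame(frame = out$frame, x_um = out$x_um, y_um = out$y_um)
}

# Shared small quantities
px <- function(um, pixel_size) um / pixel_size
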