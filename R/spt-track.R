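#' Trajectory-linking configuration
#'
#' Conservative linking settings: localizations are linked across
#' consecutive frames only (no blinking gaps) within a 1.0 um search
#' radius; frames with more than \code{max_spots_per_frame} detections are
#' excluded so that dense early frames cannot seed misconnected
#' trajectories; frames before \code{start_frame} are discarded.
#'
#' @param search_radius_um Maximum jump length (um).
#' @param max_blinks Allowed gap frames (only 0 is supported:
#'   conservative).
#' @param max_spots_per_frame Density cutoff per frame.
#' @param start_frame First frame used for linking.
#' @return Object of class \code{link_config}.
#' @export
link_config <- function(search_radius_um = 1.0, max_blinks = 0L,
                        max_spots_per_frame = 7L, start_frame = 100L) {
  stopifnot_scalar(search_radius_um, "search_radius_um", 1e-9)
  if (max_blinks != 0L) stop("conservative linking supports max_blinks = 0 only")
  stopifnot_scalar(max_spots_per_frame, "max_spots_per_frame", 1)
  stopifnot_scalar(start_frame, "start_frame", 0)
  structure(list(search_radius_um = search_radius_um, max_blinks = 0L,
                 max_spots_per_frame = as.integer(max_spots_per_frame),
                 start_frame = as.integer(start_frame)),
            class = "link_config")
}

#' Detect spot candidates by a generalized log-likelihood-ratio test
#'
#' In each sliding window the image is modelled as a Gaussian spot of
#' kernel width \code{k} pixels plus flat background versus flat background
#' alone; the test statistic is \code{-(n/2) log(1 - R^2)} where \code{R^2}
#' is the squared correlation between the window and the centred kernel.
#' Candidates are positive-amplitude local maxima of the statistic above
#' \code{threshold}.
#'
#' @param frame 2D intensity matrix.
#' @param window Window side (pixels, odd).
#' @param k Gaussian kernel standard deviation (pixels).
#' @param threshold Detection threshold on the LLR statistic.
#' @return data.frame with integer pixel coordinates \code{x, y} (1-based
#'   column/row) and \code{llr}.
#' @export
detect_spots_llr <- function(frame, window = 15L, k = 1.2, threshold = 18.0) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (nrow(frame) < window || ncol(frame) < window) {
    stop("frame smaller than detection window")
  }
  n <- window^2
  hw <- window %/% 2L
  ax <- (-hw):hw
  g <- exp(-outer(ax^2, ax^2, "+") / (2 * k^2))
  gc <- g - mean(g)
  Sgg <- sum(gc^2)
  box <- matrix(1, window, window)
  SI <- as.matrix(EBImage::filter2(frame, box / 1))
  SII <- as.matrix(EBImage::filter2(frame^2, box))
  Sgi <- as.matrix(EBImage::filter2(frame, gc))
  ss <- pmax(SII - SI^2 / n, 1e-12)
  r2 <- pmin(Sgi^2 / (Sgg * ss), 1 - 1e-12)
  llr <- -(n / 2) * log1p(-r2)
  llr[Sgi <= 0] <- 0
  # drop the border where the circular convolution wraps
  llr[c(seq_len(hw), nrow(llr) - seq_len(hw) + 1L), ] <- 0
  llr[, c(seq_len(hw), ncol(llr) - seq_len(hw) + 1L)] <- 0
  mx <- as.matrix(EBImage::dilate(llr, EBImage::makeBrush(3, "box")))
  hit <- which(llr >= mx & llr > threshold, arr.ind = TRUE)
  data.frame(x = as.integer(hit[, 2]), y = as.integer(hit[, 1]),
             llr = llr[hit])
}

# Integrated-Gaussian PSF over one pixel axis: pixel j covers [j-1, j].
.igauss <- function(j, mu, sd) pnorm(j, mu, sd) - pnorm(j - 1, mu, sd)

#' Subpixel Gaussian localization by damped least squares
#'
#' Fits an integrated 2D Gaussian of fixed width plus flat background to a
#' square window around each candidate, by damped, ridge-regularized
#' Gauss-Newton iteration on (x, y, intensity, background). Fits that do
#' not converge, run out of the window or end with nonpositive intensity
#' are flagged.
#'
#' @param frame 2D intensity matrix.
#' @param candidates data.frame with integer \code{x, y} (e.g. from
#'   [detect_spots_llr()]).
#' @param window Fit window side (pixels).
#' @param sigma PSF standard deviation (pixels), fixed during the fit.
#' @param max_iter,damp,ridge Iteration controls.
#' @param tol Convergence tolerance on the position step (pixels).
#' @return data.frame: subpixel \code{x, y} (pixel units; pixel j's centre
#'   is at j - 0.5), \code{intensity}, \code{background},
#'   \code{converged}.
#' @export
localize_gaussian <- function(frame, candidates, window = 9L, sigma = 1.0,
                              max_iter = 20L, damp = 0.3, ridge = 1e-3,
                              tol = 1e-4) {
  hw <- as.integer(window) %/% 2L
  nres <- nrow(candidates)
  out <- data.frame(x = rep(NA_real_, nres), y = NA_real_,
                    intensity = NA_real_, background = NA_real_,
                    converged = FALSE)
  for (i in seq_len(nres)) {
    cx0 <- candidates$x[i]; cy0 <- candidates$y[i]
    xs <- (cx0 - hw):(cx0 + hw); ys <- (cy0 - hw):(cy0 + hw)
    if (min(xs) < 1 || min(ys) < 1 || max(xs) > ncol(frame) ||
        max(ys) > nrow(frame)) next
    W <- frame[ys, xs]
    b <- min(W)
    I <- sum(W - b)
    # centroid initialization on background-subtracted window
    wpos <- pmax(W - b, 0)
    tw <- sum(wpos)
    mux <- if (tw > 0) sum(t(wpos) * (xs - 0.5)) / tw else cx0 - 0.5
    muy <- if (tw > 0) sum(wpos * (ys - 0.5)) / tw else cy0 - 0.5
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      px <- .igauss(xs, mux, sigma)
      py <- .igauss(ys, muy, sigma)
      dpx <- dnorm(xs - 1, mux, sigma) - dnorm(xs, mux, sigma)
      dpy <- dnorm(ys - 1, muy, sigma) - dnorm(ys, muy, sigma)
      M <- I * outer(py, px) + b
      r <- as.vector(W - M)
      J <- cbind(as.vector(I * outer(py, dpx)),
                 as.vector(I * outer(dpy, px)),
                 as.vector(outer(py, px)),
                 1)
      A <- crossprod(J) + diag(ridge, 4)
      step <- tryCatch(solve(A, crossprod(J, r)), error = function(e) NULL)
      if (is.null(step)) break
      mux <- mux + damp * step[1]
      muy <- muy + damp * step[2]
      I <- I + damp * step[3]
      b <- b + damp * step[4]
      if (max(abs(step[1:2])) * damp < tol) { conv <- TRUE; break }
    }
    inside <- mux > min(xs) - 1 && mux < max(xs) && muy > min(ys) - 1 &&
      muy < max(ys)
    out$x[i] <- mux; out$y[i] <- muy
    out$intensity[i] <- I; out$background[i] <- b
    out$converged[i] <- conv && inside && is.finite(I) && I > 0
  }
  out
}

#' Detect and localize all spots of a movie
#'
#' @param movie Array \code{[row, col, frame]}.
#' @param acq An [acquisition_spec()] supplying the pixel size.
#' @param detect_args,localize_args Named lists overriding
#'   [detect_spots_llr()] / [localize_gaussian()] defaults.
#' @return data.table of localizations: \code{frame} (0-based),
#'   \code{x_um, y_um}, \code{intensity}, \code{background},
#'   \code{converged}.
#' @export
localize_movie <- function(movie, acq, detect_args = list(),
                           localize_args = list()) {
  stopifnot(length(dim(movie)) == 3)
  ps <- acq$pixel_size_um
  res <- vector("list", dim(movie)[3])
  for (f in seq_len(dim(movie)[3])) {
    fr <- movie[, , f]
    cand <- do.call(detect_spots_llr, c(list(fr), detect_args))
    if (!nrow(cand)) next
    loc <- do.call(localize_gaussian, c(list(fr, cand), localize_args))
    loc <- loc[loc$converged, , drop = FALSE]
    if (!nrow(loc)) next
    res[[f]] <- data.table::data.table(frame = f - 1L, x_um = loc$x * ps,
                                       y_um = loc$y * ps,
                                       intensity = loc$intensity,
                                       background = loc$background,
                                       converged = loc$converged)
  }
  out <- data.table::rbindlist(res)
  if (!nrow(out)) {
    out <- data.table::data.table(frame = integer(0), x_um = numeric(0),
                                  y_um = numeric(0), intensity = numeric(0),
                                  background = numeric(0),
                                  converged = logical(0))
  }
  out
}

#' Conservative trajectory linking
#'
#' Links localizations across consecutive frames only when the
#' correspondence is unambiguous: a link is made iff exactly one candidate
#' lies within the search radius of the track head, and that candidate has
#' exactly one track head within its own radius (mutual uniqueness). Any
#' ambiguity terminates the affected trajectories and starts new ones.
#' Frames with more than \code{max_spots_per_frame} localizations are
#' excluded from linking entirely, and frames before \code{start_frame}
#' are discarded.
#'
#' @param locs data.frame/data.table with \code{frame} (integer, 0-based),
#'   \code{x_um}, \code{y_um}.
#' @param cfg A [link_config()].
#' @param movie_id Identifier stamped on the output.
#' @return data.table trajectory table: \code{movie_id, trajectory_id,
#'   frame, x_um, y_um}.
#' @export
link_conservative <- function(locs, cfg = link_config(), movie_id = "movie") {
  locs <- data.table::as.data.table(locs)
  empty <- data.table::data.table(movie_id = character(0),
                                  trajectory_id = integer(0),
                                  frame = integer(0), x_um = numeric(0),
                                  y_um = numeric(0))
  if (!nrow(locs)) return(empty)
  locs <- locs[locs$frame >= cfg$start_frame, ]
  if (!nrow(locs)) return(empty)
  data.table::setorderv(locs, "frame")
  counts <- table(locs$frame)
  dense <- as.integer(names(counts)[counts > cfg$max_spots_per_frame])
  locs <- locs[!locs$frame %in% dense, ]
  if (!nrow(locs)) return(empty)
  frames <- sort(unique(locs$frame))
  byf <- split(seq_len(nrow(locs)), locs$frame)
  traj <- integer(nrow(locs))
  next_id <- 1L
  r2 <- cfg$search_radius_um^2
  prev_idx <- integer(0); prev_frame <- -2L
  for (f in frames) {
    cur <- byf[[as.character(f)]]
    if (f == prev_frame + 1L && length(prev_idx)) {
      px <- locs$x_um[prev_idx]; py <- locs$y_um[prev_idx]
      cx <- locs$x_um[cur]; cy <- locs$y_um[cur]
      d2 <- outer(px, cx, function(a, b) (a - b)^2) +
        outer(py, cy, function(a, b) (a - b)^2)
      within <- d2 <= r2
      cand_per_track <- rowSums(within)
      cand_per_det <- colSums(within)
      for (ti in seq_along(prev_idx)) {
        if (cand_per_track[ti] == 1L) {
          dj <- which(within[ti, ])
          if (cand_per_det[dj] == 1L) {
            traj[cur[dj]] <- traj[prev_idx[ti]]
          }
        }
      }
    }
    new <- cur[traj[cur] == 0L]
    if (length(new)) {
      traj[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    prev_idx <- cur; prev_frame <- f
  }
  out <- data.table::data.table(movie_id = movie_id, trajectory_id = traj,
                                frame = as.integer(locs$frame),
                                x_um = locs$x_um, y_um = locs$y_um)
  data.table::setorderv(out, c("trajectory_id", "frame"))
  # relabel trajectory ids contiguously in order of first appearance
  out[, trajectory_id := match(trajectory_id, unique(trajectory_id))]
  out
}

#' Derive a nuclear mask from a snapshot image
#'
#' Gaussian blur (sigma 2 px), minimum-method histogram threshold, hole
#' filling and two binary erosions. If the resulting mask covers more than
#' half the frame the image polarity is inverted and the mask re-derived
#' (cells with predominantly cytoplasmic signal appear as dark nuclei on a
#' bright background).
#'
#' @param snapshot 2D intensity matrix.
#' @param sigma Blur width (pixels).
#' @param erosions Binary erosions applied after hole filling.
#' @return Logical mask matrix; empty (all \code{FALSE}) with a warning
#'   when the histogram has no bimodal structure.
#' @export
make_nuclear_mask <- function(snapshot, sigma = 2, erosions = 2L) {
  derive <- function(img) {
    sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
    th <- threshold_minimum(sm)
    if (is.na(th)) return(NULL)
    m <- sm > th
    m <- EBImage::fillHull(EBImage::Image(m * 1))
    kern <- EBImage::makeBrush(3, "box")
    for (i in seq_len(erosions)) m <- EBImage::erode(m, kern)
    matrix(as.numeric(EBImage::imageData(m)) > 0.5, nrow(img))
  }
  mask <- derive(snapshot)
  if (is.null(mask)) {
    warning("no bimodal intensity structure; returning empty mask")
    return(matrix(FALSE, nrow(snapshot), ncol(snapshot)))
  }
  if (mean(mask) > 0.5) {
    inv <- derive(max(snapshot) - snapshot)
    if (!is.null(inv)) mask <- inv
  }
  mask
}

#' Keep only trajectories entirely inside a nuclear mask
#'
#' A trajectory is retained iff every one of its localizations falls on a
#' mask pixel; a single excursion discards the whole trajectory.
#'
#' @param tracks Trajectory table (\code{movie_id, trajectory_id, frame,
#'   x_um, y_um}).
#' @param mask Logical mask matrix.
#' @param pixel_size_um Pixel size (um) mapping coordinates onto the mask.
#' @return Filtered trajectory table.
#' @export
filter_nuclear_trajectories <- function(tracks, mask, pixel_size_um) {
  tracks <- data.table::as.data.table(tracks)
  if (!nrow(tracks)) return(tracks)
  ix <- floor(tracks$x_um / pixel_size_um) + 1L
  iy <- floor(tracks$y_um / pixel_size_um) + 1L
  inb <- ix >= 1L & ix <= ncol(mask) & iy >= 1L & iy <= nrow(mask)
  ok <- inb
  ok[inb] <- mask[cbind(iy[inb], ix[inb])]
  tracks[, .ok := ok]
  keep <- tracks[, .(all_in = all(.ok)), by = .(movie_id, trajectory_id)]
  out <- merge(tracks, keep, by = c("movie_id", "trajectory_id"))
  out <- out[out$all_in == TRUE, ]
  out[, c(".ok", "all_in") := NULL]
  data.table::setorderv(out, c("movie_id", "trajectory_id", "frame"))
  out
}
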