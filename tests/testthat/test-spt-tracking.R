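test_that("LLR detection finds rendered spots and rejects blank noise", {
  acq <- acquisition_spec(roi_px = 64)
  loc <- data.frame(frame = 0L, x_um = 20.5 * 0.16, y_um = 30.5 * 0.16)
  mov <- render_movie(loc, acq, intensity = 800, background = 10,
                      poisson_noise = FALSE)
  cand <- detect_spots_llr(mov[, , 1])
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$x - 21) + abs(cand$y - 31), 2)

  # two spots 10 px apart resolve separately
  loc2 <- data.frame(frame = c(0L, 0L), x_um = c(20, 30) * 0.16,
                     y_um = c(30, 30) * 0.16)
  mov2 <- render_movie(loc2, acq, intensity = 800, poisson_noise = FALSE)
  expect_equal(nrow(detect_spots_llr(mov2[, , 1])), 2)

  # blank Poisson frames: false-positive rate < 1e-3 per frame over 100
  set.seed(1)
  fp <- sum(vapply(1:100, function(i) {
    nrow(detect_spots_llr(matrix(rpois(64 * 64, 10), 64)))
  }, numeric(1)))
  expect_equal(fp, 0)

  expect_error(detect_spots_llr(matrix(0, 8, 8)), "window")
})

test_that("Gaussian localization is subpixel-accurate and flags degenerate fits", {
  acq <- acquisition_spec(roi_px = 64)
  # off-center spot recovered within 0.05 px on a noiseless render
  loc <- data.frame(frame = 0L, x_um = (20 + 0.3) * 0.16,
                    y_um = (30 + 0.2) * 0.16)
  mov <- render_movie(loc, acq, intensity = 800, background = 10,
                      poisson_noise = FALSE)
  fit <- localize_gaussian(mov[, , 1], data.frame(x = 21, y = 31))
  expect_true(fit$converged)
  expect_lt(abs(fit$x - 20.3), 0.05)
  expect_lt(abs(fit$y - 30.2), 0.05)

  # pixel-centred spot: offset below 1e-3 px by symmetry
  locc <- data.frame(frame = 0L, x_um = 20.5 * 0.16, y_um = 30.5 * 0.16)
  movc <- render_movie(locc, acq, intensity = 800, background = 10,
                       poisson_noise = FALSE)
  fitc <- localize_gaussian(movc[, , 1], data.frame(x = 21, y = 31))
  expect_lt(abs(fitc$x - 20.5), 1e-3)
  expect_lt(abs(fitc$y - 30.5), 1e-3)

  # flat window: flagged non-converged
  flat <- matrix(100, 64, 64)
  fitf <- localize_gaussian(flat, data.frame(x = 30, y = 30))
  expect_false(fitf$converged)
})

test_that("conservative linking follows a single molecule and breaks on ambiguity", {
  # single molecule stepping 0.3 um/frame -> one trajectory over all frames
  locs <- data.frame(frame = 0:49, x_um = 1 + 0.3 * (0:49), y_um = 2)
  lk <- link_conservative(locs, link_config(start_frame = 0))
  expect_equal(length(unique(lk$trajectory_id)), 1)
  expect_equal(nrow(lk), 50)

  # two detections within radius of one prior point: no link is made
  locs2 <- data.frame(frame = c(0L, 1L, 1L),
                      x_um = c(5, 5.2, 4.8), y_um = c(5, 5, 5))
  lk2 <- link_conservative(locs2, link_config(start_frame = 0))
  expect_equal(length(unique(lk2$trajectory_id)), 3)

  # mutual ambiguity: one detection within radius of two prior heads
  locs3 <- data.frame(frame = c(0L, 0L, 1L),
                      x_um = c(5, 5.6, 5.3), y_um = c(5, 5, 5))
  lk3 <- link_conservative(locs3, link_config(start_frame = 0))
  expect_equal(length(unique(lk3$trajectory_id)), 3)

  # frames denser than max_spots_per_frame are excluded entirely
  dense <- data.frame(frame = rep(0:1, c(8, 1)),
                      x_um = c(seq(1, 29, 4), 1), y_um = 1)
  lk4 <- link_conservative(dense, link_config(start_frame = 0,
                                              max_spots_per_frame = 7))
  expect_equal(nrow(lk4), 1)   # only the sparse frame survives

  # frames before start_frame are discarded
  lk5 <- link_conservative(locs, link_config(start_frame = 25))
  expect_equal(min(lk5$frame), 25)

  expect_equal(nrow(link_conservative(locs[0, ], link_config())), 0)
})

test_that("conservative linking equals the exhaustive-assignment oracle on sparse movies", {
  for (seed in 1:5) {
    locs <- sparse_movie_locs(seed)
    lk <- link_conservative(locs, link_config(start_frame = 0))
    oracle <- oracle_link(locs[order(locs$frame), ], radius = 1.0)
    lo <- locs[order(locs$frame), ]
    expect_identical(
      partition_signature(lk$frame, lk$x_um, lk$y_um, lk$trajectory_id),
      partition_signature(lo$frame, lo$x_um, lo$y_um, oracle))
  }
})

test_that("nuclear mask recipe recovers a synthetic nucleus within 2 px", {
  img <- matrix(100, 128, 128)
  truth <- matrix(FALSE, 128, 128)
  truth[fusionscope:::ellipse_pixels(128, 128, 64, 64, 30, 24)] <- TRUE
  img[truth] <- 1000
  set.seed(3)
  img <- img + matrix(rnorm(length(img), 0, 20), 128)
  mask <- make_nuclear_mask(img)
  dil <- matrix(as.numeric(EBImage::imageData(EBImage::dilate(
    truth * 1, EBImage::makeBrush(5, "disc")))) > 0.5, 128)
  ero <- matrix(as.numeric(EBImage::imageData(EBImage::erode(
    truth * 1, EBImage::makeBrush(9, "disc")))) > 0.5, 128)
  expect_true(all(mask[!dil] == FALSE))   # mask within dilated truth
  expect_true(all(ero[!mask] == FALSE))   # mask covers eroded truth

  # inverted-contrast cell yields the same mask after the polarity check
  mask_inv <- make_nuclear_mask(max(img) - img)
  expect_gt(sum(mask_inv & mask) / sum(mask_inv | mask), 0.9)

  # uniform image: empty mask with a warning
  expect_warning(m0 <- make_nuclear_mask(matrix(7, 64, 64)), "bimodal")
  expect_false(any(m0))
})

test_that("trajectories with any excursion outside the mask are dropped whole", {
  mask <- matrix(FALSE, 100, 100)
  mask[20:80, 20:80] <- TRUE   # rectangle: rows(y) 20..80, cols(x) 20..80
  ps <- 0.16
  inside <- data.frame(movie_id = "m", trajectory_id = 1L, frame = 0:4,
                       x_um = seq(5, 6, length.out = 5),
                       y_um = seq(5, 6, length.out = 5))
  excurs <- data.frame(movie_id = "m", trajectory_id = 2L, frame = 0:4,
                       x_um = c(5, 5.1, 1.0, 5.2, 5.3),  # one point outside
                       y_um = rep(5, 5))
  out <- filter_nuclear_trajectories(rbind(inside, excurs), mask, ps)
  expect_setequal(unique(out$trajectory_id), 1L)

  # agreement with per-point brute force on random tracks
  set.seed(11)
  tr <- data.frame(movie_id = "m",
                   trajectory_id = rep(1:50, each = 4),
                   frame = rep(0:3, 50),
                   x_um = runif(200, 0, 16), y_um = runif(200, 0, 16))
  got <- filter_nuclear_trajectories(tr, mask, ps)
  keep_bf <- vapply(split(tr, tr$trajectory_id), function(d) {
    all(mask[cbind(floor(d$y_um / ps) + 1, floor(d$x_um / ps) + 1)])
  }, logical(1))
  expect_setequal(unique(got$trajectory_id),
                  as.integer(names(keep_bf))[keep_bf])
})

test_that("movie localization recovers simulated positions end to end", {
  acq <- acquisition_spec(roi_px = 64, n_frames = 30, track_start_frame = 0,
                          infer_start_frame = 0)
  mod <- diffusion_model(0.5, 1, loc_error_um = 0, bleach_mean_frames = 1e6)
  sim <- simulate_trajectories(mod, acq, 2, seed = 6)
  tr <- sim$tracks[sim$tracks$frame < 30, ]
  tr <- tr[tr$x_um > 1 & tr$x_um < 9 & tr$y_um > 1 & tr$y_um < 9, ]
  mov <- render_movie(tr, acq, intensity = 1500, background = 10,
                      poisson_noise = FALSE)
  locs <- localize_movie(mov, acq)
  expect_gte(nrow(locs), 0.9 * nrow(tr))
  # every recovered localization sits within 0.05 um of a true position
  for (i in seq_len(nrow(locs))) {
    same <- tr[tr$frame == locs$frame[i], ]
    d <- sqrt((same$x_um - locs$x_um[i])^2 + (same$y_um - locs$y_um[i])^2)
    expect_lt(min(d), 0.05)
  }
})
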