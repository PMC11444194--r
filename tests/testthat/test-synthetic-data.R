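test_that("two-color generator respects fused_fraction boundaries and is deterministic", {
  spec0 <- field_spec(n_cells = 20, fused_fraction = 0, width_px = 512,
                      height_px = 512, seed = 3)
  f0 <- generate_two_color_field(spec0)
  expect_equal(sum(f0$truth$nuclei$fused), 0)
  expect_equal(f0$truth$true_fused_area_px, 0)

  spec1 <- field_spec(n_cells = 20, fused_fraction = 1, width_px = 512,
                      height_px = 512, seed = 3)
  f1 <- generate_two_color_field(spec1)
  expect_true(all(f1$truth$nuclei$fused))
  expect_equal(nrow(f1$truth$nuclei), 20)

  fa <- generate_two_color_field(spec1)
  expect_identical(f1$image$channels, fa$image$channels)

  # degenerate: zero cells -> empty field, empty truth, no failure
  fe <- generate_two_color_field(field_spec(n_cells = 0, width_px = 128,
                                            height_px = 128))
  expect_equal(nrow(fe$truth$nuclei), 0)
  expect_equal(dim(fe$image$channels$hoechst), c(128, 128))
})

test_that("unfused cells carry one fluorophore and syncytia carry both over member nuclei", {
  spec <- field_spec(n_cells = 24, fused_fraction = 0.5, width_px = 768,
                     height_px = 768, seed = 11)
  f <- generate_two_color_field(spec)
  ch <- f$image$channels
  nuc <- f$truth$nuclei
  for (i in seq_len(nrow(nuc))) {
    pxs <- fusionscope:::ellipse_pixels(768, 768, nuc$x[i], nuc$y[i],
                                        nuc$rx[i], nuc$ry[i])
    g <- mean(ch$gfp[pxs] > 1000); m <- mean(ch$mcherry[pxs] > 1000)
    if (nuc$fused[i]) {
      expect_gte(g, 0.9); expect_gte(m, 0.9)
    } else {
      expect_true(xor(g > 0.9, m > 0.9))
    }
  }
})

test_that("split-GFP generator records exact fused sheet area", {
  spec <- field_spec(n_cells = 20, fused_fraction = 0, seed = 5,
                     width_px = 512, height_px = 512, noise_sd = 0)
  expect_equal(generate_splitgfp_field(spec)$truth$true_fused_area_px, 0)

  spec2 <- field_spec(n_cells = 20, fused_fraction = 0.5, seed = 5,
                      noise_sd = 0)
  f <- generate_splitgfp_field(spec2)
  # truth equals the rendered GFP-positive pixel count exactly
  expect_equal(sum(f$image$channels$gfp > spec2$background_mean),
               f$truth$true_fused_area_px)
  f2 <- generate_splitgfp_field(spec2)
  expect_identical(f$image$channels, f2$image$channels)
})

test_that("lysosome generator places the exact requested puncta without overlap", {
  spec <- field_spec(n_cells = 5, width_px = 512, height_px = 512, seed = 7,
                     noise_sd = 0)
  f0 <- generate_lysosome_field(spec, puncta_per_cell = 0)
  expect_equal(f0$truth$lyso_count, 0)

  f <- generate_lysosome_field(spec, puncta_per_cell = 10)
  expect_equal(f$truth$lyso_count, 50)
  # non-overlap: recorded truth equals the rendered foreground exactly
  expect_equal(f$truth$lyso_area_px,
               sum(f$image$channels$lyso > spec$background_mean))
  expect_identical(f$image$channels,
                   generate_lysosome_field(spec, puncta_per_cell = 10)$image$channels)

  expect_error(generate_lysosome_field(spec, puncta_per_cell = 500),
               "density too high")
})

test_that("nc generator solves the ratio identity before noise", {
  spec <- field_spec(n_cells = 4, width_px = 400, height_px = 400, seed = 2,
                     noise_sd = 0)
  f <- generate_nc_field(spec, nc_ratios = 2, background_level = 200,
                         cyto_level = 600)
  rp <- f$image$channels$reporter
  expect_setequal(unique(as.vector(rp)), c(200, 600, 1000))
  # ratio 1 -> nuclear level equals cytoplasmic level
  f1 <- generate_nc_field(spec, nc_ratios = 1, background_level = 200,
                          cyto_level = 600)
  expect_setequal(unique(as.vector(f1$image$channels$reporter)), c(200, 600))
  expect_identical(f$image$channels,
                   generate_nc_field(spec, nc_ratios = 2,
                                     background_level = 200,
                                     cyto_level = 600)$image$channels)
})

test_that("simulated jumps obey the Brownian closed form 4 D dt + 4 sigma^2", {
  acq <- acquisition_spec(focal_depth_um = 1e6)
  # sigma = 0: pure Brownian, MSD = 4 D dt
  m <- diffusion_model(1, 1, loc_error_um = 0, bleach_mean_frames = 20)
  s <- simulate_trajectories(m, acq, 4000, seed = 2)
  jt <- fusionscope:::trajectory_jumps(s$tracks)
  sq <- unlist(Map(function(a, b) a^2 + b^2, jt$dx, jt$dy))
  expect_gt(length(sq), 5e4)
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 4 * 1 * 0.00748), 3 * se)

  # with localization error the +4 sigma^2 term appears
  m2 <- diffusion_model(1, 1, loc_error_um = 0.05, bleach_mean_frames = 20)
  s2 <- simulate_trajectories(m2, acq, 4000, seed = 3)
  jt2 <- fusionscope:::trajectory_jumps(s2$tracks)
  sq2 <- unlist(Map(function(a, b) a^2 + b^2, jt2$dx, jt2$dy))
  se2 <- sd(sq2) / sqrt(length(sq2))
  expect_lt(abs(mean(sq2) - (4 * 1 * 0.00748 + 4 * 0.05^2)), 3 * se2)

  # D = 0 and sigma = 0: all jumps exactly zero
  m0 <- diffusion_model(0, 1, loc_error_um = 0, bleach_mean_frames = 10)
  s0 <- simulate_trajectories(m0, acq, 50, seed = 4)
  jt0 <- fusionscope:::trajectory_jumps(s0$tracks)
  expect_true(all(unlist(jt0$dx) == 0) && all(unlist(jt0$dy) == 0))
})

test_that("per-track state frequencies follow the mixture occupancies", {
  m <- diffusion_model(c(0.01, 2.5), c(0.3, 0.7))
  s <- simulate_trajectories(m, acquisition_spec(), 10000, seed = 9)
  phat <- s$truth$occupancy[1]
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(phat - 0.3), 4 * se)
  expect_equal(sum(s$truth$occupancy), 1)
})

test_that("track lengths without defocalization follow the geometric bleaching law", {
  m <- diffusion_model(0.5, 1, bleach_mean_frames = 6)
  acq <- acquisition_spec(focal_depth_um = 1e6, n_frames = 100000)
  s <- simulate_trajectories(m, acq, 10000, seed = 21)
  lens <- s$truth$n_obs
  # chi-squared goodness of fit against Geometric(1/6) on {1, 2, ...}
  kmax <- 25
  obs <- tabulate(pmin(lens, kmax), nbins = kmax)
  p <- (5 / 6)^(0:(kmax - 1)) * (1 / 6)
  p[kmax] <- (5 / 6)^(kmax - 1)   # tail lump
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("render_movie puts the brightest pixel at the rendered position", {
  acq <- acquisition_spec(roi_px = 32)
  loc <- data.frame(frame = 0L, x_um = (10 - 0.5) * 0.16,
                    y_um = (17 - 0.5) * 0.16)
  mov <- render_movie(loc, acq, intensity = 1000, background = 5,
                      poisson_noise = FALSE)
  peak <- which(mov[, , 1] == max(mov[, , 1]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(17, 10))
  # empty input renders pure background
  mov0 <- render_movie(data.frame(frame = integer(0), x_um = numeric(0),
                                  y_um = numeric(0)), acq,
                       poisson_noise = FALSE)
  expect_true(all(mov0 == 10))
  # seeded noise is reproducible
  m1 <- render_movie(loc, acq, seed = 5)
  m2 <- render_movie(loc, acq, seed = 5)
  expect_identical(m1, m2)
})
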