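#' Field specification for synthetic image generation
#'
#' Describes one synthetic multi-channel field of plated cells: geometry,
#' plating density, the fraction of nuclei belonging to multinucleated
#' syncytia, foreground/background intensity levels and noise. Intensities
#' are arbitrary 16-bit-like camera counts so that the default background
#' cutoff of 200 used by the nuclear/cytoplasmic assay is meaningful.
#'
#' @param width_px,height_px Field size in pixels.
#' @param pixel_size_um Pixel size in micrometres (default 0.6, a 10x
#'   widefield configuration).
#' @param n_cells Number of nuclei to render.
#' @param fused_fraction Proportion of nuclei belonging to syncytia, in
#'   \[0, 1\].
#' @param syncytium_size_mean Expected nuclei per syncytium (>= 2).
#' @param channel_gains Named foreground mean intensities (counts).
#' @param background_mean,noise_sd Background level and additive Gaussian
#'   noise standard deviation (counts). The default noise (50 counts against
#'   foreground gains of ~2500) emulates a modest camera read/shot noise
#'   floor; set 0 for exact-truth renders.
#' @param nucleus_rx_px,nucleus_ry_px Nucleus ellipse semi-axes (pixels);
#'   the defaults give nuclear areas of roughly 55-90 um^2 at 0.6 um/px,
#'   comfortably above the 50 um^2 debris filter.
#' @param seed Integer seed; every generator is bit-reproducible given the
#'   spec and seed.
#' @return An object of class \code{field_spec}.
#' @export
field_spec <- function(width_px = 768, height_px = 768, pixel_size_um = 0.6,
                       n_cells = 60, fused_fraction = 0,
                       syncytium_size_mean = 4,
                       channel_gains = c(hoechst = 3000, gfp = 2500,
                                         mcherry = 2500, lyso = 2500,
                                         reporter = 600),
                       background_mean = 100, noise_sd = 50,
                       nucleus_rx_px = c(8, 10), nucleus_ry_px = c(6, 8),
                       seed = 1L) {
  stopifnot_scalar(width_px, "width_px", 16)
  stopifnot_scalar(height_px, "height_px", 16)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", 1e-6)
  stopifnot_scalar(n_cells, "n_cells", 0)
  stopifnot_scalar(fused_fraction, "fused_fraction", 0, 1)
  stopifnot_scalar(syncytium_size_mean, "syncytium_size_mean", 2)
  stopifnot_scalar(background_mean, "background_mean", 0)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  if (any(channel_gains < 0)) stop("channel_gains must be >= 0")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
    fused_fraction = fused_fraction,
    syncytium_size_mean = syncytium_size_mean,
    channel_gains = channel_gains, background_mean = background_mean,
    noise_sd = noise_sd, nucleus_rx_px = nucleus_rx_px,
    nucleus_ry_px = nucleus_ry_px, seed = as.integer(seed)
  ), class = "field_spec")
}

#' Multi-channel field container
#'
#' @param channels Named list of equally sized numeric matrices
#'   (row = y, column = x).
#' @param pixel_size_um Pixel size in micrometres.
#' @param plate,well,field Identifiers carried through to tidy outputs.
#' @return An object of class \code{field_image}.
#' @export
field_image <- function(channels, pixel_size_um, plate = "P1", well = "A1",
                        field = 1L) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channels must have the same shape")
  }
  stopifnot_scalar(pixel_size_um, "pixel_size_um", 1e-6)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 plate = plate, well = well, field = as.integer(field)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %dx%d px @ %.3g um/px, channels: %s (%s/%s/f%d)\n",
              d[2], d[1], x$pixel_size_um,
              paste(names(x$channels), collapse = ", "),
              x$plate, x$well, x$field))
  invisible(x)
}

# Lay out mononucleated cells and syncytia for one field. Returns the cell
# "units" (cytoplasm discs) and the nuclei within them, with guaranteed
# separation so segmentation correctness can be tested independently of
# clumping.
layout_field <- function(spec, cyto_margin_px = 8) {
  n <- spec$n_cells
  if (n == 0L) {
    return(list(units = data.frame(), nuclei = data.frame()))
  }
  n_fused <- round(spec$fused_fraction * n)
  if (n_fused == 1L) n_fused <- if (n >= 2L) 2L else 0L
  sizes <- integer(0)
  while (sum(sizes) < n_fused) {
    k <- 2L + rpois(1L, max(0, spec$syncytium_size_mean - 2))
    sizes <- c(sizes, min(k, 6L))
  }
  if (length(sizes)) {
    excess <- sum(sizes) - n_fused
    while (excess > 0) {
      i <- which(sizes - excess >= 2)[1]
      if (is.na(i)) { sizes <- sizes[-length(sizes)]; excess <- sum(sizes) - n_fused }
      else { sizes[i] <- sizes[i] - excess; excess <- 0 }
    }
  }
  k_units <- c(sizes, rep(1L, n - sum(sizes)))
  n_units <- length(k_units)
  rx <- runif(n, min(spec$nucleus_rx_px), max(spec$nucleus_rx_px))
  ry <- runif(n, min(spec$nucleus_ry_px), max(spec$nucleus_ry_px))
  r_nuc <- max(spec$nucleus_rx_px, spec$nucleus_ry_px)
  # ring radius keeping >= 2 px between nuclei of a syncytium
  ring_r <- ifelse(k_units >= 2,
                   pmax(2, (2 * r_nuc + 4) / (2 * sin(pi / pmax(k_units, 2)))),
                   0)
  unit_r <- ring_r + r_nuc + cyto_margin_px + 2
  centers <- place_on_grid(spec$width_px, spec$height_px, n_units, unit_r,
                           what = "cells")
  units <- data.frame(unit = seq_len(n_units), x = centers$x, y = centers$y,
                      radius = unit_r, k = k_units, fused = k_units >= 2)
  nuc <- vector("list", n_units)
  idx <- 1L
  for (u in seq_len(n_units)) {
    k <- k_units[u]
    if (k == 1L) {
      nx <- units$x[u]; ny <- units$y[u]
    } else {
      ang <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi)
      nx <- units$x[u] + ring_r[u] * cos(ang)
      ny <- units$y[u] + ring_r[u] * sin(ang)
    }
    nuc[[u]] <- data.frame(nucleus = idx:(idx + k - 1L), unit = u,
                           x = nx, y = ny,
                           rx = rx[idx:(idx + k - 1L)],
                           ry = ry[idx:(idx + k - 1L)],
                           fused = k >= 2)
    idx <- idx + k
  }
  list(units = units, nuclei = do.call(rbind, nuc))
}

render_blank <- function(spec) {
  matrix(spec$background_mean, nrow = spec$height_px, ncol = spec$width_px)
}

add_noise <- function(m, sd) {
  if (sd > 0) m <- m + matrix(rnorm(length(m), 0, sd), nrow = nrow(m))
  pmax(m, 0)
}

#' Generate a two-color fusion field with ground truth
#'
#' Emulates the dual-reporter fusion assay: two cell populations expressing
#' GFP or mCherry are cocultured; syncytia formed by fusion carry both
#' fluorophores over a shared cytoplasm while unfused cells carry exactly
#' one. Hoechst marks every nucleus. Cytoplasm discs extend well beyond the
#' nuclei so the 5-pixel region erosion used by the quantification leaves
#' member nuclei fully covered.
#'
#' @param spec A [field_spec()].
#' @param seed Seed overriding \code{spec$seed}.
#' @return A list with \code{image} (a [field_image()] with channels
#'   \code{hoechst}, \code{gfp}, \code{mcherry}) and \code{truth}, a list
#'   holding the per-nucleus table (centres, fused flag, unit, color) and
#'   pixel-count summaries.
#' @export
generate_two_color_field <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    lay <- layout_field(spec)
    h <- spec$height_px; w <- spec$width_px
    ho <- render_blank(spec); gf <- render_blank(spec); mc <- render_blank(spec)
    fused_px <- 0L
    dapi_px <- 0L
    if (nrow(lay$units)) {
      mono <- which(!lay$units$fused)
      color <- rep(NA_character_, nrow(lay$units))
      if (length(mono)) {
        color[mono] <- sample(rep_len(c("gfp", "mcherry"), length(mono)))
      }
      color[lay$units$fused] <- "both"
      for (u in seq_len(nrow(lay$units))) {
        px <- ellipse_pixels(h, w, lay$units$x[u], lay$units$y[u],
                             lay$units$radius[u])
        if (color[u] %in% c("gfp", "both")) gf[px] <- spec$channel_gains[["gfp"]]
        if (color[u] %in% c("mcherry", "both")) mc[px] <- spec$channel_gains[["mcherry"]]
        if (color[u] == "both") fused_px <- fused_px + length(px)
      }
      for (i in seq_len(nrow(lay$nuclei))) {
        px <- ellipse_pixels(h, w, lay$nuclei$x[i], lay$nuclei$y[i],
                             lay$nuclei$rx[i], lay$nuclei$ry[i])
        ho[px] <- spec$channel_gains[["hoechst"]]
        dapi_px <- dapi_px + length(px)
      }
      lay$nuclei$color <- color[lay$nuclei$unit]
    }
    img <- field_image(list(hoechst = add_noise(ho, spec$noise_sd),
                            gfp = add_noise(gf, spec$noise_sd),
                            mcherry = add_noise(mc, spec$noise_sd)),
                       spec$pixel_size_um)
    list(image = img,
         truth = list(nuclei = lay$nuclei, units = lay$units,
                      true_fused_area_px = fused_px,
                      true_dapi_area_px = dapi_px))
  })
}

#' Generate a split-GFP fusion field
#'
#' Emulates the complementation assay in which GFP fluorescence is
#' reconstituted only where the two non-fluorescent halves meet in a shared
#' cytoplasm: fused sheets are GFP-positive, unfused cells are dark in GFP
#' but stained by Hoechst.
#'
#' @inheritParams generate_two_color_field
#' @return As [generate_two_color_field()], with channels \code{hoechst}
#'   and \code{gfp}; \code{truth$true_fused_area_px} is the exact rendered
#'   GFP-sheet pixel count.
#' @export
generate_splitgfp_field <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    lay <- layout_field(spec)
    h <- spec$height_px; w <- spec$width_px
    ho <- render_blank(spec); gf <- render_blank(spec)
    fused_px <- 0L; dapi_px <- 0L
    if (nrow(lay$units)) {
      for (u in which(lay$units$fused)) {
        px <- ellipse_pixels(h, w, lay$units$x[u], lay$units$y[u],
                             lay$units$radius[u])
        gf[px] <- spec$channel_gains[["gfp"]]
        fused_px <- fused_px + length(px)
      }
      for (i in seq_len(nrow(lay$nuclei))) {
        px <- ellipse_pixels(h, w, lay$nuclei$x[i], lay$nuclei$y[i],
                             lay$nuclei$rx[i], lay$nuclei$ry[i])
        ho[px] <- spec$channel_gains[["hoechst"]]
        dapi_px <- dapi_px + length(px)
      }
    }
    img <- field_image(list(hoechst = add_noise(ho, spec$noise_sd),
                            gfp = add_noise(gf, spec$noise_sd)),
                       spec$pixel_size_um)
    list(image = img,
         truth = list(nuclei = lay$nuclei, units = lay$units,
                      true_fused_area_px = fused_px,
                      true_dapi_area_px = dapi_px))
  })
}

#' Generate a lysosome-staining field
#'
#' Renders mononucleated cells with a known number of non-overlapping
#' lysosomal puncta (hard discs) per cell in a lysotracker-like channel, so
#' spot counts and thresholded areas have exact ground truth.
#'
#' @inheritParams generate_two_color_field
#' @param puncta_per_cell Puncta rendered inside each cell.
#' @param puncta_radius_px Punctum disc radius (pixels).
#' @return List with \code{image} (channels \code{hoechst}, \code{lyso})
#'   and \code{truth} (\code{lyso_count}, \code{lyso_area_px}, puncta
#'   centres, nuclei).
#' @export
generate_lysosome_field <- function(spec, puncta_per_cell = 10,
                                    puncta_radius_px = 2, seed = spec$seed) {
  stopifnot_scalar(puncta_per_cell, "puncta_per_cell", 0)
  stopifnot_scalar(puncta_radius_px, "puncta_radius_px", 1)
  spec2 <- spec
  spec2$fused_fraction <- 0
  with_seed(seed, {
    lay <- layout_field(spec2, cyto_margin_px = 14)
    h <- spec$height_px; w <- spec$width_px
    ho <- render_blank(spec); ly <- render_blank(spec)
    count <- 0L; area <- 0L
    pts <- list()
    if (nrow(lay$units)) {
      for (i in seq_len(nrow(lay$nuclei))) {
        px <- ellipse_pixels(h, w, lay$nuclei$x[i], lay$nuclei$y[i],
                             lay$nuclei$rx[i], lay$nuclei$ry[i])
        ho[px] <- spec$channel_gains[["hoechst"]]
      }
      if (puncta_per_cell > 0) {
        sp <- 2 * puncta_radius_px + 3
        for (u in seq_len(nrow(lay$units))) {
          rmax <- lay$units$radius[u] - puncta_radius_px - 2
          offs <- expand.grid(dx = seq(-rmax, rmax, by = sp),
                              dy = seq(-rmax, rmax, by = sp))
          offs <- offs[sqrt(offs$dx^2 + offs$dy^2) <= rmax, , drop = FALSE]
          if (nrow(offs) < puncta_per_cell) {
            stop("puncta density too high to place without overlap",
                 call. = FALSE)
          }
          pick <- offs[sample.int(nrow(offs), puncta_per_cell), , drop = FALSE]
          for (j in seq_len(puncta_per_cell)) {
            cx <- lay$units$x[u] + pick$dx[j]
            cy <- lay$units$y[u] + pick$dy[j]
            px <- ellipse_pixels(h, w, cx, cy, puncta_radius_px)
            ly[px] <- spec$channel_gains[["lyso"]]
            count <- count + 1L
            area <- area + length(px)
            pts[[length(pts) + 1L]] <- c(cx, cy)
          }
        }
      }
    }
    img <- field_image(list(hoechst = add_noise(ho, spec$noise_sd),
                            lyso = add_noise(ly, spec$noise_sd)),
                       spec$pixel_size_um)
    centers <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 2)
    list(image = img,
         truth = list(nuclei = lay$nuclei, units = lay$units,
                      lyso_count = count, lyso_area_px = area,
                      puncta_centers = centers))
  })
}

#' Generate a nuclear/cytoplasmic reporter field
#'
#' Each cell's reporter intensity is piecewise constant: background
#' everywhere, a cytoplasmic level over the cell disc and a nuclear level
#' over the nucleus solved from the requested ratio, so that
#' (nuclear - background) / (cytoplasmic - background) equals the request
#' exactly before noise.
#'
#' @inheritParams generate_two_color_field
#' @param nc_ratios Requested per-cell ratios, recycled across cells.
#' @param background_level Rendered background (counts); default 150 sits
#'   below the assay's 200-count background cutoff.
#' @param cyto_level Rendered cytoplasmic plateau (counts).
#' @return List with \code{image} (channels \code{hoechst},
#'   \code{reporter}) and \code{truth$per_cell_nc_ratio}.
#' @export
generate_nc_field <- function(spec, nc_ratios = 2, background_level = 150,
                              cyto_level = 600, seed = spec$seed) {
  if (any(nc_ratios <= 0)) stop("nc_ratios must be positive")
  if (cyto_level <= background_level) stop("cyto_level must exceed background_level")
  spec2 <- spec
  spec2$fused_fraction <- 0
  with_seed(seed, {
    lay <- layout_field(spec2, cyto_margin_px = 18)
    h <- spec$height_px; w <- spec$width_px
    ho <- render_blank(spec)
    rp <- matrix(background_level, h, w)
    ratios <- numeric(0)
    if (nrow(lay$units)) {
      ratios <- rep_len(nc_ratios, nrow(lay$units))
      for (u in seq_len(nrow(lay$units))) {
        px <- ellipse_pixels(h, w, lay$units$x[u], lay$units$y[u],
                             lay$units$radius[u])
        rp[px] <- cyto_level
      }
      nuc_levels <- background_level + ratios * (cyto_level - background_level)
      for (i in seq_len(nrow(lay$nuclei))) {
        px <- ellipse_pixels(h, w, lay$nuclei$x[i], lay$nuclei$y[i],
                             lay$nuclei$rx[i], lay$nuclei$ry[i])
        ho[px] <- spec$channel_gains[["hoechst"]]
        rp[px] <- nuc_levels[lay$nuclei$unit[i]]
      }
    }
    img <- field_image(list(hoechst = add_noise(ho, spec$noise_sd),
                            reporter = add_noise(rp, spec$noise_sd)),
                       spec$pixel_size_um)
    list(image = img,
         truth = list(nuclei = lay$nuclei, units = lay$units,
                      per_cell_nc_ratio = ratios,
                      background_level = background_level,
                      cyto_level = cyto_level))
  })
}
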