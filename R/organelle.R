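#' Lysosome metrics for one field
#'
#' Counts lysosomal puncta (LoG detection) and measures the thresholded
#' lysosomal region area, then normalizes both by the number of nuclei in
#' the field: spots / nuclei and summed thresholded area / nuclei. A field
#' with zero nuclei is flagged and its ratios are \code{NA}.
#'
#' @param lyso_channel 2D intensity matrix (single middle plane by
#'   convention for moving organelles).
#' @param nuclei Integer nucleus label matrix for the same field.
#' @param pixel_size_um Pixel size (um).
#' @param spot_radius_px Expected punctum radius for detection.
#' @param intensity_threshold Absolute intensity threshold for the
#'   lysosomal region area (the assay thresholds the lysotracker channel at
#'   a fixed level; default 1000 counts on the package's intensity
#'   convention, or \code{NULL} for Otsu).
#' @param min_response LoG response floor passed to [find_spots()].
#' @return List of class \code{lyso_field_result}: \code{n_spots},
#'   \code{thresholded_area_um2}, \code{n_nuclei}, \code{spots_per_nucleus},
#'   \code{area_per_nucleus_um2}, \code{flag_no_nuclei}.
#' @export
lysosome_metrics <- function(lyso_channel, nuclei, pixel_size_um,
                             spot_radius_px = 2, intensity_threshold = 1000,
                             min_response = 100) {
  stopifnot(all(dim(lyso_channel) == dim(nuclei)))
  n_nuc <- max(nuclei)
  spots <- find_spots(lyso_channel, radius_px = spot_radius_px,
                      min_response = min_response,
                      area_threshold = intensity_threshold)
  th <- intensity_threshold %||% threshold_otsu(lyso_channel)
  area_px <- if (is.na(th)) 0L else sum(lyso_channel > th)
  area_um2 <- area_px * pixel_size_um^2
  structure(list(
    n_spots = nrow(spots),
    thresholded_area_um2 = area_um2,
    n_nuclei = n_nuc,
    spots_per_nucleus = if (n_nuc > 0) nrow(spots) / n_nuc else NA_real_,
    area_per_nucleus_um2 = if (n_nuc > 0) area_um2 / n_nuc else NA_real_,
    flag_no_nuclei = n_nuc == 0,
    spots = spots
  ), class = "lyso_field_result")
}

#' Mean nuclear area of a field
#'
#' Mean area in um^2 over the selected nuclei (the label image is assumed
#' already filtered for debris and border objects by [find_nuclei()]).
#'
#' @param nuclei Integer label matrix.
#' @param pixel_size_um Pixel size (um).
#' @return Scalar mean area; \code{NA} with attribute \code{empty = TRUE}
#'   when no nucleus survived selection.
#' @export
nuclear_area_stats <- function(nuclei, pixel_size_um) {
  areas <- label_areas(nuclei) * pixel_size_um^2
  if (!length(areas)) {
    return(structure(NA_real_, empty = TRUE, n_nuclei = 0L))
  }
  structure(mean(areas), empty = FALSE, n_nuclei = length(areas))
}

#' Background-corrected nuclear/cytoplasmic ratio
#'
#' Per cell: (mean nuclear intensity - mean background intensity) /
#' (mean cytoplasmic intensity - mean background intensity). The
#' background region is all field pixels strictly below
#' \code{bkgd_cutoff}; when none exists the background is taken as 0 with
#' a warning and the ratio reduces to nuclear/cytoplasmic. Cells whose
#' cytoplasmic mean does not exceed the background mean, or whose ring was
#' clipped below \code{min_ring_px} pixels, are flagged and excluded from
#' the field mean. A \code{guard_px} band at the nucleus boundary is
#' excluded from both compartments to avoid segmentation edge mixing.
#'
#' @param reporter_channel 2D intensity matrix.
#' @param nuclei Integer nucleus label matrix.
#' @param rings Ring label matrix from [surrounding_region()]; pass
#'   \code{NULL} to derive rings with defaults.
#' @param bkgd_cutoff Background intensity cutoff (counts), default 200.
#' @param min_ring_px Minimum usable ring size (pixels).
#' @param guard_px Erosion applied to each nucleus before averaging; rings
#'   should be built with the same \code{gap_px}.
#' @param ring_width_px Ring width when \code{rings} is \code{NULL}.
#' @return List of class \code{nc_ratio_result}: per-cell data.frame
#'   \code{cells} (label, nuc_mean, cyto_mean, ratio, excluded, reason),
#'   \code{bkgd_mean}, and \code{field_mean} over included cells.
#' @export
nc_ratio <- function(reporter_channel, nuclei, rings = NULL,
                     bkgd_cutoff = 200, min_ring_px = 20, guard_px = 2,
                     ring_width_px = 10) {
  stopifnot(all(dim(reporter_channel) == dim(nuclei)))
  if (is.null(rings)) {
    rings <- surrounding_region(nuclei, width_px = ring_width_px,
                                gap_px = guard_px)
  }
  stopifnot(all(dim(rings) == dim(nuclei)))
  if (any(rings > 0 & nuclei > 0)) stop("rings must be disjoint from nuclei")
  bk_px <- reporter_channel[reporter_channel < bkgd_cutoff]
  if (length(bk_px) == 0) {
    warning("no pixels below background cutoff; using background = 0")
    bkgd <- 0
  } else {
    bkgd <- mean(bk_px)
  }
  core <- nuclei
  if (guard_px > 0 && max(nuclei) > 0) {
    kern <- EBImage::makeBrush(3, "diamond")
    m <- nuclei > 0
    for (i in seq_len(guard_px)) {
      m <- matrix(as.numeric(EBImage::imageData(
        EBImage::erode(m * 1, kern))) > 0.5, nrow(nuclei))
    }
    core[!m] <- 0L
  }
  n <- max(nuclei)
  cells <- data.frame(label = seq_len(n), nuc_mean = NA_real_,
                      cyto_mean = NA_real_, ratio = NA_real_,
                      excluded = FALSE, reason = "")
  for (l in seq_len(n)) {
    npx <- reporter_channel[core == l]
    if (!length(npx)) npx <- reporter_channel[nuclei == l]
    rpx <- reporter_channel[rings == l]
    cells$nuc_mean[l] <- mean(npx)
    cells$cyto_mean[l] <- if (length(rpx)) mean(rpx) else NA_real_
    if (length(rpx) < min_ring_px) {
      cells$excluded[l] <- TRUE; cells$reason[l] <- "ring_clipped"
    } else if (cells$cyto_mean[l] <= bkgd) {
      cells$excluded[l] <- TRUE; cells$reason[l] <- "cyto_below_background"
    } else {
      cells$ratio[l] <- (cells$nuc_mean[l] - bkgd) / (cells$cyto_mean[l] - bkgd)
    }
  }
  ok <- !cells$excluded
  structure(list(cells = cells, bkgd_mean = bkgd,
                 field_mean = if (any(ok)) mean(cells$ratio[ok]) else NA_real_,
                 n_included = sum(ok)),
            class = "nc_ratio_result")
}
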