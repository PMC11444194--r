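#' Quantification configuration
#'
#' Filters and thresholds shared by the image assays. Defaults follow the
#' published analysis: nuclei below 50 um^2 are discarded as debris,
#' fluorophore regions below 100 um^2 are discarded, regions are eroded by
#' 5 pixels before overlap scoring, nuclei are called channel-positive above
#' 90% (AND rule) or 70% (OR rule) overlap, the split-GFP channel is
#' smoothed with a 2-pixel Gaussian, and reporter background sits below an
#' intensity cutoff of 200 counts.
#'
#' @param nucleus_min_area_um2,region_min_area_um2 Area filters (um^2).
#' @param region_erosion_px Binary erosions applied to fluorophore regions.
#' @param overlap_hi_pct,overlap_lo_pct Fusion-index thresholds (percent);
#'   strict inequalities are applied at both.
#' @param splitgfp_smooth_sigma_px Gaussian sigma for the split-GFP channel.
#' @param bkgd_intensity_cutoff Background cutoff (counts) for the
#'   nuclear/cytoplasmic assay.
#' @param exclude_border_nuclei Drop nuclei touching the field border.
#' @param nucleus_smooth_sigma_px Gaussian sigma before nuclear thresholding.
#' @param threshold_method \code{"otsu"} or \code{"minimum"} histogram
#'   threshold for segmentation.
#' @return Object of class \code{quant_config}.
#' @export
quant_config <- function(nucleus_min_area_um2 = 50, region_min_area_um2 = 100,
                         region_erosion_px = 5, overlap_hi_pct = 90,
                         overlap_lo_pct = 70, splitgfp_smooth_sigma_px = 2,
                         bkgd_intensity_cutoff = 200,
                         exclude_border_nuclei = TRUE,
                         nucleus_smooth_sigma_px = 2,
                         threshold_method = c("otsu", "minimum")) {
  if (!(overlap_lo_pct > 0 && overlap_lo_pct <= overlap_hi_pct &&
        overlap_hi_pct <= 100)) {
    stop("need 0 < overlap_lo_pct <= overlap_hi_pct <= 100")
  }
  stopifnot_scalar(nucleus_min_area_um2, "nucleus_min_area_um2", 0)
  stopifnot_scalar(region_min_area_um2, "region_min_area_um2", 0)
  stopifnot_scalar(region_erosion_px, "region_erosion_px", 0)
  structure(list(nucleus_min_area_um2 = nucleus_min_area_um2,
                 region_min_area_um2 = region_min_area_um2,
                 region_erosion_px = as.integer(region_erosion_px),
                 overlap_hi_pct = overlap_hi_pct,
                 overlap_lo_pct = overlap_lo_pct,
                 splitgfp_smooth_sigma_px = splitgfp_smooth_sigma_px,
                 bkgd_intensity_cutoff = bkgd_intensity_cutoff,
                 exclude_border_nuclei = isTRUE(exclude_border_nuclei),
                 nucleus_smooth_sigma_px = nucleus_smooth_sigma_px,
                 threshold_method = match.arg(threshold_method)),
            class = "quant_config")
}

#' Maximum-intensity projection
#'
#' @param stack A list of equally sized matrices or a 3D array with planes
#'   in the third dimension.
#' @return Matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  }
  stopifnot(is.list(stack), length(stack) >= 1)
  dims <- vapply(stack, dim, integer(2))
  if (any(dims != dims[, 1])) stop("plane shape mismatch")
  Reduce(pmax, stack)
}

# ImageJ-style "Minimum" histogram threshold: smooth the 256-bin histogram
# with a running mean of 3 until it is bimodal, then threshold at the
# minimum between the two modes. Returns NA for images with no bimodal
# structure (e.g. uniform).
threshold_minimum <- function(x, levels = 256L, max_smooth = 10000L) {
  r <- range(x)
  if (diff(r) == 0) return(NA_real_)
  br <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = levels)
  h <- as.numeric(h)
  n_modes <- function(v) {
    n <- length(v)
    sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n])
  }
  it <- 0L
  while (n_modes(h) > 2L && it < max_smooth) {
    h <- (c(h[1], h[-length(h)]) + h + c(h[-1], h[length(h)])) / 3
    it <- it + 1L
  }
  if (n_modes(h) != 2L) return(NA_real_)
  n <- length(h)
  peaks <- which(h[2:(n - 1)] > h[1:(n - 2)] & h[2:(n - 1)] >= h[3:n]) + 1L
  lo <- peaks[1]; hi <- peaks[length(peaks)]
  between <- lo:hi
  mid <- between[which.min(h[between])]
  (br[mid] + br[mid + 1L]) / 2
}

# Otsu threshold on the raw intensity scale.
threshold_otsu <- function(x, levels = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(NA_real_)
  img <- EBImage::Image((x - r[1]) / diff(r))
  t01 <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  r[1] + t01 * diff(r)
}

auto_threshold <- function(x, method = "otsu") {
  switch(method,
         otsu = threshold_otsu(x),
         minimum = threshold_minimum(x),
         stop("unknown threshold method: ", method))
}

# Relabel a label matrix so labels are contiguous 1..n, dropping `drop`.
relabel <- function(lab, drop = integer(0)) {
  u <- setdiff(sort(unique(as.integer(lab))), c(0L, drop))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0 & !(lab %in% drop)
  out[pos] <- map[as.integer(lab[pos])]
  out
}

label_areas <- function(lab) {
  m <- max(lab)
  if (m == 0) return(integer(0))
  tabulate(as.integer(lab[lab > 0]), nbins = m)
}

border_labels <- function(lab) {
  unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
}

#' Segment nuclei from a DNA-stain channel
#'
#' Gaussian smoothing, automatic histogram threshold, hole filling and a
#' distance-transform watershed to split touching nuclei, followed by the
#' area filter (> \code{nucleus_min_area_um2}) and optional exclusion of
#' border-touching objects. This is an open substitute for the instrument
#' vendor's unpublished "find nuclei" routine; the published area and
#' border filters are preserved exactly.
#'
#' @param hoechst 2D intensity matrix.
#' @param pixel_size_um Pixel size (um).
#' @param cfg A [quant_config()].
#' @return Integer label matrix (0 = background), labels contiguous.
#' @export
find_nuclei <- function(hoechst, pixel_size_um, cfg = quant_config()) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um", 1e-6)
  sm <- if (cfg$nucleus_smooth_sigma_px > 0) {
    as.matrix(EBImage::gblur(hoechst, sigma = cfg$nucleus_smooth_sigma_px))
  } else hoechst
  th <- auto_threshold(sm, cfg$threshold_method)
  if (is.na(th)) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  mask <- sm > th
  if (!any(mask)) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 3, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(hoechst))
  areas <- label_areas(lab)
  drop <- which(areas * pixel_size_um^2 <= cfg$nucleus_min_area_um2)
  if (cfg$exclude_border_nuclei) drop <- union(drop, border_labels(lab))
  relabel(lab, drop = drop)
}

#' Threshold fluorophore-positive regions with a minimum area
#'
#' @param channel 2D intensity matrix.
#' @param intensity_threshold Absolute threshold; pixels strictly above are
#'   foreground. \code{NULL} uses an automatic Otsu threshold.
#' @param min_area_um2 Connected components at or below this area are
#'   removed.
#' @param pixel_size_um Pixel size (um).
#' @return Logical mask matrix.
#' @export
threshold_regions <- function(channel, intensity_threshold = NULL,
                              min_area_um2 = 100, pixel_size_um = 0.6) {
  th <- intensity_threshold %||% threshold_otsu(channel)
  if (is.na(th)) return(matrix(FALSE, nrow(channel), ncol(channel)))
  mask <- channel > th
  if (!any(mask) || min_area_um2 <= 0) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(channel))
  areas <- label_areas(lab)
  small <- which(areas * pixel_size_um^2 <= min_area_um2)
  lab %in% setdiff(seq_along(areas), small) & mask
}

#' Erode a binary region mask
#'
#' One-pixel binary erosions with a 4-connected (plus-shaped) structuring
#' element, repeated \code{iterations} times.
#'
#' @param mask Logical matrix.
#' @param iterations Number of single-pixel erosions (default 5).
#' @return Logical matrix, a subset of the input.
#' @export
erode_regions <- function(mask, iterations = 5L) {
  stopifnot_scalar(iterations, "iterations", 0)
  m <- mask * 1
  if (iterations >= 1) {
    kern <- EBImage::makeBrush(3, shape = "diamond")
    for (i in seq_len(iterations)) m <- EBImage::erode(m, kern)
  }
  matrix(as.numeric(EBImage::imageData(EBImage::Image(m))) > 0.5,
         nrow(mask))
}

#' Detect puncta with a Laplacian-of-Gaussian blob filter
#'
#' Scale-normalized LoG response at the configured punctum radius, local
#' maxima above an absolute response floor, with parabolic subpixel
#' refinement. An open substitute for the vendor's unpublished "find spots"
#' routine.
#'
#' @param channel 2D intensity matrix.
#' @param radius_px Expected punctum radius in pixels; the LoG scale is
#'   \code{radius_px / sqrt(2)}.
#' @param min_response Absolute response floor (counts); blank fields give
#'   zero detections at the default.
#' @param area_threshold Absolute intensity threshold used to report each
#'   spot's thresholded area; \code{NULL} for Otsu.
#' @return data.frame with \code{x, y} (subpixel, pixel units), \code{peak}
#'   (intensity at the maximum) and \code{area_px}.
#' @export
find_spots <- function(channel, radius_px = 2, min_response = 100,
                       area_threshold = NULL) {
  sigma <- max(0.8, radius_px / sqrt(2))
  hw <- ceiling(3 * sigma)
  ax <- (-hw):hw
  g <- exp(-ax^2 / (2 * sigma^2))
  g <- g / sum(g)
  # separable scale-normalized LoG: sigma^2 * (d2/dx2 + d2/dy2) gaussian
  x2 <- ax^2
  g2 <- (x2 / sigma^2 - 1) / sigma^2 * g
  K <- sigma^2 * (outer(g2, g) + outer(g, g2))
  resp <- as.matrix(EBImage::filter2(channel, -K))
  mx <- as.matrix(EBImage::dilate(resp, EBImage::makeBrush(3, "box")))
  is_max <- resp >= mx & resp > min_response
  # suppress the 1-px frame where filter2's circular padding leaks
  is_max[c(1, nrow(resp)), ] <- FALSE
  is_max[, c(1, ncol(resp))] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x = numeric(0), y = numeric(0), peak = numeric(0),
                      area_px = integer(0)))
  }
  sub_off <- function(m1, m0, m2) {
    den <- m1 - 2 * m0 + m2
    off <- ifelse(abs(den) > 1e-12, 0.5 * (m1 - m2) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  ry <- idx[, 1]; cx <- idx[, 2]
  # greedy non-maximum suppression: strongest response wins within 2 radii
  ord <- order(resp[idx], decreasing = TRUE)
  acc <- integer(0)
  min_sep2 <- (2 * radius_px)^2
  for (i in ord) {
    if (!length(acc) ||
        all((ry[acc] - ry[i])^2 + (cx[acc] - cx[i])^2 >= min_sep2)) {
      acc <- c(acc, i)
    }
  }
  acc <- sort(acc)
  ry <- ry[acc]; cx <- cx[acc]
  dy <- sub_off(resp[cbind(ry - 1, cx)], resp[cbind(ry, cx)],
                resp[cbind(ry + 1, cx)])
  dx <- sub_off(resp[cbind(ry, cx - 1)], resp[cbind(ry, cx)],
                resp[cbind(ry, cx + 1)])
  th <- area_threshold %||% threshold_otsu(channel)
  area <- rep(NA_integer_, nrow(idx))
  if (!is.na(th)) {
    lab <- EBImage::bwlabel(EBImage::Image((channel > th) * 1))
    lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(channel))
    comp <- lab[cbind(ry, cx)]
    areas <- label_areas(lab)
    area <- ifelse(comp > 0, areas[pmax(comp, 1L)], NA_integer_)
  }
  data.frame(x = cx - 0.5 + dx, y = ry - 0.5 + dy,
             peak = channel[cbind(ry, cx)], area_px = area)
}

#' Per-nucleus percentage overlap with a region mask
#'
#' @param nuclei Integer label matrix.
#' @param region Logical mask of the same shape.
#' @return Numeric vector indexed by label: 100 * |nucleus intersect
#'   region| / |nucleus|, in \[0, 100\].
#' @export
overlap_percent <- function(nuclei, region) {
  stopifnot(all(dim(nuclei) == dim(region)))
  m <- max(nuclei)
  if (m == 0) return(numeric(0))
  tot <- tabulate(as.integer(nuclei[nuclei > 0]), nbins = m)
  hit <- tabulate(as.integer(nuclei[nuclei > 0 & region]), nbins = m)
  100 * hit / tot
}

#' Cytoplasmic ring ("surrounding region") per nucleus
#'
#' Fixed-width dilation annulus around each nucleus, clipped at the
#' equidistant (Voronoi) boundary between neighbouring nuclei, so rings are
#' disjoint from every nucleus and from each other. Open substitute for the
#' vendor's "find surrounding region" routine; the width is configurable
#' because none is published.
#'
#' @param nuclei Integer label matrix.
#' @param width_px Ring width in pixels.
#' @param gap_px Guard gap between the nucleus boundary and the inner ring
#'   edge, excluded from the ring to avoid segmentation edge mixing.
#' @return Integer label matrix of rings sharing the nucleus labels.
#' @export
surrounding_region <- function(nuclei, width_px = 10L, gap_px = 0L) {
  stopifnot_scalar(width_px, "width_px", 0)
  stopifnot_scalar(gap_px, "gap_px", 0)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (max(nuclei) == 0 || width_px == 0) return(out)
  nucmask <- nuclei > 0
  outer_b <- EBImage::makeBrush(2 * (width_px + gap_px) + 1, "disc")
  collar <- as.matrix(EBImage::dilate(nucmask * 1, outer_b)) > 0.5 & !nucmask
  band <- collar
  if (gap_px > 0) {
    inner_b <- EBImage::makeBrush(2 * gap_px + 1, "disc")
    inner <- as.matrix(EBImage::dilate(nucmask * 1, inner_b)) > 0.5 & !nucmask
    band <- band & !inner
  }
  # propagate over the full collar (gap included) so growth stays connected
  # to the seeds, then restrict to the ring band
  vor <- EBImage::propagate(EBImage::Image(matrix(0, nrow(nuclei), ncol(nuclei))),
                            seeds = EBImage::Image(nuclei),
                            mask = EBImage::Image((collar | nucmask) * 1),
                            lambda = 1e8)
  vor <- matrix(as.integer(EBImage::imageData(vor)), nrow(nuclei))
  out[band] <- vor[band]
  out
}
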