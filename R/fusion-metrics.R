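#' Fusion index from per-nucleus overlap percentages
#'
#' A nucleus is counted fused when it overlaps both eroded fluorophore
#' regions by strictly more than \code{overlap_hi_pct} (90% AND rule); it
#' is counted fluorescent when it overlaps either region by strictly more
#' than \code{overlap_lo_pct} (70% OR rule). The index is
#' fused / fluorescent. Double-positive nuclei satisfy the OR rule and so
#' are included in the denominator. A field with no fluorescent nuclei
#' returns 0 with attribute \code{empty_denominator = TRUE} so well means
#' remain defined.
#'
#' @param records data.frame with columns \code{pct_overlap_mch} and
#'   \code{pct_overlap_gfp}, one row per selected nucleus of one field.
#' @param cfg A [quant_config()].
#' @return Proportion in \[0, 1\] with attributes \code{n_fused},
#'   \code{n_fluorescent} and \code{empty_denominator}.
#' @export
fusion_index <- function(records, cfg = quant_config()) {
  pm <- records$pct_overlap_mch
  pg <- records$pct_overlap_gfp
  if (any(c(pm, pg) < 0 | c(pm, pg) > 100)) {
    stop("overlap percentages must lie in [0, 100]")
  }
  num <- sum(pm > cfg$overlap_hi_pct & pg > cfg$overlap_hi_pct)
  den <- sum(pm > cfg$overlap_lo_pct | pg > cfg$overlap_lo_pct)
  value <- if (den == 0) 0 else num / den
  structure(value, n_fused = num, n_fluorescent = den,
            empty_denominator = den == 0)
}

#' Plating-density-normalized split-GFP fused area
#'
#' The GFP-positive area fraction of a field divided by its normalized
#' DAPI area, where the normalized DAPI area is the field's DAPI area
#' fraction divided by the biological-replicate mean DAPI area fraction.
#' Equivalently: \code{(gfp_area / total_area) * replicate_mean /
#' (dapi_area / total_area)}.
#'
#' @param gfp_area,dapi_area,total_area Areas in any common unit;
#'   \code{total_area > 0}, \code{dapi_area > 0}.
#' @param replicate_mean_dapi_fraction Mean of \code{dapi_area /
#'   total_area} over the biological replicate (> 0).
#' @return Nonnegative scalar; invariant to uniform rescaling of all areas.
#' @export
splitgfp_normalized_area <- function(gfp_area, dapi_area, total_area,
                                     replicate_mean_dapi_fraction) {
  stopifnot_scalar(total_area, "total_area", 1e-12)
  stopifnot_scalar(replicate_mean_dapi_fraction,
                   "replicate_mean_dapi_fraction", 1e-12)
  if (!is.numeric(dapi_area) || dapi_area <= 0) {
    stop("dapi_area must be positive: field is uninterpretable")
  }
  if (gfp_area < 0) stop("gfp_area must be >= 0")
  gfp_frac <- gfp_area / total_area
  norm_dapi <- (dapi_area / total_area) / replicate_mean_dapi_fraction
  gfp_frac / norm_dapi
}

#' Aggregate per-field metric values to well means
#'
#' Each well's value is the arithmetic mean over its imaged fields (nine
#' fields of view per well for the fusion assays); missing fields are
#' tolerated and the field count is recorded.
#'
#' @param per_field data.frame with columns \code{plate}, \code{well},
#'   \code{value} (and optionally \code{metric}).
#' @return data.frame with one row per (plate, well\[, metric\]):
#'   \code{value} = mean and \code{n_fields}.
#' @export
aggregate_well <- function(per_field) {
  stopifnot(all(c("plate", "well", "value") %in% names(per_field)))
  dt <- data.table::as.data.table(per_field)
  by <- intersect(c("plate", "well", "metric"), names(dt))
  out <- dt[, .(value = mean(value), n_fields = .N), by = by]
  as.data.frame(out)
}

#' Two-color fusion quantification of one field
#'
#' Composes the published pipeline in its printed order: segment nuclei
#' from the Hoechst channel, threshold the GFP- and mCherry-positive
#' regions with the 100 um^2 area filter, erode both region masks by 5
#' pixels, score the per-nucleus percentage overlap against each channel's
#' (union) region mask, and evaluate the fusion index.
#'
#' @param field A [field_image()] with channels \code{hoechst},
#'   \code{gfp}, \code{mcherry}; pass a per-channel list of plane stacks
#'   through [max_project()] beforehand if needed.
#' @param cfg A [quant_config()].
#' @param region_threshold Absolute intensity threshold for the
#'   fluorophore channels (\code{NULL}: Otsu per channel).
#' @return List: \code{index} (as [fusion_index()]) and \code{nuclei},
#'   the per-nucleus table of areas and overlap percentages.
#' @export
end_to_end_two_color <- function(field, cfg = quant_config(),
                                 region_threshold = NULL) {
  stopifnot(inherits(field, "field_image"))
  need <- c("hoechst", "gfp", "mcherry")
  miss <- setdiff(need, names(field$channels))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  ps <- field$pixel_size_um
  nuc <- find_nuclei(field$channels$hoechst, ps, cfg)
  masks <- lapply(field$channels[c("gfp", "mcherry")], function(ch) {
    m <- threshold_regions(ch, region_threshold, cfg$region_min_area_um2, ps)
    erode_regions(m, cfg$region_erosion_px)
  })
  n <- max(nuc)
  areas <- label_areas(nuc) * ps^2
  records <- data.frame(
    label = seq_len(n),
    area_um2 = areas,
    pct_overlap_gfp = if (n) overlap_percent(nuc, masks$gfp) else numeric(0),
    pct_overlap_mch = if (n) overlap_percent(nuc, masks$mcherry) else numeric(0)
  )
  list(index = fusion_index(records, cfg), nuclei = records)
}

#' Split-GFP fused-area quantification of one field
#'
#' Smooths the GFP channel with a 2-pixel Gaussian, thresholds GFP-positive
#' regions with the 100 um^2 area filter, thresholds the total DAPI-positive
#' region, and returns the area fractions entering
#' [splitgfp_normalized_area()].
#'
#' @inheritParams end_to_end_two_color
#' @param gfp_threshold,dapi_threshold Absolute thresholds (\code{NULL}:
#'   Otsu).
#' @return List with \code{gfp_area_px}, \code{dapi_area_px},
#'   \code{total_area_px}, \code{gfp_fraction}, \code{dapi_fraction}.
#' @export
end_to_end_splitgfp <- function(field, cfg = quant_config(),
                                gfp_threshold = NULL, dapi_threshold = NULL) {
  stopifnot(inherits(field, "field_image"))
  miss <- setdiff(c("hoechst", "gfp"), names(field$channels))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  ps <- field$pixel_size_um
  g <- field$channels$gfp
  if (cfg$splitgfp_smooth_sigma_px > 0) {
    g <- as.matrix(EBImage::gblur(g, sigma = cfg$splitgfp_smooth_sigma_px))
  }
  gmask <- threshold_regions(g, gfp_threshold, cfg$region_min_area_um2, ps)
  dth <- dapi_threshold %||% threshold_otsu(field$channels$hoechst)
  dmask <- if (is.na(dth)) {
    matrix(FALSE, nrow(g), ncol(g))
  } else field$channels$hoechst > dth
  total <- length(g)
  list(gfp_area_px = sum(gmask), dapi_area_px = sum(dmask),
       total_area_px = total,
       gfp_fraction = sum(gmask) / total,
       dapi_fraction = sum(dmask) / total)
}
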