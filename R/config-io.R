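#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file describing one pipeline run:
#' which assay to execute, the seed, the output directory, and optional
#' sections \code{quant}, \code{link}, \code{grid}, \code{field},
#' \code{model}, \code{acquisition} overriding the corresponding
#' constructor defaults ([quant_config()], [link_config()],
#' [state_grid()], [field_spec()], [diffusion_model()],
#' [acquisition_spec()]). Unknown keys are rejected with the offending
#' name; an empty file yields all defaults.
#'
#' @param path Config file path (.yaml/.yml/.json).
#' @return A validated \code{run_config} list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  build_run_config(raw)
}

build_run_config <- function(raw) {
  known_top <- c("assay", "seed", "out_dir", "n_fields", "quant", "link",
                 "grid", "field", "model", "acquisition", "n_tracks",
                 "n_subsample", "plate", "well")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  build <- function(section, ctor) {
    args <- raw[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")))
    }
    do.call(ctor, args)
  }
  cfg <- list(
    assay = raw$assay %||% "two_color",
    seed = as.integer(raw$seed %||% 1L),
    out_dir = raw$out_dir %||% ".",
    n_fields = as.integer(raw$n_fields %||% 1L),
    n_tracks = as.integer(raw$n_tracks %||% 10000L),
    n_subsample = as.integer(raw$n_subsample %||% 20000L),
    plate = raw$plate %||% "P1", well = raw$well %||% "A1",
    quant = build("quant", quant_config),
    link = build("link", link_config),
    grid = build("grid", state_grid),
    field = build("field", field_spec),
    model = build("model", diffusion_model),
    acquisition = build("acquisition", acquisition_spec)
  )
  ok <- c("two_color", "splitgfp", "lyso", "ncratio", "spt")
  if (!cfg$assay %in% ok) {
    stop("assay must be one of: ", paste(ok, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  sci <- unclass(cfg)
  sci$out_dir <- NULL   # hash the scientific settings, not the destination
  s <- jsonlite::toJSON(sci, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small stable checksum; enough to tie outputs to their settings
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_along(utf8ToInt(as.character(s))) %% 251 + 1)) %% 0xFFFFFFFF)
}

#' Write a multi-channel field as multi-page TIFF with a JSON sidecar
#'
#' Channels are stored as 16-bit pages; the sidecar records channel order,
#' pixel size and identifiers so the image round-trips losslessly through
#' [read_field_tiff()].
#'
#' @param field A [field_image()].
#' @param path Output TIFF path (sidecar gets \code{.json} appended).
#' @return \code{path}, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(field$channels, function(m) {
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(channels = names(field$channels),
                  pixel_size_um = field$pixel_size_um,
                  plate = field$plate, well = field$well,
                  field = field$field)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- sidecar$channels
  field_image(channels, sidecar$pixel_size_um, sidecar$plate, sidecar$well,
              sidecar$field)
}

#' Write / read a trajectory table CSV
#'
#' Schema: \code{movie_id, trajectory_id, frame, x_um, y_um, cell_id}.
#'
#' @param tracks Trajectory table.
#' @param path CSV path.
#' @return \code{path} / a data.table.
#' @export
write_trajectories <- function(tracks, path) {
  dt <- data.table::as.data.table(tracks)
  if (!"cell_id" %in% names(dt)) dt$cell_id <- 1L
  cols <- c("movie_id", "trajectory_id", "frame", "x_um", "y_um", "cell_id")
  miss <- setdiff(cols, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data.table::fwrite(dt[, cols, with = FALSE], path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  data.table::fread(path)
}

#' Run one configured pipeline end to end
#'
#' Simulates the configured assay's synthetic input, quantifies it with
#' the corresponding module, and writes tidy CSV outputs plus a JSON
#' summary (stamped with the seed and a config hash) under
#' \code{config$out_dir}. Per-stage object counts (nuclei found, nuclei
#' after filters, trajectories after masking, ...) are logged so filter
#' behaviour is auditable.
#'
#' @param config A \code{run_config} from [load_config()].
#' @return Named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  out <- list()
  stamp <- function(df) {
    df$seed <- config$seed; df$config_hash <- hash
    df
  }
  log_count <- function(...) message(sprintf(...))
  ps <- config$field$pixel_size_um
  if (config$assay == "two_color") {
    rows <- lapply(seq_len(config$n_fields), function(fi) {
      fld <- generate_two_color_field(config$field, seed = config$seed + fi)
      res <- end_to_end_two_color(fld$image, config$quant)
      log_count("field %d: %d nuclei selected, %d fluorescent, %d fused",
                fi, nrow(res$nuclei), attr(res$index, "n_fluorescent"),
                attr(res$index, "n_fused"))
      data.frame(plate = config$plate, well = config$well, field = fi,
                 metric = "fusion_index", value = as.numeric(res$index))
    })
    per_field <- do.call(rbind, rows)
    out$per_field <- file.path(config$out_dir, "two_color_per_field.csv")
    data.table::fwrite(stamp(per_field), out$per_field)
    out$per_well <- file.path(config$out_dir, "two_color_per_well.csv")
    data.table::fwrite(stamp(aggregate_well(per_field)), out$per_well)
  } else if (config$assay == "splitgfp") {
    rows <- lapply(seq_len(config$n_fields), function(fi) {
      fld <- generate_splitgfp_field(config$field, seed = config$seed + fi)
      res <- end_to_end_splitgfp(fld$image, config$quant)
      data.frame(plate = config$plate, well = config$well, field = fi,
                 gfp_fraction = res$gfp_fraction,
                 dapi_fraction = res$dapi_fraction)
    })
    per_field <- do.call(rbind, rows)
    mean_dapi <- mean(per_field$dapi_fraction)
    per_field$value <- mapply(splitgfp_normalized_area,
                              per_field$gfp_fraction, per_field$dapi_fraction,
                              1, mean_dapi)
    per_field$metric <- "splitgfp_normalized_area"
    log_count("replicate mean DAPI fraction: %.4f", mean_dapi)
    out$per_field <- file.path(config$out_dir, "splitgfp_per_field.csv")
    data.table::fwrite(stamp(per_field), out$per_field)
  } else if (config$assay == "lyso") {
    rows <- lapply(seq_len(config$n_fields), function(fi) {
      fld <- generate_lysosome_field(config$field, seed = config$seed + fi)
      nuc <- find_nuclei(fld$image$channels$hoechst, ps, config$quant)
      res <- lysosome_metrics(fld$image$channels$lyso, nuc, ps)
      log_count("field %d: %d nuclei, %d spots", fi, res$n_nuclei, res$n_spots)
      data.frame(plate = config$plate, well = config$well, field = fi,
                 n_spots = res$n_spots, n_nuclei = res$n_nuclei,
                 spots_per_nucleus = res$spots_per_nucleus,
                 area_per_nucleus_um2 = res$area_per_nucleus_um2)
    })
    out$per_field <- file.path(config$out_dir, "lyso_per_field.csv")
    data.table::fwrite(stamp(do.call(rbind, rows)), out$per_field)
  } else if (config$assay == "ncratio") {
    rows <- lapply(seq_len(config$n_fields), function(fi) {
      fld <- generate_nc_field(config$field, seed = config$seed + fi)
      nuc <- find_nuclei(fld$image$channels$hoechst, ps, config$quant)
      res <- nc_ratio(fld$image$channels$reporter, nuc,
                      bkgd_cutoff = config$quant$bkgd_intensity_cutoff)
      log_count("field %d: %d nuclei, %d cells included", fi, max(nuc),
                res$n_included)
      data.frame(plate = config$plate, well = config$well, field = fi,
                 metric = "nc_ratio", value = res$field_mean,
                 n_cells = res$n_included, bkgd_mean = res$bkgd_mean)
    })
    out$per_field <- file.path(config$out_dir, "ncratio_per_field.csv")
    data.table::fwrite(stamp(do.call(rbind, rows)), out$per_field)
  } else if (config$assay == "spt") {
    sim <- simulate_trajectories(config$model, config$acquisition,
                                 config$n_tracks, seed = config$seed)
    log_count("simulated %d tracks (%d localizations)", config$n_tracks,
              nrow(sim$tracks))
    out$tracks <- file.path(config$out_dir, "trajectories.csv")
    write_trajectories(sim$tracks, out$tracks)
    sp <- infer_spectrum(sim$tracks, config$grid, seed = config$seed)
    log_count("%d trajectories entered inference (%d jumps)",
              sp$n_trajectories, sp$n_jumps)
    out$spectrum <- file.path(config$out_dir, "spectrum.csv")
    data.table::fwrite(stamp(data.frame(D_um2s = sp$D,
                                        occupancy = sp$occupancy)),
                       out$spectrum)
    out$summary <- file.path(config$out_dir, "spt_summary.json")
    jsonlite::write_json(list(
      bound_fraction = bound_fraction(sp, config$grid$bound_threshold_um2s),
      n_trajectories = sp$n_trajectories, n_jumps = sp$n_jumps,
      truth_occupancy = sim$truth$occupancy, seed = config$seed,
      config_hash = hash
    ), out$summary, auto_unbox = TRUE, digits = NA)
  }
  out$config <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(c(unclass(config)[c("assay", "seed", "n_fields",
                                           "n_tracks")],
                         list(config_hash = hash)),
                       out$config, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
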