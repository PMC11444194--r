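#!/usr/bin/env Rscript
# Generate one ground-truthed example field per image assay and archive the
# images (multi-page TIFF + JSON sidecar) and truth tables under
# results/fields/. These are the inputs the later quantification scripts
# re-measure, so every downstream number can be checked against truth.

suppressMessages(library(fusionscope))
out <- "results/fields"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

spec <- field_spec(n_cells = 40, fused_fraction = 0.5, seed = seed)

two <- generate_two_color_field(spec)
write_field_tiff(two$image, file.path(out, "two_color.tif"))
write.csv(two$truth$nuclei, file.path(out, "two_color_truth_nuclei.csv"),
          row.names = FALSE)

sg <- generate_splitgfp_field(spec)
write_field_tiff(sg$image, file.path(out, "splitgfp.tif"))

ly <- generate_lysosome_field(field_spec(n_cells = 8, seed = seed),
                              puncta_per_cell = 12)
write_field_tiff(ly$image, file.path(out, "lysosome.tif"))

nc <- generate_nc_field(field_spec(n_cells = 16, seed = seed),
                        nc_ratios = c(1, 2))
write_field_tiff(nc$image, file.path(out, "nc_reporter.tif"))

cat(sprintf("two-color: %d nuclei (%d fused), %d px dual-labeled cytoplasm\n",
            nrow(two$truth$nuclei), sum(two$truth$nuclei$fused),
            two$truth$true_fused_area_px))
cat(sprintf("split-GFP: %d px reconstituted sheet, %d px DAPI\n",
            sg$truth$true_fused_area_px, sg$truth$true_dapi_area_px))
cat(sprintf("lysosome: %d puncta, %d px total\n",
            ly$truth$lyso_count, ly$truth$lyso_area_px))
cat(sprintf("n/c reporter: requested ratios %s\n",
            paste(unique(nc$truth$per_cell_nc_ratio), collapse = ", ")))
cat("fields written to", out, "\n")
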