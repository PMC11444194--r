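#!/usr/bin/env Rscript
# State-array diffusion spectra across the study's dynamic range: two-state
# mixtures whose immobile share spans a diffusing control (~9%), the
# untreated and Forskolin-treated regimes (19%, 42%, 62%) and a
# chromatin-bound control (~85%). Each preset is simulated at 20,000
# molecules and the bound fraction (occupancy < 0.1 um^2/s) is compared
# with its simulated truth.

suppressMessages(library(fusionscope))
dir.create("results", showWarnings = FALSE)

acq <- acquisition_spec()
grid <- state_grid()
shares <- c(nls_like = 0.09, dmso_like = 0.19, fsk24h_like = 0.42,
            fsk48h_like = 0.62, h2b_like = 0.85)

rows <- list(); spectra <- list()
for (i in seq_along(shares)) {
  mod <- diffusion_model(c(0.01, 2.5), c(shares[i], 1 - shares[i]))
  sim <- simulate_trajectories(mod, acq, 20000, seed = 100 + i)
  sp <- infer_spectrum(sim$tracks, grid, seed = 1)
  bf <- bound_fraction(sp)
  rows[[i]] <- data.frame(preset = names(shares)[i],
                          immobile_truth = sim$truth$occupancy[1],
                          bound_fraction = bf,
                          n_trajectories = sp$n_trajectories,
                          n_jumps = sp$n_jumps)
  spectra[[i]] <- data.frame(preset = names(shares)[i], D_um2s = sp$D,
                             occupancy = sp$occupancy)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/bound_fraction_presets.csv", row.names = FALSE)
write.csv(do.call(rbind, spectra), "results/diffusion_spectra.csv",
          row.names = FALSE)

cat("bound fraction by preset (20,000 simulated molecules each):\n")
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("max |error|: %.3f; ordering preserved: %s\n",
            max(abs(tab$bound_fraction - tab$immobile_truth)),
            all(diff(tab$bound_fraction) > 0)))
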