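# fusionscope

Quantification machinery for studies of trophoblast cell–cell fusion and
TFEB nuclear dynamics, in R. BeWo cytotrophoblasts fuse into multinucleated
syncytiotrophoblast-like cells under cAMP stimulation; alongside, the
transcription factor TFEB moves into the nucleus and engages chromatin.
`fusionscope` implements the image-based readouts of that biology and the
single-particle-tracking (SPT) workflow that measures TFEB's
chromatin-bound fraction, together with a synthetic-data module that
renders ground-truthed inputs so every stage is verifiable without any
instrument data.

It is aimed at quantitative cell biologists and image-analysis developers
who need the published formulas and filters as tested, scriptable
functions rather than vendor-software recipes.

## What it computes

**Image assays** (per field, aggregated to wells):

- *Two-color fusion index* — nuclei > 50 µm², fluorophore regions
  > 100 µm² eroded by 5 px, per-nucleus percentage overlap, then

  ```
  fusion index = #nuclei(>90% mCh AND >90% GFP) / #nuclei(>70% mCh OR >70% GFP)
  ```

- *Split-GFP fused area* — GFP⁺ area fraction normalized by the field's
  DAPI fraction relative to the replicate mean.
- *Lysosomal metrics* — LoG-detected puncta and absolute-thresholded
  lysosomal area, each per nucleus.
- *Nuclear area* — mean over selected nuclei, border objects excluded.
- *N/C ratio* — (nuclear − background) / (cytoplasmic − background) mean
  reporter intensity, background = pixels below a 200-count cutoff.

**SPT workflow**: mixed-Brownian simulation (localization error,
geometric photobleaching, continuous-time focal-slab defocalization),
log-likelihood-ratio spot detection, damped-least-squares subpixel
Gaussian localization, conservative mutual-nearest-neighbour linking,
nuclear masking, and Bayesian state-array inference over a 100-point
log-spaced grid of diffusion coefficients with the exact
regular-Brownian-motion-with-error (RBME) tridiagonal likelihood and a
defocalization debias. The **bound fraction** is the posterior occupancy
at D < 0.1 µm²/s.

## Worked example

Fusion quantification on a synthetic field whose truth is known:

```r
library(fusionscope)
spec <- field_spec(n_cells = 40, fused_fraction = 0.5, seed = 5)
fld  <- generate_two_color_field(spec)
res  <- end_to_end_two_color(fld$image)
res$index
#> [1] 0.5
#> attr(,"n_fused")        20
#> attr(,"n_fluorescent")  40
```

Half the 40 nuclei belong to dual-labelled syncytia, and the pipeline's
index is 0.5: 20 of the 40 fluorescent nuclei exceed 90% overlap with
both eroded fluorophore regions.

Diffusion-spectrum inference across the study's dynamic range
(`analysis/05_diffusion_spectra.R`) simulates 20,000 molecules per
two-state preset (immobile D = 0.01, free D = 2.5 µm²/s) and prints:

```
      preset immobile_truth bound_fraction n_trajectories n_jumps
    nls_like         0.0894          0.102           8890   25128
   dmso_like         0.1855          0.213           9296   30815
 fsk24h_like         0.4248          0.450          10693   46488
 fsk48h_like         0.6228          0.642          11988   58902
    h2b_like         0.8499          0.856          13599   74045
max |error|: 0.027; ordering preserved: TRUE
```

Each preset's bound fraction lands within 3 percentage points of its
simulated truth and the five conditions stay strictly ordered — the
property the biological comparison rests on.

The `analysis/` directory holds the numbered drivers
(`01_simulate_fields.R` … `06_subsample_stability.R`); each is a thin
narrative script over the package functions that writes its tables under
`results/`.

## Layout

```
R/                  package code (generators, imaging core, fusion metrics,
                    organelle metrics, SPT tracking + inference, config/IO)
analysis/           numbered analysis drivers writing results/
scripts/acceptance.R
tests/testthat/     unit, property and end-to-end suites
vignettes/          methods vignette (model, assumptions, design choices)
```
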