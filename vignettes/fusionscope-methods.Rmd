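---
title: "Methods: quantifying trophoblast fusion and TFEB single-molecule dynamics"
author: "fusionscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying trophoblast fusion and TFEB single-molecule dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fusionscope` reimplements, as tested and reusable R code, the
quantification machinery of a high-content study of syncytiotrophoblast
formation: BeWo trophoblasts fuse into multinucleated syncytia under
cAMP stimulation, and the transcription factor TFEB relocalizes to the
nucleus and engages chromatin during differentiation. Two workflows are
covered:

1. **Image assays** — two-color fusion index, split-GFP fused-area,
   lysosomal puncta and area, nuclear area, and background-corrected
   nuclear/cytoplasmic (N/C) reporter ratios, each with the published
   filters and formulas.
2. **Single-particle tracking (SPT)** — simulation of mixed Brownian
   populations under stroboscopic acquisition, spot detection and subpixel
   localization, conservative trajectory linking, nuclear masking, and
   Bayesian state-array inference of the diffusion-coefficient spectrum,
   from which the chromatin-**bound fraction** (posterior occupancy at
   D < 0.1 um^2/s) is read out.

No instrument data ship with the package. A synthetic-data module renders
ground-truthed fields and trajectory datasets so that every stage is
verifiable end to end; what that does and does not establish about real
data is discussed at the end.

# Image assays

## Two-color fusion index

Two cocultured populations express GFP or mCherry; fusion produces
syncytia whose shared cytoplasm carries both fluorophores. Per field:
nuclei are segmented from the Hoechst channel and filtered at
> 50 um^2 (debris), GFP^+^ and mCherry^+^ regions are thresholded with a
100 um^2 minimum area, both region masks are eroded by 5 one-pixel steps
(suppressing spurious double-positivity at apposed cell boundaries), and
each nucleus receives a pixel-based percentage overlap against each
channel's region mask. The index is

$$\mathrm{fusion\ index} =
\frac{\#\,\mathrm{nuclei}\;(>90\%\ \mathrm{mCh}\ \mathrm{AND}\ >90\%\ \mathrm{GFP})}
     {\#\,\mathrm{nuclei}\;(>70\%\ \mathrm{mCh}\ \mathrm{OR}\ >70\%\ \mathrm{GFP})},$$

with strict inequalities at both thresholds. Double-positive nuclei
satisfy the OR rule and are counted in the denominator. A field with no
fluorescent nuclei returns 0 and is flagged (`empty_denominator`) rather
than dropped, so well means stay defined. Wells are the arithmetic mean
over their fields.

```{r}
library(fusionscope)
fld <- generate_two_color_field(field_spec(n_cells = 40, fused_fraction = 0.5))
res <- end_to_end_two_color(fld$image)
res$index
```

Overlap is evaluated against the union mask per channel; whether the
source instrument distinguishes regions from different cells is not
published, and on well-separated synthetic fields the two readings agree.
Nuclei are filtered by area *before* overlap scoring, following the order
in which the steps are described.

## Split-GFP fused area

GFP fluorescence is reconstituted only where the two non-fluorescent GFP
halves meet in a shared cytoplasm. The GFP channel is smoothed with a
2-pixel Gaussian, GFP^+^ regions are thresholded with the 100 um^2 area
filter, and the GFP area fraction is normalized by the field's DAPI area
fraction divided by the biological-replicate mean DAPI fraction — a
plating-density correction that leaves the metric invariant to uniform
rescaling of all areas.

## Lysosome, nuclear-area and N/C readouts

* **Lysosomes**: puncta are detected (see below) and the lysosomal region
  is thresholded at an absolute intensity (default 1000 counts on the
  package's intensity convention, configurable); both are divided by the
  field's nucleus count. A single middle focal plane is the intended
  input, since lysosomes move during slow z-stacks.
* **Nuclear area**: mean area over selected nuclei, border objects
  excluded, > 50 um^2 filter applied.
* **N/C ratio**: per cell,
  $(\bar I_\mathrm{nuc} - \bar I_\mathrm{bkgd}) /
   (\bar I_\mathrm{cyto} - \bar I_\mathrm{bkgd})$,
  where the background region is every field pixel strictly below the
  intensity cutoff (default 200 counts). The subtraction cancels any
  constant offset added to the foreground. Cells whose cytoplasmic mean
  does not exceed the background, or whose ring is clipped below 20
  pixels, are excluded with a recorded reason. If no pixel falls below
  the cutoff the background is 0 with a warning (never encountered on
  realistic data).

## Substitutions for proprietary steps

The source instrument's segmentation routines ("find nuclei method C",
"find spots method D", "find surrounding region method A") are
unpublished. Open, testable substitutes preserve the published filters
exactly:

* **Nuclei**: Gaussian smoothing (sigma 2 px), automatic histogram
  threshold (Otsu by default; the ImageJ-style *minimum* method is
  available), hole filling, distance-transform watershed to split
  touching nuclei, then the 50 um^2 and border filters.
* **Spots**: scale-normalized Laplacian-of-Gaussian blob detection at the
  configured punctum radius, local maxima above an absolute response
  floor, greedy non-maximum suppression within two radii, parabolic
  subpixel refinement.
* **Surrounding region**: a fixed-width dilation annulus (default 10 px;
  none is published) clipped at the equidistant boundary between
  neighbouring nuclei (Voronoi propagation), disjoint from all nuclei and
  from other rings.

Two package-level conventions: component labeling and binary erosion are
4-connected throughout (the labeling convention of the underlying image
library; immaterial for the well-separated objects these assays measure),
and pixel indices are 1-based with pixel *j* centred at *j* − 0.5 pixel
units, the native R convention. Physical coordinates are in micrometres.
A 2-px guard band (nucleus erosion plus ring gap) is excluded from both
compartments of the N/C measurement to avoid segmentation edge mixing —
a design choice made where the source pipeline's region definitions are
unpublished; it is what makes zero-noise recovery exact.

Flat-field and bright-field corrections are out of scope
(instrument-specific); the generators render flat illumination.

# Synthetic fields

`field_spec()` describes plating density, the fraction of nuclei in
syncytia, the expected syncytium size, intensity gains, background and
noise. Cells are laid out as cytoplasm discs on a jittered grid with
guaranteed separation, so segmentation correctness is testable
independently of clumping; nuclei are ellipses with >= 2 px separation
inside each disc. Intensities are arbitrary 16-bit-like counts
(background 100, foreground ~2500-3000) so the 200-count background
cutoff is meaningful; the default additive noise (sd 50) emulates a
modest camera noise floor and exact-truth tests set it to 0. Cell and
nucleus size distributions for BeWo are not published; the defaults
(nuclear semi-axes 6-10 px at 0.6 um/px, i.e. ~55-90 um^2) are stated
assumptions and configurable.

What the generator does **not** emulate: optical aberrations, channel
bleed-through, EMCCD gain statistics, illumination gradients, clumped or
overlapping nuclei (a stress mode exists via the layout parameters but is
not the default), 3D stacks. Passing tests therefore establish the
*formulas and filters* are implemented correctly and recover truth under
controlled imaging, not that segmentation is robust to every real-world
artefact.

# Single-particle tracking

## Acquisition model and simulation

Defaults mirror the study's stroboscopic HILO configuration: 160 nm
pixels, 7.48 ms frames, 8,000 frames per cell, 150 x 150 px ROI centred
on a nucleus, 0.7 um focal slab. Tracking starts at frame 100;
trajectories beginning before frame 1000 are excluded from inference
(photoactivation density is highest early in the movie).

`simulate_trajectories()` draws one diffusive state per molecule from the
mixture occupancies (the state-array model assumption; within-track
switching exists behind a flag for robustness experiments only), then:

* 2D Brownian steps with per-coordinate variance $2D\Delta t$;
* independent localization error sigma per coordinate per frame
  (default 0.035 um);
* geometric photobleaching with configurable mean lifetime;
* an axial coordinate started uniformly inside the slab and absorbed in
  continuous time — a step is lost if an endpoint leaves the slab *or*
  the Brownian bridge between in-slab endpoints crosses a boundary within
  the frame (crossing probability
  $e^{-2 z_k z_{k+1} / s^2} + e^{-2 (L - z_k)(L - z_{k+1}) / s^2}$).

Continuous-time absorption matters: checking only at frame boundaries
would overestimate slab survival (0.78 vs 0.56 for D = 2.5 um^2/s at one
frame) and desynchronize the simulation from the defocalization
correction below. Motion blur is neglected as a modeling choice: the
excitation pulse is 1 ms in a 7 ms frame, so within-frame motion
contributes little to the apparent spot shape.

## Detection, localization, linking, masking

* **Detection** is a generalized log-likelihood-ratio test of a Gaussian
  spot (kernel sd 1.2 px) versus flat background in each 15 px window,
  thresholded at 18; on blank Poisson frames the false-positive rate is
  below 10^-3 per frame.
* **Localization** fits an integrated 2D Gaussian of fixed width 1 px
  plus background by damped (0.3), ridge-regularized (10^-3) Gauss-Newton
  in a 9 px window, at most 20 iterations; non-converged, out-of-window
  or nonpositive-intensity fits are flagged and dropped.
* **Linking** is deliberately conservative: consecutive frames only
  (no blink gaps), 1.0 um search radius, and a link is made only when the
  correspondence is *mutually unambiguous* — exactly one candidate within
  radius of the track head, and exactly one head within radius of the
  candidate. Any ambiguity terminates the affected trajectories. Frames
  with more than 7 localizations are excluded from linking entirely,
  which is how the density cap is interpreted here (the source package's
  exact rule is unpublished; the interpretation is configurable and the
  linker is tested against an exhaustive optimal-assignment oracle on
  sparse movies, where the two coincide).
* **Nuclear masks** follow the published recipe: Gaussian blur sigma 2,
  minimum-method histogram threshold, hole filling, two binary erosions,
  with automatic polarity inversion when the mask covers over half the
  frame (cells with predominantly cytoplasmic signal). Only trajectories
  entirely inside the mask are analyzed; one excursion discards the whole
  trajectory.

## RBME likelihood and the state array

For a trajectory with jumps $v_1, \dots, v_n$ per coordinate, regular
Brownian motion with localization error gives a zero-mean Gaussian jump
vector with tridiagonal covariance

$$\Sigma = \begin{pmatrix}
2D\Delta t + 2\sigma^2 & -\sigma^2 & \\
-\sigma^2 & 2D\Delta t + 2\sigma^2 & \ddots \\
 & \ddots & \ddots
\end{pmatrix},$$

because successive jumps share one noisy endpoint. The density is
evaluated exactly by the tridiagonal LDL factorization (O(n) per
trajectory per state, shared across all trajectories of equal length); x
and y contribute independently. The suite verifies equality with a dense
Cholesky evaluation to 10^-8 and the sigma = 0 independent-jump limit to
10^-10.

The state array is a fixed log-spaced grid of 100 diffusion coefficients
over [10^-2, 10^2] um^2/s (the reference inference tool does not publish
its grid; this one is stated and configurable). Occupancies come from the
iterative responsibility update

$$r_{ij} \propto \tau_j L_{ij}, \qquad
\tau_j \leftarrow \frac{\alpha - 1 + \sum_i r_{ij}}
                        {\sum_j (\alpha - 1 + \sum_i r_{ij})},$$

with a uniform Dirichlet prior (alpha = 1), run to an L1 change below
10^-6 or 250 iterations. At most `max_sample` trajectories (default
10^6) enter the posterior, drawn uniformly with a seed.

**Defocalization correction.** Fast molecules leave the focal slab and
are underrepresented among observed trajectories. The survival
probability of Brownian z from a uniform start in an absorbing slab of
depth L through time t is the odd-term eigenseries

$$S(t) = \sum_{k\ \mathrm{odd}} \frac{8}{k^2\pi^2}
         e^{-k^2 \pi^2 D t / L^2},$$

truncated when terms fall below 10^-10 (`defocalization_weights()`
exposes it for any track length). Since a trajectory is observed at all
iff its z survives the first frame interval, final occupancies are
divided by $S(\Delta t)$ per state and renormalized. On two-state
mixtures this removes most of the ~10-point naive deficit in the fast
state's occupancy; a residual bias of ~2 points remains because longer
(slower) trajectories carry sharper likelihoods.

**Localization error is treated as known** (default 0.035 um) rather
than jointly inferred: the study does not report how sigma was handled,
and fixing it keeps the estimator identifiable at the simulation scales
used here. The `loc_error_um` field of `state_grid()` is the single knob.

The **bound fraction** sums occupancy at grid states strictly below
0.1 um^2/s. `subsample_stability()` reruns the inference on a seeded
uniform subsample of the analyzed trajectories (default 20,000) and
reports the absolute bound-fraction difference in percentage points —
the control showing that unequal trajectory counts across conditions do
not bias comparisons.

# Numerical choices and degenerate inputs

* Histogram thresholds use 256 bins on the observed range; a constant
  image yields no threshold (empty mask, warning where user-facing).
* The minimum-method threshold smooths the histogram with a running mean
  of 3 until exactly two modes remain; non-bimodal images return `NA`.
* Erosion uses the 4-connected plus-shaped element; 0 iterations is the
  identity; erosion is anti-extensive and idempotent at its fixed point.
* Blob detection clamps subpixel offsets to half a pixel and suppresses
  the 1-px frame affected by circular convolution padding.
* Empty trajectory sets, gapped frames and non-finite coordinates are
  errors; single-localization trajectories carry no jumps and are
  excluded from inference.
* All randomness flows through explicit integer seeds; generators are
  bit-reproducible given (spec, seed).

# Problem sizes used by tests and scripts

The suite and the analysis scripts run at sizes chosen to give tight
Monte-Carlo error on a single CPU: ~60,000 trajectories for the
subsampling-stability control (the study's scale), 20,000 per two-state
preset across immobile shares {9, 19, 42, 62, 85}%, 5,000 per
single-state recovery point across D in {0.01, 0.1, 1, 10} um^2/s, and
fields of 40-60 nuclei for the image assays. The goodness-of-fit check of
the bleaching law uses a chi-squared test (the geometric distribution is
discrete, where a KS null is inappropriate) at alpha = 0.01 on 10^4
tracks.

# Known limitations

* The fusion-index pipeline assumes the union-mask overlap reading and
  filter-then-overlap order noted above; both are stated, not published.
* The state array infers static mixtures; within-track state switching
  (HMM-style) is out of scope, and the simulator's switching mode exists
  only to probe robustness.
* Defocalization debias uses the one-frame survival weight; per-length
  reweighting is exposed but not applied by default.
* The synthetic data's idealizations (flat illumination, separated cells,
  known sigma) mean quantitative agreement on real instrument data still
  depends on instrument-specific calibration of thresholds and sigma.
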