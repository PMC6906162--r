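---
title: "Vessel distance analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel distance analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Solid tumors develop oxygen gradients because oxygen diffuses out of
perfused capillaries while cells consume it: pO~2~ falls with distance from
a vessel, cells become hypoxic, and beyond the diffusion limit — typically
on the order of 150 µm — tissue becomes necrotic. Multiplexed
immunofluorescence can image this microanatomy directly: a nuclear
counterstain (DAPI) for segmentation, CD31 for all endothelium, an
intravenously injected Hoechst bolus that labels only tissue around vessels
that were actually perfused at excision, EF5 whose adducts accumulate in
viable cells at low pO~2~, and EdU marking S-phase (proliferating) cells.

Vessel distance analysis (VDA) turns those images into quantitative
gradients: every segmented cell gets its marker intensities and its
Euclidean distances to the nearest perfused region, to the nearest vessel of
any kind, and to necrosis; cells are then aggregated in uniform distance
bins. Distance to perfused vessels reads chronic (diffusion-limited)
hypoxia; distance to all vessels mixes chronic and acute components;
distance to necrosis approaches the same gradient from the other side.
`vesseldist` implements this pipeline end to end, together with a synthetic
tumor phantom whose oxygen physics are known exactly, so that every stage
can be validated against ground truth without slide data.

## The phantom

### Oxygen model

The phantom solves the steady-state diffusion–consumption equation on the
section plane:

$$ D\,\nabla^2 p \;=\; \frac{M\,p}{p + k_m}, $$

with Dirichlet condition $p = p_v$ on perfused vessel lumens, a zero-flux
outer boundary, and $p$ clamped to $[0, p_v]$. Michaelis–Menten consumption
is used rather than constant consumption: it recovers the classical
Krogh-type profile in the limit $k_m \to 0$ while keeping oxygen
non-negative and making the approach to anoxia smooth rather than a hard
kink. Non-perfused vessels contribute CD31 signal but are not oxygen
sources and carry no Hoechst halo — this is precisely what makes the
perfused-vs-all-vessel analyses distinguishable on phantoms.

The solver is red–black successive over-relaxation (ω = 1.85) with the
consumption term lagged in the local solve, which preserves positivity.
Convergence is declared when the largest pointwise relaxation residual at
non-source pixels falls below `tol` = 10⁻⁴ mmHg; `oxygen_residual()` lets
tests assert this directly. Large grids are initialized from a solution at
half resolution (recursively), which cuts sweep counts by roughly an order
of magnitude without changing the fixed point. The unit tests compare the
2-D solver against an independent 1-D radial shooting solution of the same
equation; agreement is checked relative to the vessel-wall pO~2~ (the
dynamic range of the field), since pointwise relative error is dominated by
lumen rasterization where the field itself approaches zero.

### Default physics and geometry

Defaults describe a 1.024 × 1.024 mm section at 1 µm/px:

| parameter | default | meaning |
|---|---|---|
| `D` | 2000 µm²/s | oxygen diffusion coefficient in tissue |
| `M` | 2.75 mmHg/s | maximal consumption; with `D`, `p_v` this places anoxia ≈ 150 µm from a perfused vessel (closed-form Krogh estimate, verified on the solved field) |
| `k_m` | 1 mmHg | Michaelis constant; small relative to `p_v` |
| `p_v` | 40 mmHg | vessel-wall pO~2~ |
| `p_nec` | 0.5 mmHg | necrosis threshold |
| vessels | 14, ≥ 150 µm apart, radii 8–15 µm, 50 % perfused | keeps necrotic area below half the section while leaving distinct perfused/non-perfused populations |
| cells | 4000 /mm² over habitable tissue, ≥ 8 µm apart | a realistic nuclear density at which plateau-profile nuclei of radius 3.5 µm remain individually resolvable |

### Marker responses

EF5 intensity follows a decreasing Hill curve
$A\,K_h^h / (K_h^h + p^h)$ with $K_h$ = 10 mmHg and $h$ = 2, zeroed inside
necrosis because adduct formation requires viable cells; the EdU-positive
probability is the saturating $e_{max}\,p/(p + K_p)$ with $e_{max}$ = 0.6
and $K_p$ = 5 mmHg, and each cell's proliferation state is an independent
Bernoulli draw. These functional forms are deliberate stand-ins: no
quantitative EF5-vs-pO~2~ binding curve is established, so the parameters
here are plumbing for a monotone, saturating response — not biological
claims — and none of the package's validation depends on their exact
values, only on their monotonicity.

Rendering: nuclei are super-Gaussian plateaus (`exp(-(d²/r²)⁴)`, r =
3.5 µm) rather than Gaussians so the thresholded nuclear area is
insensitive to the exact threshold, as real counterstained nuclei are; EF5
is painted as cytoplasmic disks (r = 7 µm) carrying the field value at the
cell center; CD31 as annular vessel walls; Hoechst as an exponential halo
(decay 15 µm) of distance to perfused lumens only. All channels share an
additive background (5 a.u.) plus optional Gaussian read noise clipped at
zero, in an 8-bit-like 0–255 range.

### What the phantom does and does not emulate

It emulates: perfused and non-perfused vessels, a radially decaying oxygen
field with realistic length scale, hypoxia marker intensity rising as
oxygen falls, proliferation falling with vessel distance, and necrosis
beyond the hypoxic rim. It does not emulate vascular network topology,
time-varying (cycling/acute) occlusion, 3-D diffusion, optical PSF blur, or
staining artifacts. Tests passing on phantoms therefore demonstrate the
correctness of the measurement machinery — segmentation, distances,
binning, gating — under known physics; they do not certify performance on
real slides, where registration error, autofluorescence, and
section-to-section variation add failure modes the phantom deliberately
omits.

## Segmentation

Nuclei: Gaussian smoothing (σ = 1 µm), thresholding (explicit value or Otsu
on the smoothed channel — explicit always wins, since operator-chosen
thresholds are the norm in tissue cytometry), then a watershed on the exact
Euclidean distance transform with seed maxima at least 4 µm apart to split
touching nuclei. Components are 4-connected throughout. The area filters
are strict by the printed conventions: nuclei *smaller than* 23 µm² are
excluded (exactly 23 µm² is kept) and only vessels *strictly larger than*
5 µm² are kept (exactly 5 µm² is dropped); adversarial fixtures at
20/23/26 and 4/5/6 µm² pin this down.

Cell bodies are simulated, in the absence of a membrane marker, by growing
each nucleus outward by 5 µm. Growth is Euclidean and constrained:
contested pixels go to the nucleus whose nearest pixel is closest, exact
ties to the lower label id, so cells partition the dilated union with no
double counting. A blank image yields zero objects, not an error.

Accuracy is validated by centroid counts in random 350 × 350 µm tiles
against phantom truth (percent error per tile, tiles without truth objects
excluded), mirroring how segmentation is audited manually on real slides.

## Regions, distances, and the per-cell table

The ROI map partitions every pixel into background / viable / hypoxia /
necrosis / perfusion / artifact by explicit rules: tissue = smoothed DAPI
above `t_tissue`; perfusion = Hoechst above `t_hoechst`; hypoxia = smoothed
EF5 above `t_ef5`; precedence artifact > necrosis > perfusion > hypoxia >
viable. Necrosis and artifact come from supplied masks (phantom truth, or a
user's annotation of an H&E section) and are passed through unchanged; a
trainable classifier is out of scope, so the rule-based map *is* the
specification on phantoms. Threshold-derived regions smaller than 10 µm²
are merged into the neighboring threshold-derived class (never into the
mask-derived ones, which would break passthrough). The default
`t_ef5` = 30 a.u. corresponds to roughly half the EF5 amplitude after
accounting for the fraction of tissue area the cytoplasmic disks cover, so
the hypoxia ROI onset tracks the EF5 half-max oxygen level.

Distance maps use an exact Euclidean distance transform
(Felzenszwalb–Huttenlocher two-pass lower envelope, implemented in C++),
reported in micrometers from pixel center to nearest target pixel center.
Exactness matters: tests compare against brute-force nearest-target search
bit for bit, and the 1-Lipschitz and target-monotonicity properties are
asserted on random masks. Distances are measured to the vessel *mask*
rather than to vessel center points — center-point distance penalizes large
lumens — and per-cell distances are sampled at the nucleus centroid (the
tabulation granularity of the per-cell table) rather than minimized over
the footprint; both choices are cheap, deterministic, and documented here
because the opposite conventions are defensible too. The three layers are
distance to the perfusion ROI united with perfused-vessel pixels, to all
vessel pixels, and to the necrosis class; an absent target (a tumor without
necrosis) yields an absent layer, not an error, and downstream statistics
use only cells inside the viable, hypoxia, and perfusion regions.

## MAD and CC positivity

Both classifiers share one ordered threshold set (negative/low/medium/high)
with half-open intervals — a value exactly on a boundary promotes upward,
a convention that had to be fixed arbitrarily. Marker Area Detection (MAD)
classifies pixels and reports area fractions, after reassigning connected
supra-threshold regions smaller than 10 µm² to negative; the filter applies
once to the union of positive pixels, not per class. Cellular
Classification (CC) applies the same intervals to the mean intensity over
each simulated cell. Because cytoplasmic staining is graded, a cell's mean
can clear the first threshold while most of its pixels do not, so CC
systematically scores higher positivity than MAD on gradient markers —
the package asserts the direction of this disagreement on constructed
fixtures, not any particular fold-change, which is data-dependent.

## Distance-binned statistics and gating

`bin_cells()` uses half-open uniform bins `[kw, (k+1)w)` to a 700 µm limit
(cells at exactly the limit are excluded), emitting empty bins so tables
align across samples; SEM is sd/√n and reported as missing for n < 2 rather
than zero. Doubling the bin width must equal pooling adjacent bins — an
exact bookkeeping identity the tests enforce. Ring composition applies the
same binning to ROI area fractions around the perfusion target, with
perfusion in the denominator but not the numerators; `peak_distance()`
takes the maximizing ring center with ties to the smallest distance.
Gradient slopes are finite differences of per-bin means between two
distances: against vessels they read oxygen consumption, against necrosis
hypoxia tolerance, and on paired phantoms doubling the consumption rate
must strictly steepen the EF5-vs-perfused slope.

Scatter gates are drawn at mean + 1 SD per marker, on `log10(x + 1)`
intensities by default because the scatterplots themselves are log-scaled;
whether the gate belongs on the log or linear scale is genuinely
undetermined, so both are supported behind a flag. Population distance
differences (each positive quadrant vs the double-negative population) use
a two-sided permutation test with the add-one correction
`p = (1 + #{|Δperm| ≥ |Δobs|}) / (1 + n_perm)`: it assumes only
exchangeability, which suits tissue-cytometry data with unknown intensity
distributions. Calibration is tested two ways: the Gaussian tail of the
gate (Φ(−1) ≈ 15.87 %) and the type-I error of the permutation test over
200 null replicates.

For the monotone-trend checks on the default phantom the acceptance suite
aggregates at 50 µm bins rather than 10 µm: proliferation is a Bernoulli
outcome, so per-bin positive fractions carry sampling noise of order
1/√n per bin, and 50 µm is the width at which that noise is comfortably
below the gradient signal for the default cell density. The 10 µm bins
remain the analysis default; the coarse bins are a property of the test,
chosen once from the binomial error budget.

## Registration utilities

Control-point alignment uses the closed-form least-squares similarity fit
(rotation, isotropic scale, translation — no shear), solved in the complex
plane; noise-free correspondences are recovered to machine precision and
noisy fits are cross-checked against an independent grid-refinement
minimizer. Image warping is inverse-mapped resampling with nearest or
bilinear interpolation and zero fill outside the frame; the identity
transform with nearest interpolation returns the input bit for bit.
Intensity-based automatic registration is deliberately not implemented:
phantoms are born aligned, and for real multi-round data the control-point
path covers the documented fallback without pulling an optimizer choice
into scope.

## Numerical conventions

* Coordinates: 0-based pixel indices, x = column, y = row, origin top-left;
  physical position of a pixel is `(index + 0.5) × pixel_size_um`.
* Connectivity: 4-connected components everywhere.
* All randomness flows through explicit integer seeds; `make_phantom()` and
  `run_pipeline()` derive per-stage sub-seeds from the master seed, so a
  repeated run is byte-identical including rendered noise.
* Float TIFFs are stored in `[0, 1]` with the physical scale in a JSON
  sidecar; integer TIFFs round-trip exactly at 8 and 16 bits.
* Test problem sizes: the shared validation phantom is the full default
  (1024² px, ~2000 analyzed cells); solver-vs-oracle comparison runs at
  512² with a single centered vessel; paired-consumption replicates run at
  320² so ten seed pairs stay inexpensive.

## Known limitations

The phantom's marker responses are monotone stand-ins, not calibrated
binding curves; absolute intensities and fold-changes on phantoms carry no
biological meaning. The 2-D physics ignores out-of-plane supply, so the
anoxia distance is a calibrated emergent property, not a prediction.
Rule-based ROI classification approximates what was originally an
operator-trained, manually corrected step; on real data the thresholds are
operator inputs, and results inherit that subjectivity. The pipeline
assumes pre-registered channels; only the control-point similarity path is
provided for multi-round alignment.
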