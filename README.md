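# vesseldist

Vessel distance analysis (VDA) of hypoxia and proliferation gradients in
multiplexed immunofluorescence tissue sections.

Solid tumors oxygenate from their perfused capillaries outward: pO₂ falls
with distance from a vessel as cells consume oxygen, cells become hypoxic,
and beyond the diffusion limit (~150 µm) tissue turns necrotic. Because
hypoxia is a *gradient*, a single positive-area threshold misrepresents it.
VDA instead measures marker signal as a function of distance to
biologically meaningful structures: for every segmented cell, its mean
intensity of each stain (DAPI, Hoechst, CD31, EF5, EdU) and its Euclidean
distances to the nearest perfused region, to all vessels, and to necrosis,
aggregated in uniform distance bins

- mean intensity per bin ± SEM and percent gate-positive per bin,
- ROI composition (viable / hypoxia / necrosis fractions) in concentric
  rings around the perfusion region,
- gradient slopes Δintensity/Δdistance (consumption against vessels,
  hypoxia tolerance against necrosis),
- flow-cytometry-style per-cell scatterplots with mean + 1 SD gates and
  permutation tests on gated-population vessel distances.

The package is aimed at image-analysis and tumor-microenvironment
researchers who have co-registered single-channel images (or who want a
fully synthetic test bed). It includes a tumor **phantom generator** that
solves the steady-state oxygen diffusion–consumption equation
`D ∇²p = M p/(p + k_m)` around perfused vessels (Dirichlet `p = p_v` on
lumens, zero-flux boundary), derives EF5/EdU responses from the oxygen
field, samples cells, and renders all five channels with known ground
truth — so segmentation, distance maps, binning, and gating are all
testable against exact answers.

## Worked example

```r
library(vesseldist)

cfg <- default_config()
cfg$grid <- list(width_px = 512L, height_px = 512L)
cfg$vessels$n_vessels <- 4L

res <- run_pipeline(cfg, seed = 42)
str(res$summary)
#> List of 8
#>  $ seed                 : num 42
#>  $ n_nuclei             : int 581
#>  $ n_vessels            : int 4
#>  $ n_perfused_vessels   : int 2
#>  $ n_cells_analyzed     : int 581
#>  $ mad_positive_fraction: num 0.582
#>  $ cc_positive_fraction : num 0.943
#>  $ hypoxia_peak_um      : num 145
```

581 cells were segmented and analyzed around 4 vessels (2 perfused). The
pixel-level positivity (MAD, 58 %) undershoots the cell-level positivity
(CC, 94 %) because cytoplasmic EF5 staining is graded — a cell's mean
intensity clears the first threshold while most of its pixels do not. The
hypoxia ROI fraction peaks 145 µm from the perfusion region, between the
EF5 half-max oxygen radius and the anoxia radius of this phantom.

```r
b <- bin_cells(res$analyzed, "perfused", bin_width_um = 50, d_max_um = 400)
subset(b, n_cells > 0,
       select = c(d_lo, d_hi, n_cells, mean_EF5, sem_EF5, pct_pos_EdU))
#>   d_lo d_hi n_cells mean_EF5 sem_EF5 pct_pos_EdU
#> 1    0   50     141     32.4   1.035       0.518
#> 2   50  100     205     65.7   0.971       0.371
#> 3  100  150     179     90.4   0.917       0.235
#> 4  150  200      56     97.2   1.255       0.107
```

Mean EF5 rises and EdU positivity falls with distance from perfused
vessels — the chronic-hypoxia gradient, read per cell.

```r
res$gates
#> <gate_result> gates (log scale): EF5=2.012, EdU=1.509
#>   population   n mean_dist_perfused_um     delta           p
#> 1    double- 344              91.15880        NA          NA
#> 2    double+  10             125.57422  34.41542 0.018981019
#> 3       EdU+ 187              65.77941 -25.37940 0.000999001
#> 4       EF5+  40             144.41859  53.25979 0.000999001
```

EF5-positive cells sit on average 53 µm farther from perfused vessels than
double-negative cells, EdU-positive cells 25 µm closer; both permutation
p-values are at the resolution floor of 1000 permutations.

A thin command-line front end is included at `inst/cli/vda.R`
(`simulate`, `run`, `segment`, `register-points` subcommands).

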