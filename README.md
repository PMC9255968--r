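# podonano

Quantitative image analysis of the **osteoclast sealing zone** — the
podosome-based actin superstructure with which osteoclasts seal the bone
resorption compartment. Super-resolution imaging resolves the sealing zone
into densely packed **actin cores** (~100 nm radius, neighbors 400–700 nm
apart) grouped into **islets** bordered by adhesion complexes, whose actin
content oscillates in local synchrony. `podonano` implements the full
measurement chain for characterizing that organization, for microscopists
and image analysts working with reconstructed super-resolution frames,
time-lapse stacks and 3D single-molecule localization tables:

- **Detection** — actin cores as prominent local maxima with
  intensity-weighted centroids; core radii from the first maximum of
  gradient-magnitude (Sobel) radial profiles traced in 8 directions
  (1 µm × 100 nm, sub-pixel parabolic refinement):
  `r = mean over directions of argmax_d |∇I|(d)`.
- **Morphometry** — Delaunay tessellation over core centroids with
  convex-hull edge exclusion; per-vertex mean *direct-neighbor* distances
  and minimum *nearest-neighbor* distances, pooled distributions and
  medians.
- **Dynamics** — histogram-matching bleach correction, per-core signals in
  100 nm discs, zero-lag Pearson synchrony vs pair distance with half-decay
  length, Fourier spectra with median-relative peak detection
  (`|X(f)| > k · median|X|`), signed rate-of-change movies
  (`D_t = I_{t+1} − I_t`), robust-threshold segmentation of coordinated
  growing/decreasing clusters, and kymographs.
- **Profiles / islets** — oriented 1.5 µm two-color line profiles with
  core-width normalization (positions in units of the median edge-estimated
  core radius), per-core actin–marker correlation in 1 µm discs, and islet
  segmentation from adhesion-marker images (Otsu border mask, interior
  components).
- **3D localizations** — signed r–z analysis: 10 µm × 200 nm boxes along
  and transverse to the belt per core, r negative toward the cell exterior,
  variable-width classes (100 nm to ±1 µm, 500 nm beyond), per-cell median
  heights, radial/vertical distributions and an interior/exterior symmetry
  index `(N_int − N_ext)/(N_int + N_ext)`.
- **Synthetic data** — a seeded generator (Matérn-clustered layouts,
  rendered frames/movies with Poisson–Gaussian noise, oscillating signals
  with islet-shared phases, 3D protein clouds with 15 nm precision) with
  exported ground truth, so the entire chain is testable without any
  download.

All lengths are nm, times s, areas µm². See the vignette
(`vignettes/sealing-zone-analysis.Rmd`) for the models, parameter meanings
and validation design.

## Worked example

```r
library(podonano)

lay   <- make_layout(layout_params(seed = 42))   # ground-truth sealing zone
img   <- render_frame(lay)                       # noisy frame, 32.25 nm/px
cores <- analyze_frame(img)                      # detect + estimate radii
g     <- build_graph(cores)                      # Delaunay neighbor graph

nrow(cores)                                  # 90 cores detected (90 true)
median(cores$radius_nm, na.rm = TRUE)        # 81.2 nm
direct_neighbor_stats(g)$pooled_median_nm    # 701 nm
nearest_neighbor_stats(g)$median_nm          # 462 nm

mv  <- simulate_movie(lay, osc_spec(phase_model = "islet_shared"), seed = 42)
sig <- extract_signals(bleach_correct(mv$stack),
                       core_set(data.frame(id = lay$cores$core_id,
                                           x_nm = lay$cores$x_nm,
                                           y_nm = lay$cores$y_nm)))
synchrony_curve(pairwise_synchrony(sig), bin_width_nm = 200)$half_decay_nm
#> 1374 nm    (default islets are 1.7 um across: synchrony decays at islet scale)
natural_frequencies(signal_spectrum(sig$signals[1, ], sig$dt_s))
#> 0.0124 0.0435 0.1493   (planted at 0.01 / 0.04 / 0.15 Hz; 160 s window)
```

The detected radii sit ~20% below the nominal 100 nm because neighbor
overlap on crowded fields shifts the first derivative maximum slightly
inward; neighbor medians (701 / 462 nm) match the generator's spacing, and
the synchrony half-decay tracks the islet diameter.

A thin command-line wrapper is installed with the package
(`inst/exec/podonano`): `podonano run --config run.yaml`,
`podonano detect --image frame.tif --out cores.csv`, etc.

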