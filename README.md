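# ribbonmorph

3D morphometry of afferent ribbon synapses of cochlear inner hair cells
(IHCs) from segmented voxel volumes.

Each IHC drives several auditory nerve fibers through ribbon synapses on
its basolateral pole, and fibers contacting the same cell differ widely in
spontaneous rate and threshold. A long-standing hypothesis ties that
functional diversity to synaptic ultrastructure — ribbon size, the size and
shape of the presynaptic (PD) and postsynaptic (PSD) membrane densities,
vesicle pools, and position along the modiolar–pillar (M–P) axis of the
cell. Testing it requires measuring dozens of synapses in three dimensions
from isotropic volume-EM (FIB-SEM) segmentations and comparing groups with
statistics suited to small, skewed samples. `ribbonmorph` packages that
entire analysis:

- **Morphometry** — per-structure volume (voxel count × spacing³),
  voxel-face surface area (exposed 6-connectivity faces × spacing²),
  longest/shortest **Feret axes through the center of gravity** (not
  constrained to be orthogonal; chord-through-centroid definition for solid
  ribbons, in-plane calipers for sheet-like PDs/PSDs), and the
  ellipse-model area *A = π·L·S/4* for membrane densities.
- **Proximity descriptor** — for the ribbon-facing surface of each PSD, the
  distribution of shortest distances to the ribbon surface, summarized as a
  normalized cumulative curve (Cum. PDF) with median and 15th-percentile
  summaries, plus equal-weight group means across synapses.
- **Position mapping** — synapse anchors (ribbon-union centroids) expressed
  in the *native* tissue frame and the *translated* cell-centric frame
  (per-cell superposition), with modiolar/pillar assignment by the sign of
  the M–P coordinate and gradient tests along either axis.
- **Vesicle pools** — ribbon-associated (≤ 80 nm of the ribbon surface) and
  membrane-associated (≤ 20 nm of the PD) marker counts, full-3D or an
  every-5th-section emulation mode.
- **Statistics** — two-tailed Wilcoxon rank-sum, Spearman's ρ with a
  two-tailed t-test, a Kolmogorov–Smirnov normality screen, and the
  median-based Hedge's *g*:

  *g* = |median₁ − median₂| / *s*\*,  *s*\* = √[((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2)]

- **Synthetic data** — the four geometric model synapses (hemisphere, disk,
  ring, donut: 300 nm spherical ribbon, 84 nm offset from the PSD center,
  1400 nm projected PSD, 250 nm hole) and full multi-IHC scenes with
  programmed size distributions, an age-dependent M–P ribbon-size gradient,
  staggered cells, and vesicle pools — all with constructive ground truth
  for recovery testing.

## Worked example

Build the "disk" model synapse, measure it, and compute its proximity
profile:

```r
library(ribbonmorph)

mp <- make_model_synapse(phantom_spec("disk"))
measure_all(mp$volume, mp$table)[, c("structure", "volume_nm3",
                                     "long_axis_nm", "short_axis_nm",
                                     "ellipse_area_um2")]
#>   structure volume_nm3 long_axis_nm short_axis_nm ellipse_area_um2
#> 1    ribbon   14121996     306.4034      295.1058               NA
#> 2       PSD   21559608    1406.8931     1400.0000          1.54696

prof <- proximity_profiles(mp$volume, mp$table)[[1]]
prof
#> <proximity_profile> synapse 1: n=31428, median=396.1 nm, p15=207.8 nm, range [84.0, 586.4]
```

The ribbon measures 307 × 295 nm — a 300 nm digital sphere measured to one
voxel (7 nm). The PSD's in-plane axes recover its 1400 nm projected
diameter, and the shortest PSD-to-ribbon distance is the constructed 84 nm
gap, rising to ~586 nm at the rim of the flat disk (point-to-sphere closed
form: 588 nm). The hemisphere model, by contrast, concentrates all
distances in a narrow band — the basis of the curve-shape comparison among
the four models.

An effect size from printed group statistics:

```r
hedges_g(0.58, 0.36, 41, 0.31, 0.30, 34)$g
#> [1] 0.8078731
```

A full synthetic study — generate a mature-like scene (3 staggered IHCs, 32
synapses, programmed modiolar > pillar ribbon sizes), run the pipeline, and
test the gradient:

```r
b <- run_pipeline(pipeline_config(scene_spec("p34-like", seed = 42L),
                                  seed = 42L))
axis_gradient(b$per_ribbon$volume_nm3, b$per_ribbon$z_mp_translated)
#>         rho           p
#> -0.38779843  0.02340426
```

The programmed decreasing gradient is recovered in the translated view
(ρ < 0, p < 0.05) and attenuated in the native view, where cell stagger
mixes modiolar and pillar faces of neighboring cells.

## Command line

A thin launcher over the same functions is installed at
`inst/cli/ribbonmorph`:

```sh
ribbonmorph phantom --kind donut --out out/
ribbonmorph scene --age p34 --seed 7 --out out/
ribbonmorph measure out/scene.tif out/scene_labels.csv --out morpho.csv
ribbonmorph pipeline --config run.yaml
```

## Documentation

The methods vignette (`vignettes/ribbonmorph-methods.Rmd`) describes the
measurement definitions, the synthetic-data generator and what it does and
does not emulate, numerical choices, and known limitations.
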