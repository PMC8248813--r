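Package: ribbonmorph
Title: Three-Dimensional Morphometry of Cochlear Ribbon Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative 3D analysis of afferent ribbon synapses of cochlear
    inner hair cells from segmented voxel volumes (FIB-SEM label maps).
    Measures ribbon volumes, voxel-face surface areas, and unconstrained
    long/short (Feret) axes through the center of gravity; summarizes
    presynaptic and postsynaptic membrane densities with an ellipse model;
    computes per-synapse distributions of shortest distances from the
    ribbon-facing PSD surface to the ribbon surface (cumulative probability
    curves and percentile summaries); maps synapse positions in native and
    cell-centric translated coordinate frames along the modiolar-pillar and
    habenular-cuticular axes; counts ribbon-associated and
    membrane-associated vesicle pools by distance thresholds; and applies a
    nonparametric statistical battery (Wilcoxon rank-sum, Spearman rank
    correlation, Kolmogorov-Smirnov normality screen, median-based Hedge's g
    with pooled SD). Includes a synthetic-data module that builds four
    geometric model synapses (hemisphere, disk, ring, donut) and full
    multi-cell scenes with programmed morphology distributions, spatial
    gradients, and vesicle pools, together with ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
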