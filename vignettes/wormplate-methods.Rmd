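---
title: "From WormToolbox objects to per-well phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From WormToolbox objects to per-well phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormplate)
```

# The data and the problem

CellProfiler's WormToolbox segments brightfield images of *C. elegans* in
96-well plates using several probabilistic worm models, each calibrated to a
size class (here labelled L1, L2/L3, L4, Adult). Soft matching — fitting all
models to every detected animal so that animals of slightly different sizes
across strains and conditions are still found — is what makes the export
usable across genetic backgrounds, but it produces a one-to-many table: one
*primary object* (real animal) may carry rows for two L1 fits, one L2/L3 fit
and one L4 fit. On top of that, segmentation near the periphery of a
circular well degrades because background correction is uneven there, and
small non-animal debris is picked up by the smallest model.

`wormplate` resolves this table to one reliable row per animal and
summarizes animal length (µm) per experimental unit. Length is the primary
phenotype; any other exported measurement column is carried through and can
be summarized identically (`extra_cols`).

# Model selection

Models are ranked by **dataset-wide frequency**: a small model is fitted
repeatedly to parts of large animals and is therefore the most frequent,
while the largest model can only describe a whole animal and is the least
frequent. Rank 1 is the smallest/most frequent model. Frequency is computed
over all plates read together, not per plate, so that sparse plates do not
reorder the ranking. Exact frequency ties — possible in small datasets — are
broken by ascending mean length per model, length being the direct size
measure that frequency proxies.

Within each (plate, well, primary object) group the largest-ranked model
present is selected. If the selected model occurs more than once in the
group, the object is **cluster-flagged**: repeated assignment of the same
model typically means overlapping animals whose measurements cannot be
trusted. The row retained for a cluster is the selected model's instance
with maximal length. This choice is deliberately conservative: cluster rows
are dropped from processed data by default, so the representative only
affects raw-data views, and the longest instance best approximates the
extent of the underlying animal.

# Flagging

**Well edge.** An object is edge-flagged when the Euclidean distance from
the image center to its selected centroid is *strictly greater* than the
even-illumination radius (default 825 px). The comparison is strict —
boundary points are unflagged — because a flag marks deviation *beyond* the
threshold; with continuous coordinates the choice is immaterial in
practice, but it must be fixed for reproducibility. The center defaults to
half the image dimensions when those are supplied; it is never guessed from
the data, because centroid clouds are biased by where animals happen to
lie.

**Outliers.** Within each well, Tukey's fences
$[Q_1 - k \cdot IQR,\; Q_3 + k \cdot IQR]$ are computed over the lengths of
rows that carry no excluded flag (default: cluster and edge rows are
excluded, since their known-bad measurements would inflate the IQR).
Eligible rows strictly outside the fences are outlier-flagged; excluded
rows keep `flag_outlier = FALSE` because they already carry a flag and
would otherwise be double-counted. The multiplier defaults to the
conventional $k = 1.5$ and is exposed to the user. Quartiles use linear
interpolation between order statistics at position $(n-1)p$ (base R's
default rule, `type = 7`); the fence values depend on this convention, so
it is fixed and shared with the summary quantiles. Wells with fewer than
`min_n = 3` eligible rows are left unflagged — quartiles of one or two
points flag everything or nothing, neither of which is informative.

Per-well fences assume wells are roughly age-synchronized (the standard
bleach-synchronization protocol), so that within-well lengths are unimodal
and debris or mis-segmentations stand out. In genuinely mixed-stage wells
the IQR widens and the outlier screen loses power; that is a property of
the statistic, not a failure mode of the implementation, and users can
instead raise or lower $k$ or pre-split by design factors.

# Pruning and summaries

`process_bundle()` returns four elements — the flag-annotated raw table,
the pruned table, and per-group summaries of both — so that every
downstream view can compare raw and processed data. By default all three
flag families are dropped; a user who excluded a family upstream keeps
those rows. Summaries report n, mean, sample variance ($n-1$ denominator;
reported missing for $n = 1$ rather than zero), min, max, and the 10/25/
50/75/90% quantiles. The quantile set is a package choice: the median and
quartiles describe the bulk, and the 10/90% tails bracket the range without
being order-statistic-noisy in 30-animal wells. Wells whose objects are all
pruned disappear from the processed summary; plate views render them as
empty cells rather than zeros.

# Visualization choices

- Plate views draw the complete 8 × 12 grid row-major A→H, 1→12, so absent
  wells are visible as gaps. The interactive export is a dependency-free
  self-contained HTML/SVG file whose cells carry hover tooltips (well, n,
  mean length).
- Well views place markers at the exact centroid coordinates (no jitter)
  with the y-axis oriented downward to match image convention, so overlays
  can be verified against the table; the edge radius is drawn in red.
  16-bit brightfield TIFFs are contrast-stretched to their 1st–99th
  intensity percentiles for display, since raw 16-bit values render
  near-black.
- Dose panels show one representative well per concentration, ascending.
  The representative is the well whose mean length is closest to the median
  of that dose's well means — the most typical well, robust to a single
  aberrant well per dose.

# The synthetic generator

`generate_plate_set()` emulates the *structure* of a WormToolbox export,
not its optics. Each well draws one developmental stage (synchronized
wells); each animal draws a true length from its stage distribution —
L1 N(250, 25), L2/L3 N(450, 50), L4 N(700, 60), Adult N(1000, 80) µm,
generator fixtures chosen to match the relative scale of larval growth and
configurable throughout. Each animal emits its own stage's model row plus
1–3 rows for every smaller model at 25–65% of its true length (partial
fits), reproducing soft matching; 5% of animals duplicate their selected
model row (clusters, each instance covering 50–90% of the animal); 10% are
placed beyond the 825 px radius with lengths degraded to 30–80% of truth
(edge segmentation failure); debris arrives at 0.1 objects per animal,
N(60, 20) µm under the smallest model. Clean measurements carry 2%
multiplicative noise. One RNG stream per plate is derived from the master
seed so plates can be regenerated independently.

What the simulator does **not** model: optical blur, touching-worm
untangling, stage mixtures within a well, intensity/texture features, or
model-assignment errors (the selected model always equals the true stage's
model for non-cluster animals). Passing the recovery tests therefore shows
that the pipeline's bookkeeping — ranking, selection, flagging, pruning,
summarization — is correct under its stated assumptions, not that
WormToolbox itself segments well. The optional image renderer (dark
elongated shapes on a vignetted bright disc) exists to exercise overlay
plots, with no claim of optical realism.

`evaluate_against_truth()` closes the loop: flag precision/recall per
family, per-well error of raw and processed mean length against the true
animal mean, and model-selection accuracy on unflagged animals. Under the
default rates the processed mean is closer to truth than the raw mean in
essentially every well — the pipeline's purpose, demonstrated by
construction.

# Numerical and degenerate-input choices

- Quantile rule: type-7 interpolation everywhere (fences and summaries).
- Strict inequalities define all three flags; boundary values pass.
- `tukey_fences()` requires ≥ 2 finite values; constant wells yield
  degenerate fences (lower = upper) and flag nothing inside them.
- Ties in the cluster representative (equal maximal lengths) keep the first
  occurrence; ties in model frequency break by mean length.
- Wells named `C3` are normalized to `C03` on input so joins never split on
  dialect; normalization is idempotent.
- Validation fails loudly and names the offending columns, files or wells.

# Problem sizes

The test suite validates fences against an independent sort-and-interpolate
oracle on 1,000 random vectors (n = 4–50) and model selection against
brute-force enumeration on 200 random tables; the end-to-end recovery run
uses 4 plates × 96 wells × 30 animals (≈ 46,000 model-object rows), the
scale of a real multi-plate assay, and completes in seconds.

# Limitations

- Frequency-based ranking assumes the dataset is large and mixed enough
  that small models genuinely outnumber large ones; a dataset of only
  adults imaged with a single model is unaffected, but two models with
  near-equal counts rely on the mean-length tie-break.
- The edge flag models the unevenly illuminated zone as a circle; optical
  vignetting that is not radially symmetric needs a smaller radius or
  upstream correction.
- Only CSV exports are read; cluster-oriented serialized archives from
  other pipelines are out of scope.
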