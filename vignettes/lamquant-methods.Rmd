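---
title: "Methods: lung morphometry and cluster crosstalk in lamquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung morphometry and cluster crosstalk in lamquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamquant)
```

# What the package measures

Diseases that destroy alveolar architecture — emphysema, and the cystic
lung disease lymphangioleiomyomatosis (LAM) — enlarge the distal
airspaces. The standard stereological readout of airspace size on a 2-D
histological section is the **mean linear intercept (MLI)**: lay a grid of
test lines over the section and measure, along each line, the maximal runs
("chords" or "intercepts") of airspace bounded by tissue. The mean chord
length, in micrometres, is the MLI; a larger MLI means larger airspaces.
The complementary measurement on the tissue phase, the mean wall chord
length, serves as the **alveolar septal thickness (AST)**.

`lamquant` implements this measurement as an automated pipeline over
brightfield images, together with a second, independent analysis: directed
**ligand-receptor crosstalk graphs** between single-cell clusters, and the
group-comparison statistics used to report both.

# The morphometry pipeline

`analyze_image()` composes seven deterministic stages:

1. **Load** (`load_grayscale()`): PNG/JPEG/ASCII-PGM to an 8-bit grayscale
   raster; RGB collapses to Rec. 601 luminance
   $Y = 0.299R + 0.587G + 0.114B$. A pixel size in µm/px must be supplied
   by the user — it is metadata the image itself does not carry.
2. **Binarize** (`binarize_otsu()`): the global threshold $t^\*$ maximizes
   the between-class variance
   $\sigma_b^2(t) = w_0(t)\,w_1(t)\,[\mu_0(t)-\mu_1(t)]^2$ over the 256-bin
   histogram; ties break toward the lowest maximizer. Under brightfield
   polarity the bright class is airspace.
3. **Fill capillary lumens** (`fill_lumens()`): alveolar walls contain
   capillary lumina that binarize as small airspace holes and would
   register as spurious short chords. Morphological closing of the wall
   phase (dilation then erosion, disk of radius 3 px by default) fills
   holes up to twice the radius in diameter.
4. **Phase convention**: masks carry the explicit convention airspace = 0,
   wall = 1, which realizes the inversion step of the original procedure
   (airspaces one class, walls the other) without an extra pass.
5. **Line grid** (`make_line_grid()`): 20 horizontal lines (configurable)
   at 0-based rows $\lfloor (i + 0.5)\,H / n \rfloor$ — centred equal
   spacing derived from the vertical image dimension, so no line lies on
   the extreme border rows.
6. **Intercepts** (`measure_intercepts()`): per line, maximal airspace
   runs bounded by wall on both ends are complete chords
   (length = run length × pixel size); runs touching the image border are
   truncated, counted, and excluded by default. Airspace-to-wall
   transitions are tallied as wall intersections; wall chords are measured
   identically on the wall phase.
7. **Statistics** (`compute_mli()`): MLI = arithmetic mean of the complete
   airspace chords; SD with the sample ($n-1$) denominator; dispersion
   index = variance/mean of the chord-length histogram (µm). AST and its
   SD are the same statistics on wall chords.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `pixel_size` | (required) | µm/px | converts run lengths to physical chords |
| `n_lines` | 20 | lines | test-line density of the grid |
| `closing_radius` | 3 | px | fills lumens of diameter ≤ 6 px; must be ≥ the lumen radius and ≪ the wall-free airspace width |
| `min_chord` | 0 (off) | µm | optional floor excluding residual speckle chords |
| `keep_truncated` | FALSE | — | truncated chords bias the MLI downward; excluded unless airspaces are comparable to the field of view |
| `dispersion` | variance/mean | µm | see below |

## Design choices where the procedure was underdetermined

* **MLI as mean chord length.** The defining step builds a histogram of
  the intercept lengths and computes its mean and SD, so the histogram
  mean is the headline MLI. The classic count-based estimator (total test
  line length / number of wall intersections) is computed alongside as
  `mli_intersection` for cross-checking; the two differ when truncated
  chords are excluded.
* **Dispersion index.** Defined nowhere in the source procedure. The
  variance-to-mean ratio (index of dispersion, units µm) is the default;
  the coefficient of variation is selectable (`dispersion = "cv"`) since
  either reading is defensible.
* **AST procedure.** Only the name of the measurement is given. Measuring
  the complementary (wall) phase on the same line grid, with the same
  completeness rule, is the minimal choice consistent with the airspace
  measurement.
* **Closing structuring element.** Shape and size are unstated; a
  Euclidean disk of radius 3 px is the default, configurable. Closing
  borders are handled asymmetrically: dilation pads with airspace (only
  real walls grow), erosion pads with wall (border walls are not shaved).
  Consequence: border airspace is never spuriously closed and hole-free
  walls keep their thickness exactly. One caveat discovered during
  validation: *any* closing rounds the concave airspace corners at wall
  junctions by a few pixels; this is a property of the operator, not a
  bug, and moves the lattice MLI by far less than the accepted 2 µm.
* **Grid placement.** "Equal spaced" admits border lines at rows 0 and
  $H-1$; centred spacing avoids them, so every line can in principle carry
  complete chords.
* **Tie-break in Otsu.** Lowest maximizing threshold, making the result
  deterministic under permutations of equal-variance candidates.

# The synthetic world

The original study validated the pipeline on H&E sections that are not
available at desk scale, and it describes no validation images. The
package therefore ships generators whose defaults are the package's own
stated world, chosen once to resemble mouse lung parenchyma at 20×
magnification and not revisited:

* **Lattice** (`generate_lattice()`): square airspaces (default exercised
  at 30–80 µm side, spanning the normal-to-emphysematous range of mouse
  alveolar MLI) separated by 5 µm walls at 1 µm/px. Every horizontal
  airspace chord equals the side length, so the MLI ground truth is
  analytic and rasterization error is bounded by 2 px.
* **Voronoi** (`generate_voronoi()`): seeds uniform on the field; a point
  is wall iff $d_2 - d_1 \le$ wall thickness, where $d_1, d_2$ are
  distances to the two nearest seeds — a "dilated ridge" tessellation with
  irregular, convex-ish airspaces. No closed form exists for its
  chord-length distribution, so ground truth is brute-force sampling of
  the *continuous* geometry: 10× the analysis line density, quarter-pixel
  marching step, complete chords only. Mask and oracle share the geometry
  definition but not the raster.
* **Degradations**: `punch_lumens()` carves disk-shaped holes strictly
  interior to walls (hole centres at distance > radius from airspace), so
  the correct post-closing geometry is unambiguously the unpunched mask;
  `render_grayscale()` draws airspace/wall intensities (defaults 220/60,
  additive Gaussian noise) and quantizes with round-half-up, matching
  common 8-bit image inputs.

What a green test does **not** establish: real H&E sections have staining
gradients, airways and vessels that should be excluded, touching-tissue
artifacts, and anisotropy — none of which the generators emulate. The
pipeline's accuracy on real slides therefore rests on the operator checks
(audit dumps of intermediate masks), not on these tests.

# Crosstalk inference

From a cluster-labeled UMI matrix, the detection fraction of gene $g$ in
cluster $c$ is the proportion of $c$'s cells with UMI > 0. A gene is
*expressed* in a cluster iff its detection fraction is ≥ 0.30 — the
inclusive reading of the 30% rule (a gene detected in exactly 30% of
cells qualifies; the threshold is configurable). Given a FANTOM5-style
ligand-receptor pair table, the directed graph has clusters as nodes and,
for each ordered pair (A, B), an edge weighted by the number of L-R pairs
with the ligand expressed in A and the receptor in B. Autocrine self-loops
are retained by default (nothing in the graph definition excludes A = B);
`self_loops = FALSE` drops them. Hub scores are weighted total degree
(out + in, self-loops in both), with betweenness centrality reported for
reference only — "centrality" was asserted in the source without naming a
statistic. No expression-magnitude weighting and no permutation-based
significance testing is performed: the detection-fraction rule is the
entire model.

The synthetic expression generator plants per-(cluster, gene) detection
rates (background 0.05, shifted-Poisson counts for detected cells). One
scenario from the acceptance criteria deserves a note: planting only
*ligands* at 0.9 in one cluster while every receptor stays at the 0.05
background yields an empty graph with near certainty (a background gene
reaches 30% detection in 500 cells with probability ~1e-60), so the
planted-hub test plants both the ligands and the receptors of the pair
table in the hub cluster — the minimal completion that makes the scenario
well-posed.

# Group statistics

Each measurement row (e.g., MLI at one age) is tested individually with
the Welch unequal-variance $t$ statistic and Satterthwaite degrees of
freedom — the literal reading of "without assuming a consistent SD" — and
two-tailed p values. Across rows, the Holm–Šidák step-down procedure at
$\alpha = 0.05$: with $m$ tests sorted ascending, the $i$-th is rejected
iff $p_{(i)} \le 1 - (1-\alpha)^{1/(m-i+1)}$ and all earlier ones were
rejected; adjusted p values are the running maximum of
$1-(1-p_{(i)})^{m-i+1}$, clipped to [0, 1], so `p_adj <= alpha` reproduces
the decisions exactly. Degenerate rows follow stated conventions: both
variances zero with equal means gives $p = 1$; unequal means is exact
separation, flagged, with $p = 0$ rather than NaN.

# Numerical and degenerate-input policy

* Constant images have no Otsu threshold → explicit error, not NaN.
* Images with no complete airspace chord → explicit empty-result error.
* Coincident Voronoi seeds → perturb and log, up to 10 attempts.
* More holes requested than interior wall pixels → place what fits,
  warn with the count.
* All seeded generators save and restore the caller's RNG state, so they
  are pure functions of their spec and compose without side effects.

# Known limitations

* Horizontal test lines only; anisotropic structures need rotation
  outside the package.
* No airway/vessel exclusion masking, stain normalization, or
  destructive-index scoring.
* TIFF input is not supported in this build (no reader available in the
  target environment); convert to PNG.
* The crosstalk module quantifies pair counts only; "enriched"
  interactions in the statistical sense are out of scope.
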