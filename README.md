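# lamquant

Quantitative tools for two readouts used in studying cystic and
emphysematous lung disease (e.g., lymphangioleiomyomatosis, LAM):

1. **High-throughput lung morphometry.** The mean linear intercept (MLI)
   is the standard stereological measure of airspace size on a histology
   section: over a grid of `n` horizontal test lines, every maximal run of
   airspace bounded by tissue wall is a chord, and

   MLI = mean(airspace chord lengths, µm),

   reported with its sample SD and dispersion index (variance/mean of the
   chord-length histogram). Alveolar septal thickness (AST) is the same
   statistic on the wall phase. The pipeline is: Otsu binarization →
   morphological closing of the walls (fills capillary lumens) →
   20-line grid → intercept counting → chord statistics, for images in
   PNG/JPEG/ASCII-PGM with a user-supplied pixel size in µm/px.

2. **Ligand-receptor crosstalk networks.** From a cluster-labeled UMI
   count matrix, a gene counts as *expressed* in a cluster when ≥ 30 % of
   that cluster's cells have UMI > 0. Given a FANTOM5-style
   ligand-receptor pair table, the directed graph over clusters weights
   the edge A→B by the number of pairs whose ligand is expressed in A and
   receptor in B; hub clusters are ranked by weighted total degree.

Both analyses come with synthetic generators carrying known ground truth
(analytic square-lattice and brute-force-sampled Voronoi parenchyma;
planted-detection expression matrices) and with the group-comparison
statistics used to report results: per-row Welch t tests and Holm–Šidák
step-down correction at α = 0.05.

## Worked example

```r
library(lamquant)

# A 10x10 lattice of 50 um airspaces with 5 um walls at 1 um/px, degraded
# with 20 capillary-like lumens and additive noise, then analyzed blind:
gen <- generate_lattice(lattice_spec(50, 5, 1, 10, 10))
img <- render_grayscale(punch_lumens(gen$mask, 20, 2, rng_seed = 1),
                        render_spec(220, 60, 10, rng_seed = 2))
analyze_gray_image(img, morphometry_config(pixel_size = 1))
#> <morphometry_result> <unnamed>
#>   MLI 50.00 um (SD 0.00, dispersion 0.000, n = 200 chords)
#>   AST 5.00 um (SD 0.00)
```

The pipeline recovers the analytic ground truth (MLI = 50 µm) exactly:
the Otsu threshold (104) separates the noisy phases and closing removes
every punched lumen before chords are measured.

```r
# Crosstalk: one cluster planted with all ligands and receptors at 90%
# detection; everything else at the 5% background.
ligs <- paste0("LIG", 1:10); recs <- paste0("REC", 1:10)
expr <- generate_synthetic_expression(5, 500, c(ligs, recs),
  planted = data.frame(cluster = "C1", gene = c(ligs, recs),
                       detection_rate = 0.9),
  rng_seed = 1)
g <- infer_crosstalk(expr, load_lr_pairs(
  data.frame(ligand = ligs, receptor = recs)))
g
#> <crosstalk_graph> 5 clusters, 1 edges, total weight 10
head(hub_scores(g), 3)
#>   cluster out_weight in_weight total betweenness
#> 1      C1         10        10    20           0
#> 2      C2          0         0     0           0
#> 3      C3          0         0     0           0
```

All 10 pairs connect C1 to itself (autocrine self-loop, counted in both
degrees), making it the hub with total weighted degree 20.

```r
# Group comparison, paper-style: N = 6 per group, rows tested with Welch t
# and Holm-Sidak correction.
rows <- list(mli_8wk = list(a = c(52.1, 49.8, 50.7, 51.2, 48.9, 50.3),
                            b = c(78.4, 81.2, 79.9, 80.5, 82.1, 79.0)),
             ast_8wk = list(a = c(5.1, 4.9, 5.0, 5.2, 4.8, 5.0),
                            b = c(5.0, 5.1, 4.9, 5.2, 5.0, 4.8)))
as.data.frame(compare_groups(rows))[, c("row", "t", "df", "p", "p_adj",
                                        "significant")]
#>       row         t        df            p        p_adj significant
#> 1 mli_8wk -41.09976  9.577089 4.286105e-12 8.572254e-12        TRUE
#> 2 ast_8wk   0.00000 10.000000 1.000000e+00 1.000000e+00       FALSE
```

The 30 µm MLI separation is detected (adjusted p ≈ 8.6e-12); the null AST
row is not.

## Command line

An installed copy ships `lam-quant` under `inst/cli/`:

```sh
lam-quant synth lattice --airspace-side 50 --wall 5 --px 1 --out fx --seed 3
lam-quant morphometry --input fx --px 1 --out results.csv
lam-quant crosstalk --matrix m.csv --clusters cl.csv --pairs lr.tsv --out ct
lam-quant compare --input subjects.csv --value-col value --out report.csv
```

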