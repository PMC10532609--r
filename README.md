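# cslrecon

One-shot coded structured light (CSL) for 3D reconstruction and
morphometry of smooth, fusiform subjects — designed around the use case of
measuring farmed fish (total length, height) without contact, from a
single projector–camera frame.

A binary pattern of white geometric symbols (rectangle, L, T, triangle, X,
Π) on black is projected onto the subject; one camera image is captured.
Every 3×3 neighbourhood of pattern symbols, read in a fixed order, forms a
nine-symbol **codeword**, and the pattern is constructed so that any two
codewords satisfy

```
HD(SP_i, SP_j) = Σ_k [ SP_i(k) ≠ SP_j(k) ] ≥ 3   for all i ≠ j,
```

which lets the decoder correct one misclassified symbol per codeword.
Detected symbols are classified by minimum normalized SAD over a ±22°
rotation sweep with bounding-box scale matching,

```
SAD(X, Y) = Σ |X_ij − Y_ij| / max(|X|, |Y|) ∈ [0, 2],
```

assembled into 3×3 subpatterns by nearest-neighbour chaining with
dual/quadruple geometric consistency checks, matched against the codeword
book with iterative single-error correction, and triangulated (midpoint of
the common perpendicular of the camera and projector rays) into a point
cloud, a depth map, and principal-axis morphometrics.

The package covers the whole pipeline:

- `generate_pattern()`, `render_pattern()`, `codeword_book()`,
  `verify_min_distance()` — error-correcting pattern design;
- `sauvola_binarize()` (adaptive, bright-foreground), `otsu_binarize()`
  (global baseline), `extract_components()` — image front end;
- `classifier_config()`, `classify_components()` — symbol classification;
- `extract_subpatterns()`, `decode_codeword()`, `propagate_corrections()`,
  `extract_correspondences()` — neighbourhood decoding;
- `csl_calibration()`, `triangulate_correspondences()`, `measure_cloud()`
  — geometry and morphometrics;
- `scene_config()`, `render_scene()`, `evaluate_scene()` — a synthetic
  capture simulator with exact ground truth, standing in for real fish
  images;
- a command-line driver, `inst/cli/cslrecon.R`, with `generate-pattern`,
  `simulate`, `reconstruct` and `evaluate` subcommands.

## Worked example

Reconstruct a synthetic fusiform body (ellipsoid with semi-axes
15 × 5.5 × 2 cm, front face at 72 cm) through the full pipeline at a
14 dB capture SNR:

```r
library(cslrecon)

pattern <- generate_pattern(rows = 18, cols = 16, seed = 0)
verify_min_distance(pattern)
#> [1] 3

calib  <- csl_calibration()   # 53.4 cm baseline, 78.7°/42.5° hfov devices
scene  <- render_scene(scene_config("ellipsoid", snr_db = 14, seed = 1),
                       pattern, calib)
result <- reconstruct_image(scene, pattern, calib)
stage_counts(result)
#>                                  stage count
#> 1       Number of symbols in the image   182
#> 2            Number of valid codewords   101
#> 3 Final number of corresponding points   150
#> 4                  Components detected   182
#> 5                    Subpatterns valid   112
#> 6                  Points triangulated   150

metrics <- evaluate_scene(result, scene)
sprintf("interior decode rate %.3f, false match rate %.3f",
        metrics$interior_decode_rate, metrics$false_match_rate)
#> [1] "interior decode rate 1.000, false match rate 0.007"

range(result$cloud$points[, 3])   # recovered depth range, cm
#> [1] 72.01 73.76
```

Every symbol whose full 3×3 neighbourhood was imaged is decoded; 101
decoded codewords identify 150 distinct symbols (each codeword decodes
nine symbols at once, with heavy overlap). The recovered depths span the
front face of the ellipsoid, whose ground-truth depth runs from 72 cm at
the pole toward 74 cm at the silhouette. `result$morphometrics` reports
principal-axis extents of the decoded patch (here 17.5 × 8.9 cm — the
pattern only covers part of the 30 cm body); `write_ply()`,
`write_xyz()`, `depth_map()` and `write_depth_map_png()` export the cloud.

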