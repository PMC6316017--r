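# depthvol

Food-portion volume estimation from a **single depth image**.

A depth camera sees only the near half of an object; meshing that half-shell
misestimates volume badly. `depthvol` implements the opposite-view synthesis
approach to this problem: predict the depth map an opposite-facing camera
would have seen, fuse the two views into one metric point cloud under a
fixed 180° rotation model with a translation-only ICP refinement, and
measure the volume of an alpha-shape reconstruction of the fused cloud. It
is aimed at researchers in dietary assessment / mHealth imaging who need a
reproducible, fully synthetic test bed for single-view volumetry.

The core model: a pixel $(u, v)$ with depth $Z$ back-projects as
$[X, Y, Z]^\top = Z\,K^{-1}[u, v, 1]^\top$; the opposite camera is related
to the initial one by $R_y(180°)$ and an unknown translation $T$, so its
points register into the initial frame as
$p_w = R_y(180°)^{-1}(p_c - T)$. $T$ comes from a view-synthesis network
(or a noisy oracle) and is refined by an iterative-closest-point loop
constrained to translation, using the occluding contours of the two views.
Volume is the enclosed volume of the alpha complex (Delaunay tetrahedra
with circumradius ≤ α, interior voids filled), with α escalated from
3× the median point spacing until the estimate plateaus.

The package includes:

* a ray-casting depth renderer over analytic primitives (cube, sphere,
  cylinder, ellipsoid, capsule, bent capsule) with pose sampling matching
  the study conditions (azimuth 0–360°, elevation 90–270°, distance
  0.5–0.6 m, centre shifts ±0.1 m), 16-bit millimetre PNG + JSON I/O, and
  70/10/20 holdout splits;
* a compact encoder–decoder view-synthesis model (naive and
  inception + extrinsic-head variants) with its own im2col/BLAS training
  engine;
* the completion + ICP + volumetry pipeline and a Table-style evaluation
  protocol (per-object mean volume, SD, percent error).

## Worked example

```r
library(depthvol)

k    <- default_intrinsics()                    # 640x480, fx = fy = 570
mesh <- make_primitive("sphere", r = 3.65)      # analytic volume 203.69 cm^3

set.seed(7)
pair  <- render_pair(mesh, k)                   # initial + opposite depth views
cloud <- complete_cloud(pair$initial, pair$opposite, k, pair$t_gt,
                        refine = FALSE)         # known-extrinsics fusion
cloud
#> <point_cloud: 10765 points, frame = world>

estimate_volume(cloud)
#> <volume_result: 203.68 cm^3, alpha = 0.0203 m, 4210 triangles, watertight, 3 alpha doublings>
```

The estimate is within 0.01% of the closed form: the two opposite
hemispherical views cover the whole sphere, and the alpha shape closes the
thin seam where both views graze the surface. A noisy end-to-end trial
(oracle-synthesised far view with 3 mm depth noise, translation off by
2 cm/axis, ICP refinement) is one call:

```r
v <- run_trial(mesh, seed = 8, mode = "oracle_icp", k = k)
round(as.numeric(v), 1)        # cm^3
#> [1] 194.8
```

and a full evaluation over the four-primitive study suite prints a
per-object table:

```r
report <- evaluate(study_primitives(), n_trials = 15,
                   modes = c("known_extrinsics", "oracle_icp"),
                   base_seed = 7, k = k)
report$summary
#>               mode error_pct accuracy_pct
#> 1 known_extrinsics 0.5663727     99.43363
#> 2       oracle_icp 1.0423383     98.95766
```

(`evaluate()` scores each object by the error of its *mean* estimate over
trials, the convention of per-object report tables; the acceptance script
instead averages the per-trial absolute errors, a stricter summary of the
same runs.)

A thin command-line interface over the same functions is installed at
`inst/cli/depthvol` (`render-dataset`, `complete`, `volume`, `evaluate`,
`train`, `synthesize`).

## Package layout

| Area | Files |
| --- | --- |
| Camera geometry & containers | `R/geometry.R` |
| Depth/PLY I/O | `R/io.R` |
| Primitives & meshes | `R/primitives.R` |
| Renderer, poses, datasets | `R/render.R`, `src/raycast.cpp` |
| View synthesis (loss, oracle, network) | `R/synthesis.R`, `R/nn.R`, `R/model.R` |
| Completion & translation-only ICP | `R/completion.R` |
| Alpha-shape volumetry | `R/volumetry.R` |
| Evaluation protocol | `R/evaluate.R` |

The methods vignette (`vignettes/methods.Rmd`) documents the models,
parameter choices, numerical decisions and known limitations in detail.
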