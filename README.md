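# platemorph

Quantitative platelet morphodynamics from phase-contrast time-lapse
microscopy. `platemorph` is an R implementation of a deep-learning-assisted
morphometry pipeline for spreading and migrating platelets:

1. **Ground truth** — binarize fluorescence images of membrane-stained
   platelets (rolling-ball background removal → threshold → hole filling);
2. **Segmentation** — a trainable U-net-style encoder–decoder that
   binarizes the *phase-contrast* channel (min–max normalization,
   reflection padding to the network input size, rotation/flip/resize
   augmentation, training to the minimum-validation-loss snapshot);
3. **Morphometry** — per-platelet shape parameters from the binary masks;
4. **Spreading dynamics** and **haptotactic migration** statistics;
5. **Validation statistics** — pixel confusion / IoU, Bland–Altman limits of
   agreement, Pearson correlation, and Dunn's non-parametric multiple
   comparisons;
6. **Phantoms** — a synthetic platelet generator (bodies, filopodia,
   renders, spreading and migration sequences) with known ground truth, so
   every stage above is testable without microscope data.

## The quantities

For a platelet with mask area *A* and outline perimeter *P*:

- circularity  c = 4πA / P²  (1 for a perfect circle),
- aspect ratio  e = a/b  from an ellipse fit (second central image moments),
- filopodia counted as high-curvature convex tips flanked by concave necks,
  with length and curvature thresholds,
- idle time: time from adhesion to a 15 % area increase,
- initial spreading rate: least-squares slope of A(t) over the 2 min after
  idle time ends,
- migration velocity: accumulated path length / time,
- straightness: Euclidean displacement / accumulated path length (1 =
  perfectly straight),
- directional change ⟨cos θ⟩ between movement directions separated by a time
  interval (1 = persistent, 0 = random).

## Worked example

Generate a phantom platelet with 5 designed filopodia at 0.1 µm/px and
measure it:

```r
library(platemorph)
ph <- make_platelet_mask(phantom_spec(a = 20, b = 14, n_filopodia = 5,
                                      filopodium_length = 15, seed = 3),
                         pixel_size = 0.1)
measure_masks(ph$mask, min_tip_curvature = 2, min_filopodium_length = 0.8)
#>   frame platelet_id     x     y  area perimeter circularity aspect_ratio
#> 1     0           1 4.704 4.718 12.12     26.11      0.2233        1.255
#>   major minor n_filopodia
#> 1 5.337 4.254           5

ph$truth
#>   platelet_id frame_index   x   y  area aspect_ratio n_filopodia
#> 1           1           0 4.7 4.7 12.11        1.429           5
```

The measured area (12.12 µm²) matches the designed analytic area
(12.11 µm²) and all 5 filopodia are recovered; the measured aspect ratio
(1.26) is that of the *whole* component including the protrusions, while
the designed 1.43 refers to the body ellipse alone. The low circularity
(0.22) reflects the five spikes — exactly why filopodia-rich platelets have
low c.

Migration metrics on a constructed 2-step path (0,0) → (3,0) → (3,4) µm at
30 s/frame:

```r
tr <- track(cbind(c(0, 3, 3), c(0, 0, 4)), frame_interval = 30)
migration_velocity(tr)   # (3+4) um / 1 min      -> 7
straightness(tr)         # 5 / 7                 -> 0.714
```

Train the desk-scale segmenter on phantom phase-contrast renders and
evaluate on held-out phantoms:

```r
pairs <- make_segmentation_set(200, side = 64, seed = 1)
model <- build_and_train(pairs, net_config(input_size = 64, depth = 2,
                                           base_filters = 8,
                                           max_epochs = 25, seed = 1))
mask <- predict(model, pairs[[1]]$phase)
```

(Held-out pooled IoU with this configuration: ~0.99; see the acceptance
report below.)

## Command line

```sh
Rscript exec/platemorph simulate --kind migration --frames 10 --out seq.tif
Rscript exec/platemorph measure  --input seq.tif --pixel-size 1 --out shapes.csv
Rscript exec/platemorph migrate  --input seq.tif --frame-interval 30 --out metrics.csv
```

Subcommands: `simulate`, `groundtruth`, `train`, `segment`, `measure`,
`spreading`, `migrate`, `validate`, `run` (JSON-configured pipeline).
Images are uncompressed grayscale TIFF (8/16-bit or float, single- or
multi-page, pixel size in the resolution tags).

## Vignette

`vignettes/platemorph-methods.Rmd` documents the models, the phantom
world, numerical choices (perimeter estimation, curvature smoothing,
thresholds) and known limitations.
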