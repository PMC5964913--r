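# pelviseg

Semi-automated bone segmentation for pelvic CT slice sequences, built for
medical-image analysts who need expert-quality contours on hundreds of
axial slices without contouring each one by hand.

CT sequences are spatially continuous: adjacent slices look almost alike,
and the bone *topology* — how many bone cross-sections there are and how
they are arranged — changes only at a sparse set of slices.  `pelviseg`
finds those **key frames**, lets an expert mark just them, and propagates
the marking to every remaining slice with a skeleton-marker watershed.

## Method

1. **Pre-processing.** Calibrated intensities are windowed to 8 bits
   (`f(x) = [x − (c − w/2)]·255/w`, clamped to 0 and 255; bone window
   `w = 600`, `c = 900` Hu), the table and cables are removed by keeping
   the largest connected component of the binarized slice as the body
   mask, and the whole sequence is cropped to one union bounding box.
2. **Key-frame extraction.** For each slice an "interesting image" is
   built (Gaussian smoothing, Haar approximation reconstruction,
   thresholding at the mean of the non-zero pixels `T1`).  Slice `i+1`
   becomes a candidate when the summed absolute difference of adjacent
   interesting images exceeds `T2 = 0.7·mean(Dif)`.  Candidates are then
   filtered twice over adjacent pairs — keep the later frame when mutual
   information `I ≤ T3 = mean(I)`, then when normalized correlation
   `R ≤ T4 = mean(R)` — leaving the target key-frame set.
3. **Marking.** Each key frame gets a bone mask: automatic bright-region
   thresholding refined through the watershed, with programmatic marker
   point edits (`edit_markers()`) standing in for the expert's clicks.
4. **Propagation.** Every slice is matched to its most correlated key
   frame.  The matched mask's foreground and background are thinned to
   one-pixel skeletons (two-subiteration thinning), imposed as the only
   regional minima of the slice's Sobel gradient magnitude, and a
   marker-controlled watershed floods the surface; regions grown from
   foreground skeletons form the bone mask, and contours are traced
   around them.

Accuracy is reported as the overlap `O = |P ∩ T| / |T| × 100` against the
expert/truth mask and the directed mean contour deviation `Mad` (mean
distance from each predicted contour point to the nearest truth contour
point, in pixels), with slices classed *accurate* (`O > 90`), *fair*
(`80 ≤ O ≤ 90`) or *unacceptable* (`O < 80`).

A synthetic phantom module (`generate_phantom()`) emulates a CT stack —
body ellipse, 1–6 drifting bone ellipses with a known topology-change
schedule, table artifact, Gaussian noise — with per-slice ground-truth
masks, so the entire pipeline is testable without patient data.

See `vignettes/pelvic-ct-watershed.Rmd` for the full method description,
parameter defaults and known limitations.

## Worked example

```r
library(pelviseg)

ph <- generate_phantom(phantom_spec(
  n_slices = 30, topology_schedule = list(c(1, 3), c(10, 4), c(20, 3)),
  noise_sigma = 5, seed = 7))

kf <- extract_keyframes(ph$stack)
print(kf)
#> <keyframe_sets> 19 candidate -> 8 intermediate -> 3 target
#>   target: 1, 10, 20
#>   T2 = 7845  T3 = 1.635  T4 = 0.9077

masks <- setNames(ph$truth_masks[kf$target], kf$target)  # "expert" marking
seg <- segment_sequence(ph$stack, masks)

rep <- evaluate_segmentation(seg, ph$truth_masks)
summary(rep)
#> eval_report over 30 slice(s): mean O 100.00%, mean Mad 0.554 px
#>   accurate 100.0%  fair 0.0%  unacceptable 0.0%
```

The extractor lands exactly on the scheduled topology changes (slices 1,
10, 20) — 3 key frames out of 30 slices, so only 10 % of the sequence
would need expert marking.  Propagating the three truth masks recovers
every slice's bone mask completely (`O = 100 %`) with contours within
about half a pixel of the truth (`Mad = 0.554 px`).

A command-line front end with `phantom`, `keyframes`, `run` and
`evaluate` subcommands is installed under `inst/cli/pelviseg`.

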