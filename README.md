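# octstrut

Automatic stent strut detection in intravascular optical coherence
tomography (IVOCT) pullback runs, working directly on the native polar
(A-line × depth) 16-bit frames.

## The problem

After percutaneous coronary intervention, IVOCT is the modality of
choice for checking how a stent sits in the vessel: whether struts are
apposed to the wall, malapposed (floating in the lumen), or covered by
neointimal tissue. A pullback run contains thousands of struts, so any
quantitative or 3D analysis needs automatic detection. In polar frames a
metal strut is a bright specular blob with a *trailing shadow* — a dark,
almost horizontal stripe running from the strut to the far depth edge,
because the metal blocks the light.

`octstrut` detects struts with no lumen/vessel contours and no prior
knowledge of strut status:

1. **Preprocess** — zero the lowest 5% of the global intensity histogram
   (noise floor); exclude constant catheter ring artifacts found on the
   z-minimum projection (bright vertical lines near the catheter).
2. **Candidate pixels** — per A-line, take the intensity peak and the
   start of the trailing shadow (a window of 30 consecutive pixels below
   the 89th percentile of the ROI histogram); keep the A-line iff the
   two-point slope `(I(shadow_start) − peak)/dist` is steeper than the
   slope threshold (−48): struts drop to their shadow much faster than
   tissue attenuates.
3. **Shadow edges** — Gaussian smoothing, then two directional 3×3
   Prewitt compass kernels detect the top (bright→dark) and bottom
   (dark→bright) edges of each shadow; only edges ≥ 100 px long survive,
   which kills short false edges from an eccentric lumen.
4. **Edge-guided clustering** — single-linkage agglomeration of
   candidates (merge below 4 px, wrap-aware across the frame seam); for
   each top edge keep the first cluster below it, for each bottom edge
   the first above it, drop the rest; shadow intervals with both edges
   but no cluster trigger recovery of *non-bright* struts (dim struts
   with a clear shadow). Strut position = cluster mean (circular over
   rows), i.e. the middle of the strut front edge.
5. **3D false-positive removal** — the guide wire is the detection
   closest to the catheter with a continuous position along the whole
   pullback; its track is flagged and removed. Frames outside the
   automatically detected stented segment (long run of strut-rich
   frames) are cleared.

A synthetic phantom generator (speckled attenuating tissue, eccentric
rotating lumen, apposed/malapposed/covered/non-bright struts, guide
wire, catheter artifacts, strut-free margins) provides ground truth for
every stage, and an evaluation module implements tolerance-based optimal
matching (10 px ≈ 0.05 mm), sensitivity / false-positive ratio /
distance-error statistics, and a ±20% parameter sensitivity sweep.

## Worked example

```r
library(octstrut)

spec <- phantom_spec(n_frames = 16, seed = 42)   # 128 x 256 polar frames
ph <- generate_phantom(spec)
ph$pullback
#> IVOCT polar pullback: 16 frame(s) of 128 A-lines x 256 depth samples
#>   intensity range [0, 25820]; depth pixel 0.005 mm

params <- scale_parameters(detection_parameters(), 128, 256)
det <- detect_struts(ph$pullback, params, verbose = TRUE)
#> preprocess: noise floor 10, ROI from depth column 9
#> candidate detection: shadow intensity threshold 2067.0
#> clustering: 136 strut candidates over 16 frames
#> guide wire: not present
#> stented segment: frames 1-16

evaluate_detections(det$struts, ph$truth, params$acceptance_distance, 128)
#> Strut detection evaluation: 128 reference, 136 detected
#>   sensitivity 99.2% (127 TP), FP ratio 7.0% (9 FP)
#>   distance error 0.08 +/- 0.27 px
#>   by status:
#>     apposed      99.2% of 128
```

The noise floor (10) and shadow-intensity threshold (2067) are the
rank-based 5th/89th percentiles of this pullback's histograms; the
detector found 136 clusters over 16 frames, 127 of the 128 true struts
were matched within the 3 px tolerance (the 10 px clinical tolerance
scaled to the 256-sample depth axis) with a mean position error of
0.08 px, and 9 detections — speckle clusters adjacent to shadow edges —
were false positives. `det$struts$kind` records the audit trail
(`bright`, `non_bright`, `guide_wire_removed`,
`outside_segment_removed`); `active_struts(det)` returns the surviving
detections.

Full-size clinical pullbacks (504 × 960 TIFF stacks or raw binary with a
YAML sidecar) are read with `read_pullback()` and processed with the
unscaled `detection_parameters()` defaults.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/octstrut.R", package = "octstrut"))')
Rscript "$CLI" simulate --spec phantom.yaml --out sim/
Rscript "$CLI" detect   --input sim/pullback.tif --out det/ --scale-to-input
Rscript "$CLI" evaluate --detections det/detections.csv --truth sim/truth.csv \
                        --out eval/ --acceptance-distance 3 --n-alines 128
Rscript "$CLI" sweep    --input sim/pullback.tif --truth sim/truth.csv \
                        --out sweep/ --scale-to-input
```

Exit codes: 0 success, 2 input error, 3 stage failure.

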