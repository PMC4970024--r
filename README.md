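# weedvol

Maize and weed volume estimation from colored 3D field meshes.

`weedvol` is an R package plus analysis workflow for depth-camera
(RGB-D) surveys of weed-infested maize fields at the early,
treatment-relevant growth stage. From a colored triangular mesh of a
1 m × 1 m framed field plot it:

1. filters isolated sensor points (no neighbor within 1 cm);
2. detects the white sampling frame by color, crops the scene to it,
   and splits it into four 0.5 m × 0.5 m quadrats;
3. separates **maize** from **weeds** and **soil** with a dual rule —
   height selection of edge-connected faces for the crop (maize at
   0.40–0.55 m towers over weeds at ≤ 0.20 m; default cut 0.30 m),
   then an excess-green color filter (ExG = 2G − R − B > 20) for the
   low weeds that soil microrelief hides from height alone;
4. estimates per-class plant volume by polyhedral mass properties
   (divergence-theorem volume after sealing open canopy boundaries to
   the ground plane);
5. relates volumes to dry biomass and weed density (Pearson r, simple
   linear regression) and classifies the weed community into
   monocots, dicots, and mixtures by canonical discriminant analysis
   (CDA) of weed height features, with leave-one-out confusion
   matrices.

Because no field scans are publicly deposited, the package includes a
synthetic field-scene generator (`generate_scene()`,
`generate_study()`) that emulates the study design — tilled-soil
microrelief, white frame, a maize row through half the quadrats,
grass/broadleaf/mixed weed cover, sensor noise — with exact per-face
and per-plant ground truth. Every pipeline stage is validated against
it; see `vignettes/weedvol-methods.Rmd` for the model and design
notes.

## Worked example

```r
library(weedvol)

report <- run_pipeline(pipeline_config(seed = 1))
report$analysis$relationships[, c("relationship", "r", "r_squared")]
```

On the default synthetic study (10 scenes, 40 quadrats, sensor noise
on, volume–biomass correlation target 0.85) this prints:

```
               relationship     r r_squared
 total_volume~total_biomass 0.768     0.590
 maize_volume~maize_biomass 0.762     0.580
   weed_volume~weed_biomass 0.887     0.788
  total_volume~weed_density 0.269     0.073
   weed_volume~weed_density 0.511     0.261
   maize_count~maize_volume 0.991     0.982
```

Estimated volumes track dry biomass strongly for the totals and for
each class; weed density correlates with weed volume; and scene-level
volume recovery is within a few percent of ground truth (+3.5% maize,
+0.6% weed here — canopy closure overestimates tissue volume by
design). The weed-class confusion matrix is in
`report$analysis$confusion_loo`:

```r
print(report$analysis$confusion_loo)
#>           predicted
#> true       monocots dicots mixture
#>   monocots      100      0       0
#>   dicots          0    100       0
#>   mixture        20      0      80
```

Broad-leaved (dicot) quadrats separate perfectly on height features;
mixtures are partly confused with pure grass because a mixed sample's
tallest plant is a grass.

The same analysis, written as a narrative workflow, lives under
`analysis/` (`01_simulate_study.R` … `04_weed_classification.R`);
each driver prints what it found and writes its tables under
`results/`.

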