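# mitoshape

Quantification of mitochondrial network morphology in calibrated
fluorescence microscopy images.

Mitochondria in adherent cells range from long interconnected tubules to
fragmented spheres, and the balance between those shapes is a readout of
fusion/fission activity and mitochondrial stress. `mitoshape` turns a
MitoTracker-style image (2D or a Z-stack, with a known pixel size in µm)
into a per-cell census of four morphology classes:

| class | definition |
|---|---|
| filament | networked structure with skeleton extension E > 11 µm |
| rod | elongated structure below the filament threshold |
| punctum | round structure with radius < 0.6 µm |
| swollen | round, compact structure with radius ≥ 0.6 µm |

For every segmented object the package measures area (A), perimeter (P),
aspect ratio (AR), circularity (C = 4πA/P²), solidity (S), minimum Feret
diameter (MLE, the minimum projection width from rotating calipers) and
extension (E, the longest shortest-path between endpoints of the
object's skeleton, on an 8-connected graph with axial weight = pixel
size and diagonal weight = √2 × pixel size). Classification is
sequential, first match wins: punctum → swollen → filament → rod, with
"round" operationalized as C ≥ 0.8 and AR ≤ 2 and the radius taken as
r_eq = √(A/π).

The analysis chain per cell is: maximum-intensity Z-projection → cell
masking → rolling-ball background subtraction (2.5 µm ball) →
Laplacian-of-Gaussian enhancement (1 µm scale) with CLAHE (2.5 µm
tiles) → Yen thresholding → 8-connected segmentation with a small-object
exclusion (default 0.25 µm², the diffraction-limit floor) → morphometry
→ classification → per-cell and per-group statistics. Every parameter is
a physical quantity in µm, converted through the image's pixel size. A
synthetic scene generator with exact ground truth (`generate_scene`)
makes the whole pipeline testable without microscopy data.

## Worked example

Generate a synthetic cell, analyse it end to end, and read the census:

```r
library(mitoshape)

scene <- generate_scene(scene_spec(seed = 42))   # 5/8/8/4 planted objects
write_scene(scene, "demo", name = "cell01")

res <- run_batch(
  data.frame(image = "demo/cell01.tif", group = "wt"),
  out_dir = "demo/results",
  config  = run_config(pixel_size_um = 0.065))

res$summaries[[1]]
#> <cell_summary> cell01: 28 object(s)
#>   filament: 5 (17.9%)
#>   rod: 10 (35.7%)
#>   punctum: 9 (32.1%)
#>   swollen: 4 (14.3%)
```

The scene planted 5 filaments, 8 rods, 8 puncta and 4 swollen
structures; the pipeline recovers every planted object in its planted
class (the three extra detections are noise specks classified as small
rods/puncta). `run_batch` writes `objects.csv` (one row per object with
class and all features in µm units), `cells.csv` (one row per cell with
counts and count- and area-based percentages), `groups.csv` (mean ± SD
of per-cell percentages per group) and `run_manifest.json`, which
records every parameter actually used:

```
# A,P,MLE,E,r_eq in um^2/um; AR,C,S dimensionless
"cell_id","label","class","A","P","AR","C","S","MLE","E","r_eq"
"cell01",1,"punctum",0.908375,3.47464,1.0000859,0.9454866,0.9267241,1.1030865,0,0.5377218
"cell01",2,"rod",2.67865,8.361535,4.7417911,0.4814529,0.8690884,0.8996018,2.9723149,0.9233854
```

Real images go through the same call: point `run_batch` at TIFF files
(pixel size from the TIFF resolution tags, an ImageJ `unit=micron`
description, or `pixel_size_um`), with cells outlined either as integer
label-mask TIFFs or ImageJ `.roi`/ROI-zip files via the `regions`
column.

A command-line wrapper with `analyze`, `batch`, `simulate` and
`evaluate` subcommands ships in `inst/cli/mitoshape`:

```sh
Rscript inst/cli/mitoshape batch --input-dir images/ --out-dir results \
    --pixel-size-um 0.065
```

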