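# tavimetrics

Automated morphometry of the aortic valvular complex for transcatheter
aortic valve implantation (TAVI) planning.

Planning a TAVI procedure requires a standard panel of geometric
measurements of the aortic root, taken today from CT angiography: annulus
area/perimeter/diameters (valve sizing; under-sizing risks paravalvular
leak, over-sizing annular rupture), LVOT metrics, sinus-of-Valsalva
diameters, sinotubular-junction diameters, and the coronary ostia heights
above the annulus plane (coronary-obstruction risk, especially below 10 mm
with narrow sinuses). `tavimetrics` computes all **22 measurements** from
two upstream artifacts — a closed triangular surface mesh of the aortic
root + left ventricle (mm, LPS) and five anatomical landmarks (left/right
coronary ostium, left/right/non-coronary leaflet nadir) — deterministically
and with QC flags for implausible geometry. It is aimed at researchers
building or validating automated TAVI-planning pipelines.

## Method core

With nadirs $n_{LC}, n_{RC}, n_{NC}$ and a lumen centerline $c(s)$
(extracted by Laplacian-based contraction of the mesh, with a
cross-section-marching fallback):

* **annulus plane**: through the three nadirs, origin at their centroid,
  normal toward increasing $s$; the plane–mesh intersection contour gives
  area $A$ (shoelace), perimeter $P$, centroid-chord $d_{min}, d_{max}$,
  $d_{avg} = (d_{min}+d_{max})/2$, $d_{area} = 2\sqrt{A/\pi}$,
  $d_{perim} = P/\pi$;
* **LVOT plane**: the annulus plane translated 4 mm down the centerline,
  normal unchanged (same 7 metrics);
* **area profile**: sections every 1 mm along $c(s)$ above the annulus;
  **SOV** = argmax of area, **SNTJ** = first station where the relative
  area change stays < 2% for 3 consecutive stations ($d_{min}, d_{max},
  d_{avg}$ there);
* **sinus diameters**: each nadir projected onto the SOV plane; the chord
  through the projection and the section centroid, measured boundary to
  boundary (LCC/RCC/NCC);
* **coronary heights**: perpendicular distance of each ostium to the
  annulus plane, $h = (p - o) \cdot \hat{n}$.

A parametric synthetic phantom with analytic ground truth
(`generate_phantom`), landmark-mask post-processing (binarize at 0.5,
largest 26-connected component, centroid, affine to LPS mm), and
expert-agreement statistics (CI with half-width $Z s / \sqrt{n-1}$, mean
absolute relative error, Pearson r with Fisher-z CI, Bland–Altman limits of
agreement) complete the toolbox. See the methods vignette
(`vignettes/aortic-root-morphometry.Rmd`) for assumptions, parameters and
numerical choices.

## Worked example

```r
library(tavimetrics)
ph <- generate_phantom(phantom_spec())   # synthetic root: 25 mm annulus,
                                         # 34 mm sinuses, LCH/RCH 14/12 mm
report <- run_pipeline(ph$mesh, ph$landmarks)
print(report)
#> <measurement_report> 22 measurements
#>   annulus.area                           489.601 mm^2
#>   annulus.perimeter                       78.469 mm
#>   annulus.diameter_min                    24.958 mm
#>   annulus.diameter_max                    24.988 mm
#>   annulus.diameter_avg                    24.973 mm
#>   annulus.diameter_area_derived           24.968 mm
#>   annulus.diameter_perimeter_derived      24.978 mm
#>   lvot.area                              406.320 mm^2
#>   ...
#>   sov.diameter_lcc                        30.984 mm
#>   coronary.height_left                    14.000 mm
#>   coronary.height_right                   12.000 mm
#>   QC flags: none
```

The phantom's analytic truth is `pi * 12.5^2 = 490.87` mm² annulus area and
exactly 14/12 mm coronary heights: the pipeline recovers the area within
0.3% (the residual is mesh polygonization) and the heights to machine
precision. `write_report(report, "case.json")` /
`write_report(report, "case.csv")` serialize the report;
`read_mesh()`/`read_landmarks()` ingest STL/PLY/OBJ/VTP meshes and landmark
JSON for real cases.

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "tavimetrics.R", package="tavimetrics"))') \
    measure --mesh root.stl --landmarks lm.json --out report.json
```

with subcommands `measure`, `phantom`, `landmarks-from-mask` and
`agreement` (exit codes: 0 ok, 2 input/validation error, 3 pipeline-stage
error).

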