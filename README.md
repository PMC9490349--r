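# percussr

Surface morphometry and assemblage statistics for percussive stone tools.

Primate archaeologists and Palaeolithic researchers characterise
nut-cracking hammerstones and anvils by the discrete impact pits on their
active surfaces. percussr takes a 3D surface scan of a tool (PLY/OBJ/XYZ
point cloud, coordinates in mm) and produces the standard quantitative
description of its percussive damage:

- **orientation** of the tool into the six-plane frame (maximum length on
  the Y axis, active Plane A facing up) and per-point plane assignment;
- **pit detection** by the topographic position index,
  `TPI(i) = z_i − mean{ z_j : ‖(x,y)_i − (x,y)_j‖ ≤ r }` with r = 20 mm;
  points with TPI below a noise-adaptive threshold form depression masks
  whose connected components, if longer than 10 mm, are discrete pits;
- **3D pit morphometrics**: depth as the signed distance to the tool's
  encompassing convex hull (mean and deepest-point), gradient as the mean
  local rise-over-run, and surface roughness in a 0.5 mm window;
- **2D planform measures**: active-surface outline (alpha shape), pit
  areas and minimum-area rotated bounding boxes, PA (% of the surface
  covered by pitting), pit density D (pits/cm²), DAC and DAE (distances of
  pit centres to the surface centre and nearest edge);
- **assemblage statistics**: min/max/mean/s.d. blocks, Mann–Whitney U
  (`U = min(U1, U2)`, exact two-sided p by enumeration for pooled n ≤ 12
  without ties), Kruskal–Wallis with tie correction, Dunn's post hoc with
  Bonferroni correction, and correlation-matrix PCA — the toolkit used to
  contrast hammerstones with anvils and one site's assemblage with
  another's.

The package ships the published per-tool tables of the Djouroutou (Taï
National Park, Côte d'Ivoire) chimpanzee nut-cracking assemblage — 11
hammerstones and 7 stone anvils — as fixtures, and a synthetic
surface/assemblage generator with known ground truth for validation.

## Worked example

```r
library(percussr)

# the packaged Djouroutou per-tool tables
tools <- load_djouroutou_tables()
describe_distribution(tools, max_length_mm, by = tool_type)
#> # A tibble: 2 × 7
#>   group      n n_missing   min   max  mean    sd
#>   <chr>  <int>     <int> <dbl> <dbl> <dbl> <dbl>
#> 1 anvil      7         0 210    1504  644. 433.
#> 2 hammer    11         0  93.1   315  224.  70.7

# hammerstone volume differs by nut species cracked
h <- dplyr::filter(tools, tool_type == "hammer")
kruskal_wallis(h, var = volume_cm3, group = nut_species)
#> <kruskal_wallis>
#>   H = 6.061, df = 2, p = 0.0483
#>   n: coula = 3, panda = 6, parinari = 2

# a synthetic granodiorite block with two known pits, analysed end to end
sp <- surface_spec(
  length_mm = 160, width_mm = 120, thickness_mm = 40,
  pits = tibble::tibble(x = c(-30, 25), y = c(-45, 30),
                        radius_mm = c(12, 15), depth_mm = c(4, 6)),
  raw_material = "GD", density_per_cm2 = 150, seed = 7)
surf <- generate_surface(sp)
res <- analyze_surface(surf$model, pipeline_config())

dplyr::select(res$pits, pit_id, depth_max_mm, gradient, roughness_mm,
              area_cm2, length_mm, dac_mm, dae_mm)
#> # A tibble: 2 × 8
#>   pit_id depth_max_mm gradient roughness_mm area_cm2 length_mm dac_mm dae_mm
#>   <chr>         <dbl>    <dbl>        <dbl>    <dbl>     <dbl>  <dbl>  <dbl>
#> 1 pit_01        -4.24    0.396       0.0229     2.76      20.6   54.6   28.5
#> 2 pit_02        -6.27    0.449       0.0246     4.08      25.5   40.2   33.8

dplyr::select(res$summary, n_pits, pa_percent, density_per_cm2,
              dac_mean_mm, dae_mean_mm)
#> # A tibble: 1 × 5
#>   n_pits pa_percent density_per_cm2 dac_mean_mm dae_mean_mm
#>    <int>      <dbl>           <dbl>       <dbl>       <dbl>
#> 1      2       3.88          0.0105        47.4        31.2
```

Both planted pits are recovered: the deepest-point depths (−4.24 and
−6.27 mm) match the carved depths of 4 and 6 mm up to the documented
hull-over-noise bias, the detected footprints sit 28–34 mm from the
nearest surface edge, and the two pits cover 3.9% of the 192 cm² active
face. `run_pipeline()` wraps the same chain over a whole assemblage and
writes per-pit, per-surface and hammer-vs-anvil comparison CSVs plus a
parameter-echo log; `compare_assemblages()` runs the Table-style
Mann–Whitney battery and a pooled PCA between two per-tool summary
tables; `autoplot()` methods and `plot_active_surface()` give ggplot2
views of TPI fields, detected pits and PCA scores.

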