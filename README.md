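# cubecyte

Cube-based spatial image cytometry for 3D (and 2D) fluorescence images of
biofilms and other structured microbial communities.

Biofilm images often cannot be segmented into single cells, yet their
*internal* organization — density gradients, reporter expression versus
depth, strain mixing, wrinkle morphology — is what matters biologically.
cubecyte segments the biomass (semantic segmentation: every voxel is
biomass or background), dissects the binary biovolume into a cubical grid
of user-defined edge length, and treats each occupied cube as a
pseudocell. Each cube carries a parameter vector (49 parameters with two
fluorescence channels: structural, textural, fluorescence and correlation
families), which supports flow-cytometry-style gating, user-defined
derived parameters, lineage tracking over time and spatiotemporal
kymographs. Whole-biofilm outputs include the COMSTAT-compatible
structure metrics

- biovolume `V`, maximum/mean thickness, substratum coverage,
- roughness coefficient `Ra* = (1/N) Σ_i |L_i − L̄| / L̄` over occupied
  column thicknesses `L_i`,
- face-counting surface area `A` and surface-to-biovolume ratio `A/V`,

voxel-level colocalization (Pearson, Manders overlap
`MOC = ΣA_iB_i / √(ΣA_i² ΣB_i²)`, Manders M1/M2, overlap fractions,
relative abundances) and 3D spatial correlation functions with
cluster-size (first 1/e crossing) and separation (first cross-correlation
maximum) summaries. Results export to CSV and legacy VTK files that load
directly into ParaView for 3D rendering. A seeded synthetic-colony
generator (hemispheres, slabs, wrinkled slabs, spheres, strain mixtures,
growth series) provides ground truth for every estimator.

Who it is for: microbiologists quantifying confocal stacks of biofilms,
colonies and aggregates, and method developers who need a scriptable,
reproducible cytometry backend with exact conservation guarantees.

## Worked example

```r
library(cubecyte)
g <- voxel_geometry(0.25, 0.25, 0.25)           # 0.25 um isotropic voxels
spec <- synth_spec("hemisphere", list(radius = 3), dim_zyx = c(16, 32, 32),
                   geometry = g, seed = 1)
mask <- make_colony(spec)                        # ground-truth biovolume
channels <- mix_strains(mask, c(0.5, 0.5), cluster_edge_um = 1, seed = 2)

grid <- build_cube_grid(mask, edge_um = 1)       # 1-um cubes (4^3 voxels)
tab  <- assign_voxels(mask, grid)
tab  <- quantify_cubes(tab, mask, channels)

length(cube_parameters(tab))
#> [1] 49
nrow(tab)
#> [1] 80
round(tab[1:3, c("fill_fraction", "dist_surface_um", "ch1_mean", "ch1ch2_moc")], 3)
#>   fill_fraction dist_surface_um ch1_mean ch1ch2_moc
#> 1         0.516           0.356      200          1
#> 2         0.875           0.515       10          1
#> 3         0.875           0.515      200          1
```

80 cubes of the hemisphere are occupied, each with 49 parameters: the
first cube is half-filled rim biomass 0.36 um below the outer surface,
dominated by strain 1 (mean 200 vs the dim level 10). The Manders overlap
is 1 within cubes where both channels are spatially constant.

```r
gm <- global_structure(mask)
gm[gm$metric %in% c("biovolume_um3", "mean_thickness_biomass_um",
                    "roughness_coefficient", "surface_to_biovolume_um_inv"), ]
#>                       metric      value units
#>                biovolume_um3 56.3125000  um^3
#>    mean_thickness_biomass_um  2.0111607    um
#>        roughness_coefficient  0.2854368
#>  surface_to_biovolume_um_inv  1.9889012  1/um

prof <- spatial_correlation(mask, NULL, dr_um = 0.5, rmax_um = 4)
metric_value(correlation_summaries(prof), "cluster_size_um")
#> [1] 1.917469
```

The digitized hemisphere's 56.3 um^3 biovolume is within 2% of the
analytic (2/3)πR³ = 56.5 um^3, and the autocorrelation decays below 1/e
at about 1.9 um — the hemisphere's characteristic cluster size at this
window.

A command-line driver wraps the same pipeline
(`segment`, `quantify`, `global`, `track`, `kymograph`, `export-vtk`,
`synth`, `all`) around a YAML configuration:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cubecyte.R", package = "cubecyte"))') \
    all --config run.yaml --seed 1
```

See `vignettes/cube-cytometry-methods.Rmd` for the conventions
(substratum handling, truncated cubes, texture quantization, correlation
estimators, tracking rules) and their rationale.

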