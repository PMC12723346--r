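# gridcodes

Design, simulation and machine reading of **coordinate-encoding fiducial
microgrids** for multimodal and correlative microscopy.

Relocating one cell across a fluorescence microscope, a confocal and an SEM
is hard: fields of view differ by orders of magnitude and the substrate
deforms during processing. A coordinate-encoding microgrid solves this by
microfabricating, into the sample substrate, a lattice of markers that each
encode their own grid coordinate as simple rectilinear geometry. Any one
marker in any field of view fixes the absolute position; two markers
calibrate an instrument stage; markers shared between two images are exact
correspondences for co-registration.

`gridcodes` implements the full desk-side toolchain:

* **codes** — encode grid coordinates (x, y) into marker geometry in four
  schemes: binary (the compact default: a chiral 7f x 7f "L" of bit squares
  plus an align mark, where f is the minimum feature size), ternary
  (stroke thickness as a third level), rectilinear seven-segment decimal,
  and the postal two-of-five bar scheme.
* **layout** — place codes on a pitch chosen from the bottleneck
  instrument's field of view (`select_spacing`), compute marker densities,
  and export photomask layouts as GDSII (1 nm database unit), SVG previews
  and layout JSON.
* **synthimg** — a parametric camera model (`render`, `ground_truth`):
  pixel scale, in-plane rotation, brightfield/darkfield/SEM polarity,
  Gaussian PSF, seeded noise, and substrate deformation fields.
* **decode** — classical machine-vision decoding (`detect_codes`):
  segmentation, blur-invariant pitch estimation, chirality-based
  orientation, blurred-template bit reading, sub-pixel align-corner
  positions, and a lattice-consistency filter.
* **navigate** — two-anchor stage calibration (`calibrate`): the scale
  factor s = |Δstage| / |Δgrid| is the substrate-deformation metric;
  affine and piecewise-affine models quantify anisotropic deformation.
* **register** — identity-based fiducial matching (`match_by_code`),
  least-squares similarity/affine transforms, and 50 %-transparency or
  colour-tinted overlays (`warp_and_overlay`).

## Worked example

```r
library(gridcodes)

spec <- grid_spec("binary", feature_size = 10, spacing = 500)
footprint(spec)
#> [1] 70 70            # 7 x the minimum feature: 6 bits + 1 align mark
marker_density(500)
#> per_mm2 per_cm2
#>       4     400       # one code in every 600 um bottleneck field of view

layout <- generate_grid(spec, extent = c(10000, 10000))
layout
#> grid_layout: 400 codes (binary, f = 10 um) on 500 um pitch over 10000 x 10000 um
write_gdsii(layout, "grid.gds")   # mask file, 1 nm database unit

# simulate a darkfield image of a 600 x 600 um region and decode it back
small <- generate_grid(grid_spec("binary", 10, 200), c(600, 600))
cam <- camera_model(pixel_size = 1, image_size = c(512, 512),
                    rotation = 25, translation = c(235, 235),
                    blur_sigma = 2, noise_sigma = 0.02)
img <- render(small, cam)
det <- detect_codes(img, decode_hints(small$spec, approx_pixel_size = 1))
det
#>   x_index y_index    px_row    px_col orientation_deg confidence
#> 1       0       1 188.89264  28.75133        24.90477          1
#> 2       1       1 273.38704 209.96559        24.84239          1
#> 3       2       1 358.03911 391.29070        24.90477          1
#> 4       1       2  92.20424 294.46776        25.01689          1
# decoded coordinates, sub-pixel align-corner positions, and the in-image
# rotation (the camera's 25 degrees, recovered)

# two-point stage calibration: scale factor 1.1 = 10 % substrate swelling
m <- calibrate(anchors(c(0, 2), c(0, 0),
                       stage_x = c(10, 10 + 1100 * cos(pi / 15)),
                       stage_y = c(20, 20 + 1100 * sin(pi / 15))),
               spacing = 500)
m
#> stage_mapping (similarity): theta = 12.0000 deg, scale = 1.100000 (sx 1.100000, sy 1.100000), t = (10, 20)
#>   reflection: FALSE, rms residual: 0
grid_to_stage(m, c(3, 4))   # stage position of code (3, 4)
#> [1] 1166.538 2514.979
```

A command-line wrapper with subcommands `mask`, `render`, `decode`,
`navigate`, `register` and `overlay` is installed at
`system.file("cli/ucodes", package = "gridcodes")`; see `?ucodes_cli`.

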