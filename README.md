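# semquant

Quantitative cell morphometry for calibrated scanning electron micrographs
(SEM). The package turns grayscale micrographs of cells into the descriptor
sets used across SEM-based cell biology:

- **Segmentation** — global thresholding (Otsu or manual), mask cleaning,
  connected-component cell instances with ordered outlines.
- **Bacterial rod morphometry** — per-cell length *L*, width *W*, aspect
  ratio *W/L*, projected area, spherocylinder model volume
  *V = (πW²/4)(L − W/3)*, model surface *S = πWL*, and the surface-to-volume
  ratio *S/V*.
- **Neuronal morphometry** — soma as the maximal inscribed disc, neurite
  tracing on the medial axis (count, average and maximum length, radial
  distance, straightness = length − radial distance), angular alignment
  classes (parallel < 15°, perpendicular > 75°, intermediate between),
  cell area *A*, perimeter *P*, circularity *C = 4πA/P²*, and
  differentiated-cell counting (a neurite at least one soma diameter long).
- **Fractal descriptors** — box-counting fractal dimension *D* (slope of
  log N(ε) vs log 1/ε) and gliding-box lacunarity
  *Λ(r) = var(M)/mean(M)² + 1*.
- **GLCM texture** — gray-level co-occurrence matrices and the Haralick
  descriptors: angular second moment, entropy, contrast, correlation,
  inverse difference moment; whole-image or sliding-window maps.
- **Synthetic fixtures** — seeded generators for rod populations, neuron
  silhouettes, exact fractal patterns, and analytic textures, each shipping
  its ground truth, so the entire pipeline is testable without external
  images.

All physical quantities carry µm units derived from a user-supplied
pixel-size calibration (SEM vendor metadata is ignored by design).

## Worked example

Generate a synthetic E. coli-like field, segment it, and measure every rod:

```r
library(semquant)

syn   <- gen_rod_population(50, length_range_um = c(2, 4), aspect = 0.25,
                            pixel_size_um = 0.02, seed = 1)
mask  <- binarize(syn$micrograph, "otsu")
cells <- label_instances(mask, connectivity = 8, exclude_border = TRUE)
pop   <- measure_population(cells, pixel_size_um = 0.02)
subset(pop$summary, descriptor %in%
       c("length_um", "width_um", "aspect_ratio", "volume_um3"))
```

```
    descriptor      mean          sd  n
1    length_um 3.1443754 0.548242859 50
2     width_um 0.7518249 0.135030980 50
3 aspect_ratio 0.2389460 0.007604388 50
5   volume_um3 1.4008628 0.672385697 50
```

The recovered mean aspect ratio (0.239) matches the generator's 0.25 within
measurement tolerance; volumes come from the spherocylinder model applied to
the per-cell *L* and *W*. A single neuron works the same way:

```r
syn <- gen_neuron(soma_radius_um = 6,
                  arms = list(c(30, 0, 0), c(40, 45, 0), c(50, 90, 0)),
                  pixel_size_um = 0.2)
res <- measure_neuron(label_instances(syn$mask)[[1]])
res$morph[, c("neurite_count", "max_neurite_length_um", "circularity")]
#   neurite_count max_neurite_length_um circularity
# 1             3               50.8737  0.06194211
```

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/semquant.R measure-bacteria \
    --input field.tif --pixel-size 0.02 --min-object 50 --out results/
```

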