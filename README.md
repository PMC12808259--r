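# gsrquant

Quantitative image analysis of gunshot residue (GSR) patterns on fabrics and
adhesive tape lifts.

When a firearm is discharged at close range, burned and unburned primer and
propellant particles settle on nearby surfaces — clothing above all. Forensic
examiners photograph these patterns (visible light for bright fabrics,
infrared through a long-pass filter for dark ones, where residue keeps its
contrast) or lift them with adhesive tape developed by the sodium-rhodizonate
colour reaction, and then need objective numbers: **how many** discrete
particles, and **how much area** they cover. Counting by eye is slow and
rater-dependent; `gsrquant` automates it and ships the statistics used to
evaluate rater agreement alongside.

## Method

For a photograph with intensities normalized to [0, 1]:

1. **Fabric suppression in the Fourier domain.** The 2-D FFT of the image is
   multiplied by a radially symmetric mask and inverted. Bright weaves
   (white cotton) get a **high-pass** filter that removes illumination
   gradients and coarse structure; patterned dark fabrics (denim) get a
   **band-pass** filter that additionally removes the high-frequency twill
   periodicity, keeping only the particle-scale band. Cutoffs are in cycles
   per image, so presets transfer across resolutions. The filtered image is
   affinely re-normalized to [0, 1].
2. **Dark-spot segmentation.** Pixels darker than a threshold (manual, or
   Otsu's between-class-variance criterion with a plausibility guard) become
   foreground.
3. **Particle counting.** Each maximal connected foreground region (8- or
   4-connectivity) is one particle; regions below a small pixel floor are
   discarded as noise.
4. **Physical area.** With the calibration *L*<sub>pixel</sub> (mm per
   pixel), each particle's area is

   *A* = (*L*<sub>pixel</sub>)² · *n*<sub>pixel</sub>

   and totals are reported both in pixels and mm².

Tape scans go through the HSV **value channel** (V = max(R, G, B), invariant
to the violet hue of the lead reaction) and then steps 2–4.

For visibility rating studies the package provides the 0–5 ordinal scale
(`none_visible` … `substantial`), the two-way mixed single-measures
intraclass correlation ICC(3,1) with the conventional agreement bands
(≥ 0.75 excellent, 0.60–0.75 good, 0.40–0.60 fair, < 0.40 poor), and
independent-samples t-tests (pooled or Welch) at α = 0.05.

Because forensic photographs are rarely shareable, a seeded synthetic scene
generator renders ground-truthed fabrics (weave, twill, illumination,
optional bullet defect and wet/dry blood with modality-correct contrast) and
tape scans, so the whole pipeline is testable end to end.

## Worked example

```r
library(gsrquant)

params <- scene_params("DENIM", n_particles = 200, seed = 13)
scene  <- simulate_scene(params)          # IR render + ground truth
scene$image$l_pixel <- 0.05               # calibration: 0.05 mm per pixel

result <- run_fabric_pipeline(scene$image)
result
#> <gsr_quant> 199 particles, 2964 foreground pixels (7.41 mm^2)
#>   filter = band_pass, threshold = 0.6855, min_pixels = 2, connectivity = 8

glance(result)
#> # A tibble: 1 × 7
#>   count total_pixels total_area_mm2 threshold min_pixels connectivity filter
#>   <int>        <int>          <dbl>     <dbl>      <int>        <int> <chr>
#> 1   199         2964           7.41     0.686          2            8 band_pass

detection_score(result, scene$truth)$f1
#> [1] 0.9974937
```

199 of the 200 planted particles are recovered (F1 = 0.997): the band-pass
filter flattens the twill and wash patches, Otsu finds the particle mode, and
the size floor drops isolated dark pixels. `tidy(result)` returns the
per-particle table (label, pixel count, centroid, bounding box, mm²);
`autoplot(result)` draws the detected pattern.

Rater statistics work from plain matrices or CSV files:

```r
ratings <- rating_matrix(cbind(c(4,2,5,1,3,4,0,2,3,5),
                               c(4,3,5,1,2,4,1,2,3,5),
                               c(5,2,4,1,3,3,0,1,3,4)))
icc_two_way_mixed_single(ratings)
#> ICC = 0.9004 (excellent)
#> two-way mixed, single measures, consistency (ICC(3,1))
#> 10 subjects, 3 raters
```

## Command line

A thin launcher lives at `inst/cli/gsrquant` (installed under
`system.file("cli", "gsrquant", package = "gsrquant")`):

```sh
gsrquant simulate --fabric denim --n 200 --seed 13 -o scene/
gsrquant count scene/scene.png --fabric denim --l-pixel 0.05 -o particles.csv
gsrquant tape  tape_scan.png --json tape.json
gsrquant icc   ratings.csv
gsrquant ttest groupA.csv groupB.csv --welch
```

Per-fabric parameters (filter band, threshold, size floor, connectivity) can
be kept in a YAML config (`--config analysis.yaml`); flags override the file.

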