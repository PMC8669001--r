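# nucquant

Quantification of nuclear architecture, gene-locus positioning and focal
adhesions in multi-channel fluorescence microscopy, with a synthetic
phantom generator that provides exact ground truth for every stage.

## What it measures, and for whom

Depleting nuclear-envelope components (nucleoporins, LINC-complex
proteins) redistributes heterochromatin away from the nuclear periphery,
repositions gene loci, and blunts the mechanoresponse of the cell. These
phenotypes are read out from images, as per-object measurements that are
then compared nonparametrically between conditions. `nucquant` implements
that measurement chain for cell biologists who have segmentable
2D fields or Z-stacks and want reproducible, scriptable numbers instead
of point-and-click analysis:

- **Periphery/total intensity ratio.** The nucleus is segmented from the
  DNA stain; the *peripheral band* is the region within
  `f · r_eq` of the nuclear edge (default `f = 0.25`, with
  `r_eq = sqrt(area/π)` the equivalent radius), measured on the Euclidean
  distance transform. For a marker channel (H3.1/3.2, H3K27me3, SUN2,
  lamins, ...) the readout is
  `mean intensity in band / mean intensity in whole nucleus` — exactly 1
  for a uniform nucleus, above 1 for peripherally enriched marks.
- **Heterochromatic-foci/total ratio.** Bright chromocenter-like DNA
  foci are segmented per nucleus (white top-hat + Otsu) and the analogous
  mean-intensity ratio is reported.
- **FISH spot positioning.** Spots are detected by Laplacian-of-Gaussian
  filtering with subpixel refinement. Each spot gets (i) a
  size-normalized *relative radial position*
  `r = d(centroid, spot) / d(centroid, boundary along the same ray)`
  in [0, 1], reported per condition as cumulative distribution
  frequencies, and (ii) its distance to the nearest heterochromatic
  focus, via a distance map of the focus mask (anisotropy-aware in 3D).
- **Focal adhesions.** The adhesion channel (e.g. p-FAK) is band-pass
  filtered with a difference of Gaussians, thresholded per cell at
  `mean + k·SD` of the response, and adhesions are counted and measured
  per cell together with the cell-spreading area from the cell-body
  (phalloidin) mask.
- **Statistics.** Two-group comparisons use the two-tailed Mann–Whitney
  U test (exact enumeration for small tie-free samples, tie-corrected
  normal approximation otherwise); three or more groups use
  Kruskal–Wallis with Dunn's post-hoc z-tests and Bonferroni adjustment.
  Summaries report median, IQR and per-group n, as figure legends do.

Because real micrographs for such studies are rarely deposited, the
package ships a first-class phantom generator: elliptical nuclei with a
controllable fraction `f_p` of marker signal in the peripheral band,
discrete DNA foci, FISH spots placed at exact relative positions, cells
with punctate adhesions, Poisson–Gaussian noise, and two-condition
(control vs perturbed) experiments with known effect sizes. Every
measurement is validated against this ground truth.

## Worked example

A two-condition experiment in which the perturbed population keeps only
30% (vs 60%) of its marker signal in the peripheral band:

```r
library(nucquant)

ctrl <- phantom_spec(n_nuclei = 3, peripheral_fraction = 0.6)
pert <- phantom_spec(n_nuclei = 3, peripheral_fraction = 0.3)
ds   <- generate_two_condition_experiment(ctrl, pert, n_fields = 4, seed = 42)

cfg <- pipeline_config(lapply(ds, `[[`, "field"),
                       channels = list(dna = "dna", markers = "marker"))
res <- run_pipeline(cfg)
res
#> PipelineResult: 72 measurement row(s), 3 comparison(s), 0 field error(s)
#>   config hash: 6916fcd5d01f29958faae2119c09f767

res$comparisons$periphery_total_ratio_marker
#> ComparisonResult [periphery_total_ratio_marker]
#>   control: n = 12, median = 1.287, IQR = [1.275, 1.299]
#>   perturbed: n = 12, median = 0.695, IQR = [0.6839, 0.7169]
#>   two-tailed Mann-Whitney U (normal approximation): statistic = 144, p = 3.658e-05
```

The control nuclei show a periphery/total ratio above 1 (peripheral
enrichment), the perturbed nuclei fall below 1 (signal displaced to the
interior), and the Mann–Whitney test on the 12 nuclei per condition
rejects equality — the direction and reporting style used for
per-nucleus intensity-ratio figures. `run_pipeline()` also writes
`measurements.csv`, `comparisons.csv`/`.json` and a run log when
`output_dir` is set, and every measurement row carries the config hash
for provenance.

Individual stages are available as plain functions
(`segment_nuclei()`, `partition_periphery()`, `periphery_total_ratio()`,
`detect_spots()`, `relative_radial_position()`,
`distance_to_nearest_focus()`, `dog_bandpass()`, `segment_adhesions()`,
`mann_whitney_two_tailed()`, ...) for use outside the pipeline, and
fields round-trip to multi-page TIFF with a YAML metadata sidecar via
`write_field()` / `read_field()`.

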