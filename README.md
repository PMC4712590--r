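# rgfbreast

Classification of fibroglandular tissue (FT) distribution in breast CT
from radial glandular fraction (RGF) texture features.

Breast FT can be centrally condensed ("non-sparse") or scattered in
small islands ("sparse"). The pattern — distinct from the overall
fibroglandular composition (FC) — matters for tissue segmentation and
biomechanical modelling in adaptive breast radiotherapy, where sparse
breasts are the hard cases. `rgfbreast` measures the pattern from a CT
volume with breast and FT masks and classifies it:

1. **Reorientation.** The supine axial volume is resampled to cubic
   1 mm voxels and rotated about the superior–inferior axis by the
   nipple angle, so the breast axis points anteriorly and coronal
   slices are comparable across patients.
2. **RGF curves.** For a coronal slice with area-equivalent breast
   radius R (πR² = breast area), RGF(r) is the fraction of FT pixels on
   the circle of radius rR centred at the slice's centre of mass,
   sampled at r = 0.01, …, 1. The breast is divided into posterior,
   middle and anterior thirds, each summarized by the mean RGF over
   five slices around the region's central slice. Non-sparse breasts
   give decaying curves (high at r = 0, low at r = 1); sparse breasts
   give flat ones.
3. **Features.** Thirteen statistics per region curve (mean, SD,
   regression slope vs r, position of the maximum, min/max/range,
   inner/outer-half means and difference, highest/lowest-10 % means
   and difference).
4. **Statistics.** Two-sided Wilcoxon rank-sum tests per feature (and
   for FC) between the sparse and non-sparse groups.
5. **Classification.** Leave-one-out SVMs (C = 1) with linear,
   polynomial (order 3), RBF (σ = 1) and sigmoid kernels, per region
   and for all three regions combined.

Because clinical datasets of this kind cannot be redistributed, the
package includes a phantom generator (`generate_phantom()`,
`generate_cohort()`) producing breast-shaped label volumes with
controllable FT patterns, used throughout the tests and the worked
examples. Volumes are read and written as NIfTI with a JSON landmark
sidecar; feature tables as CSV.

## Worked example

```r
library(rgfbreast)

# a non-sparse phantom, tilted 12 degrees off the anterior axis
v <- generate_phantom(phantom_spec(ft_mode = "nonsparse",
                                   nipple_offset_deg = 12, seed = 3))
v
#> <labeled_volume> 96 x 88 x 112 voxels @ 1 x 1 x 1 mm
#>   breast voxels: 226268; FT voxels: 56567 (FC = 0.250)
#>   nipple voxel: [49, 16, 69]

nipple_angle(v)      # recovers the constructed tilt
#> [1] 12.06

ob <- preprocess_volume(v)           # resample + rotate
curves <- subject_rgf(ob)            # RGF per region
round(compute_features(curves$middle), 3)
#>         mean_rgf           sd_rgf            slope         r_at_max
#>            0.471            0.470           -1.475            0.010
#>          min_rgf          max_rgf        range_rgf     mean_inner50
#>            0.000            1.000            1.000            0.917
#>     mean_outer50 diff_inner_outer       mean_top10    mean_bottom10
#>            0.025            0.893            1.000            0.000
#>  diff_top_bottom
#>            1.000
```

The FT is condensed at the centre: the curve falls from 1 to 0
(slope −1.48), the inner half mean (0.92) dwarfs the outer (0.03).
A full study — 15 non-sparse and 8 sparse phantoms through the whole
pipeline — takes about half a minute:

```r
study <- run_study(n_nonsparse = 15, n_sparse = 8, seed = 1)
study$experiment
#> <rgf_experiment> leave-one-out accuracy
#>            kernel
#> region_set  linear polynomial   rbf sigmoid
#>   all            1          1 0.957       1
#>   anterior       1          1 0.957       1
#>   middle         1          1 1.000       1
#>   posterior      1          1 1.000       1

subset(study$tests, feature == "FC")
#>  region feature mean_nonsparse mean_sparse   p_value significant
#>  breast      FC      0.2453272   0.2490574 0.6355234       FALSE
```

The two phantom groups differ in pattern, not composition: the FC test
is non-significant while the pattern features separate the groups
(`study$tests` lists all 13 per region with group means and p-values).

A command-line front end for the individual stages (simulate,
preprocess, segment, rgf, features, stats, classify, run-all) is in
`inst/cli/rgfbreast.R`; see its header for usage and the YAML
configuration keys.

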