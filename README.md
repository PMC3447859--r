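# ihcquant

Reproducible quantification for antitumor-peptide studies that score
DAB-immunostained tumor sections and the standard cell-based assays around
them. The package has three layers:

1. **`ihcseg`-style stained-area segmentation** — a brightfield pipeline for
   DAB (3,3′-diaminobenzidine, brown positive signal) over a hematoxylin
   (blue nuclear) counterstain: flat-field illumination correction,
   hue-sector suppression of non-specific color, an *adaptive red–blue stain
   contrast* `C = αR − (1−α)B` whose weight α is optimized per field,
   difference-of-Gaussians band-pass background removal, isodata (intermeans)
   automatic thresholding, 8-connected component labeling, and a final
   red/blue color sort that rejects artifacts. The output is the positive
   stained area (px, µm², area fraction) and object counts per field.
2. **Assay statistics** — four-parameter logistic (4PL) dose–response fitting
   with closed-form GI50 inversion
   (`y(x) = bottom + (top − bottom)/(1 + (x/ec50)^(−hill))`, GI50 = the dose at
   half the untreated-control response), LDH-release percent cytotoxicity
   (`100·released/total`), caliper tumor volume (`V = 4/3·π·R₁²·R₂`, R₁ ≤ R₂),
   percent inhibition / percent-of-control normalization, and the unpaired
   two-tailed Student t-test with the conventional star code
   (`*` p<0.05, `**` p<0.01, `***` p<0.001).
3. **A synthetic-data module** — ground-truthed immunohistochemistry fields
   (stained blobs + nuclei + uneven illumination + noise) and tabular assay
   datasets (4PL counts, LDH plates, lognormally dispersed xenograft growth,
   Poisson colony counts) with *named presets* encoding realistic effect
   sizes, so the whole analysis chain can be validated against known truth.

It is aimed at researchers who quantify immunostained sections with scripted
image analysis and want the surrounding assay arithmetic, statistics and
validation data in one tested, pipeable toolbox. All user-facing functions
take data frames first and return tibbles; fitted objects support
`tidy()`/`glance()`/`autoplot()`.

## Worked example

Generate a six-fields-per-group synthetic study whose ground truth encodes a
36% decrease in proliferation-marker area, segment every field with the
default configuration, and summarize:

```r
library(ihcquant)
library(dplyr)
library(purrr)

study <- generate_ihc_study("ki67-fig3c", n_fields_per_group = 6, seed = 42,
                            width = 256, height = 256)
quant <- map2_dfr(study$field, study$group,
                  \(f, g) mutate(tidy(segment_field(f)), group = g))
head(quant, 3)
#> # A tibble: 3 × 9
#>   field_id   alpha threshold area_px area_um2 fraction objects rejected group
#>   <chr>      <dbl>     <int>   <int>    <dbl>    <dbl>   <int>    <int> <chr>
#> 1 control-01   0.3       123   14577    3644.    0.222      14        0 control
#> 2 control-02   0.3       125   15560    3890     0.237      22        0 control
#> 3 control-03   0.3       127   15575    3894.    0.238      18        0 control

quantify_section(quant, group, control = "control")
#> <section_summary>
#>   area_fraction  control 0.2319 vs treated 0.1527: change -34.1% (p = 4.21e-07 ***)
#>   area_um2       control 3799 vs treated 2502: change -34.1% (p = 4.21e-07 ***)
#>   object_count   control 19.5 vs treated 17.17: change -12.0% (p = 0.263 ns)
```

Each field reports the optimized contrast weight (`alpha`, here 0.30 — the
weighting that nulls the achromatic background and separates DAB from the
counterstain), the isodata threshold on the 8-bit contrast image, and the
positive area; the section summary recovers a −34.1% change in stained area
against the 36% encoded in the preset (the residual gap is per-field
biological jitter at n = 6).

Dose–response fitting and GI50, on noisy synthetic counts generated around a
true GI50 of 1.24 µM:

```r
d <- generate_dose_response(fourpl(bottom = 0, top = 1000, ec50 = 1.24, hill = -1.5),
                            doses = c(0, 0.1, 0.3, 1, 3, 10, 15), cv = 0.1, seed = 8)
fit <- fit_4pl(d, dose_uM, count)
fit
#> <fourpl_fit> bottom -44.92, top 1017, ec50 1.13 uM, hill -1.09 (SSE 7.046e+04, n 21)
gi50(fit, mean(d$count[d$dose_uM == 0]))
#> [1] 1.058898
```

`run_pipeline(run_config(seed = 4), "out/")` runs the whole chain (simulate →
quantify → fit → summarize → report) into a run directory with a config echo,
per-field CSVs and a plain-text report; identical configurations give
byte-identical outputs.

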