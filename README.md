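# phaquant

Single-cell quantification of polyhydroxyalkanoate (PHA) storage granules
from multi-channel epifluorescence micrographs, with growth-cycle yield
metrics for methanotrophic enrichment cultures.

Type II methanotrophs such as *Methylocystis* convert CH₄ into
intracellular PHA granules — an energy store and a promising bioplastic.
Estimating how much PHA a mixed community holds, cell by cell, can be done
from three co-registered fluorescence channels: a nucleic-acid stain (DNA,
for cell counting), a membrane stain (cell outlines) and a PHA-granule
stain. `phaquant` implements that measurement chain for microbiologists
working on CH₄-fed PHA accumulation, together with the surrounding batch
growth-cycle arithmetic (substrate consumption, carbon- and nitrogen-based
cell yields) and a synthetic micrograph generator that makes the whole
pipeline testable against known ground truth.

## The measurement chain

For each channel, pixels are binarized with a **Bernsen adaptive local
threshold** over a circular window of radius *r*: with local extrema
`max`, `min` of the window, contrast `c = max − min` and midgray
`m = (max + min)/2`, a high-contrast pixel (`c ≥ c₀`) is object iff its
intensity exceeds *m*; a low-contrast window is assigned wholesale by
comparing *m* against a fixed cut. Binary masks go through **particle
analysis**: 8-connected components with per-particle area, centroid,
bounding box, and size/border filters. Each PHA particle is assigned to
the membrane-defined cell containing its centroid (falling back to maximal
pixel overlap).

Per cell, with membrane cross-sectional area `A` and assigned granule
areas `aᵢ`:

- area fraction `f = min(1, Σaᵢ / A)`
- volume fraction, sphere assumption: `v = f^{3/2}` (aggregate, default)
  or `v = Σaᵢ^{3/2} / A^{3/2}` (per granule)
- mass fraction, density-ratio mixture with ρ = 1.099:
  `w = ρv / (ρv + 1 − v)`

The sample statistic *percent of cells with detectable PHA* divides the
number of membrane cells with ≥ 1 assigned granule by the DNA-channel cell
count (the membrane stain does not mark every cell, so the two channels are
deliberately mixed).

Growth-cycle metrics convert headspace CH₄ percentages to grams of
CH₄-carbon by the ideal gas law, dissolved NH₄⁺ to grams of nitrogen, and
report consumed fractions and cell yields (cells gained per gram consumed).

## Worked example

Simulate a realistic field (50 coccoid cells, 40% bearing 1–2 polar
granules, ~12% true per-cell PHA mass fraction) and quantify it:

```r
library(phaquant)

scene <- generate_scene(scene_config(seed = 1))
field <- quantify_field(scene$dna, scene$membrane, scene$pha,
                        quantify_config(conversion = conversion_params(
                          volume_model = "per_granule")))
summarize_sample(list(field))
#> <sample_summary> 1 image(s), 50 DNA cells, 20/50 membrane cells with PHA
#>   percent cells with PHA: 40.0%
#>   mean PHA content (PHA-positive cells): 11.91% (m/m)

truth_summary(scene$truth)$mean_true_mass_fraction_pct
#> [1] 11.94531
```

The pipeline recovers the generator's truth (40% of cells bearing granules;
11.95% true mean mass fraction) to within a few tenths of a percent.

Enrichment arithmetic on printed per-core values works the same way:

```r
mean_sd(c(13.47, 9.27, 14.95), "population")
#>  mean    sd
#> 12.56  2.41
normalized_pha_content(12.56, 47.6)   # PHA content per methanotroph biomass
#> [1] 26.4
yield_ratio(128.81e6, 10.12e6)        # low- vs high-resource C-based yield
#> [1] 12.7
```

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/scripts/phaquant.R simulate --seed 1 --out sim/
Rscript inst/scripts/phaquant.R quantify --dna sim/dna.tif \
    --membrane sim/membrane.tif --pha sim/pha.tif --out quant/
```

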