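---
title: "Quantifying single-cell PHA content from fluorescence micrographs"
author: "phaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell PHA content from fluorescence micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaquant)
```

## The measurement problem

Bacteria that accumulate polyhydroxyalkanoate (PHA) store it as discrete
intracellular granules. In mixed communities — for instance methanotrophic
enrichments where a *Methylocystis*-type population does the storing — a
bulk measurement such as gas chromatography reports one number for the
whole biomass. Epifluorescence imaging of triple-stained cells (a
nucleic-acid stain for every cell, a membrane stain for cell outlines, a
granule stain for PHA) resolves the same quantity cell by cell: which
cells store at all, and how much of each storer's mass is polymer.

`phaquant` implements this image-based measurement as a deterministic,
configurable pipeline, and pairs it with a synthetic scene generator so
every stage can be validated against known ground truth.

## Segmentation: Bernsen local thresholding

Each channel is binarized independently with Bernsen's adaptive local
method. For a pixel $p$, let $I_{\max}, I_{\min}$ be the intensity extrema
over the circular window of radius $r$ centred at $p$ (windows are clipped
at image borders — no synthetic padding intensities are invented), and let
$c = I_{\max} - I_{\min}$ and $m = (I_{\max} + I_{\min})/2$. Then

- if $c \ge c_0$ (high contrast): $p$ is object iff $I(p) > m$ (strict);
- if $c < c_0$ (low contrast): the whole neighbourhood is treated as
  uniform, and $p$ is object iff $m \ge \ell$.

Defaults $r = 15$ px, $c_0 = 15$, $\ell = 128$ follow the widely used
reference implementation of the method; they are exposed per channel in
`quantify_config()` because the appropriate values depend on
magnification and staining intensity. Because $m$ is a half-integer, all
comparisons are carried out on $2m = I_{\max} + I_{\min}$ in integer
arithmetic — no floating-point rounding enters the decision. 16-bit input
is min–max rescaled to the 8-bit range first, since $\ell$ is defined on
that scale.

**Setting the contrast threshold on noisy images.** In a flat region,
additive noise of standard deviation $\sigma$ makes the local range
$I_{\max} - I_{\min}$ over a radius-15 window concentrate around
$6.5\sigma$ (the expected range of ~700 Gaussian draws). If $c_0$ falls at
or below this, flat background flips into the high-contrast branch and
roughly half its pixels become object — dense speckle that connects into
large spurious components. The rule is therefore: choose
$c_0 > 6.5\sigma$ (plus a margin for quantization) while keeping it well
below the object-to-background contrast. The package's validation runs on
noisy scenes use $c_0 = 40$ for $\sigma = 2$; on noiseless scenes this
changes nothing relative to the default 15, because local contrast there
is either ~0 (flat) or the full edge contrast.

## Particle analysis and granule-to-cell assignment

Object pixels are grouped into 8-connected components (the convention of
the standard particle-analysis tooling this mirrors), measured (pixel
area, centroid, bounding box, border contact) and filtered by area and
optional border exclusion. Survivors are relabelled $1..n$ in raster order
of their first pixel, which makes labels reproducible. Default filters
(cells ≥ 20 px, granules ≥ 4 px) suppress single-pixel artifacts at the
scale of the synthetic defaults; at other magnifications they should be
rescaled with object size.

Each PHA particle is assigned to the membrane-channel cell whose region
contains its centroid (rounded to the nearest pixel). If the centroid
lands on background — possible for crescent-shaped or blurred particles —
the cell with maximal pixel overlap wins; ties break to the lowest cell
label, and zero overlap leaves the particle unassigned. The procedure is
deterministic.

## From area to volume to mass

For a cell of membrane cross-section $A$ px with assigned granule areas
$a_i$:

$$f = \min\left(1, \frac{\sum_i a_i}{A}\right), \qquad
  v = f^{3/2}, \qquad
  w = \frac{\rho v}{\rho v + (1 - v)}, \quad \rho = 1.099.$$

The volume step assumes both the cell and the PHA cross-sections are
equatorial sections of spheres: a cross-section of area $A$ implies volume
$\tfrac{4}{3}\pi (A/\pi)^{3/2}$, and the ratio collapses to $f^{3/2}$.
The mass step treats the cell as a two-component mixture of PHA (relative
density $\rho$) and non-PHA biomass; unlike the linear form $w = \rho v$
(available via `mass_model = "linear"`), the mixture form satisfies
$w(1) = 1$ exactly and is bounded in $[0, 1]$.

**Aggregate versus per-granule conversion.** Applying the sphere
assumption to the *summed* granule area (the default,
`volume_model = "aggregate"`) is the natural reading of "fraction of
membrane area occupied by PHA, converted to volume" — but it is biased
when a cell holds several granules: $k$ equal granules of area $a$ give
$(ka/A)^{3/2} = \sqrt{k}\, \cdot k\,a^{3/2}/A^{3/2}$, i.e. a $\sqrt{k}$
overestimate of the true combined sphere volume (+41% for the typical
two-granule cell). The `per_granule` alternative
$v = \sum_i a_i^{3/2} / A^{3/2}$ is exact for spherical granules and is
what the package's own recovery validation uses; the $\sqrt{2}$ ratio
between the two models is itself asserted in the test suite. For real
images the choice is a documented trade-off: `aggregate` is robust to a
single granule fragmenting under thresholding, `per_granule` is unbiased
for genuinely separate granules.

## Sample statistics

The headline statistic, *percent of cells with detectable PHA*, divides
PHA-positive membrane-channel cells by the DNA-channel cell count. The
two channels are mixed on purpose: the membrane stain does not produce
signal for every organism in a mixed community, while the DNA stain does,
so the DNA count is the honest denominator. The ratio can therefore
exceed 100% if segmentation under-counts DNA objects; such values are
flagged with a warning, never silently clipped. Fields are pooled at the
count level (not averaged per field), and the mean single-cell PHA mass
fraction is reported over PHA-positive cells, with an all-cells mean
alongside.

## The synthetic generator

`generate_scene()` renders fields of non-overlapping coccoid cells with
0–2 polar granules into three co-registered 8-bit channels: whole-cell
disks in DNA and membrane, granule disks in PHA, then Gaussian PSF blur,
then per-pixel noise (none, additive Gaussian, or Poisson shot noise).
Granule centres sit at $\min(0.6R, R - r_g)$ from the cell centre along a
random axis, one per pole — the clamp keeps large granules fully inside
the cell. Cell placement is rejection sampling with a minimum
edge-to-edge gap (default 6 px) so blur cannot merge neighbours; an
infeasible packing fails with an explicit error after bounded retries.

Defaults describe the morphology the pipeline targets: a 512×512 field of
50 cells with radius 20 ± 2 px, granule-bearing fraction 40% (one granule
with probability 0.1, two with 0.3 — storers mostly carry two), granule
radius 8 px, interiors at ~180 over background ~20, PSF σ = 1.2 px. With
these numbers the mean true mass fraction over granule-bearing cells is
≈ 12% (m/m), matching the regime the defaults are meant to emulate. Truth
records are three-dimensional: the true volume fraction is
$\sum r_g^3 / R^3$ from sphere volumes, *not* the projected area ratio, so
validation measures the whole chain including the sphere assumption
itself.

What the generator deliberately does **not** model: rod-shaped or
irregular cells, touching/clumped cells, uneven illumination, stain
bleed-through between channels, membrane stains that miss cells, and
focus drift. Passing the recovery tests therefore demonstrates
correctness of the measurement chain on well-behaved fields, not
robustness to every pathology of real micrographs — on real data the
filters and thresholds must be tuned, and touching cells remain a known
failure mode (no watershed splitting is attempted).

## Growth-cycle metrics

`growth_cycle_yields()` implements the batch-bottle arithmetic for
methanotrophic enrichments. Headspace CH₄ percentages convert to grams of
CH₄-carbon by the ideal gas law, $n = (p/100)\,PV/(R_gT)$ with
$R_g = 0.082057$ L·atm·mol⁻¹·K⁻¹ and defaults $P = 1$ atm, $V = 110$ mL
headspace, $T = 303.15$ K (a 160-mL serum bottle with 50 mL of medium at
30 °C). Dissolved NH₄⁺ converts via mM × liquid volume × 14.007 g N/mol.
Consumed fractions are $(\text{initial} - \text{final})/\text{initial}$,
clipped to $[0,1]$ with a warning on negative values (measurement
fluctuation). Yields are cells gained per gram consumed, on a total-bottle
cell basis (cells·mL⁻¹ × liquid volume); note that yield *ratios* between
conditions are invariant to that basis choice.

Two reporting conventions are worth making explicit. `mean_sd()` defaults
to the population (divisor-$n$) standard deviation, the convention that
reproduces the reference summary "12.6% ± 2.4%" from its three per-core
values (the sample SD gives 2.9); both modes are exposed.
`normalized_pha_content()` divides a community-level PHA content by the
methanotroph relative abundance, estimating the storers' own PHA content
under the assumption that essentially all PHA resides in that population —
e.g. 12.56% community PHA at 47.6% methanotrophs ⇒ 26.4% per methanotroph
biomass.

## Numerical and design choices

- **Exact midgray comparisons.** All Bernsen decisions are integer
  comparisons on $2m$; the implementation (row-segment sliding extrema,
  $O(nr)$) is tested for exact pixel equality against a naive
  $O(nr^2)$ window scan.
- **Window clipping.** Border windows shrink rather than pad; no
  intensities are invented at edges.
- **Determinism.** Labels are raster-ordered; assignment ties break to the
  lowest label; the generator restores the caller's RNG state and is fully
  reproducible from (config, seed); provenance files carry config, seed
  and package version but no timestamps, so identical runs are
  byte-identical.
- **Degenerate inputs.** Empty images error at construction; all-zero
  channels yield empty results rather than errors; zero DNA counts make
  the percent statistic `NA` at field level and an error at sample level;
  granule-free truths flag the undefined mean instead of returning 0.
- **Validation problem sizes.** The recovery study uses 20 scenes × 50
  cells (10 noiseless, 10 with Gaussian σ = 2), pooled to 1,000 cells;
  oracle-equivalence checks use 100 random images up to 32×32 for
  thresholding and 50 random masks for labelling. At these sizes the full
  suite and the acceptance script each complete in well under five
  minutes on a single CPU.

## Known limitations

- The sphere assumption is exactly that; for non-spherical cells or
  granules both volume models are biased in ways the generator cannot
  reveal.
- No registration is performed: channels are trusted to be co-registered.
- Mixed denominators (membrane numerator, DNA denominator) make the
  percent statistic sensitive to differential staining efficiency between
  channels; values are flagged, not corrected.
- Bulk chemical validation (e.g. GC) of image-based content on real
  samples is outside what synthetic scenes can establish; the package
  ships the arithmetic, the user must ship the micrographs.
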