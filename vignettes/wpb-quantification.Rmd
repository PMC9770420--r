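---
title: "Counting Weibel-Palade bodies: the model behind wpbquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting Weibel-Palade bodies: the model behind wpbquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpbquant)
```

## The scientific problem

Weibel-Palade bodies (WPBs) are the rod-shaped secretory organelles in which
endothelial cells store von Willebrand factor (VWF): roughly 0.1-0.3 um in
diameter and 1-5 um long. Their abundance responds to the state of the
monolayer — confluent endothelial cultures carry more WPBs per cell than
sparse ones — so any quantitative comparison of WPB content must control for
confluency and for how confluency was reached (seeding density versus
incubation time).

`wpbquant` implements the complete quantification chain for such
experiments:

1. **Synthetic imaging** (`scene_spec()`, `render_field()`,
   `simulate_experiment()`): ground-truthed two-channel z-stacks standing in
   for DAPI/anti-VWF confocal data, plus whole simulated experiment designs.
2. **Segmentation** (`count_field()` and its stages): the classic
   FIJI-macro recipe — channel split, auto-contrast, 8-bit conversion,
   auto-threshold, particle analysis with area and circularity filters —
   yielding nuclei and WPB counts per field.
3. **Quantification** (`summarize_slide()`, `assign_cohorts()`): the
   per-slide statistic WPB/nuclei, confluency classification, and cohort
   assembly.
4. **Growth statistics** (`interval_doubling_time()`,
   `fit_growth_regression()`, `slopes_equal_test()`, `one_way_anova()`,
   `paired_t_test()`): doubling times and the comparison tests.

Because no public image set accompanies this kind of experiment, the
synthetic generator is a first-class, tested component: it defines the
conditions under which the pipeline's accuracy claims are made.

## The imaging model

A scene renders three object classes into two channels:

* **Nuclei** — filled ellipses with semi-axes drawn from 4-8 um, in the
  DAPI channel.
* **Mature WPBs** — capsules (a rectangle with semicircular caps, matching
  the rod-like, cylindrical morphology) with lengths 1-5 um and diameters
  0.1-0.3 um, in the VWF channel.
* **Immature vesicles** — small discs (0.25-0.45 um radius, always below
  0.5 um), also in the VWF channel. These are the designed target of the
  circularity filter.

Each object is brightest at its own `z_center` slice with a Gaussian axial
fall-off (`z_sigma_um`, default 0.5 um for VWF objects; nuclei are optically
thicker at 1.5 um). Stacks default to 23 slices at a 0.3 um step. Lateral
blur is modeled as a Gaussian edge profile of `psf_sigma_um` (default
0.15 um, the sigma corresponding to a diffraction-limited ~0.35 um FWHM at
high NA); a full 3-D PSF, spectral bleed-through and photobleaching are
deliberately out of scope.

**Radiometric convention.** Object intensities are peak-normalized: after
the lateral blur model every object's in-focus peak is ~1.0 above
background. This keeps "signal-to-noise ratio" well defined even for rods
thinner than a pixel, as `SNR = 1 / noise_sd`. The default `noise_sd = 0.1`
(SNR 10) represents good confocal acquisition; the package's accuracy
claims are made at that level. Per-slice Gaussian noise is added and
intensities clamp at zero.

**Placement.** Objects never overlap. VWF objects are placed by rejection
sampling with a minimum surface-to-surface clearance (`min_separation_um`,
default 0.4 um — just above the lateral resolution limit, so "separate
objects" in the ground truth remain separable in the image). Nuclei use a
jittered grid: one nucleus per randomly chosen grid cell, radii capped so
the footprint plus margin fits the cell. This emulates the packing of
contact-inhibited monolayers (nuclei in crowded fields draw from the small
end of the radius range) and guarantees placement feasibility up to high
densities. When a requested count cannot be placed within
`max_place_retries`, the scene errors out rather than silently overlapping
objects — extremely dense designs (e.g. fully confluent ECFC fields at
~95 WPB/cell) can hit this capacity, which is a documented limit of the
non-overlap assumption.

**Geometry defaults.** Single-field benchmarks use 1024 x 1024 px at
0.11 um/px (Nyquist-level sampling at 60X/1.0 NA). Simulated *experiments*
default to 0.25 um/px at 1024 px, i.e. a ~256 um field of view: that is the
geometry under which the conventional confluency cutoffs (51 HUVEC / 75
ECFC cells per field, standing for ~80% surface coverage) are numerically
consistent with seeding 30,000 cells/cm^2 and reaching confluence in about
two days — 30,000 cells/cm^2 over 6.55e-4 cm^2 is ~20 cells/field, doubling
every 33 h crosses 51 near 48 h. A 0.11 um/px field of the same pixel count
covers only ~12,700 um^2 and could never reach 51 cells/field from that
seeding density; both samplings are exposed in the scene configuration.

## The growth model

`simulate_growth_counts()` is purely exponential:
`N(t) = N0 * 2^((t - t0) / DT)`, with optional Poisson observation noise.
`simulate_experiment()` additionally caps the expected cells per field at a
carrying capacity (default 1.25x the confluency cutoff), emulating contact
inhibition: cultures do not double indefinitely after the monolayer closes.
The expected WPB count per cell follows a parameterized, monotone
non-decreasing `wpb_curve()` of the field's realized cell count. The
default logistic curves (HUVEC: 50 to 64 WPB/cell around a 40 cells/field
midpoint; ECFC: 85 to 95) place sub-confluent and confluent cultures in the
ranges reported for these cell types, and are simulator parameters — not
measurements.

## The segmentation pipeline

Per channel, `count_field()` runs:

1. **Projection.** Default is a maximum-intensity projection, which avoids
   counting one WPB once per z-slice it appears in. A `per_slice` mode
   (slice counts summed) is provided because macro descriptions of this
   type of workflow are ambiguous between the two readings; neither is
   asserted to be "the" original.
2. **Auto-contrast** (`auto_contrast()`): percentile stretch with 0.35%
   total saturation, the ImageJ convention.
3. **8-bit conversion** (`to_8bit()`): linear min-max scaling.
4. **Auto-threshold** (`auto_threshold()`): Ridler-Calvard iterative
   intermeans ("isodata", the default) or Otsu. The isodata iteration is
   initialized at the midpoint of the occupied intensity range — the
   original Ridler-Calvard form — because a mean-initialized iteration
   converges to a background-internal fixed point on fields where
   foreground occupies ~1% of pixels (sparse sub-confluent fields), placing
   the threshold inside the noise. Otsu breaks ties toward the lowest
   threshold (relevant only for degenerate histograms).
5. **Background-contrast guard.** Contrast stretching plus per-image
   8-bit rescaling has no absolute intensity scale, so a plane containing
   no objects would have its noise stretched across the full range and
   thresholded mid-noise, manufacturing hundreds of spurious particles.
   The guard declares a plane object-free when the threshold fails to
   exceed the 15th intensity percentile by at least `min_contrast` (2.5)
   times the 15th-minus-2nd percentile spread. This is an addition beyond
   the plain macro recipe; disable it with `min_contrast = 0`.
6. **Particle analysis** (`label_particles()`): connected components
   (8-connectivity by default, matching the ImageJ wand), measured in
   physical units: area = pixel count x pixel size squared; perimeter by
   Moore boundary tracing with chain-code weights 1 (axial) and sqrt(2)
   (diagonal); circularity `4 pi A / P^2`, capped at 1. The chain-code
   perimeter of digitized shapes is biased by up to ~10% against the
   continuous value (a 50 px square measures ~0.82 instead of pi/4 =
   0.785); all shape tests carry that documented tolerance. Single-pixel
   particles take the perimeter of the equal-area circle, making them
   maximally circular — the correct behavior for the filter below.
7. **Filtering** (`filter_particles()`): nuclei by area only (>= 20 um^2);
   WPBs by area (>= 0.05 um^2) and circularity (<= 0.8). An ideal 5 x 0.3
   um rod has circularity ~0.17 and a disc ~1, so 0.8 separates the two
   populations with a wide margin; the macro tradition names the
   circularity feature but no universal cutoff, so 0.8 is this package's
   declared default, not an inferred ground truth.

No watershed splitting of touching nuclei is attempted; accuracy claims
are made on non-overlapping scenes and real clumped monolayers will
undercount nuclei (and ECFC cultures past ~65% nuclear coverage will merge
badly). That is the main gap between passing synthetic tests and real
data, together with the absence of optical artifacts in the renderer.

### Measured accuracy under the study conditions

On 20 benchmark fields (1024 px @ 0.11 um/px, 5-60 nuclei, 50-600 rods,
SNR 10), the pipeline recovers nuclei exactly in all fields and WPB counts
within 2%; on fields of 100 rods + 50 immature discs, >= 95% of rods are
retained and >= 95% of discs excluded by the default filter (the numbers
are recomputed by `scripts/acceptance.R` and the test suite). Two physical
caveats: at 0.25 um/px sampling a fraction (~10-15%) of sub-resolution
rods (0.1-0.15 um wide) drop below the threshold or merge, and blur-free
sub-pixel-wide footprints can fragment during rasterization — the
ground-truth-recovery oracle therefore uses widths of at least ~2 px.

## Quantification and cohorts

The central statistic is **WPB/nuclei per slide**: the *pooled* ratio
(total WPBs over the slide's 9 fields / total nuclei), not the mean of
per-field ratios — pooling is robust to low-count fields; the alternative
is available via `ratio = "mean_of_fields"`. A slide is **confluent** when
its mean cells per field is at or *above* the cell-type cutoff (inclusive,
so a slide at exactly 51 cells/field classifies confluent); the cutoffs
(51 HUVEC, 75 ECFC) stand for ~80% surface coverage at the 256 um field
geometry and scale with field area for other geometries. Cohorts are
assembled at slide level — slides are the biological replicates — by
confluency, culture method, time, or density. Methods are named by their
design (`constant_density`, `constant_time`), never "method one/two":
published descriptions of such designs label the numbering inconsistently,
and design names are unambiguous.

`method_endpoint_filter()` restricts a method comparison to the confluency
endpoints (96 h for constant-density, 30,000 cells/cm^2 for
constant-time), which is how the two routes to confluence are compared.

## Growth statistics

The doubling time of one interval is `DT = (t1 - t0) log 2 / (log N1 -
log N0)`; the printed form of this formula in parts of the literature is
typographically garbled, and the implementation follows the standard form
above. A series' doubling time is the arithmetic mean over consecutive
intervals; degenerate intervals (equal counts) are excluded with a
warning, and negative doubling times are returned as-is (shrinking
cultures are meaningful). One caveat quantified during development: with
per-field counts of only ~20 cells, the interval estimator's small-count
bias (Jensen's inequality applied to `1 / Delta log N` under Poisson
noise) alone is ~14%; pooled over a slide's 9 fields (~180 cells) it drops
to ~1-2%. Doubling-time estimation should therefore use slide-level
counts, and the calibration tests do.

Growth-rate regression (`fit_growth_regression()`) is ordinary least
squares of raw counts on time — the convention growth-curve figures use —
with a `count_scale` divisor and a `log2_count` response available (the
log-linear fit is exponential growth's natural scale and returns
doublings/hour). Slope equality between two growth curves is the standard
ANCOVA homogeneity-of-slopes F-test (`y ~ t * group` against
`y ~ t + group`), the test statistical packages report for "are these
slopes different". Group comparisons use the classical one-way ANOVA;
`paired_t_test()` covers paired designs. Degenerate inputs have explicit
contracts: identical groups give F = 0 / p = 1, zero within-group variance
with distinct means gives F = Inf / p = 0, and a paired test of a vector
against itself gives t = 0 / p = 1. The nested structure of the design
(fields within slides within experiments) is *not* modeled — the
comparisons are simple fixed-effects tests on slide-level values, which is
a known limitation.

## Reproducibility

Every stochastic entry point takes a mandatory seed, and
`simulate_experiment()` derives one child seed per field from the design
seed, so any field can be regenerated in isolation. `run_pipeline()`
writes a `manifest.json` holding the canonical configuration (seeds
included, no timestamps); re-running from the manifest reproduces every
output file bit-for-bit. TIFF output is 32-bit float, channel-major, with
calibration in a JSON sidecar.

## Problem sizes used by the tests

The test suite and acceptance script run: 20 fields at 1024 px / 0.11
um/px for count recovery; two 512 px fields for filter selectivity; a
simulated constant-density experiment of 2 time points x 5 slides x 9
fields at 512 px / 0.25 um/px (128 um fields, cutoff and density curve
scaled by the area factor 4) for the cohort comparison; 100 Poisson
replicates per doubling time; 2000 replicates per statistical null; and
the demo pipeline configuration (256 px fields) twice for bit-identical
reproduction.

```{r example, eval = FALSE}
# one small field end to end
sp <- scene_spec(field_width_px = 384, field_height_px = 384, n_slices = 7,
                 nucleus_count = 7, wpb_count = 30, immature_count = 10,
                 noise_sd = 0.05, seed = 41)
f <- render_field(sp)
count_field(f$image)$counts
#>   field_id slide_id condition_id nuclei_count wpb_count
#> 1   field1   slide1        cond1            7        30
```
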