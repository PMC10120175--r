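---
title: "Methods: standard refractive-surgery outcome graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standard refractive-surgery outcome graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refracto)
```

`refracto` computes the journal-standard set of refractive-surgery outcome
panels from per-eye records and attaches design-appropriate statistics.
This vignette is the package's account of the underlying methods: the
optical algebra, the acuity model, the vector analysis, the statistical
dispatch, the panel definitions, and the design choices made where more
than one defensible convention exists.

## Refraction algebra

A refraction is a sphero-cylinder S / C × θ at a vertex distance v (mm).
Axes live on the clinical half-circle (0°, 180°]; an entered axis of 0 is
normalized to 180 so that "0, 0, 0" plano targets are accepted without
creating a duplicate 0/180 representation. The cylinder sign carries the
notation: input files use negative-cylinder notation (the dominant clinical
convention), and `transpose_cylinder()` moves to the positive-cylinder form
required by the vector analysis (sphere absorbs the cylinder, cylinder
flips sign, axis rotates 90°). Transposition is an involution and leaves
SEQ and DEQ unchanged — both properties are asserted in the test suite over
randomized refractions.

Vertex propagation treats the two principal meridians independently:
meridian power F referenced to a plane Δd meters closer to the cornea
becomes F′ = F / (1 − Δd·F). The transformation is exact, invertible, and
nearly the identity at low power (below 1 D the spectacle- and
corneal-plane powers differ by under 0.02 D). A meridian whose denominator
approaches zero (power ≈ 1/Δd, far outside any physiologic refraction) is
a domain error naming the offending meridian.

Two scalar summaries drive the accuracy panels: the spherical equivalent
SEQ = S + C/2 (signed defocus) and the defocus equivalent
DEQ = |SEQ| + |C|/2 (total blur burden, always ≥ |SEQ| with equality only
for spherical refractions).

**Plane convention.** Astigmatism vectors are always computed at the
corneal plane: entered refractions are propagated to 0 mm and transposed
to positive cylinder before any vector is formed. For the SEQ-based panels
the package defaults to the plane the user entered (clinicians reason
about spectacle-plane SEQ), with `study_config(seq_plane = "corneal")`
switching everything to the corneal plane. The postoperative astigmatism
magnitudes of the accuracy panel use the corneal plane for consistency
with the vector analysis.

## Visual acuity

Acuity tokens are `20/XX` Snellen denominators with an optional signed
letter suffix: `"25-2"` is two letters short of the 20/25 line. Parsing
tolerates whitespace, a leading apostrophe (the spreadsheet idiom that
prevents date coercion) and en-dashes. Cells that a spreadsheet silently
converted to dates — ISO date strings, month names, or bare five-digit
Excel day serials — abort the read with the remedial instruction (format
the column as Text), because silently interpreting a date serial as a
denominator would corrupt every downstream index.

Conversion to LogMAR is `log10(XX/20) − k·letters`, with k the per-letter
increment, default 0.02 LogMAR (five-letter lines). The value is a chart
convention, not a measurable constant, so it is a parameter of
`acuity_config()`. Decimal acuity is `10^(−LogMAR)`. The reverse mapping
snaps a LogMAR value to the nearest line-plus-letters representation on
the configured chart lines (default 20/10 through 20/200 in standard
0.1-LogMAR steps), breaking ties toward the smaller letter offset; on
exactly representable values it inverts the forward conversion, which the
tests assert over the whole line × offset grid.

Line changes are whole lines of 0.1 LogMAR with half-away-from-zero
rounding, so a gain and a loss of the same magnitude always round
symmetrically. The efficacy index is the ratio of the mean decimal postop
UDVA to the mean decimal baseline CDVA (the safety index substitutes
postop CDVA). Ratio-of-means is the default because the index is defined
against "the mean" baseline acuity; the per-eye mean-of-ratios variant is
available via `per_eye_index = TRUE`. The baseline is the preoperative
CDVA for LVC, RLE and ICL; for cataract surgery the postoperative CDVA is
used, the one procedure-specific rule in the workflow.

## Astigmatism vector analysis

Astigmatic states add like vectors only in doubled-angle space:
(C, θ) ↦ (C·cos 2θ, C·sin 2θ). The target-induced astigmatism TIA is the
doubled-angle difference target − preop; the surgically-induced
astigmatism SIA is postop − preop. Both are formed from corneal-plane,
positive-cylinder refractions. The correctness of this representation is
checked against an independent oracle: combining cylinders via 2×2
dioptric power matrices and recovering the resultant from the
eigen-decomposition agrees with doubled-angle addition to 10⁻⁹ over 10,000
random pairs.

The correction index CI = |SIA|/|TIA| (1 = perfect magnitude correction,
above 1 overcorrection) and the angle of error — half the signed
doubled-angle from TIA to SIA, counterclockwise positive, in (−90°, 90°] —
are undefined for eyes with no intended astigmatic change (|TIA| = 0) and,
for the angle, when either vector vanishes. Such eyes are excluded from
the CI and AoE panels and their count is reported separately in the panel
annotation rather than silently dropped. When every eye hits its target
exactly, CI = 1 and AoE = 0 for all treated eyes; this identity is
exercised end-to-end through file writing and re-reading.

Magnitude of error and difference vectors are implicit in the
representation but not plotted; the panel set deliberately stops at the
scattergram and the CI/AoE histograms, leaving polar vector displays to
dedicated vector-analysis tools.

## Statistical engine

Two-group comparisons are dispatched automatically. Both samples are first
screened for normality with the Lilliefors-corrected Kolmogorov–Smirnov
test — the naive KS test with estimated mean and SD is anticonservative,
so the corrected form is the default gate. If both samples pass at α =
0.05 the parametric branch runs (Welch unpaired t-test, or paired t-test);
otherwise the matching nonparametric test (Mann–Whitney U, Wilcoxon
signed-rank). Requiring *both* samples to pass is the stricter reading of
"where applicable" and is the documented choice. Samples that cannot be
assessed (fewer than 5 observations, or zero variance) are treated as
non-normal. All tests are two-sided; no directional hypotheses are
imposed. The suite verifies the dispatcher's type-I error stays at
5% ± 1.5% over 2000 null simulations at n = 50 per arm.

Cohen's d accompanies every comparison — pooled-SD form (n−1 weights) for
unpaired designs, mean-over-SD of differences for paired — and is computed
from means and SDs even when the nonparametric branch ran, so effect sizes
remain comparable across panels. Identical paired samples yield d = 0 (a
true null), while a constant non-zero paired difference has no spread to
scale by and is flagged not-computable rather than reported as infinite.
Scattergram panels carry ordinary least-squares fits with R² (squared
Pearson correlation) instead of hypothesis tests.

The paper-facing convention p < 0.05 marks significance, and |d| < 0.20 is
conventionally not clinically relevant; the package displays both and
leaves interpretation to the reader.

**Per-panel analysis variables.** The source material does not enumerate
which variable each panel tests, so the package fixes them as: A/B postop
UDVA LogMAR; C CDVA line change; D SEQ error; E none (regression only);
F the selected-pair SEQ change (stability variant) or DEQ; G postop
astigmatism magnitude; H none; I correction index; J angle of error. The
stats table (`tidy()` on a run) names the variable next to every p-value.

## Panel definitions and numerical choices

- Accuracy thresholds are inclusive: "within 0.50 D" means |x| ≤ 0.50.
  Defaults: SEQ 0.25/0.50/0.75/1.00 D; DEQ adds 2.00 D; astigmatism
  0.50/0.75/1.00 D.
- The stability panel counts SEQ changes *strictly* greater than 0.50 D
  between the two selected time points (a change of exactly 0.50 D is not
  counted), over eyes present at both points; per-timepoint Ns may shrink
  as eyes miss later visits, and are reported per timepoint rather than
  excluding eyes globally.
- When the optional stability columns are blank the panel slot is filled
  by the DEQ accuracy histogram — the run family therefore produces 11
  distinct graph types across its two variants.
- Line-change histograms use the five standard bins with open-ended
  extremes (≤−2, −1, 0, +1, ≥+2), keeping the partition exhaustive; every
  histogram's percentages sum to 100 over included eyes, an invariant the
  tests assert.
- Cumulative acuity curves count eyes at each configured line or better
  with a 10⁻⁹ tolerance so an eye exactly on a line counts; curves are
  monotone by construction and the CDVA curve dominates the UDVA curve
  whenever each eye's CDVA is at least as good.
- Histogram bin widths for the CI (0.1) and AoE (5°) panels are display
  choices, configurable in `study_config()`.
- Diopter values are never rounded internally; display rounding to 0.01 D
  happens only when annotations are formatted.
- Scatter panels draw the identity line and the fitted line, with axis
  limits from the data range padded 10%.
- Panel A annotates mean ± SD LogMAR for preop CDVA, postop CDVA and
  postop UDVA — the three acuities the record layout contains (there is no
  preoperative UDVA column).
- Exports: one TIFF per panel at 400 dpi and a one-page 2×5 composite of
  all ten panels at 1200 dpi, resolution metadata embedded; physical sizes
  (5×4 in per panel, 5×12.5 in composite) keep even the 1200-dpi raster
  modest. A `stats_summary.csv` accompanies the figures so results are
  machine-readable as well.

## The synthetic cohort generator

`scenario()` defines a population and treatment model in exactly the
quantities the analysis estimates, which closes the validation loop:

- Preop refractions are drawn at the corneal plane (sphere normal,
  cylinder magnitude truncated normal, axis uniform over whole degrees)
  and written to file at the spectacle plane (12 mm by default), so the
  reader's vertex handling is exercised on every generated dataset.
- The treatment acts in doubled-angle space: the TIA is scaled by a
  per-eye correction index drawn from N(ci_mean, ci_sd) and rotated by a
  per-eye axis error from N(0, axis_error_sd). The achieved SEQ is the
  target plus `seq_bias` plus noise. Consequently the generator's
  `ci_mean` *is* the mean CI the pipeline should recover, `seq_bias` the
  mean SEQ error, and the injected abrupt stability shift the exact
  flagged fraction — the acceptance tests recover 0.9/−0.25 D/20% at
  n = 500 within 0.02, 0.03 D and 0.1 points respectively.
- Uncorrected acuity responds to residual blur as
  LogMAR = max(0, k·DEQ) + noise with k = 0.3 LogMAR per diopter, floored
  at the eye's corrected acuity and snapped to chart lines — a simple
  monotone defocus–acuity link sufficient for plausible graphs, not a
  psychophysical model. Corrected acuity changes by sampled whole lines.
- With every SD, bias and drift at zero the generator is degenerate by
  design: postop equals target, acuities are unchanged, and all panels hit
  their ideals (indices 1.00, 100% within the smallest thresholds, slope 1
  with R² = 1, CI = 1, AoE = 0).

The three `trial_scenario()` presets emulate the demonstration study
populations — a paired hyperopic-astigmatism LVC contralateral study with
a five-timepoint stability series, a single-group toric phakic IOL cohort
with moderate-to-high cylinder (1.5 D floor), and two unpaired
myopic-astigmatism cataract groups — with parameters chosen as plausible
clinical magnitudes (sub-diopter biases, correction indices slightly below
1, a few degrees of axis noise). They are labeled emulations: the original
demonstration datasets' parameters are not published. Default problem
sizes (100 eyes per arm in presets and examples, 500 for parameter
recovery, 2000 replicates for the type-I calibration) were chosen as
ordinary study scales at which the recovered quantities' sampling error is
well inside the asserted tolerances.

What the generator does not emulate: complications (haze, ectasia,
decentration), enhancement decisions, correlated bilateral eyes beyond row
alignment, chart-specific letter scoring, or test–retest acuity noise.
Passing tests therefore demonstrate the *pipeline's* correctness on data
whose ground truth is known by construction — not clinical realism of any
particular outcome distribution.

## File handling

Column identity in input files is positional (the 20-column layout);
header text is advisory. XLSX (first worksheet) and CSV dialects are read
identically. Blank optional cells mean absent; zero is a value; blank
mandatory cells are row errors. Failed rows are dropped into a validation
report carrying row numbers and reasons — dropped plus kept always equals
input rows, and reading a generator-written file reproduces the in-memory
records exactly. Paired designs require equal counts in aligned row order.
Every validation emits the reminder that statistical validity expects one
eye per patient per group. The generator writes CSV; both formats are read.

## Known limitations

- Three-or-more-group designs (ANOVA) are out of scope; run single-group
  analyses per group and combine externally.
- Keratometric/topographic astigmatism, IOL power calculation and
  accommodation are not modeled; the vector substrate is refractive.
- Direct LogMAR or metric Snellen entry is supported only via the bundled
  conversion table (`logmar_snellen_table()`).
- Statistical results are per-panel; no multiplicity correction is applied
  across panels.
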