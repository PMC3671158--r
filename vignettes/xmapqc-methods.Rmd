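---
title: "Models and methods behind xmapqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xmapqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmapqc)
```

`xmapqc` analyzes multiplexed bead-array (xMAP) immunoassay runs: it reads
instrument workbooks, normalizes fluorescence intensities, fits weighted
logistic titration curves, interpolates unknown concentrations, and applies
within-run and cross-run quality control. This vignette explains the models
and the choices made where the underlying conventions leave room.

## The workbook dialect

A run workbook carries one worksheet per bead region (analyte). Each sheet
has header metadata rows, one or two data tables, and a footer. The parser
treats every row above the first row whose first cell is `Type` as
key/value metadata, a table as running from its header row to the first
fully blank row, and everything after the tables as an opaque footer that
is retained but never interpreted. Tables are *raw* (one well per row,
`Well` column, bead counts) or *summary* (one sample per row, `Wells`
column listing the replicate wells, replicate-averaged FI and a reported
%CV). When both tables are present, raw rows are authoritative for
computation and summary rows are kept for cross-checking; when only summary
rows exist, computation proceeds on them and the file's reported %CV is
used, since the per-well values needed to recompute it are absent.

Sample type codes map `B` → background, `S` → standard, `C` → quality
control, `X` → unknown (case-insensitive), with trailing digits as the
sample index. A trailing parenthesized integer in a sheet name
(`"ENV1 (34)"`) is taken as the bead number. Well labels are any
letter+number string, so plates larger than 96 wells parse unchanged.
Dilutions are stored as fold-dilutions (100 means 1:100) and expected
concentrations stay in the file's own units.

Several files can be merged into one run; identical analyte names must
carry identical bead numbers, and a standard titration parsed from one file
serves unknowns of the same analyte parsed from another.

## Normalization

The response used for fitting is produced by a fixed-order pipeline, each
step optional except the conversion:

1. **Blank-bead subtraction** — subtract the same-well FI of an uncoupled
   bead region (non-specific binding to beads).
2. **Background subtraction** — subtract the mean FI of buffer-only wells
   (detector background). The mean is recomputed from the background wells
   rather than trusting the file's `FI - Bkgd` column, which may be stale
   in summary files; the file's column is retained for comparison.
3. **Conversion** — `FI' = max(FI, 0) + 1`, always applied. Subtraction can
   drive FI negative; the conversion restores positivity and guarantees a
   value ≥ 1 so the optional log transform is defined.
4. **Log transform** — natural log of the converted FI. The convention
   only fixes that a log is taken, not its base; the natural log is used
   for fitting, and plots may display log10 axes independently.

Both subtractions are additive constants per well, so their relative order
does not change the result; the order above is fixed purely so provenance
columns are well defined. Replicate %CVs are computed on the subtracted,
pre-conversion FI (the scale on which reported FI flags operate).

## Curve model and fitting

Titration curves use the asymmetric five-parameter logistic in log dose,

$$f(x) = A_{min} + \frac{A_{max} - A_{min}}{\left(1 + e^{-h(\ln x - \ln m)}\right)^{s}},$$

with inflection dose $m > 0$, slope $h$, and asymmetry $s > 0$; $s = 1$
gives the symmetric four-parameter logistic, so the 4pl fit is the same
optimization with $s$ pinned at 1 and 5pl always nests 4pl. Fitting
minimizes the weighted residual sum of squares
$\sum_i w_i (y_i - f(x_i))^2$ over non-excluded replicate-group means, with
power-law weights $w_i = 1/\max(y_i, 1)^p$. Bead-array FI is
heteroscedastic — variance grows with signal — and down-weighting bright
points markedly improves the low end of the curve, expanding the usable
range. The default exponent is $p = 1.8$, a conventional choice for these
assays, overridable per assay design; weights are computed from observed
(not fitted) responses, and the floor at 1 guards the division for small or
log-scale responses. Iteratively refitted weights are deliberately out of
scope.

Optimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) over
$(A_{min}, A_{max}, \ln m, h, \ln s)$, so $m$ and $s$ stay positive by
construction. Initialization: asymptotes from the observed response range,
slope sign from the observed monotone direction, $m$ at the dose nearest
the half-range crossing, $s = 1$. If the first attempt does not converge,
three jittered restarts are tried under a fixed seed; the best converged
solution wins, and a fit that still fails is reported honestly as
non-converged with its metrics absent. Fits require at least as many
non-excluded points as free parameters (4 or 5) and fail loudly otherwise.

### Titration metrics

* **EC50** — the dose at the midpoint between the asymptotes, in closed
  form $m (2^{1/s} - 1)^{-1/h}$; for $s = 1$ this is exactly $m$. The
  midpoint-dose definition (rather than the inflection parameter) is used
  for the 5pl because the metric's meaning — effective concentration at 50%
  of the asymptote difference — is the midpoint.
* **AUC** — trapezoidal area under (log10 dose, mean response) over the
  observed points only, sorted by dose, with no extension toward the
  asymptotes. Users comparing AUC across runs should keep dilution series
  identical, since the integration range follows the observed points.
* **HighMFI** — the maximum replicate-group mean FI across non-excluded
  points, always computed on the converted (non-log) FI scale even when
  fitting used log responses, because the metric is a fluorescence
  intensity.

### Interpolation of unknowns

The fitted standard curve is inverted in closed form,
$x = m\,(R^{1/s} - 1)^{-1/h}$ with $R = (A_{max} - A_{min})/(y - A_{min})$,
and the interpolated dose is multiplied by the sample's fold dilution.
Responses at or outside the asymptotes are never extrapolated; they are
reported as out-of-range with the side identified relative to the curve
orientation (low = beyond the dose→0 asymptote). Titrated quality controls
and unknowns are fitted with the same machinery as standards, but
interpolation always uses the assigned standard's fit.

## Within-run quality control

The %CV of each replicate group (sample/dilution/analyte) is
$100 \cdot s/\bar{y}$ with the sample (n−1) standard deviation; it is
undefined for singleton groups and for zero means. A group is automatically
flagged when its mean FI exceeds 100 **and** its %CV exceeds 15 (unknowns)
or 20 (standards and quality controls). Both comparisons are strict
("greater than"), so boundary values do not flag; the FI gate exists to
save review time, since only potentially positive samples warrant
investigation. All three constants are configuration, defaulting to the
printed values.

Exclusions remove an analyte or a replicate group from analysis without
deleting anything: rows are retained and marked, output row counts are
unchanged, and the exclusion log is append-only. Excluding a titration
point triggers recomputation of every curve that contained it, and of the
interpolations downstream of those curves. Analytes are computed
independently (the blank-bead channel being the one shared input), so the
incremental recomputation after an exclusion equals a full re-analysis
exactly — a property the test suite verifies over random exclusion
sequences.

Positivity calls require both a fold increase over a per-sample baseline
and exceedance of an analyte-specific threshold
(`value ≥ fold × baseline` and `value > threshold`). The baseline and
threshold are user inputs; the fold-change magnitude is likewise a user
parameter with default 3, as the underlying convention fixes only that an
increase is required, not its size.

## Cross-run quality control

Four metrics per (analyte, titration) participate: 4pl EC50, 5pl EC50,
AUC, and HighMFI. A *guide set* is an explicit, user-chosen suite of
baseline runs sharing a lot scope (reagent lot, isotype, conjugate); per
metric it stores the mean and sample SD over members carrying that metric.
Later runs in the same lot scope are flagged when a metric falls strictly
outside mean ± 3 SD — values exactly on the boundary are inside — and
member runs are never flagged against their own set. Flags can be
inactivated after review; inactivation keeps the record with the reviewer's
comment and is idempotent. Levey-Jennings series order runs by acquisition
date (ties by run id) and carry ± 1/2/3 SD bands that switch at lot
boundaries. Only the ± 3 SD rule is automated; trend detection is left to
the eye, and multi-rule schemes (Westgard-style) are out of scope.

A caveat worth stating: the ± 3 SD rule attains its nominal two-sided
normal false-flag rate $2\Phi(-3) \approx 0.27\%$ only asymptotically in
the guide-set size. With mean and SD estimated from $n$ baseline runs, the
exceedance probability of the strict rule for a normal metric is
$2\,P\!\left(t_{n-1} > 3/\sqrt{1 + 1/n}\right)$ — about 0.62% at $n = 30$ —
and the realized rate for any one guide set varies further with the
sampling error of its SD. Labs using small guide sets should expect
somewhat more than 0.27% of metrics to be flagged under stable conditions.

## The synthetic-data generator

The generator writes workbooks in the exact dialect the parser reads, with
known ground truth serialized alongside. Its defaults describe a typical
binding-antibody run: a 10-point 3-fold standard dilution series from a top
concentration of 10,000 (assay units) in triplicate, unknowns at 1:100,
three buffer-only background wells, and multiplicative replicate noise.
Noise is lognormal with unit median and configurable CV (default 5%,
a realistic replicate CV for these assays): FI stays positive and its
spread grows with signal, matching the heteroscedasticity that motivates
the power-law fit weights. Background wells draw from a normal around the
configured mean (default 25 FI) with 10% CV, truncated at zero. An optional
blank-bead sheet carries background-only signal with no dose dependence,
and an optional summary table exercises the summary-parsing path. The same
configuration and seed always produce a byte-identical workbook.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: plate-position effects, bead-count
failures and doublets, carryover, drift within a plate, non-logistic
binding (hook effects at high concentration), and correlated noise between
analytes sharing a well. The generator validates the pipeline's
correctness, not the assay's biology.

## Numerical choices and degenerate inputs

* Weight floor ε = 1 in $1/\max(y, 1)^p$; responses below 1 (possible
  after log transform) get weight 1.
* EC50 is reported absent when the closed form is non-finite (slope
  numerically 0).
* AUC requires ≥ 2 distinct doses; HighMFI requires ≥ 1 non-excluded
  point; both are absent otherwise, and a fully excluded analyte keeps its
  metric row with empty cells.
* Strict comparisons throughout the flag rules (within-run and ± 3 SD);
  boundary values never flag.
* Duplicate exclusions are no-ops; unknown exclusion targets are errors.
* Unparseable numeric cells fail the parse by default and are skipped with
  a warning under the lenient flag; either way no row is silently dropped.
* Canonical CSVs have a fixed column order and deterministic formatting, so
  identical inputs produce byte-identical outputs.

## Problem sizes used by the test suite

The packaged tests run on deliberately small simulations chosen to give
tight checks at interactive speeds: 8–10-point dilution series with 2–3
replicates, 100-trial parameter-recovery sweeps at 5% noise, 1,000-point
interpolation round trips, 100 random point sets for the AUC oracle,
10,000 simulated run metrics against a 30-run guide set for the null flag
rate, 20 random exclusion-equivalence trials, and 10 seeded
generate-then-parse round trips. All randomness is seed-controlled.

## Known limitations

* Only the Bio-Plex-Manager export dialect is parsed; xPONENT and
  MILLIPLEX dialects are not.
* No limits of detection/quantitation, no Bayesian or mixed-effects curve
  models, no drift correction, no plate-layout or instrument control.
* AUC depends on the observed dilution range (see above).
* The finite-guide-set false-flag inflation described under cross-run QC.
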