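---
title: "Isoeffective DVH conversion and treatment-gap compensation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoeffective DVH conversion and treatment-gap compensation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodvh)
```

## The problem

Unscheduled interruptions to a radiotherapy course — machine breakdowns,
patient illness, or large-scale events such as the 2021 ransomware attack on
the Irish health service — extend the overall treatment time $T$. For
rapidly proliferating tumors, every day beyond the repopulation onset lag
costs biologically effective dose, reducing tumor control probability.
Compensation schedules (extra weekly fractions, twice-daily treatment,
hypofractionation) can recover that dose, but always at a price paid by the
organs at risk (OARs). The standard gap calculation collapses each structure
to a single point dose; `isodvh` instead converts the whole dose–volume
histogram (DVH) of every structure into repopulation-corrected isoeffective
dose, so the trade-off can be judged across each structure's full dose
distribution.

## The model

All conversions use the linear-quadratic (LQ) isoeffect model. For a
schedule of $N$ fractions of $d$ Gy:

$$\mathrm{BED}_{\mathrm{tumor}} = N d \left(1 + \frac{d(1+h)}{\alpha/\beta}\right) - K\,(T - T_{delay})_+ ,
\qquad
\mathrm{BED}_{\mathrm{OAR}} = N d \left(1 + \frac{d(1+h)}{\alpha/\beta}\right)$$

$$\mathrm{EQD}_2 = \frac{\mathrm{BED}}{1 + 2/(\alpha/\beta)}$$

* $\alpha/\beta$ (Gy) — fractionation sensitivity; the BED unit carries it
  as a subscript (Gy$_{10}$, Gy$_3$, Gy$_2$) and `isodvh` refuses to add
  values with different subscripts.
* $K$ (Gy/day) — dose lost per day to rapid tumor repopulation once
  $T > T_{delay}$; the loss is clamped at zero before onset. OARs have
  $K = 0$: normal-tissue repopulation is negligible within a course.
* $h$ — incomplete-repair factor for closely spaced fractions, the
  mono-exponential form $h = 2^{-m/T_{1/2}}$ for two fractions $m$ hours
  apart with repair half-time $T_{1/2}$; $h \equiv 0$ for intervals above
  8 h, where repair is taken as complete.

The per-bin (variable-dose) conversion replaces the prescription $d$ by the
bin's own dose per fraction $D_i/N$, where $D_i$ is the physical dose of DVH
bin $i$. Bin volumes are untouched; only the dose axis is mapped. The map is
strictly increasing in $D_i$, so bin ordering is preserved, and it has an
exact fixed point: $d = 2$ Gy with $h = 0$, $K = 0$ maps to itself, which
the test suite verifies to $10^{-10}$ Gy over 1000 random schedules.

### Default parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| $\alpha/\beta$ tumor | 10 | Gy | conventional value for rapidly proliferating squamous tumors |
| $\alpha/\beta$ OAR | 3 (2 for cord) | Gy | late-responding normal tissue |
| $K$ (Category-1 tumor) | 0.9 | Gy/day | RCR-recommended repopulation rate |
| $T_{delay}$ | 28 | days | RCR-recommended onset lag |
| $T_{1/2}$ | 2 | h | median normal-tissue repair half-time |
| $m$ | 6 | h | minimum recommended twice-daily interval |
| DVH bin width | 0.01 | Gy | 1 cGy; configurable everywhere |

These live in `inst/extdata/tissue_presets.csv` (and any user CSV with the
same columns), never hard-coded into the operations. With the defaults,
$h_{\mathrm{OAR}} = 2^{-6/2} = 0.125$ and tumor $h = 0$ (tumor sublethal
damage is taken as fully repaired after 6 h).

### Mixed once-/twice-daily schedules

The published equations carry a single $h$, yet reported dose statistics
rise stepwise with each added twice-daily day. `isodvh` resolves this by
*session groups*: each bin's dose is apportioned over groups of fractions
in proportion to their fraction counts ($n_g/N$), each group gets its own
$h_g$ (0 for once-daily fractions, $2^{-m/T_{1/2}}$ for the $2\,TD$
fractions on twice-daily days), and group contributions are summed. With a
single group this reduces exactly to the scalar formula; the per-bin result
is verified against an independent fraction-by-fraction LQ accumulation to
$10^{-9}$ Gy.

### Segment accounting for interrupted courses

An interrupted course is scored as contiguous segments (pre-gap, post-gap,
compensation blocks). Repopulation loss is attributed *cumulatively*: a
segment ending at overall time $T_e$ carries
$K(T_e - T_{delay})_+ - \text{loss already attributed}$. A segment ending
before $T_{delay}$ therefore carries zero loss, and a short post-gap block
can come out negative — it delivered less dose than repopulation removed
while it was being delivered. Negative BED/EQD$_2$ values are preserved,
never clamped; they are diagnostic. Segment BEDs are additive: pre-gap plus
post-gap equals the scalar BED of the whole delivered course, which the
suite asserts to $10^{-12}$.

## The DVH engine

`dvh_from_grid()` assigns each masked voxel's full volume to the bin
containing its **center** dose — no interpolation of the dose grid and no
inter-slice contour interpolation. That choice follows the finding that
zero interpolation best matches a commercial planning system's own DVHs and
avoids interpolation-induced volume drift; its known cost, deliberately
reproduced here, is a staggered DVH for structures small relative to the
dose grid (≤ 1 cm³). Contours are rasterized by an even–odd
point-in-polygon test of voxel centers, so holes (shells) work, and voxels
are included wholly or not at all.

Numerical conventions:

* Bins are left-closed/right-open; zero-width "point mass" bins are legal
  (convenient for toy DVHs quoted at exact doses).
* $D_{x\%}$/$D_{x\mathrm{cc}}$ are read from the cumulative curve with
  linear interpolation *within* the bin where the crossing occurs (mass is
  uniform within a bin; the curve is flat across empty gaps). At a plateau
  the highest dose still covering the requested volume is returned, so two
  equal half-volumes at 10 and 20 Gy give $D_{50\%} = 20$ Gy. This readout
  interpolation is the single, deliberate exception to the
  no-interpolation rule: it concerns the histogram readout, not the
  spatial dose or contours.
* $D_{max}$/$D_{min}$ are the centers of the highest/lowest occupied bins
  (upper edge minus half a bin width), matching the voxel-center binning.

## Synthetic phantoms: what a green test establishes

No clinical DICOM accompanies the package, so every engine-level claim is
tested against `build_phantom()`: geometric primitives (sphere, box,
shell) in analytic dose fields (uniform, linear gradient, centered
Gaussian) with closed-form DVHs — a step, a linear cumulative curve, an
error-function-free radial form $V(D) = \tfrac43\pi \min(r(D), R)^3$ with
$r(D) = \sigma\sqrt{2\ln(A/D)}$. Phantom grids are pre-quantized to the
32-bit scaling step they will be written with, so the
phantom → DICOM → reader → DVH round trip is bit-exact. The acceptance
phantoms use mid-bin dose alignment (e.g. a uniform 20.025 Gy field at
0.05 Gy bins); doses sitting exactly on bin edges would make voxel binning
depend on nanogray quantization noise, which is a statement about float
rounding, not about the engine.

What the phantoms do **not** emulate: heterogeneous patient anatomy,
planning-system dose calculation, contour digitization noise, or
partial-volume geometry of real organs. A green phantom test establishes
the engine's arithmetic and geometry, not agreement with any commercial
system — the published cross-validation against a clinical TPS (correlation
and gamma pass rates on patient plans) is not reproducible without that
clinical data and is deliberately out of scope.

## Gap planning

`make_calendar()`/`validate_schedule()` encode the scheduling constraints
used for compensation planning: at most 6 fractions per ISO (Monday–Sunday)
week, no twice-daily fractionation on consecutive calendar days, same-day
fractions at least 6 h apart. The week window is a design choice — the
guidance does not define it — and ISO weeks make "6 per week" stable under
calendar shifts. Overall time is counted inclusively in calendar days,
weekends and gap days included.

Revised plans reuse the original plan's dose distribution: a revised plan's
DVH is the original scaled on the dose axis by its physical-dose ratio, and
in DVH mode each segment's histogram is converted with its own session
groups and summed bin-wise. This assumes identical structure geometry and
an identical normalized dose distribution across segments — the stated
approximation of the revised-plan approach (no re-optimization), and the
reason DVH-mode plan sums are only as good as that assumption.

`point_dose_rcr()` implements the current standard single-point method
side by side; on a dose-gradient OAR its worst-case point dose provably
upper-bounds the DVH-derived near-maximum EQD$_2$, which the suite checks.

## Gamma analysis of DVH pairs

`gamma_dvh()` computes a 1-D gamma index along the cumulative curve with a
dose criterion $\Delta D$ (fraction of the reference maximum DVH dose) and
a volume criterion $\Delta V$ (fraction of total volume), defaults 1 %/1 %
with a 95 % pass threshold. Reference points sit at the occupied reference
bin edges; the evaluated curve is linearly densified `oversample`-fold
(default 10) before the minimum search.

One subtlety is worth spelling out. For a strictly decreasing curve shifted
in dose by exactly $\Delta D \cdot D_{max}$, point-to-point comparison at
matching volumes gives $\gamma = 1$ everywhere — the classic boundary case,
tested with `oversample = 1`. Against the *densified* curve the minimum is
taken over a superset, and interior points honestly fall below 1 (for a
linear ramp under 1 %/1 % criteria the continuous minimum is $1/\sqrt2$).
Both behaviors are correct for what they measure; refining the sampling can
only decrease $\gamma$, an invariant the suite checks at three sampling
levels against a brute-force dense-search oracle.

## Known limitations

* Mono-exponential repair only; two-component (short/long) spinal-cord
  repair kinetics are a stated non-goal.
* $K$ is a population constant per tumor category; no patient-specific
  estimation.
* DVHs discard spatial information: hot/cold spot locations are invisible,
  so the tool complements, never replaces, spatial plan review.
* The DICOM codec is deliberately narrow: explicit-VR little-endian,
  uncompressed, uniform frame offsets, congruent dose/structure grids.
  Mismatched grids raise an error rather than silently resampling.
* DS attributes are written at 10 significant digits (the DICOM DS field
  width); grids not pre-quantized to a DS-representable scaling step
  round-trip only to that precision.
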