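# isodvh — isoeffective DVH conversion and radiotherapy treatment-gap compensation

`isodvh` is an R toolkit for medical physicists scoring **treatment-gap
compensation options**. When a radiotherapy course is interrupted (machine
downtime, patient illness, or a large-scale event such as a hospital
cyberattack), rapid tumor repopulation erodes the biologically effective
dose once the overall treatment time `T` passes the onset lag. The package
converts physical dose–volume histograms (DVHs) into repopulation-corrected
BED/EQD₂ histograms per structure, builds and validates compensation
schedules under RCR/NCCP constraints, and compares candidate plans against
the originally intended one — for the target volume *and* every organ at
risk, instead of the single point dose used by the standard method.

## The model

Linear-quadratic isoeffect with tumor repopulation and incomplete repair:

    BED_tumor = N·d·(1 + d(1+h)/(α/β)) − K·(T − T_delay)₊
    BED_OAR   = N·d·(1 + d(1+h)/(α/β))
    EQD₂      = BED / (1 + 2/(α/β))

where `N` is the fraction count, `d` the dose per fraction (Gy), `K` the
repopulation rate (Gy/day, 0 for OARs), `T_delay` the onset lag (days), and
`h = 2^(−m/T½)` the incomplete-repair factor for two same-day fractions `m`
hours apart (0 beyond 8 h). The per-bin converter replaces `d` by each DVH
bin's own dose per fraction `D_i/N`, so dose gradients inside a structure
are handled correctly. Mixed once-/twice-daily schedules are supported via
session groups (per-group `h`, fraction-count weighted).

Companion modules: a DVH engine (voxel-center binning, no interpolation),
a narrow DICOM RT-Dose/RT-Structure reader+writer, a synthetic phantom
factory with closed-form expected DVHs, 1-D DVH gamma analysis, and a CLI.

## Worked example

Vocal-cord case: 35 × 2 Gy intended over 50 days, interrupted after 6
fractions (day 9) by a 13-day gap; the remainder finishes uncompensated on
day 63. Category-1 tumor parameters: α/β = 10 Gy, K = 0.9 Gy/day,
T_delay = 28 d.

```r
library(isodvh)
cs <- build_case_study("C")
intended <- evaluate_plan(list(plan_segment("intended", 35, 2, 50)), cs$params)
uncomp <- evaluate_plan(list(
  plan_segment("pre-gap",  6, 2,  9),
  plan_segment("post-gap", 29, 2, 63)), cs$params, reference = intended)
print(uncomp)
```

```
      row physical_dose  d  N  T  BED EQD2 dose_lost
  pre-gap            12  2  6  9 14.4 12.0       0.0
 post-gap            58  2 29 63 38.1 31.8      31.5
     plan            70 NA 35 63 52.5 43.8      31.5
difference (reference - plan): BED 11.7 Gy[10], EQD2 9.8 Gy[10]
```

Reading: the pre-gap block ends before repopulation onset (0.0 Gy lost);
the gap pushes the remainder deep into the repopulation regime, costing
31.5 Gy₁₀ and leaving the uncompensated course 11.7 Gy₁₀ of BED
(≈ 9.8 Gy₁₀ EQD₂) short of the intended plan — the quantity a compensation
schedule must recover. The intended plan itself scores BED 64.2 Gy₁₀ /
EQD₂ 53.5 Gy₁₀. For twice-daily compensation, the OAR repair penalty uses
`incomplete_repair_factor(2, 6)` = `0.125`.

Per-structure DVH mode: `dvh_from_grid()` + `convert_dvh()` produce EQD₂
histograms, `dvh_statistic(x, "D98%")` etc. read them out, and
`gamma_dvh()` compares engines. `build_phantom()` generates synthetic
DICOM-backed test cases with analytically known DVHs.

## Command line

```sh
inst/cli/isodvh phantom --spec spec.json --out-dir dicom/
inst/cli/isodvh convert --rd dicom/RD.dcm --rs dicom/RS.dcm \
    --params inst/extdata/tissue_presets.csv --n 30 --t 40 --out-dir out/
inst/cli/isodvh compare --plans plans.json --out-dir out/
inst/cli/isodvh gamma --reference ref.csv --evaluated ev.csv --out-dir out/
```

Exit status is 0 on success; errors print a named class to stderr.

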