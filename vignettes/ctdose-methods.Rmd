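---
title: "CT organ and effective dose calculation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT organ and effective dose calculation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdose)
```

## The dosimetry chain

`ctdose` computes patient organ doses and effective dose for a CT scan in
five stages, each exposed as its own function so intermediate quantities can
be inspected:

1. **CTDI metrics** — from a measured longitudinal dose profile D(z), the
   CT dose index CTDI100 is the integral over the central ±50 mm divided by
   min(NT, 100), where N is the detector-row count and T the nominal slice
   thickness. The clamp matters for wide-cone scanners: once the beam is
   wider than the 100 mm integration length, the quantity becomes the
   average dose over the central 100 mm of a single axial exposure.
   Weighted CTDI (center/3 + 2·periphery/3) and the dose-length product
   follow their standard definitions.
2. **Scanner characterization and matching** — a new scanner is summarized
   per kV by two dimensionless "ImPACT factors", fixed linear combinations
   of the phantom-to-air CTDI ratios:
   head = 0.4738·(c/air) + 0.8045·(p/air) + 0.0752 and
   body = 3.5842·(c/air) + 0.6328·(p/air) − 0.0902. The scanner is then
   matched to the reference Monte Carlo dataset whose factors are closest.
3. **Slab-phantom organ dose** — the stylized adult phantom is divided head
   to mid-thigh into 208 axial slabs of 5 mm. A dataset gives, per organ,
   the dose per unit free-in-air CTDI when each single slab is irradiated.
   A scan protocol is mapped to per-slab coverage weights and the organ
   dose is the weighted coefficient sum scaled by CTDIair·(mAs/100), the
   collimation's relative-CTDI factor, and 1/pitch for helical scans.
4. **Phantom conversion** — per-organ conversion factors
   CF = D(reference voxel phantom)/D(stylized phantom), keyed by one of 13
   examination categories and sex, turn stylized-phantom doses into
   reference adult male/female doses.
5. **Equivalent and effective dose** — H_T = D_T·W_R with W_R = 1 for
   photons; ED = Σ_T W_T·H_T under the ICRP Publication 103 tissue weights,
   with the remainder weight applied to the arithmetic mean of the
   remainder tissues. Male, female and sex-averaged values are all
   reported.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `n_slabs`, `slab_thickness_mm` | —, mm | 208, 5 | the slab grid of the stylized adult phantom |
| kV menu | kV | 80/100/120/135 | the discrete tube-voltage menu scanners are characterized at |
| reference collimation | mm | 16 | the width whose relative-CTDI factor is pinned at exactly 1.0 |
| `pitch` | — | 1.0 | table advance per rotation over beam width; helical dose scales as 1/pitch |
| `w_r` | — | 1.0 | photon radiation weighting; the only value relevant to CT |
| tissue weights | — | ICRP 103 | shipped as a versioned JSON, validated at load by the Σ = 1 invariant |

## Numerical choices

* **Integration.** CTDI100 uses the trapezoidal rule on the supplied
  samples, with linear interpolation at the ±50 mm boundaries. The physical
  measurement is an ionization chamber that integrates continuously; no
  discretization scheme is prescribed by the method itself, so the
  trapezoid was chosen because it is exact for the piecewise-linear test
  oracles and within 0.1 % of Gaussian closed forms at 1 mm sampling.
* **Profile centering.** z = 0 is the profile's stated isocenter; when a
  file's positions are not centered, the mid-span is used. No automatic
  peak-finding is performed, so asymmetric profiles are never silently
  re-centered.
* **Relative CTDI is an exact lookup**, not an interpolation: collimations
  form a discrete scanner menu, and querying an unlisted width is an error
  that lists the menu.
* **Slab coverage** uses fractional weights for partially covered end
  slabs (overlap/thickness) on half-open intervals [start, end). This makes
  organ dose exactly additive over split ranges, which nearest-slab
  rounding would break. Helical over-ranging (extra rotations beyond the
  imaged range) is not modelled.
* **Volume (wide-cone single-axial) scans** irradiate a window of the
  collimation width centered on the requested range, with no table motion;
  the collimation must cover the range. When the narrow and wide
  collimations carry equal relative-CTDI factors, contiguous-axial and
  volume acquisitions over the same range at the same per-rotation mAs give
  identical organ doses — the engine reproduces this equivalence exactly,
  and when the factors differ the doses differ by exactly their ratio.
* **Matching score.** The reference-library scoring rule of the original
  worksheet tooling is not published; `ctdose` uses the sum of relative
  absolute differences of the head and body factors, equally weighted. It
  is symmetric, dimensionless, and isolated behind `match_scanner()` so it
  can be swapped. When the library lacks the requested kV the nearest
  available kV is used with a warning, since reference datasets exist only
  at discrete tube voltages.
* **Missing organs.** An organ with no conversion factor is dropped from
  the converted result (with a warning) rather than passed through —
  passing a stylized-phantom dose off as a voxel-phantom dose would
  silently mix phantoms. Remainder tissues absent from a dose map are
  excluded from the remainder mean rather than counted as zero, which
  would silently bias ED downward for datasets that do not score every
  remainder tissue. Named weighted tissues absent from the map contribute
  zero, with a warning.
* **Sex handling.** The stylized phantom is partially hermaphrodite (it
  has testes, ovaries and uterus but no female breasts). The male pipeline
  maps testes to the gonad tissue and drops ovaries; the female pipeline
  the reverse. The female breast conversion factor is applied even though
  the source phantom lacks female breasts — encoding that correction is
  the CF table's job. Sex averaging takes the per-tissue mean over the
  union of tissues, a single-sex tissue contributing its value at half
  weight; this is exactly how the single-sex gonad doses combine into the
  averaged gonad term.

## What the synthetic generators emulate — and what they do not

Real per-slab Monte Carlo coefficient datasets and published
conversion-factor tables are proprietary third-party data, so the package
generates structurally faithful stand-ins: organs × 208 slabs of
nonnegative coefficients with smooth, localized (Gaussian, 3σ-truncated)
longitudinal profiles; scanner CTDI sets whose free-in-air value dominates
the attenuated body center and rises roughly with kV²; conversion factors
in [0.3, 2.0] respecting sex anatomy; and reference libraries with a
planted nearest neighbour (within 0.5 % of the target's factors, decoys at
least 6 % away per factor).

Every generator is a pure function of its seed, and the dataset generator
emits a manifest of expected organ doses computed by a separate
straight-line loop that never calls the dose engine — a true oracle.

What passing tests therefore show: the bookkeeping — integration, clamping,
coverage geometry, scaling laws, ratio conversions, tissue weighting — is
correct. What they cannot show: agreement with any real scanner's measured
CTDI values or any real Monte Carlo coefficient set, since the synthetic
profiles make no claim of anatomical realism. Dose numbers printed from
fixture bundles are arbitrary-scale illustrations, not clinical values.

Problem sizes used by the test-suite and the acceptance script — hundreds
of randomized property cases, libraries of 10–30 entries, 25–100 seeded
datasets — were chosen as the smallest sizes at which the properties are
exercised across all code paths.

## Degenerate inputs and edge behaviour

Zero mAs, zero coefficient matrices and empty dose maps all produce zero
doses rather than errors. A scan range outside the phantom, a kV mismatch
between dataset and protocol, an unlisted collimation, a zero
stylized-phantom dose in a conversion ratio, and a weighting scheme whose
weights do not sum to 1 are all hard errors with descriptive messages.
Score ties in matching resolve to the earlier library entry,
deterministically.

## Known limitations

* Automatic exposure control (tube-current modulation) and ECG-gated
  acquisition are not modelled; the tube current is constant over the
  range.
* Conversion factors are treated as given per examination category; no
  interpolation between categories is attempted for nonstandard ranges,
  so scan-range flexibility is limited by the CF tables supplied.
* Chamber calibration, PMMA-to-air corrections and measurement-uncertainty
  propagation are out of scope: CTDI inputs are taken as already reduced
  to mGy per 100 mAs.
* The relative-CTDI factor is applied multiplicatively to the free-in-air
  CTDI; a collimation-specific re-measurement of CTDIair is not supported.
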