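---
title: "Methods behind anthoblue: characterising a cyan anthocyanin colorant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind anthoblue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthoblue)
```

`anthoblue` implements the quantitative analyses used to characterise an
anthocyanin-based cyan colorant — the 1:3 aluminium complex of the
sinapoylated red-cabbage anthocyanin P2 — and the esterase-driven
enrichment of P2 from the natural anthocyanin mixture. This vignette is
the package's account of the underlying models, the defaults and why
they were chosen, what the synthetic-data generator does and does not
emulate, and the numerical decisions that make results deterministic.

## Spectral metrics

A spectrum is a strictly increasing wavelength grid with absorbances in
AU. Three metrics drive the colorant assessment:

- **λmax** is the argmax of the sampled absorbance restricted to an
  analysis window, by default 400–700 nm (the visible range). Ties and
  plateaus resolve to the *longer* wavelength so the result is
  deterministic; no sub-grid interpolation is attempted, because the
  instrument grid (1 nm in all fixtures) already matches the precision
  at which band maxima are reported in this field.
- **Bathochromic shift** is the signed difference
  λmax(shifted) − λmax(reference); positive is a red-shift. Formation of
  the aluminium complex moves P2 from 598 to 640 nm, a +42 nm shift.
- **Violet contribution (VC)** is the area under the absorbance curve
  between 500 and 600 nm, computed as a *left Riemann sum*: absorbance at
  each left endpoint times the grid spacing, with 600 nm itself excluded
  as the final right endpoint. This literal summation convention (rather
  than trapezoid quadrature) is retained deliberately: VC is a
  comparative statistic, and the convention is part of its definition.
  Non-uniform grids are resampled to 1 nm first, since a Riemann sum
  presumes a single spectral resolution. Absorbances are *not* clipped at
  zero — baseline noise can dip negative, and clipping would bias VC
  upward silently.

On a 1-nm grid the left Riemann sum differs from fine-grid quadrature by
up to ~1.5% for a band edge that rises monotonically across the window;
at 0.1-nm resampling the difference falls well below 1%. The test suite
checks both the convergence under grid refinement and the 0.1-nm
agreement with an independently coded trapezoid oracle.

## Colorimetry

Absorbance is bridged to colour via Beer–Lambert transmittance
`T(λ) = 10^(−A(λ)·s)` (clipped to [0, 1]; `s` is a dimensionless
path-length scale), then integrated against the CIE 1931 2° observer
under an illuminant to tristimulus values, normalised so a perfect
transmitter has Y = 100. CIELAB, hue angle and chroma follow the
standard formulas, including the linear segment below (6/29)³; on the
neutral axis (a\* = b\* = 0) hue is undefined and returned as a flagged
`NA` rather than an arbitrary number.

The original colorimetric measurements' instrument geometry, observer
and illuminant are not available, so these are explicit settings with
conventional defaults (CIE 1931 2°, D65, 1-nm steps). The observer and
D65 tables are transcribed at 5 nm from the standard CIE tables and
interpolated linearly to the working step; they live in plain R source,
so the package ships no binary data. Consequences of this choice are
confined to third-decimal differences in Lab coordinates, far below the
hue-angle contrasts the analyses rest on. Colour *difference* is CIE76
(Euclidean in Lab) and hue matching is reported as |Δh| in degrees
alongside ΔE, because the colorant-matching argument is made in
hue-angle terms. Absolute Lab coordinates of physical product samples
are out of scope: they depend on instrument settings the package cannot
know.

## Multistate equilibria and pK′h fitting

The flavylium multistate is lumped into three pools: the red flavylium
cation AH⁺ (reference), the colored quinoidal base A (acid–base constant
pKa) and the colorless hydrated forms — hemiketal plus chalcones —
governed by the *apparent* hydration constant pK′h. The colored fraction
at a given pH is

$$f(\mathrm{pH}) = \frac{1 + 10^{\mathrm{pH} - pK_a}}
{1 + 10^{\mathrm{pH} - pK_a} + 10^{\mathrm{pH} - pK'_h}}.$$

pK′h is recovered from titration data by nonlinear least squares on the
restricted sigmoid `A(pH) = A₀ / (1 + 10^(pH − pK′h))`, valid in the
acidic regime where the quinoidal base is negligible (below pH ~6 for
cyanidin derivatives). Endpoint (equilibrium) absorbances are assumed;
pH-jump relaxation kinetics are not modelled. Starting values are data
driven and deterministic: A₀ from the maximum absorbance, pK′h from the
pH of half-maximal absorbance. The fitter is Levenberg–Marquardt
(`minpack.lm`); an exhaustive grid search over pK′h (step 10⁻³, A₀
profiled in closed form) serves as the independent oracle in tests.
Under the default simulation conditions (26 points over pH 0.5–6.5,
noise 0.005 AU) recovery is accurate to ±0.05 for a single series and
the median absolute error over 200 replicates is below 0.03, with 95% CI
coverage in the 90–99% band.

## Degradation kinetics

Colour loss is modelled mono-exponentially, `A(t) = A₀e^(−kt)` with
k ≥ 0, because stability is summarised as single percent-loss figures;
no biexponential component is fitted by default. A constant series
returns k = 0 with an infinite half-life rather than an error. Percent
loss at time t is `100·(1 − e^(−kt))` from the fitted model; requests
beyond the observed span are answered but flagged as extrapolation.

## Exact-mass stoichiometry

Anthocyanin formulas are composed by residue arithmetic: the cyanidin
flavylium core C₁₅H₁₁O₆⁺ plus, per residue, glucosyl C₆H₁₀O₅ and the
hydroxycinnamoyl increments p-coumaroyl C₉H₆O₂, feruloyl C₁₀H₈O₃ and
sinapoyl C₁₁H₁₀O₄ — each already net of the water lost on condensation.
P2 (three glucosyls, one sinapoyl on Glc-2) composes to C₄₄H₅₁O₂₅⁺,
monoisotopic m/z 979.2714.

Complex-ion m/z is `(k·M(L) + M(metal) − n·M(H) − z·mₑ)/|z|` for k
ligand units, n hydrogens removed and charge z. Two conventions matter:

- **Hydrogen loss is a free variable.** Bracket notations like
  "[3M+Al−2H]²⁻" are ambiguous about whether M counts the flavylium
  cation or a neutral base, so the engine matches by mass over a search
  range of n and reports the implied value, rather than trusting any
  notation.
- **Electron mass is included** (subtracted per positive charge, added
  per negative). At m/z ≈ 1000 and 10-ppm tolerances, the ~0.55 mDa
  electron term is the same order as the matching slack and cannot be
  dropped.

The stoichiometry search enumerates (k, n, z) over defaults k 1–6,
n 0–12, |z| 1–4 (both polarities unless the ionisation mode is given),
keeps candidates within a ppm tolerance (default 10 ppm, the
external-calibration ESI-TOF regime) and reports the ligand count that
matches *all* observed peaks as the consensus. For the P2/aluminium
system, k = 3 is the unique consensus across the default space for the
two observed peaks at m/z 1478.8629 and 985.5760 — the doubly and triply
charged tri-ligand ions. Because opposite-polarity candidates differ by
only two electron masses (~1 ppm at m/z 1000), polarity should be fixed
from the ionisation mode whenever sub-2-ppm discrimination matters.

## Chromatography

Peak handling follows routine DAD practice rather than model-based
deconvolution: local maxima above height and prominence thresholds,
boundaries at flanking valleys, trapezoid integration above a straight
valley-to-valley baseline per peak, and nearest-reference assignment
within a retention-time tolerance (conflicts resolved in favour of the
nearer peak; assignment never alters areas). Default thresholds derive
deterministically from the data — 5× and 2× the robust noise (MAD of the
running-median residual). Conversion metrics use *relative* areas so
injection-volume differences between runs cancel; the converted fraction
is `1 − (acylated relative area after)/(before)` and conversion ≥ 0.99
is flagged complete. Overlapping peaks are split at the valley minimum
(perpendicular drop); no global baseline model is fitted. These
conventions are adequate for the well-separated synthetic fixtures; on
real traces with fused peaks they under- or over-split, which is why
percent figures from real chromatograms are not asserted anywhere.

## Sequence-screen statistics

Percent identity between two enzymes is computed from a pairwise global
(Needleman–Wunsch) alignment — BLOSUM62, gap open 10 / extend 1 — as
identical columns divided by the *full alignment length including gap
columns*. A multiple-sequence alignment in a GUI tool was the original
route to the published medians; pairwise-global was chosen here because
it is reproducible and dependency-light, and the denominator convention
was kept because it produces the same qualitative regime (single-digit
identities for unrelated proteins). The two conventions do not agree
numerically: under pairwise-global scoring, two unrelated proteins of
comparable length already align to ~14–17% identity, so the published
medians of 7.0% (all tested) and 13.0% (active subset) are not
reproducible exactly under this scheme. The package therefore treats the
*ordering* — active enzymes more self-similar than the full panel — as
the property to emulate and verify, and reports medians under its own
documented convention. The alignment engine is cross-checked in tests
against an exhaustive small-alignment enumeration oracle, and medians
against a sort-based oracle.

## The synthetic-data generator

The generator defines the study conditions; every fixture carries a
machine-readable provenance note and all stochastic fixtures require an
explicit seed (same seed ⇒ bit-identical output, via a local RNG that
never touches global state).

- **Spectra** are sums of Gaussians on a 1-nm, 400–700 nm grid. Only the
  band *centers* are literature-anchored (e.g. P2 598 nm free, 640 nm
  with ⅓ eq Al³⁺; the four reference blues at 630/617/608/640 nm). Band
  widths (σ 35 nm main, 45 nm shoulder) and heights are package choices;
  violet-side shoulders on the red-cabbage mix and spirulina encode
  their larger violet contributions, and the main-band center is
  numerically calibrated so the sampled apex equals the printed λmax
  even in the presence of a shoulder.
- **Decay series** derive k from a stored calibration point — 57% loss
  at day 10 for the RCA syrup, 14% at day 55 for the Al complex — so
  noiseless series reproduce those numbers exactly by construction.
  Aqueous-series rates are package choices. The weekly sampling grid is
  a package choice as well; the original sampling intervals are not
  published.
- **Titrations** use the published pK′h values (P1 2.1, P5 2.7, P8 3.7,
  P2 4.4) as simulation truths with 0.005 AU noise over 26 points.
- **Chromatograms** place eight Gaussian peaks (σ 0.15 min) at fixed
  reference times over 8–38 min. The untreated P2 relative area is set
  to 4% — a choice satisfying the published "<5% of total anthocyanin
  content" bound, not a measured value. The complete-conversion fixture
  leaves 0.36% residual acylated area.
- **Sequence panels** build the active subset from a common ancestor
  (35% of positions conserved, lengths 120–300) and inactive members as
  unrelated random sequences (lengths log-uniform 80–500). Lengths are
  kept moderate so a full 46-enzyme identity matrix (1035 alignments)
  computes in tens of seconds.

What the generator does *not* emulate: real band asymmetry and
instrument baselines, co-eluting shoulders in chromatograms, pH-jump
kinetics, isotope envelopes, and homology structure beyond a one-level
ancestor model. Passing tests therefore demonstrate correctness of the
analysis machinery under controlled conditions, not instrument-grade
robustness.

## Numerical choices and degenerate inputs

- λmax ties break to the longer wavelength; VC excludes the 600-nm right
  endpoint; resampling refuses extrapolation and reproduces original
  points exactly when the grid is a subset.
- Fits are deterministic given data: data-driven starts, bounded
  parameters (k ≥ 0), Levenberg–Marquardt refinement.
- Degenerate inputs get sentinels, not guesses: flat traces give empty
  peak tables, constant decay series give k = 0 with infinite half-life,
  the neutral colour axis gives a flagged undefined hue, a stoichiometry
  search with no match returns an empty table, and an empty screen
  returns NA for the active fraction.
- Pipeline reports contain no timestamps and are written with
  `jsonlite` at full precision, so identical configuration and seed
  reproduce reports byte for byte.

## Problem sizes used by the test suite

Simulation sizes were chosen to probe each statistical claim at modest
cost: 200 replicate titration fits for the recovery study, 100
round-trip stoichiometry assignments, 1000 single-point replicates for
the simulation-bias check, and one full 46-sequence identity matrix.
The whole suite runs in under a minute on one core.

## Known limitations

- CIE tables are 5-nm transcriptions interpolated to 1 nm; good to the
  third decimal in Lab, not a metrology-grade implementation.
- The hydration model omits the quinoidal base above pH ~6 and assumes
  equilibrium endpoints; pK′h from pH-jump initial rates would need a
  kinetic extension.
- Valley-to-valley integration is biased for strongly fused peaks.
- Identity medians are convention-dependent (see above); trees are not
  built, only a distance export is provided.
- Average-mass (as opposed to monoisotopic) workflows and isotope
  envelopes are not implemented.
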