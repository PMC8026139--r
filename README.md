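# anthoblue

Quantitative analytics for anthocyanin-based blue colorants — in
particular the cyan Al³⁺(P2⁻)₃ complex obtainable from red cabbage
anthocyanins (RCAs) — and for the enzymatic transformation that enriches
its precursor P2.

## The problem and who this is for

A natural replacement for the synthetic cyan dye FD&C Blue No. 1 needs
three things at once: an absorbance maximum near 630–640 nm, a small
"violet contribution" (residual absorbance between 500 and 600 nm, which
muddies blends), and chemical stability at neutral pH. Assessing a
candidate colorant therefore mixes UV-visible spectroscopy, colorimetry,
equilibrium and kinetic modelling, exact-mass spectrometry and HPLC
quantitation. `anthoblue` packages those analyses as composable,
tibble-first R functions for food-colorant chemists and analytical
scientists, together with a seeded synthetic-data generator so every
stage can be exercised and tested without instrument data.

## What it computes

- **Spectral metrics** — λmax over an analysis window (default 400–700 nm,
  ties to the longer wavelength), bathochromic shift
  Δλ = λmax(shifted) − λmax(reference), and the violet contribution
  VC = Σ<sub>λ∈[500,600)</sub> A(λ)·Δλ, a left Riemann sum of absorbance
  over 500–600 nm.
- **Colorimetry** — Beer–Lambert transmittance T = 10^(−A·s), CIE 1931 2°
  tristimulus integration under D65, CIELAB (L\*, a\*, b\*), hue angle
  h = atan2(b\*, a\*), chroma, and ΔE\*₇₆ for colorant matching.
- **Multistate equilibria** — the colored fraction
  (1 + 10^(pH−pKa)) / (1 + 10^(pH−pKa) + 10^(pH−pK′h)) of the flavylium
  network, and nonlinear least-squares recovery of the apparent hydration
  constant pK′h from titration data via A(pH) = A₀ / (1 + 10^(pH−pK′h)).
- **Degradation kinetics** — first-order fits A(t) = A₀e^(−kt), half-life
  ln 2 / k, and percent loss 100·(1 − A(t)/A(0)).
- **Exact-mass stoichiometry** — molecular-formula algebra over anthocyanin
  building blocks (cyanidin + glucosyl + hydroxycinnamoyl residues),
  monoisotopic masses with electron correction, multivalent complex-ion
  m/z = (k·M(L) + M(metal) − n·M(H) − z·mₑ)/|z|, and an enumeration search
  over (k, n, z) that assigns metal:ligand stoichiometry from observed
  ESI-TOF peaks within a ppm tolerance.
- **HPLC conversion metrics** — peak detection, valley-to-valley baseline
  integration, P1–P8 assignment, and the converted fraction of acylated
  anthocyanins after esterase treatment.
- **Esterase-screen sequence statistics** — pairwise global-alignment
  percent identity (identical columns over the full alignment length),
  identity matrices, subset medians and screen summary counts.

## Worked example

```r
library(anthoblue)

# spectral character of the Al complex vs free P2
shift <- bathochromic_shift(make_spectrum_fixture("P2_0eq"),
                            make_spectrum_fixture("P2_Al13"))
vc <- violet_contribution(make_spectrum_fixture("alp2_pH7"))
c(shift_nm = shift, violet_contribution = vc)
#>            shift_nm violet_contribution
#>           42.000000            6.654839

# stoichiometry of the aluminium complex from its exact masses
p2 <- compose_anthocyanin(anthocyanin_spec(acyl_groups = c(`Glc-2` = "sinapoyl")))
format(p2)
#> [1] "C44H51O25+1"
assign_stoichiometry(c(1478.8629, 985.5760), p2, metal = "Al")$consensus_k
#> [1] 3

# hydration resistance of P2 recovered from a noisy titration
fit_pkh(make_titration_fixture("P2", seed = 42))
#> Hydration fit: pK'h = 4.389 (SE 0.005, 95% CI 4.379-4.399), A0 = 1.0036, n = 26

# syrup-stability percent losses from the calibrated decay fixtures
c(rca_day10 = percent_loss(make_decay_fixture("rca_syrup"), 10),
  alp2_day55 = percent_loss(make_decay_fixture("alp2_syrup"), 55))
#>  rca_day10 alp2_day55
#>         57         14
```

The shift of +42 nm (598 → 640 nm) is the signature of the 1:3
aluminium complex forming; a VC of ~6.7 nm·AU marks a much purer cyan
than the red-cabbage mixture (~60 nm·AU); the consensus k = 3 is the
ligand count that simultaneously explains both multivalent ion peaks
within 10 ppm; and the decay fixtures reproduce their calibration points
exactly because the generator derives its rate constants from them.

## Package tour

- `R/spectrum.R`, `R/spectral-metrics.R` — spectrum container, CSV I/O,
  resampling, λmax / VC / shift.
- `R/cie-data.R`, `R/colorimetry.R` — packaged CIE tables and the
  transmittance → XYZ → Lab → hue pipeline.
- `R/equilibria.R`, `R/kinetics.R` — multistate speciation, pK′h and
  first-order decay fitting (`tidy()`/`glance()` methods included).
- `R/formula.R`, `R/anthocyanin.R`, `R/complex-ions.R` — formula algebra,
  building-block composition, complex-ion m/z and stoichiometry search.
- `R/chromatogram.R` — peak detection, integration, assignment,
  conversion metrics.
- `R/seqid.R` — alignment-based identity statistics and FASTA/PHYLIP I/O.
- `R/fixtures.R` — the calibrated fixture library and `make_*` generators.
- `R/pipeline.R` — YAML-configurable multi-stage runner with
  byte-reproducible JSON reports.

See `vignettes/cyan-colorant-analytics.Rmd` for the methods account:
model assumptions, parameter defaults, generator calibration and known
limitations.
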