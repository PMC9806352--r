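---
title: "Band-weighted label-free quantification of venom composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-weighted label-free quantification of venom composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomcomp)
```

## The quantification model

A gel-band venomics experiment separates crude venom on SDS-PAGE, excises
the stained bands, and identifies each band's proteins by LC-MS/MS. For
protein X the pipeline computes

$$\%X = 100 \sum_{n=1}^{N}
  \frac{\mathrm{AUC}(X, B_n)}{\sum_{\mathrm{toxins}\ Y} \mathrm{AUC}(Y, B_n)}
  \; p(B_n),$$

where $\mathrm{AUC}$ is the spectral-intensity area under the curve reported
by the search engine, the inner normalisation runs over the *toxin* hits of
band $B_n$, and $p(B_n)$ is the band's densitometric proportion of the lane.
The two-level structure reflects what each measurement can support: spectral
AUCs are comparable *within* a band (same digest, same injection), while the
stained lane intensity measures how much protein each band contributes to
the whole venom. A protein spread over several bands accumulates over all of
them.

Assumptions worth making explicit:

- AUC is proportional to protein amount within a band. Ionisation
  efficiency differences between proteins are not modelled; the statistic is
  a relative, not molar, abundance (no iBAQ/NSAF-style correction).
- The densitometric proportions are normalised **over the analysed bands
  only**, not the whole lane. Under this convention the composition always
  totals 100%; unexcised lane regions are simply outside the measured
  universe.
- Non-toxin and contaminant identifications are excluded from numerator
  *and* denominator, since the statistic is a composition of the toxic
  secretome. Which accessions count as toxins comes from the annotation
  map, never from a heuristic.

## Quality filtering

Hits are retained when the protein score ($-10\log_{10} p$) is at least 50
and at least one unique peptide supports the identification; both thresholds
are inclusive, matching the usual "≥" conventions. Contaminants and decoys
are flagged by accession (exact match or prefix, e.g. `CRAP_`, `DECOY_`)
before filtering. Search-level FDR (default 0.1%) is a setting of the
upstream engine rather than an output column, so the package carries it as
metadata; `estimate_decoy_fdr()` exists so synthetic datasets with planted
decoys can verify that the score threshold enforces the intended regime. The
unique-peptide rule is applied per band: each band's identification stands
alone. Filtering is idempotent, order-independent, and monotone in the
score threshold; all three properties are tested.

## Densitometry

A lane profile is a sampled, piecewise-linear intensity curve over migration
position. Bands are half-open intervals $[start, end)$ so adjacent bands
partition cleanly. Two numerical choices matter:

- **Baseline**: a valley-to-valley straight line through the profile values
  at the band edges, subtracted inside the band and clipped at zero. Gel
  backgrounds vary slowly along the lane, and with no published algorithm to
  match this is the simplest defensible default.
- **Integration**: exact trapezoidal integration of the piecewise-linear
  profile, with interpolated boundary points, so band edges need not fall on
  sample positions and refining the sampling grid of a piecewise-linear
  signal leaves areas unchanged (tested). Proportions are scale-invariant in
  the intensities.

Users who quantified bands in external gel software can bypass both steps
with `proportions_from_areas()`.

## Transcript abundance and the translation index

Transcript abundance uses standard TPM:
$\mathrm{TPM}_i = 10^6 (c_i/\ell_i) / \sum_j (c_j/\ell_j)$ with expected
counts $c$ and effective lengths $\ell$. Family-level transcriptome
percentages are computed over toxin-annotated transcripts only, mirroring
the proteome denominator, so the two compositions are comparable.

The translation index of family $f$ is its proteome percentage divided by
its transcriptome percentage; it is undefined exactly when the family is
absent from the transcriptome. Because both compositions are closed to
100%, the vector of true translation efficiencies $\tau$ is identifiable
only up to one global factor: if transcript shares are proportional to
$\pi_f/\tau_f$, then the raw index equals $\tau_f \sum_g \pi_g/\tau_g$, not
$\tau_f$. `estimate_translation_fold()` resolves the scale by centring the
defined indices on their median (geometric mean optional), under the
assumption that most families translate at baseline efficiency — the usual
centring move for compositional ratios. With one boosted family among many
baseline families the median-centred estimate recovers the planted fold
exactly in the noise-free limit (tested), while the raw index is reported
unchanged for users who prefer to interpret it directly.

## Assay unit calculations

- **Turbidity reduction units**: one TRU is the enzyme amount halving the
  reaction's turbidity. The definition fixes the unit but not how partial
  reductions map to TRU counts; the package prorates linearly
  (reduction%/50) — the simplest convention consistent with the definition —
  and records it in output metadata. Activity divides by venom mass (mg)
  and incubation time (min), so it scales exactly inversely with both. A
  sample more turbid than the control yields a warning and activity 0.
- **Standard-curve specific activity**: ordinary least squares on all
  provided (amount, absorbance) points; the line is inverted to convert a
  sample absorbance to nmol of substrate cleaved, then normalised per mg
  per min. Extrapolation beyond the calibrated range is permitted but
  flagged, as are negative inferred amounts. A slope numerically
  indistinguishable from zero (|slope| < 1e-12) is an unusable-curve error.
  Specific activities are reported per mg; per-ng readings of the same
  quantity are dimensionally surprising and are not produced.
- **Relative haemolysis**: the positive control (e.g. 0.5% Triton X) is
  100%, the blank 0%, with linear interpolation between and no clipping;
  blank correction is on by default and can be disabled. The percentage is
  invariant to adding a constant to all three absorbances.
- **Clotting delay**: absolute delay and fold change versus control plasma.
  When no clot forms inside the instrument's observation window the result
  is censored and the fold is reported as a lower bound at
  window/control — a censored observation must never be presented as an
  exact fold.

## The synthetic-data generator

`simulate_venom_dataset()` builds every pipeline input from a planted
ground truth so each stage can be checked against known answers:

- **Migration and bands.** Each protein gets a molecular weight (drawn
  log-uniformly in 10–100 kDa unless supplied) and a migration position
  linear in $\log_{10}$ MW, descending — the standard SDS-PAGE calibration;
  the exact constants are configuration, not science. Peaks are Gaussian
  (width 0.4 position units) with height proportional to true mass share;
  bands are intervals around single-linkage clusters of peak centres, with
  margins chosen so band intervals stay disjoint.
- **Spectral hits.** The AUC of protein p in its band is (true within-band
  share) × (band area) × log-normal noise, which collapses to mass share ×
  noise after normalisation — so the noise-free pipeline recovers the
  planted composition to machine precision (tested at 1e-9). True-hit
  scores are drawn from a high distribution truncated above the score
  threshold, decoy scores from a low (null) distribution, so planted
  pass/fail counts are exact and the decoy FDR estimator has something to
  measure. Contaminants (`CRAP_`) and decoys (`DECOY_`) receive trace-level
  AUCs but contribute nothing to the lane signal: planted contamination is
  trace contamination, not a stained band.
- **Transcripts.** Family transcript abundance is proportional to
  $\pi_f/\tau_f$ with per-transcript log-normal dispersion (the same
  `noise_sd_log`), renormalised to $10^6$ TPM.
- **Determinism.** One RNG stream per dataset, seeded from `truth$seed`,
  with a fixed draw order (proteins, lane, hits, contaminants, decoys,
  transcripts); files are written with fixed full-precision formatting, so
  simulate + write + quantify is byte-identical across runs (tested).

What the generator does **not** emulate: protein-specific ionisation
efficiency, peptide-level missingness, band bleed-over (each protein's
signal lands in exactly one band), chimeric identifications, and real
assembly/annotation noise in the transcriptome. Passing the recovery tests
therefore shows the *computations* are correct and well-conditioned under
multiplicative intensity noise — not that the statistic is unbiased on real
spectra, where the within-band proportionality assumption carries the risk.

## Validation choices and problem sizes

The test suite validates composition conservation (sum 100 ± 1e-9 whenever
every analysed band holds a toxin hit), equivalence with a deliberately
naive double-loop evaluation of the abundance equation on 200 random
micro-instances (≤ 4 bands × ≤ 6 proteins, max |Δ| < 1e-10), planted
composition recovery (20 seeds, 12 families, noise 0.2: mean absolute error
< 2 percentage points), translation-fold recovery (planted 10× within
± 20% at noise 0.1, via the median-centred estimator), exact planted filter
counts, TPM normalisation to relative 1e-6, and byte-level determinism.
These sizes keep the full suite under a few seconds while giving the
stochastic checks comfortable margins (observed recovery error is ~0.7
points against the 2-point bound).

Degenerate inputs fail loudly with classed conditions: an all-zero lane, a
band outside the profile, all-zero transcript counts, a positive control at
or below the blank, conflicting annotations. The one policy decision left
to the user is the zero-toxin band: `renormalise` (default) rescales
proportions over toxin-bearing bands so the composition still closes to
100%, matching how published compositions total ~100; `error` is the audit
mode that names the offending band. Display rounding is 2 decimals with no
post-rounding renormalisation, so printed tables may total 100 ± 0.01 —
matching field practice.

## Limitations

- Relative abundances only; no molar or mass quantification.
- Protein grouping is taken from the search export; no peptide-to-protein
  inference is re-done.
- Automatic band detection from the profile is out of scope; band
  boundaries come from the user (or the generator).
- Differential expression between tissues is out of scope; precomputed DE
  results can ride along as metadata but are not interpreted.
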