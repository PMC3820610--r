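---
title: "Processing multiplexed shotgun lipidomics data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing multiplexed shotgun lipidomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunlipids)
```

This vignette explains the science behind `shotgunlipids`: the models each
stage implements, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## Mass model

All masses derive from a single frozen table of monoisotopic atomic masses
(IUPAC values at >= 9 decimals for C, H, N, O, P, S, Na) and the electron
mass, exposed via `atomic_mass_table()`. An adduct ion's m/z is

$$ m/z = \frac{m(M \pm \Delta) - z\,m_e}{|z|} $$

where $\Delta$ is the adduct's elemental delta (e.g. NH4 for [M+NH4]+) and
$m_e$ the electron mass. The electron-mass correction is not optional: at
the 5-decimal precision of Orbitrap FT MS data, omitting it shifts every
positive ion by +0.00055 Da — a quarter of the identification tolerance —
and the published reference values (e.g. 860.77017 for the TAG internal
standard ammonium adduct) are only reproducible with it. Only singly
charged adducts are supported; multiply charged lipid ions are rare in
direct infusion and out of scope. Internally all math runs at full double
precision; rounding to 5 decimals (m/z) and 1 decimal (ppm) happens only
at display time.

Isotopologue envelopes (M+0, M+1, M+2) come from the exact polynomial
expansion over per-element heavy-isotope abundances (13C 0.0107, 2H, 15N,
17/18O, 33/34/36S), computed by truncated convolution with per-element
exponentiation. A carbon-only binomial would be accurate to ~1e-3 for
typical lipids; the full expansion costs nothing and is exact, so it is
the default. The test suite checks it against an independent atom-by-atom
polynomial expansion.

## The lipid database

Species are enumerated per class as sum compositions — class plus total
chain carbons `c`, double bonds `db` and (sphingolipids only) hydroxyls
`oh`. Chain-level identities ("PC 16:0-18:1") are never represented:
survey FT MS cannot distinguish them, and pretending otherwise would
overstate the information content of the data.

Formulas are assembled from building blocks:

* `n`-acyl glycerophospholipids/glycerolipids/sterol esters:
  `backbone + C_c H_{2c-2db} O_{2n} − n · H2O`. Backbones are the
  head-group alcohols (glycerophosphocholine C8H20NO6P for PC/LPC,
  glycerophosphoethanolamine C5H14NO6P for PE/LPE, glycerol C3H8O3 for
  DAG/TAG, cholesterol C27H46O for CE, and so on).
* Ether classes (`PC O-`, `PE O-`) are separate class templates whose
  arithmetic replaces one ester bond with an ether bond, a net `+H2 −O`
  per ether chain. Keeping them as templates (rather than a modifier flag)
  keeps the formula arithmetic uniform and lets class-specific adducts and
  ranges be configured independently.
* Sphingolipids: a long-chain-base core `C_c H_{2c+1-2db} N O_{oh+1}`
  plus a head-group delta (phosphocholine for SM, hexose for HexCer,
  sulfated hexose for SHexCer). The OH index is carried in the annotation
  (`SM 36:1;2`).

A double-bond sanity cap `db <= floor(c/2)` (configurable) excludes
chemically implausible combinations. The shipped default configuration
covers the 20 classes routinely monitored in positive/negative multiplexed
analysis of tissue extracts (about 1,900 species with the default index
ranges); class templates, ranges and adducts are all data, so entire
classes can be added without code changes. The database round-trips
through a one-file-per-class tab-separated text format for auditing and
editing.

Internal standards are chain-defined molecules (e.g. TAG 17:1/17:1/17:1),
stored as the ordinary species at their summed indices (TAG 51:3) and
displayed under their chain-level spike label, so quantification can
reference them by label while all mass math flows through the same
machinery. The diether PE standard is represented through the single-ether
`PE O-` template at its summed indices; at sum-composition level this is
the conventional compromise, and its m/z is what the target list carries.

## Calibration offsets and lock masses

FT MS calibration drifts over an injection series. The package models the
drift as a per-acquisition additive m/z offset, estimated from lock mass
ions — reliably present ions of known composition (a ubiquitous chemical
background ion such as tris(ditert-butylphenyl) phosphate in positive
mode, and/or spiked internal standards).

For each lock the most intense profile bin within
`theoretical ± search_window` (default ±0.01 Da, deliberately wider than
the identification tolerance so a drifted lock is still found) is located;
if it reaches `min_intensity` (default 0) the centroid is estimated by the
three-point quadratic — the vertex abscissa of the parabola through the
apex bin and its two neighbours, solved for general non-uniform spacing.
A degenerate (flat or upward-curved) triplet is an error for the
standalone function; inside lock estimation it falls back to the apex bin
m/z, and a lock below threshold is recorded as *missing data*, never an
error — a missing lock is itself the QC signal that identifies unspiked
samples.

The combined per-acquisition offset is the unweighted arithmetic mean of
the detected per-lock offsets, in Da (not ppm): the published worked
example combines −0.00077 and −0.00128 to −0.0010 at display precision,
which is the absolute-Da mean. The offset is applied to *theoretical*
values (shifting search targets toward the instrument); measured values
are never altered. Offsets are estimated per scan range, using only the
locks whose m/z falls in that range.

## Targeted extraction

Identification is targeted: a per-scan-range target list (species whose
allowed-adduct ion m/z falls within the range bounds, filtered by class
and index predicates, plus explicit standards and lock entries) is matched
against each averaged peak list. For every target the maximum intensity
within the closed window `adjusted ± tolerance` is exported together with
the m/z bin of the maximum (ties to the lowest m/z) and a trapezoidal
integral over the window as the peak area. The default tolerance of
±0.0020 Da matches resolving power 100,000 data.

Two deliberate asymmetries are preserved from established practice: lock
ions are centroided (sub-bin accuracy matters for the offset) while lipid
targets report the raw bin of the maximum; and a row is emitted for
*every* target, with zero intensity and missing measured m/z when the
window is empty — a dense long table per acquisition is what makes blank
subtraction and QC joins trivially alignable downstream. Note that at
resolving power 100,000 the profile peak FWHM (~0.007 Da at m/z 700)
exceeds the tolerance window, so a mis-calibrated search rarely drops to
zero intensity — it reports a tail bin pinned at the window edge with a
mass error above 1 ppm. Mass error, not intensity, is the identification
quality signal.

Per-range outputs are concatenated by the unifier, which adds a `rangeID`
column and refuses mismatched column sets. Overlapping scan ranges are
never merged.

## Quantification

The amount equation is the standard single-point internal-standard ratio:

$$ \text{amount}_{\text{fmol}} = \frac{I_{\text{species}}}{I_{\text{IS}}}
   \times \text{spike}_{\text{pmol}} \times 1000 $$

per lipid class within each acquisition. Spikes are configured in pmol (as
spike protocols are written) and amounts reported in fmol (as result
tables are published); the ×1000 is the only unit conversion. Each class
maps to exactly one standard; classes quantified against a related class's
standard (lyso classes, diacyl PE and ether PC against the PC/PE O-
standards) are explicit duplicate rows in the mapping, never inferred.

The default processing order is: join sample information → intensity
filter (strict `<`, so threshold 0 removes nothing) → blank subtraction →
isotope correction → amounts → mol%. Blank subtraction computes, per
(species, adduct, rangeID), the mean intensity over blank acquisitions and
subtracts it from every row, floored at zero. Internal-standard and
lock-mass rows are exempt: blanks are themselves spiked with standards, so
subtracting blanks there would zero every denominator of the amount
equation. Isotope correction ("type2") divides intensity by the species'
M+0 fraction, restoring the signal carried by heavier isotopologues that
the monoisotopic window cannot see; mode "none" is the escape hatch since
the exact correction in any given lab workflow varies. An acquisition
whose standard is missing yields *missing* amounts (never zero) — the
distinction between "not quantifiable" and "absent" is exactly what the
lock-mass QC surfaces.

`mol_percent()` normalises amounts to 100 within arbitrary grouping cells
(per acquisition by default) over a caller-defined universe — per class,
per category, db-index roll-ups — mirroring how lipidome compositions are
displayed. Technical replicates are never averaged before amount
computation; averaging is a display-time choice.

## The synthetic study generator

The generator stands in for the instrument and the study design: by
default 14 samples (three brain tissues × two genotypes × two mice, plus
two spiked blanks), two technical replicates per polarity — 56
acquisitions — each polarity multiplexing a low and a high m/z range, for
112 averaged peak lists in 4 folders of 28. One sample (cerebellum,
knockout mouse 2) is generated without internal standards so that its two
replicates land at injections 07 and 08 of each polarity series and
surface in the lock-mass QC, and a fixed-intensity background ion
isobaric with PI 40:3 is planted in samples and blanks alike to exercise
blank-based false-identification screening.

Each planted species contributes a Gaussian profile centred at
`ion m/z + delta` with `sigma = m/z / (100000 × 2.3548)` (resolving power
100,000 fwhm) on a fixed 0.0005 Da grid; 25 repeat scans per range are
drawn and averaged, matching routine acquisition practice. Apex intensity
is `pmol × response_factor × M+0 fraction` — scaling by the monoisotopic
fraction makes type2 isotope correction an honest round-trip rather than a
no-op. Noise is multiplicative log-normal per peak and scan (default CV
5%, a realistic shot-to-shot variability for direct infusion) plus an
additive half-normal floor (default sd 25 counts against signals of
1e5–1e7). The per-acquisition true offset drifts linearly from −0.0015 to
+0.0015 Da across each polarity's injection series. All randomness flows
from a single integer seed through derived per-acquisition seeds, so any
acquisition can be regenerated in isolation and full reruns are
byte-identical.

Two simplifications are deliberate and documented: only neighbourhoods
within 4.5 sigma of planted peaks are materialised (the empty baseline
carries no information for targeted extraction), and no chemical-noise
peak library or isotopologue peaks beyond M+0 are simulated. Passing
tests therefore demonstrate correctness of the *processing* — offset
recovery, identification accuracy, amount recovery, QC logic — not
robustness to dense real-world chemical noise, isobaric co-elution beyond
exact isobars, or detector saturation.

Default study sizes were chosen to represent the full multiplexed design
while keeping a complete end-to-end run in the tens of seconds: the full
112-file study for accounting, offset and quantification checks, and a
4-sample × 1-replicate × 3-scan variant for unit-level tests.

## Numerical choices and degenerate inputs

* Window edges are closed on both sides; equal maxima tie-break to the
  lowest m/z bin.
* `findInterval` locates window bounds in O(log n); per-window maxima are
  exact, not approximated.
* Profile spectra must be strictly increasing in m/z; duplicate m/z values
  are rejected at construction.
* Averaging scans with non-identical grids linearly interpolates each scan
  onto the first scan's grid with zero extrapolation, preserving the
  reference grid exactly; identical grids take the exact per-point mean.
* A tolerance or search window must be positive; offsets are guarded at
  |offset| < 1 Da to catch unit mistakes (an offset in ppm or mDa fed as
  Da).
* Empty candidate lists, empty manifests and missing locks are valid
  results, not errors; malformed peak-list rows are errors that name the
  offending line.

## Known limitations

* Sum-composition only; no MS/MS, no molecular species assignment.
* Exact isobars (PC 32:0 / PE 35:0 share C40H80NO8P) are both reported;
  disambiguation requires orthogonal evidence and is out of scope.
* No deconvolution of partially overlapping peaks: the max-in-window rule
  assigns the apex of whichever peak dominates the window.
* Proprietary vendor raw files are not read; input is text peak lists or
  mzML (via the optional mzR reader).
* Quantification assumes one standard per class and linear response;
  per-microgram normalisation and statistical testing are downstream
  concerns.
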