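---
title: "Methods: proteoform assignment and quantification for AEX–MS of intact AGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteoform assignment and quantification for AEX-MS of intact AGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aexms)
```

## The model

Alpha-1-acid glycoprotein (AGP) is analyzed here at the intact-protein
level, where isotopes are not resolved and all arithmetic is in **average
mass**. A proteoform is modeled as a strict sum:

$$ M = M_\text{backbone} + h\,m_\text{Hex} + n\,m_\text{HexNAc}
     + f\,m_\text{Fuc} + s\,m_\text{NeuAc} + \sum_k \Delta_k $$

with residue masses $m_\text{Hex} = 162.14$, $m_\text{HexNAc} = 203.20$,
$m_\text{Fuc} = 146.14$, $m_\text{NeuAc} = 291.26$ Da and modification
deltas $\Delta_k$ (pyroglutamate $-17.03$ on every variant;
cysteinylation $+119.14$ on AGP2, which has a free cysteine). The glycan
counts $(h, n, f, s)$ are protein-level totals over the five
N-glycosylation sites, written canonically as `H{h}N{n}F{f}S{s}`. A
monoisotopic table can be configured through
`residue_mass_table()`, but average masses are always the default.

### Composition constraints

Complex-type N-glycans on five cores impose structure on feasible
compositions (`composition_constraints()`):

* **Offset rule** `H = N + 5`: each of the five cores contributes 3 Hex
  and 2 HexNAc, and each antenna adds one Hex–HexNAc pair, so Hex always
  leads HexNAc by exactly $5 \times (3 - 2) = 5$.
* **Core floor** `N >= 10` (two HexNAc per core).
* **Antenna capacity** `S <= N − 10`: each antenna carries at most one
  sialic acid. The structures observed for AGP justify this, but it is
  not a law of glycan chemistry, so it is a flag
  (`enforce_sa_le_antennae`), on by default.
* **Fucose cap** `F <= 4` (the per-protein maximum observed on AGP).
* Enumeration bounds `N` in 10–40 and `S` in 0–25 by default — a
  deliberately generous superset of the observed ranges (HexNAc up to 28,
  sialic acids 10–19), so nothing observable is excluded by default;
  whether fully asialylated species should ever be enumerated in a native
  run is left to these configurable bounds rather than hard-coded.

`validate_composition()` is a total function returning every violated
rule, and the enumeration engine is property-tested against a brute-force
triple loop that uses only this scalar validator.

### Why retention time is part of the assignment

Two structural increments are nearly isobaric at the protein level:

$$ |2 m_\text{Fuc} - m_\text{NeuAc}| = 1.02\ \text{Da}, $$

and pairs like `H29N24F1S14` / `H31N26S12` differ by only 2.02 Da. At
~34 kDa no realistic mass tolerance separates these. AEX retention under
a salt-mediated pH gradient, however, tracks the sialic-acid count, which
differs between the members of both pairs. `calibrate_rt_to_sa()` turns
anchor points (one chromatographic peak per count; by default counts
10–19 spread linearly over the 16–50 min elution window) into a monotone
map, either a step map to the nearest anchor (default — each peak *is*
one count) or rounded linear interpolation. Non-monotone anchors are
refused, predictions outside the anchor range are clamped and flagged
`extrapolated`.

### Ambiguity semantics

`match_feature()` enumerates candidates within ± `tol_Da` (default
1.0 Da — the accuracy scale at which the 1–2 Da near-isobars above are
unresolvable, configurable) and ranks by absolute error. **Any** second
candidate inside the tolerance makes the feature `ambiguous`, with all
survivors listed. We deliberately do not break such ties by the smaller
mass error: on this mass scale a sub-Da difference in error carries no
structural information, and the correct resolver is the chromatographic
constraint. The `ambiguity_report()` then classifies each ambiguous
feature by what would resolve it: differing sialic-acid counts
(`sa_count` — the constraint does it), equal counts but distinct masses
(`tighter tolerance`), or exactly coincident theoretical masses
(`unresolvable isobar`).

A consequence verified in the tests and the acceptance script: enabling
the sialic-acid constraint never increases the candidate count of any
feature, and disabling it strictly increases the number of ambiguous
features in a realistic run.

### Desialylated mode

Sialidase treatment removes all sialic acids and collapses the AEX
separation into a single peak; an adapted gradient then resolves the
genetic variants instead. `assign_desialylated()` models this by forcing
S = 0 during enumeration, dropping the retention calibration, and
optionally using retention *clusters* (`rt_lo`, `rt_hi`, `variant`) to
resolve features whose mass matches several variants' candidate sets.
This mode recovers variant shares and the variant-specific fucose and
branching distributions, which the native workflow can then take as
priors.

## Raw-signal processing

The vendor maximum-entropy deconvolution is intentionally **not**
reimplemented. Downstream analysis needs neutral masses and areas, not a
specific algorithm, so `deconvolute_ladder()` uses a transparent
adjacent-charge solver: peaks at m/z values consistent with charges $z$
and $z+1$ of one neutral mass (implied masses agreeing within 0.5 Da)
emit that mass; emitted masses are clustered within 1.0 Da and their
intensities summed. On noiseless ladders this inverts
`charge_ladder()` exactly (tested to < 0.1 Da), and the simulator
produces data this solver inverts.

Raw scans are processed per retention window (windows come from the
calibration anchors by default — midpoints between adjacent anchors —
mirroring integration of one sialic-acid peak at a time, with optional
explicit windows): sum the window's spectra, centroid
(`centroid_spectrum()`, gap clustering plus valley splitting at interior
minima below 50% of the smaller adjacent maximum), deconvolute, then
quantify each mass by trapezoidal integration of its combined 8+/9+
extracted-ion chromatograms over the window (`features_from_scans()`).
Features below 0.1% of the run's strongest area are dropped — this
suppresses chromatographic tail spillover into neighbouring windows.
`integrate_peak()` supports subtraction of a linear baseline between the
window endpoints with the corrected signal floored at zero.

## Quantification

`relative_quant()` normalizes areas to 100% within each (variant,
condition). Ambiguous features are **excluded**, not split among their
candidates: splitting would fabricate certainty, whereas exclusion gives
an unbiased profile of the unambiguous evidence, at the price of a bias
whose size is therefore always reported (the excluded-area fraction, in
the log and the `excluded` attribute). Summaries are abundance-weighted:
mean sialic acids per protein, percent afucosylated, the fucose
distribution over 0–4, and the HexHexNAc-unit distribution reported both
as antenna-equivalents ($N - 10$) and as the `H{n+5}N{n}` label.

Because chromatographic peak overlap can bias fucosylation estimates,
`fucose_sa_subset` optionally restricts the fucose summary to selected
sialic-acid peaks (e.g. `c(11, 14, 18)`, the best-resolved ones) and
renormalizes; the default uses all calibrated peaks, since on synthetic
data there is no overlap bias to avoid.

`compare_conditions()` reports per-variant deltas of these summaries with
the explicit convention *condition1 − condition2* (a profile whose
sialylation is higher in condition 2 therefore shows a negative
`d_mean_sa`).

## The synthetic-data generator

`sample_profile()` draws proteoforms from a `profile_spec()`:

* **variant shares** default 56 / 32 / 3 / 9% (AGP1\*F1 / AGP1\*S /
  AGP1\*F2 / AGP2), the composition of pooled plasma from healthy donors;
* **sialic acids**: discrete on 10–19 with mode 16. The shape
  (triangular) is a free choice — the data constrain only the range and
  the mean;
* **fucoses**: weights 0.47 / 0.33 / 0.12 / 0.05 / 0.03 over 0–4
  (afucosylated most abundant, consistent with ~47% afucosylation for
  AGP1\*F1);
* **branching**: HexNAc triangular on 22–33 with mode 27 (the H32N27
  maximum).

Sampling respects the antenna-capacity rule by conditioning the
sialic-acid draw on the drawn HexNAc (counts exceeding $N - 10$ are
renormalized away); if no branching value in the support can carry any
allowed count, generation fails naming the constraint. Note that this
conditioning pulls the realized mean sialylation slightly below the
unconditional mean of the configured distribution; tests that assert a
configured mean therefore use branching supports large enough that the
conditioning never binds.

`instrument_spec()` controls the error model: Gaussian mass jitter
(default SD 0.2 Da, i.e. tolerance/5 at the default ±1 Da), Gaussian
retention peaks (SD 0.5 min around anchors spaced ~3.8 min, so
misclassification of a peak's sialic-acid count is rare but possible —
as in real data), multiplicative lognormal area noise (default 1%,
keeping areas positive; no noise model is dictated by the data),
and equal ionization into charges 8+ and 9+. `simulate_scans()` renders
the raw counterpart: per proteoform a Gaussian retention profile scaled
so its integrated EIC area equals the proteoform's amount, Gaussian m/z
peaks (SD twice the 0.01 m/z grid step) at the ladder positions on a
global grid, plus optional uniform noise. Fixed seeds make every level
byte-reproducible.

The shipped default registry (`default_agp_registry()`) uses **synthetic
backbone masses** at the realistic ~21.5 kDa scale with spacings of the
order of the real single-residue polymorphisms (+28.06, +42.08,
+160.10 Da relative to AGP1\*F1). They were chosen once, with a lattice
check that no two variants' candidate sets collide within 2 Da inside a
sialic-acid window, and are configuration, not ground truth — real
analyses should supply measured masses or sequences
(`registry_from_json()`, `registry_from_fasta()`).

### What the simulator does and does not emulate

It reproduces the statistical structure the analysis relies on: the
retention/sialylation coupling, near-isobaric composition lattices,
charge-ladder envelopes, area noise and chromatographic peak shape. It
does **not** simulate isotope envelopes, adducts, in-source
fragmentation, ionization bias against highly sialylated species,
pH-gradient peak broadening late in the gradient, or co-elution-driven
suppression. Passing round-trip tests therefore demonstrates the
*internal consistency* of the pipeline under its stated error model, not
performance on real spectra — where deconvolution quality and peak
overlap are the limiting factors.

## Validation problem sizes and numerical choices

The validation suite uses: 100 randomized small registries for the
enumeration/brute-force equivalence; a 200-proteoform run rendered to
raw scans (~220k profile points) for the end-to-end
simulate → deconvolute → calibrate → assign → quantify round trip, which
recovers ≥ 95% of abundance (typically ~99.6%); a 400-draw profile with
1% area noise for quantification recovery (per-proteoform abundances
within 2 percentage points, mean sialylation within 0.2 of the
configured 16.0); and closed-form checks of the signal primitives
(ladder inversion < 0.1 Da, Gaussian EIC areas within 0.5%).

Numerical conventions: internal arithmetic is unrounded, display rounds
to 2 decimals Da; candidate ordering (variant, N, F, S) and stable sorts
make every output deterministic; mass-window edges are inclusive;
degenerate inputs (empty feature lists, all-zero traces, single peaks)
return empty results rather than errors, while invalid configuration
(unknown keys, non-monotone anchors, inverted windows, inapplicable
modifications) fails fast with named reasons.

## Known limitations

* Site-level glycan placement is out of scope: intact-level data cannot
  localize glycans, and glycopeptide evidence enters only conceptually
  (e.g. as the structural constraints above).
* The adjacent-charge deconvolution needs at least two charge states per
  species within the acquisition range and resolvable centroids; heavily
  overlapped envelopes that maximum-entropy methods can untangle will be
  merged or dropped.
* Quantification by exclusion of ambiguous area is unbiased only if
  ambiguity is independent of composition; the reported excluded
  fraction is the guard rail.
* The default tolerance (±1.0 Da) and the tie rule are judgment calls
  exposed in configuration; the per-proteoform mass errors of a given
  instrument should inform overrides.
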