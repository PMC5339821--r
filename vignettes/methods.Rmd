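---
title: "Shotgun skin lipidomics: models, corrections and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shotgun skin lipidomics: models, corrections and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinlipidr)
```

This vignette documents the scientific model behind `skinlipidr`, the
parameters that matter, the numerical choices, and what the synthetic-data
validation does and does not demonstrate about real data.

## The identity model

Skin surface lipidomes mix two families: the stratum corneum barrier
lipids (12 ceramide subclasses, cholesterol, cholesteryl esters) and
sebaceous lipids (TAG, DAG, short-chain CE). The ceramide subclasses are
the Cartesian product of the amide linkage — non-hydroxy (N), alpha-hydroxy
(A) and ester-linked omega-hydroxy (EO) — with four sphingoid bases:
saturated (dS), sphingosine (S), phytosphingosine (P) and 6-hydroxy
sphingosine (H). The base type fixes the long-chain base's double bonds and
hydroxyls via the table `{dS: (0,2), S: (1,2), P: (0,3), H: (1,3)}`; that
table is the single place this convention lives (`lipid_model.R`). The
saturated base is treated as dihydrosphingosine.

Two conventions in the grammar deserve a note:

* the EO classes' esterified omega-hydroxyl is **not** counted in the
  written `;OH` sum — `EOS 68:3;2` has OH = 2 from the base alone, with
  chains `18:1;2–32:0;0–18:2;0` — so `species_formula()` adds that oxygen
  back during condensation;
* cholesterol is modelled in the form in which it is acquired, the acetate
  derivative (C29H48O2), in a separate positive-mode acquisition.

Chain separators accept both the typographic en-dash and the ASCII hyphen;
canonical output uses the en-dash.

Atomic masses are pinned package constants quoted to 7 decimals. The 3 ppm
identification gate equals 1.8 mDa at m/z 600, so the mass table's error
budget must sit well below a millidalton; for the same reason ion m/z
includes the electron mass (0.55 mDa, ~0.9 ppm at m/z 600) in both
polarities.

## Candidate space and fragment rules

`enumerate_species()` builds the combinatorial candidate space from chain
ranges. The defaults (LCB C16–22; amide FA C14–30, DB 0–2; ester FA C14–22,
DB 0–3; TAG totals C40–60; DAG totals C28–44; CE FA C12–26, all even-carbon
by default) bracket the chain lengths reported for human SC and sebum while
keeping the space desk-scale; they are constraints, not claims of
completeness, and every field is overridable.

Fragment rules are **data, not code** (`inst/extdata/fragment_rules.tsv`):
per class, a template of the diagnostic ions. The shipped defaults follow
standard shotgun fragmentation chemistry — the deprotonated, dehydrated
sphingoid base as the LCB-diagnostic anion, fatty-acid carboxylate anions
for amide and ester FAs, ammonium-adduct neutral losses of FA + NH3 for
DAG/TAG, and the cholestadienyl cation for CE/cholesterol. What matters
structurally is that the LCB-diagnostic ion differs between the isobaric
subclass pairs (NP vs AdS, NH vs AS, which share elemental formulas at
equal sum composition), so MSMS can arbitrate what precursor mass cannot.
Laboratories with their own validated transition lists can swap the table
without touching code.

## Identification and ambiguity

A peak matches a candidate when its relative mass deviation is *below* the
scan's gate and S/N is *above* 5 — all thresholds are implemented as strict
inequalities exactly as worded (below 3 ppm; greater than 5; at least
5-fold; above 2 pmol; at least two replicates), and the boundary behaviour
is pinned by tests. When several candidates fall inside one gate the match
is flagged ambiguous and **every** member is carried to MSMS confirmation;
a member is dropped only when another member of the same precursor group is
chain-confirmed and it is not. Without MSMS coverage all members are
retained, flagged, at species level — the engine never splits MS intensity
between ambiguous candidates.

One subtlety of chain combinatorics: under a spectrum of, say,
TAG 16:0–18:0–20:0, the candidate TAG 18:0–18:0–18:0 is "confirmed" too,
because its only diagnostic fragment (the 18:0 neutral loss) is present.
Confirmation therefore applies a unique-evidence rule: a chain split whose
entire fragment set is shared with the other passing splits of the same
species is dropped in their favour. The converse degeneracy — two truly
co-occurring splits where one's fragments are a subset of the other's —
cannot be resolved by this method at all and is a known limitation: the
shared split's amount is absorbed by the uniquely evidenced ones.

## Isotopic correction

*Type II* rescales a species' monoisotopic intensity by the monoisotopic
fraction of its envelope so the value represents the whole isotope cluster.
*Type I* removes the contribution that a lighter species' isotopologues
make to a heavier species' monoisotopic peak when the resolving power
cannot separate them. Envelopes come from exact per-element multinomial
convolution with pinned abundances (13C 0.0107, 2H 0.000115, 15N 0.00364,
17O 0.00038, 18O 0.00205), truncated at `k_max = 3` (M+3 is below 1% of M
for the formulas covered); the tests verify the convolution against an
independent brute-force isotopologue enumeration to 1e-9.

The peak-width model is Orbitrap-style: resolving power specified at
m/z 200 (280,000 for MS, 17,500 for MSMS) and scaling as m/z^(-1/2), so
FWHM(m/z) = m/z / (R200 · sqrt(200/m/z)). Two peaks closer than one FWHM
count as unresolved (the multiplier is configurable). Numerically this
means a 1-double-bond pair (whose M+2/monoisotopic split is 8.9 mDa) is
resolved at MS resolution below m/z ≈ 1090 but merged above it, and always
merged at MSMS resolution — which is exactly where type I subtraction
engages. Type I is applied at the MS level on precursor intensities;
fragment intensities are used as measured, since subspecies ratios compare
fragments of near-identical composition within one spectrum and a common
correction factor cancels. Corrected intensities are floored at zero with a
flag, and the subtraction is conservative: re-adding every subtracted
contribution reconstructs the observation exactly.

## Quantification and filters

Each class normalizes to one spiked standard: the deuterated NS for all N-
and A-ceramides, the deuterated EOS for the EO classes, and class-matched
standards for DAG, TAG, CE and cholesterol; the covered-class sets
partition the 16 classes. Standards are chosen (label shifts of ≥3 Da, or
odd/absent chain compositions) to stay outside native gates;
`build_species_db()` audits this and removes the standards' own species
from the native space. Equal molar response within a class family is the
platform's core assumption; the generator exposes it as a configurable
response factor for robustness experiments.

The filter cascade records a reason for every drop: `below_min_pmol`
(amount not above 2 pmol), `blank_fold` (not at least 5x the batch blank
mean; a lipid absent from blanks passes), `replicate_occurrence` (surviving
in fewer than two samples of its replicate group). The batch blank
aggregate is the mean over that batch's blank discs with absent lipids
counted as zero; the blank comparison operates on amounts (pmol), not raw
intensities. The replicate filter applies only where replicate groups
exist — singleton cohort samples are not penalized. Filters are monotone:
tightening any threshold can only shrink the surviving set (tested).

## The synthetic-data generator

The generator is the package's validation instrument: it renders centroided
spectra *from* ground truth with the same physics the engine inverts —
adduct m/z, isotope envelopes (the whole-cluster response distributed over
the truncated envelope, so the renderer and type II correction are exact
inverses), FWHM-limited centroid merging, diagnostic fragments proportional
to subspecies amounts, label-shifted standards, and per-peak noise floors.

Its defaults define the emulated study conditions:

* detector response 500 counts/pmol against a 50-count noise floor, so the
  2 pmol reporting limit sits at S/N 20 and the S/N 5 gate is crossed near
  0.7 pmol;
* multiplicative log-normal intensity noise, σ = 0.1, applied per species
  and per standard independently — reproducing the inverse CV-vs-amount
  relation qualitatively and putting a quantification ratio at ~14% CV;
* blank discs carrying 0.2 pmol backgrounds on sebum-type lipids;
* class composition as a convex mix of two endmember profiles
  (ceramide/cholesterol-rich SC proper vs TAG/DAG-rich sebum), with the
  mix fraction driven by depth (exponential decay to a plateau), body site
  (sebum-rich face/neckline), or held at 0.3 for the volar forearm;
* cohort effects injected into the sebum classes only: males carry
  exp(0.35) ≈ 40% more TAG/DAG, female sebum declines by exp(−1) over the
  20–89-year age range (males exp(−0.35)), and female totals decline with
  age on top — amounts of ceramides, cholesterol and CE are sex- and
  age-invariant by construction, though their mol% still co-vary through
  compositional closure, as they do in real data;
* subject-level total variability of 0.6 log-sd and per-class biological
  variability of 0.25 log-sd.

These values were fixed once as a realistic emulation of tape-stripped
skin; they are conditions, not tuning knobs. The panel picker additionally
avoids drawing two species whose precursors the MS resolution cannot
separate (isomeric cross-class pairs such as NS 38:1;2 / NdS 38:1;2 with
identical formulas), because the engine — by design — reports such merged
peaks as flagged ambiguities rather than splitting intensity.

What passing the synthetic round trip shows: the engine inverts its own
forward model exactly (noiseless recovery to machine precision; within 2%
under 1-DB isotope overlap) and degrades gracefully under noise. What it
does **not** show: robustness to in-source fragmentation, chromatography-
free matrix effects, response-factor heterogeneity within classes, profile
(non-centroided) data, or vendor noise models — real-data users must bring
instrument noise estimates (the native peak-list dialect carries per-peak
noise; plain mzML does not).

## Survey statistics

Replicate CVs use the sample (n−1) standard deviation over mean, on lipids
present in all replicates. Dynamic-range fits regress log10(S/N) on
log10(pmol); the limit of quantification is the lowest spike exceeding the
S/N gate and the linear range is reported in orders of magnitude. Depth
profiles report per-layer replicate means, the percent decline between two
layers, and a plateau: the first sampled layer after which successive layer
means change by less than 10% (configurable; the estimate is monotone in
the tolerance). PCA runs on mol% with centering and unit-variance scaling —
scaling is a choice, made because lipid abundances span orders of
magnitude, and can be toggled. Site clustering uses 1 − Pearson correlation
between replicate-averaged site profiles with average linkage (the
conventional default for correlation distances; configurable), serialized
as Newick. Sex classification follows the survey protocol exactly: lipids
present in ≥50% of samples per cohort (cross-cohort inclusion), 5x-repeated
10-fold cross-validation, preprocessing (median imputation, centering,
scaling, near-zero-variance removal) fitted inside each resampling fold via
caret, random forest with 500 trees and √p features per split (the named
algorithm's conventional defaults; the protocol names no hyperparameters).
"Variability" percentages are CVs (s.d./mean × 100) across the relevant
sample set — the only reading consistent with values above 100%.

## Problem sizes and determinism

The shipped tests and the acceptance script run deliberately modest
problem sizes — 2–12 samples per engine round trip, a 9-layer × 3-replicate
× 2-subject depth series, the full 14-site × 2 × 3 panel, and the full
104-subject cohort — chosen so the whole validation completes in minutes on
a single core while still exercising every code path at study-realistic
dimensions. All randomness flows from a single integer seed; identical
seeds reproduce identical studies bit for bit.

## Known limitations

* Sum/chain-level identification only: no double-bond positions, no
  sn-position isomers, no SMILES/InChI structures.
* No retention time or ion mobility; direct infusion has neither.
* The fragment-rule table is a package-authored default, not a transcribed
  instrument-validated transition list.
* Chain-split degeneracies that share all fragments are unresolvable and
  folded into the uniquely evidenced splits.
* mzML import requires centroided spectra and carries no per-peak noise;
  the S/N gate then needs a user-supplied noise estimate.
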