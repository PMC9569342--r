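---
title: "Methods: halogen dereplication, networking and substitution-series detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: halogen dereplication, networking and substitution-series detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halonet)
```

## The problem

Fungal strains such as *Penicillium sclerotiorum* and *Neonectria
discophora* produce halogenated polyketides (azaphilones, ilicicolins)
whose chlorination is catalyzed by FAD-dependent halogenases. Because
these enzymes are promiscuous, growing the producer on media supplemented
with NaCl, KBr or KI (an OSMAC strategy — one strain, many compounds)
elicits chlorinated, brominated and iodinated analogs of the same
scaffold. Dereplicating such analogs from LC-ESI(+)-MS/MS runs combines
four independent lines of evidence, each implemented here as a module:

1. **Exact-mass arithmetic** — a halogen-for-hydrogen substitution shifts
   the protonated ion by a fixed mass (Cl +33.9610, Br +77.9105,
   I +125.8966 Da).
2. **MS1 isotopologue envelopes** — <sup>37</sup>Cl (24.23% vs 75.77%
   <sup>35</sup>Cl) and <sup>81</sup>Br (49.31% vs 50.69% <sup>79</sup>Br)
   produce diagnostic M+2 peaks; iodine is monoisotopic and invisible
   here.
3. **MS/MS homology** — analogs share fragmentation chemistry, captured
   by the modified cosine score used in molecular networking.
4. **Retention order** — on reversed phase the analogs elute in halogen
   size order, H < Cl < Br < I.

## Mass model

All masses derive from a packaged isotope table (CIAAW/IUPAC atomic
masses). Chlorine abundances are pinned to 0.7577/0.2423, the values the
envelope evidence is stated with. The protonated ion mass applies the
electron correction via the proton mass,
$m([M+H]^+) = m_\mathrm{mono}(M) + (m_H - m_e)$; this reproduces the printed
calcd value 459.0802 for C~23~H~23~BrO~5~ to four decimals, which a
hydrogen-atom (electron-uncorrected) convention does not. ppm errors
follow the dominant convention $10^6\,(obs - theo)/theo$; the source
study's printed ppm signs are internally inconsistent, so tests pin
masses, not ppm decimals.

Candidate formula enumeration (`enumerate_formulas()`) is an exhaustive
scan over element-count bounds (default C≤40, H≤60, N≤3, O≤12, S≤1,
Cl≤3, Br≤2, I≤2 — wide enough for every packaged reference compound)
filtered by RDBE in [0, 25], with RDBE
$= C + 1 - (H{+}Cl{+}Br{+}I)/2 + N/2$.

## Isotopologue simulation

`isotope_pattern()` convolves per-element isotope distributions (binary
exponentiation over atom counts), merging isotopologues closer than
`merge_tol` (default 0.05 Da: centroided Q-ToF data resolve the ~1 Da
isotope spacing but not fine structure such as ¹³C₂ vs ⁸¹Br) and pruning
peaks below `prune` (default 1e-4) of the base peak *after* normalization,
so retained abundances remain fractions of the full distribution. With
`prune = 0` abundances sum to 1 within 1e-9; the test suite verifies the
convolution against an independent brute-force multinomial enumeration.

## Envelope-based halogen calling

`classify_halogens()` scores an observed MS1 envelope against theoretical
patterns over an (n~Cl~, n~Br~) grid (defaults 0–3 × 0–2) and reports the
best call, the margin to the runner-up, and a status flag (`ambiguous`
below a 0.02 cosine margin). Numerical choices that matter:

- **M+1 is always modeled.** At C19–C23 the ¹³C M+1 (~21–25%) rivals the
  ³⁷Cl M+2 (~32%); M+2-only rules misclassify.
- **Alignment anchors.** The observed base peak is anchored on a
  theoretical peak, tolerant to upstream monoisotopic mispicks. Because
  bromine's M/M+2 doublet is nearly 1:1, intensity noise flips which
  observed peak is the base about half the time; therefore *every*
  theoretical peak with ≥50% of the maximum abundance is tried as anchor
  and the best-scoring alignment kept. Without this, brominated envelopes
  systematically mis-score against 2×Cl and Cl+Br candidates.
- **Formula-free skeletons.** When no formula is known, the carbon count
  is estimated from M+1/M ($n_C \approx ratio / 0.0107$) and a generic
  C~n~H~1.5n~ skeleton stands in; hydrogen isotopes are negligible at this
  scale, so only the carbon count matters to the pattern shape.
- The score is a cosine over the union of matched slots, hence invariant
  to uniform intensity scaling.
- **Iodine is never called from envelopes** (monoisotopic); iodinated
  members are instead gated by detection in the KI culture.

## Spectral preprocessing and networking

Spectra are window-filtered (a peak survives if it ranks in the top 6 by
intensity within ±50 Da of itself — the convention of the cited
networking tool) and stripped of peaks within ±17 Da of the precursor.
Both filters are idempotent and commute, which the suite asserts.

`modified_cosine()` matches fragment pairs either directly
(|Δm/z| ≤ 0.02 Da) or offset by the precursor mass difference, takes
square-root intensity weighting (configurable to identity), L2-normalizes
each spectrum, and selects a one-to-one pairing greedily by descending
intensity product with ties broken by the smaller fragment m/z — making
the score deterministic and symmetric. On all ≤8-peak test spectra the
greedy score equals an exhaustive maximum-weight pairing oracle to 1e-9.

Network edges require ≥2 matched peaks (as stated in the source Methods)
and a minimum score. The source never states its edge score threshold;
0.65 (the networking tool's convention) is the recorded, configurable
default. The t-SNE layout parameters are recorded in the config for
provenance only; layout and visualization are out of scope.

## Substitution-series detection

`find_series()` probes, for every candidate parent (putative H member not
already carrying a confident nonzero halogen call), partners at
+33.9610/+77.9105/+125.8966 Da. A link must pass, in order: the mass
window, envelope compatibility (a Cl/Br member with an envelope must have
a compatible call), the culture-condition gate (Br in KBr, I in KI — on
by default; the iodine gate substitutes for the impossible envelope
check), and an MS/MS modified-cosine gate (≥0.5 when both spectra exist).
RT ordering (H < Cl < Br < I) is *supporting* evidence by default
(`rt_rule = "warn"` flags violators rather than discarding, matching how
the source study used RT); `"strict"` discards.

**Tolerance semantics.** `ppm_tol` (default 5, from the instrument's
stated <10 ppm accuracy) is a *per-measurement* accuracy. A substitution
link compares the difference of two measured m/z values, so the window on
the difference propagates both errors:
$|\Delta_{obs} - shift| \le ppm_{tol} \cdot 10^{-6} (m/z_a + m/z_b)$.
Applying a single-measurement window to the difference would reject ~8%
of true pairs at the generator's 2 ppm jitter; the propagated bound is the
standard practice in mass-difference networking and is also the bound the
pairwise-consistency invariant asserts on all outputs.

Series are deduplicated by member-set equality and ordered by parent m/z;
`series_report()` cross-references members with their molecular-network
component (`consistent` / `split` / `absent`).

## The synthetic world

The study's raw LC-MS data are not deposited, so `generate_dataset()`
emulates their structure with known ground truth. Its defaults *are* the
stated test conditions and are not tuned: 20 scaffold series (12 complete
H/Cl/Br/I quartets, 8 without an iodinated member — mirroring the
observation that ilicicolin scaffolds yielded no iodinated signal) built
on halogen-free base formulas taken from the packaged reference library
(extended with CH₂ homologs when more scaffolds than bases are needed);
200 decoy features with random CHNO(Cl/Br) formulas; 2 ppm mass jitter
s.d. and 5% multiplicative envelope noise (realistic for a well-calibrated
Q-ToF); 10% spurious fragment peaks; fragment sets 60% shared / 30%
halogen-shifted / 10% member-specific across a scaffold's analogs; RT
increments +0.3/+0.6/+1.0 min for Cl/Br/I over H with 3 s RT noise (well
below the spacing); Br members appear only in the KBr culture and I
members only in KI. A fixed seed yields byte-identical output files.

What the generator does *not* emulate — and hence what a green test does
not establish: chromatographic peak shapes, adducts and in-source
fragments, charge states >1, real fragmentation chemistry (fragments are
random m/z values, so the networking test exercises the score, not
structure elucidation), and detector saturation. Recovery metrics on this
world (member-level precision/recall ≥0.9, ≥95% correct halogen calls,
≤5% confident false calls on 200 halogen-free features) validate the
pipeline's logic, not instrument performance.

## Reference library

The packaged table transcribes the 22 main-text compounds with every
formula the source prints (15 of 22); the rest are kept name-only and
excluded from mass matching — no formulas were invented. The source text
contains one internal conflict for the brominated isolate (C₂₃H₂₃BrO₅ vs
"C₂₃H₂₂BrO₅H⁺"): the neutral formula consistent with the printed calcd
459.0802 is C₂₃H₂₃BrO₅, which the library stores. It also applies the
name "5-chloroisorotiorin" to two different compound numbers; the library
keeps the name on the earlier one and a descriptive name on the other.

## Design choices on genuinely open points

- **Config format**: JSON rather than TOML — no TOML parser is available
  in the supported dependency set, and `jsonlite` round-trips the config
  losslessly into the run manifests.
- **Manifests omit wall-clock timestamps** so a rerun with identical
  config produces byte-identical artifacts, prioritizing the determinism
  contract over conventional provenance timestamps.
- **Zero-prediction convention**: with no predicted series, precision is
  reported as 1 with zero support (and a message emitted), recall 0.
- **Degenerate inputs**: empty spectra score (0, 0) in the cosine rather
  than erroring; a spectrum whose peaks all fall in the precursor
  exclusion zone becomes a valid empty spectrum excluded from networking.

## Known limitations

- Only singly protonated positive-mode ions; Na⁺/K⁺ adducts are exposed in
  `adduct_spec()` but unused by the pipeline.
- Single halogen substitution per scaffold position (the chemistry of the
  modeled halogenases); the shift grid is extensible but multi-halogen
  series are not searched by default.
- Envelope calls saturate at n~Cl~ ≤ 3, n~Br~ ≤ 2; sulfur/metal isotope
  interference is not modeled.
- Retention-time evidence is ordinal only; no retention model is fitted.
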