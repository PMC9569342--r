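# halonet

Dereplication of halogenated fungal natural products from
LC-ESI(+)-MS/MS metabolomics data.

Fungi such as *Penicillium sclerotiorum* (azaphilones) and *Neonectria
discophora* (ilicicolins) chlorinate their polyketides with promiscuous
FAD-dependent halogenases. Cultured on media supplemented with NaCl, KBr
or KI (the OSMAC approach — *one strain, many compounds*), the same
enzymes incorporate Cl, Br or I, producing **halogen substitution
series**: sets of features interpreted as one scaffold bearing H, Cl, Br
or I at one position. `halonet` is for metabolomics practitioners who
want to find and validate such series in feature-table + MGF data, using
four independent lines of evidence:

1. **Fixed mass shifts.** Replacing H by a halogen shifts the protonated
   ion `[M+H]+` by Δ(Cl) = 33.9610, Δ(Br) = 77.9105, Δ(I) = 125.8966 Da.
   A link requires `|Δobs − Δ| ≤ tol·10⁻⁶·(m/z_a + m/z_b)` (per-measurement
   accuracy `tol`, errors propagated to the difference).
2. **MS1 isotopologue envelopes.** ³⁷Cl (24.23% vs 75.77% ³⁵Cl) and ⁸¹Br
   (49.31% vs 50.69% ⁷⁹Br) give diagnostic M+2 peaks. Calls are made by
   cosine matching of the observed envelope against simulated patterns
   over an (n_Cl, n_Br) grid; iodine is monoisotopic and is instead gated
   by detection in the KI culture.
3. **MS/MS homology** via the modified cosine of molecular networking:
   fragments match directly (±0.02 Da) or offset by the precursor mass
   difference, √-intensity weighted, greedy one-to-one pairing; edges
   require ≥ 2 matched peaks.
4. **Retention order** H < Cl < Br < I on reversed phase, used as
   supporting (not gating) evidence.

Because the original study's raw data are not deposited, the package
ships a seeded synthetic-data generator with ground truth that emulates
the study's structure (scaffold series with/without iodinated members,
isotope envelopes, shared/shifted fragments, decoys), so the entire
pipeline is testable offline.

## Worked example

```r
library(halonet)

## exact-mass layer: sclerotiorin, C21H23ClO5
adduct_mz("C21H23ClO5")            # [M+H]+ theoretical
#> 391.1307                        # printed observed: 391.1309, -0.6 ppm
match_library(391.1309)[, c("number", "name", "formula", "ppm")]
#>   number         name    formula    ppm
#> 1      4 sclerotiorin C21H23ClO5 0.5677

## the chlorine envelope that flags it at MS1
isotope_pattern("C21H23ClO5")
#>    mass abundance
#> 1 390.1 5.956e-01   # M      (35Cl)
#> 2 391.1 1.380e-01   # M+1    (13C)
#> 3 392.1 2.118e-01   # M+2    (37Cl)
#> ...

## end-to-end on the default synthetic world (20 series, 200 decoys)
sim   <- generate_dataset(generator_config(seed = 42))
calls <- classify_features(sim$features)
ser   <- find_series(sim$features, halogen_calls = calls)
head(series_table(ser), 4)
#>    series_id halogen     id    mz    rt     ppm cosine condition rt_ordered
#> 1 series_001       H  S01_H 315.2 839.5  0.0000     NA       PDA       TRUE
#> 2 series_001      Cl S01_Cl 349.1 858.5  5.0342 0.7714      NaCl       TRUE
#> 3 series_001      Br S01_Br 393.1 875.4 -0.8862 0.7643       KBr       TRUE
#> 4 series_001       I  S01_I 441.1 903.3 -0.9124 0.7708        KI       TRUE

truth_compare(ser, sim$truth)$member[c("precision", "recall")]
#> $precision [1] 1
#> $recall    [1] 1
```

Each `series_table()` row is one member of a detected series: the ppm
column is the mass-shift error of the link to the H member, `cosine` the
MS/MS modified cosine to it, and `rt_ordered` whether retention times
increase with halogen size across the series.

The full pipeline (simulate → network → classify → series → annotate,
with JSON run manifests) runs via:

```r
run_pipeline("all", default_config(seed = 42), out_dir = "run1")
```

or from the shell with `Rscript inst/cli/halonet.R all --out-dir run1`
(see `--help` for the flags: `--ppm-tol`, `--min-score`, `--rt-rule`, ...).

## Scope

Feature detection (MZmine/ADAP), network layout/visualization, genome
analysis and structure elucidation are out of scope; the package consumes
upstream feature tables (CSV) and spectra (MGF) and emits CSV/GraphML/JSON.
See `vignettes/halonet-methods.Rmd` for the model, parameter rationale and
limitations.
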