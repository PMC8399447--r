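# boltzbands

Boltzmann-weighted conformer-ensemble analysis of Raman bands for acidic
peptide fragments — the beta-tubulin E-hook hexapeptide **EGEDEA** and the
ten fragments that build it (EG, ED, EA, EGE, EDE, DEA, EGED, EDEA, EGEDE,
GEDEA).

The E-hook is an intrinsically disordered, glutamate-rich tail that
protrudes from the microtubule surface and has eluded crystallography.  Its
Raman spectrum is instead interpreted against simulated spectra from
electronic-structure calculations — but a flexible peptide populates many
conformers, so the simulation must combine an *ensemble* of energetic
minima.  This package implements that ensemble layer for users of
quantum-chemistry output: computational spectroscopists and biophysicists
tracking how the amide I and C-terminal carboxylate ν(C=O) bands move with
peptide length, side-chain polarity and intramolecular hydrogen bonding.

## What it computes

Given per-conformer relative energies `E_i` (kcal/mol), harmonic modes with
Raman activities, per-atom natural electron densities and hydrogen-bond
records, the package computes:

* **Populations** — `N_i = exp(−E_i/kT) / Σ_j exp(−E_j/kT)` at 298 K
  (configurable), with `kT` from `R = 1.987204e-3 kcal mol⁻¹ K⁻¹`;
* **Spectra** — `B_T(ν) = Σ_i N_i · W_i(ν)`, each conformer spectrum `W_i`
  a sum of unit-area Lorentzians (FWHM 10 cm⁻¹ default) at 0.97-scaled
  harmonic frequencies, weighted by Raman activity;
* **Band reports** — per-conformer amide I / αCOO⁻ positions by
  displacement-projection assignment, and their Boltzmann-summed ensemble
  position (integer cm⁻¹);
* **Charge transfer** — per-conformer `qT = Σ Δq` over intramolecular
  hydrogen bonds and the ensemble sum `q_BT = Σ_i N_i·qT_i` (electrons);
* **Ramachandran summaries** — φ/ψ per conformer with Boltzmann-weighted
  circular mean angles;
* **Trends** — blue/red/flat/mixed classification of band positions along
  fragment series.

A synthetic-ensemble generator (`synthetic_spec()`,
`synthesize_ensemble()`, `build_peptide()`) emulates the statistical
features of the real data so the whole pipeline runs and is tested without
any electronic-structure software.  The per-conformer and ensemble-level
reference tables for all eleven fragments ship as plain-CSV fixtures
(`load_table1_fixture()`, `load_table2_fixture()`).

## A worked example

```r
library(boltzbands)

t1 <- load_table1_fixture()

# conformer populations of the hexapeptide from its tabulated energies
round(boltzmann_weights(t1$delta_e[t1$fragment == "EGEDEA"]), 4)
#> [1] 0.9192 0.0808 0.0000 0.0000 0.0000 0.0000

# ensemble amide I band position (cm-1), Boltzmann-weighted
band_report_from_fixture(t1, "EGEDEA", "amide_I")$boltzmann_sum
#> [1] 1658

# ensemble hydrogen-bond charge transfer (electrons)
charge_transfer_from_fixture(t1, "EGEDEA")$q_bt
#> [1] 1.651

# the amide I band blue-shifts along the polar growth chain
reports <- lapply(c("ED", "EDE", "EDEA", "GEDEA", "EGEDEA"),
                  function(f) band_report_from_fixture(t1, f, "amide_I"))
classify_trend(build_series(reports,
                            order = c("ED", "EDE", "EDEA", "GEDEA",
                                      "EGEDEA")), "amide_I")
#> <trend_report> amide_I over ED-EDE-EDEA-GEDEA-EGEDEA : blue_shift
#>   steps (cm-1): +3, +6, +14, +4
```

The hexapeptide's lowest two conformers carry 92% and 8% of the
population; their weighted amide I position, 1658 cm⁻¹, matches the
measured crystalline-solid band, and the 1.651 e⁻ total charge transfer is
the largest in the fragment family — both hallmarks of the extensively
hydrogen-bonded, locally helical C-terminal turn.

End-to-end runs (spectra, band and charge reports, Ramachandran CSVs,
trend tables, a reproducibility manifest) go through `run_pipeline()`; see
the vignette in `vignettes/conformer-band-analysis.Rmd` for the model,
parameter and design discussion.

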