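---
title: "Boltzmann-weighted conformer ensembles and Raman band tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boltzmann-weighted conformer ensembles and Raman band tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boltzbands)
```

## The problem

The last six C-terminal residues of the beta-tubulin βII isotype — the
"E-hook" peptide EGEDEA — protrude from the microtubule surface, regulate
motor-protein binding, and have no resolved crystal structure.  Raman
spectroscopy of the crystalline peptide, interpreted against simulated
spectra from electronic-structure calculations, is one of the few routes to
its local structure.  Because such a flexible peptide populates many
conformers, no single optimized geometry describes the measured spectrum;
instead one collects a set of energetic minima per fragment and combines
their simulated spectra with Maxwell–Boltzmann statistics.

`boltzbands` implements that ensemble analysis for the EGEDEA hexapeptide
and the ten smaller fragments that build it (EG, ED, EA, EGE, EDE, DEA,
EGED, EDEA, EGEDE, GEDEA).  The upstream quantum-chemistry work — geometry
optimization, harmonic frequencies, Raman activities and natural-population
(NBO) densities — is taken as given input; everything downstream of it is
computed here.

## The model

**Conformer populations.**  Conformer $i$ with relative electronic energy
$E_i$ (kcal/mol) carries the equilibrium population

$$N_i = \frac{e^{-E_i/kT}}{\sum_j e^{-E_j/kT}},$$

with $kT$ expressed through the molar gas constant
$R = 1.987204\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ so that energies in
kcal/mol divide cleanly (`R_KCAL_MOL`; configurable to full CODATA
precision).  The default temperature is 298 K — the spectra being
interpreted are acquired at room temperature.  Energies are re-referenced
to a zero minimum before exponentiation, so spreads up to the 50 kcal/mol
collection window stay numerically exact.  Populations are weighted by
electronic relative energies only: no zero-point, thermal or free-energy
corrections, matching the upstream protocol.

**Simulated spectra.**  Each harmonic frequency is scaled by 0.97 to
partially correct for anharmonicity, then broadened into a *unit-area*
Lorentzian weighted by its Raman activity; the ensemble spectrum is the
Boltzmann sum $B_T(\nu) = \sum_i N_i W_i(\nu)$.  The line width is not
fixed by the band-position analysis; the default FWHM is 10 cm$^{-1}$,
typical for condensed-phase Raman simulation, and configurable.  Unit area
(rather than unit height) makes activity control integrated intensity and
gives an exact analytic check (`sum(intensity) ≈ activity`).  Intensities
are arbitrary units; a max-normalization helper exists for plotting only.
Temperature-dependent scattering prefactors ($\nu^4$, Bose factors) are
deliberately omitted — band *positions*, not absolute intensities, are the
object of study.

**Band assignment.**  "Amide I" here always means the C=O stretch of the
first peptide bond from the protonated amino terminus; the second tracked
band is the C-terminal carboxylate $\nu$(C=O), assigned as the
antisymmetric-stretch-dominated mode (both C–O bonds projected).  Within a
search window (default 1550–1750 cm$^{-1}$, wide enough for a +81
cm$^{-1}$ protonated outlier) the mode maximizing the squared
relative-displacement projection on the target C$\to$O axis wins.  The
localization score normalizes that projection by twice the total squared
mode norm, so a pure two-atom stretch scores 1; scores below 0.2 flag
delocalized or coupled modes with a warning (transition-dipole coupling
corrections are out of scope).  For self-protonated conformers the
"carboxylate" target degrades gracefully to the neutral acid C=O and the
assignment is flagged.

**Hydrogen-bond charge transfer.**  Upstream natural-population analysis
supplies per-bond transferred-charge magnitudes $\Delta q$ (electrons).
Per conformer, $q_T^{raw} = \sum \Delta q$; the ensemble total is
$q_{BT} = \sum_i N_i\, q_{T,i}^{raw}$.  The bookkeeping of "the difference
between the electron densities of the two participating atoms" is
ambiguous about which atoms and about sign; the convention adopted —
absolute difference between the natural populations of the bridging
hydrogen and the acceptor — is isolated in `hbond_delta_q()` so it can be
swapped in one place, and the normal path consumes $\Delta q$ stored in the
interchange file, validating rather than recomputing.  Geometric detection
(`detect_hbonds()`) uses common structural-biology cutoffs (D…A ≤ 3.5 Å,
H…A ≤ 2.7 Å, D–H…A ≥ 120°), configurable because the upstream analysis
states none.  All printed magnitudes are treated as electrons; the
occasional "millielectrons" labeling upstream is a caption inconsistency.

**Ramachandran summaries.**  $\phi_i$ = C(i−1)–N(i)–C$\alpha$(i)–C(i) and
$\psi_i$ = N(i)–C$\alpha$(i)–C(i)–N(i+1), in (−180°, 180°], undefined at
the termini.  Boltzmann-weighted mean angles use the weighted *circular*
(vector) mean: angles map to unit vectors, are averaged, and map back via
`atan2`.  An arithmetic mean is available behind a flag for comparison but
breaks at the ±180° seam (170° and −170° average to 180°, not 0°).  Region
labels ("alpha" for $\phi\in(-90,-30)$, $\psi\in(-77,-17)$; "restricted"
near (+120°, −120°) with glycine exempt) are descriptive only and never
filter data.

**Trend classification.**  Across an ordered fragment series, steps of
band position are classified blue (all ≥ +2 cm$^{-1}$), red (all ≤ −2),
flat (all |step| < 2) or mixed; 2 cm$^{-1}$ sits below the integer
rounding granularity of reported positions.

## The packaged reference tables

The per-conformer reference table (66 rows: 11 fragments × 6 tabulated
minima) ships as plain CSV, stored exactly as printed: the lowest-energy
"A" row of each fragment carries absolute band positions, other rows carry
signed shifts, populations keep their printed significant digits, and
per-conformer charge transfers are stored already Boltzmann-weighted.
Three additional self-protonated geometries of EG, EGED and EGEDEA exist
upstream but were never tabulated; the fixture records them as absent
rather than inventing rows.

Two reproducibility caveats follow from using printed (rounded) numbers,
and the test suite states them explicitly rather than hiding them:

* Recomputing populations from energies rounded to 0.01 kcal/mol moves
  sub-leading populations by several units of their third significant
  digit (a ±0.005 kcal/mol energy change is a ±0.8% population change at
  298 K).  Dominant-conformer populations reproduce to the last printed
  digit; across all 66 rows agreement is absolute-error bounded at
  $10^{-3}$.
* Re-deriving the ensemble band sums from the printed table reproduces 19
  of the 22 entries exactly after integer rounding; the EG pair and the
  EDEA carboxylate entry land 1 cm$^{-1}$ away, consistent with the
  upstream sums having used unrounded positions (and, for EG, its
  untabulated seventh conformer).

## The synthetic generator

`synthesize_ensemble()` stands in for the electronic-structure layer so
that every stage is testable.  It emulates exactly the statistical features
the analysis relies on, with defaults chosen once to mirror the reference
data:

* relative energies: exponential draw with scale 2 kcal/mol truncated at
  50 — the dominant-minimum regime (lowest conformer typically > 0.9 of
  the population, as in all eleven reference fragments);
* band modes: one amide-targeted mode drawn from U(1650, 1750) raw
  cm$^{-1}$ (1600–1698 after scaling) and one carboxylate mode from
  U(1650, 1700), each 0.9-localized on its C=O pair, plus delocalized
  background modes outside the search window;
* hydrogen bonds: 2–7 per conformer with one strong amino-terminus bond
  ($\Delta q \sim$ U(0.2, 0.4) e$^-$) and weaker others, atomic densities
  constructed so the density-difference convention reproduces each planned
  $\Delta q$ exactly;
* geometry: ideal internal-coordinate backbone (N–C$\alpha$ 1.458 Å,
  C$\alpha$–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å, planar trans peptide
  bonds), side chains reduced to a C$\beta$ stub since no analysis stage
  reads beyond it; backbone torsions are set exactly, so $\phi/\psi$
  round-trips to numerical precision.

What the generator does **not** emulate: real force fields, optimized
geometries, mode coupling, realistic absolute natural populations
(densities are constructed to encode $\Delta q$), or correlations between
energy and structure.  Passing tests therefore demonstrate the *pipeline's*
correctness — weighting, broadening, assignment, aggregation, geometry —
not the physical fidelity of any electronic-structure method.

## Numerical choices

* Log-sum-exp style minimum subtraction in the weight computation; exact
  up to the 50 kcal/mol window.
* `weighted_mean(..., renormalize = TRUE)` by default: printed populations
  sum to only ≈ 0.9995–1.0002, and renormalization is what reproduces the
  tabulated ensemble sums from them.
* Final band sums round to integer cm$^{-1}$ with ties away from zero
  (`round_half_away()`), applied only to the final sum.
* Torsions use the `atan2` formulation; the test suite checks it against
  an independent arccos-plus-sign oracle (to $10^{-9}$ degrees) and
  against an established structural-biology implementation.
* Collinear torsion quadruples and antipodal circular-mean ties are
  reported as errors/`NA`, never silently patched.
* The 400–4000 cm$^{-1}$, 1 cm$^{-1}$ default grid keeps a single
  broadened band's integral within 2% of its activity; the amide window is
  a view, not a truncation.

## Problem sizes

The test suite runs entirely on the 66-row reference table, constructed
micro-geometries, and synthetic ensembles of 1–8 conformers (sequences of
2–6 residues); the distributional check averages 1000 seeded draws.  These
sizes are where the method's behaviour is fully exercised — the ensemble
algebra is dimension-free, so nothing new appears at larger mode counts.

## Known limitations

* Only one quantum-chemistry log dialect is parsed (the one the generator
  writes); other outputs must be converted to the interchange JSON first.
* Amide I tracks only the first peptide bond; other amide modes surface
  as secondary candidates at most.
* No amide II/III assignment, no coupling-constant analysis, no
  anharmonic (VPT2) corrections, no IR intensities.
* Trend classification is deliberately non-parametric: no regression of
  position on fragment length is attempted.

## A worked run

```{r worked}
t1 <- load_table1_fixture()

# populations for the hexapeptide from its tabulated energies
boltzmann_weights(t1$delta_e[t1$fragment == "EGEDEA"])

# ensemble amide I position, weighted with the tabulated populations
band_report_from_fixture(t1, "EGEDEA", "amide_I")$boltzmann_sum

# ensemble charge transfer
charge_transfer_from_fixture(t1, "EGEDEA")$q_bt
```

The full pipeline over the reference tables, synthetic specs or
interchange files is `run_pipeline()`; `scripts/acceptance.R` at the
repository root re-derives every ensemble-level quantity from scratch and
writes them as JSON.
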