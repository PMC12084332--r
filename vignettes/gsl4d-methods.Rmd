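---
title: "Methods: 4D glycosphingolipid annotation and partition-corrected semi-quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4D glycosphingolipid annotation and partition-corrected semi-quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsl4d)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the design
was genuinely open.

## The measurement problem

Glycosphingolipids (GSLs) — glycans glycosidically bound to a ceramide — are
profiled from serum by a two-fraction extraction (silica fractionation
enriching sialylated species in fraction 2, neutral species and sulfatides in
fraction 1) followed by reversed-phase LC, trapped ion mobility and PASEF
MS/MS. Each detected feature therefore carries four descriptors: m/z,
retention time (RT, min), collisional cross section (CCS, Å²) and a fragment
spectrum. The package covers the computational side of that platform:
nomenclature and mass calculation, in-silico fragmentation and diagnostic
screening, 4D library matching, internal-standard (ISTD) partition-corrected
semi-quantification, calibration/validation metrics, and nonparametric
differential statistics.

## Mass engine

Species names use lipid shorthand: a class token (`GM3`, `GD1b`,
`Neu5Ac-nLc6Cer`, `SHexCer`, ...), a sphingoid base `c:d;On` (carbons, double
bonds, oxygens), and a fatty acyl `x:y` with optional `;O`/`;O2` hydroxyls
and a `-dK` deuterium label for internal standards. The legacy `d18:1`
dialect is accepted on input; the formatter always emits `;On`.

The class registry stores, per token, a glycan composition and a rooted
residue topology (parent-child glycosidic edges, modifications attached to
the residue that carries them). Formulas are assembled additively:

* sphingoid base `C_c H_{2c−2d+3} N O_n`, fatty acid `C_x H_{2x−2y} O_{2+h}`,
  ceramide = base + acid − H₂O;
* anhydro residues Hex `C6H10O5`, HexNAc `C8H13NO5`, dHex `C6H10O4`, Neu5Ac
  `C11H17NO8`, Neu5Gc `C11H17NO9`; sulfate adds `SO3`, O-acetyl `C2H2O`;
* a `-dK` label substitutes K hydrogens by deuterium (+K × 1.006277 Da).

Ion m/z uses **1.007276 Da per charge** (proton mass, electron included).
The paper-facing check is that `GD1 18:1;O2/18:0 [M−2H]²⁻` rounds to 917.48
and `GM1 18:1;O2/18:0 [M+HCOOH−2H]²⁻` to 794.93; both hold with this
convention, which is why it was fixed. Internal arithmetic is kept at full
precision; rounding (4 d.p. for display, 2 d.p. for comparisons against
printed values) happens only at presentation.

Isomer tokens such as `GD1a`/`GD1b` share one composition (same mass); the
suffix selects a topology only, and downstream discrimination is by CCS and
fragments. `GD1` without a suffix is given the a-type tree, a neutral choice
that affects only which B/Y set is simulated for it.

## Fragmentation and diagnostic rules

B and Y ions are generated at every glycosidic bond of the topology tree;
cleaving a branch bond yields the whole branch as the B ion, so a terminal
Neu5Ac–Neu5Ac element produces the disialo B ion at nominal m/z 581 that
separates b-series from a-series GD1. All fragments are **singly charged**
(the printed diagnostic values are singly charged nominal masses); C/Z ions
(±H₂O) can be generated but feed no rule. Positive mode adds sphingoid-base
ions `[base+H−2H₂O]⁺` (264 for 18:1;O2, 262 for 18:2;O2) and fatty-acyl
neutral-loss ions. Sulfatides additionally emit the `HSO₄⁻` reporter and the
SO₃ neutral loss.

Nominal mass is round-half-away-from-zero of the singly charged fragment
m/z. The neutral loss of two hexoses is implemented as loss of free lactose
(`C12H22O11`, 342.1162 Da) — the value the screening rule uses — rather than
the anhydro-Hex₂ loss (324.1057); both peaks exist in spectra but only 342
is diagnostic.

`classify_spectrum()` sets a flag iff a peak lies within the fragment
tolerance (default **10 mDa**; precursor windows in the annotation step are
2–5 mDa, but fragment peaks are noisier, so a wider default was chosen —
configurable) of a catalog mass; neutral-loss rules compare `precursor −
peak`. An empty spectrum sets no flags.

## 4D library and matching

A library row is one (species, ion, polarity) with reference m/z
(theoretical, from the mass engine), RT, CCS, fraction and provenance.
`build_library()` averages RT/CCS over replicate runs. The packaged
`serum_fixture()` enumerates the 376-species serum inventory; because the
inventory prints acyl-carbon *ranges* with per-row species counts rather than
explicit chain lists, a deterministic enumeration rule fills each count (even
acyl carbons ascending, then odd, then further double-bond/hydroxyl
variants). Counts, not membership, are the tested contract. Fixture RT/CCS
come from a deterministic monotone model (RT rises with acyl chain length,
falls with unsaturation, hydroxylation and glycan length; CCS tracks mass
with small per-topology offsets so composition isomers stay resolved),
anchored to measured standards where available (GD1b 18:1;O2/18:0 at
456.4 Å²). These descriptors exercise matching logic; they are not reference
values.

Matching windows (defaults, valid ranges): m/z **5 mDa** (2–5), RT
**0.5 min** (0.1–0.5), CCS **2 %** (0.1–2.0), MS/MS floor **500** (500–900)
on a 0–1000 cosine scale. A candidate must pass every window that is active
(m/z always; RT/CCS when present on both sides; MS/MS when both spectra
exist). Ranking uses `0.4·(1−|Δmz|/tol) + 0.2·(1−|Δrt|/tol) +
0.2·(1−|Δccs|/tol) + 0.2·(msms/1000)` with missing dimensions renormalized —
the platform only prescribes windows, so the weighting is a package choice
with mass as the strongest evidence. Ties break deterministically by smaller
|ΔCCS|, then |Δm/z|, then name. Features missing RT or CCS match on the
remaining dimensions and are flagged `partial_evidence`; features with no
candidate return as `"unknown"`. Vendor-style isotope-pattern (mSigma)
scoring is not implemented.

## Semi-quantification

The fraction-2 partition percentage of an ISTD,
`A = 100·area_f2/(area_f1 + area_f2)`, is one function used everywhere (the
average-partition and per-sample formulas are the same expression). With
spiked amount `spiked_nmol` (12.5 µL of a 20 µg/mL mix → 0.25 µg per ISTD,
converted by molecular mass):

* **Strategy I**: `B = spiked_nmol · Ā/100` with Ā the cohort average from
  reference extracts; `C = (analyte area / ISTD fraction-2 area) · B`. Only
  fraction 2 needs to be measured per sample.
* **Strategy II**: per-sample `A` replaces Ā; both fractions are measured.
* **Combined**: one strategy is applied to all samples; samples whose ISTD
  partitions are outliers (deviation from the cohort median beyond
  `k·MAD`, k = 3.5, or beyond 15 percentage points) are recomputed with the
  other and marked `corrected`. The platform description is ambiguous about
  which strategy is the base and which corrects; both orderings are
  selectable (`base_strategy`), with Strategy I as the shipped base.

The analyte area in the ratio is the fraction-2 area, as is the ISTD area;
only the partition itself needs fraction 1. The concentration read-out is
`C · M / V` (ng/µL serum) with `M` the species' monoisotopic mass and `V`
the serum volume (default 300 µL). Replicate CVs use the sample standard
deviation (n−1) and the reproducibility summary is the share of species with
CV below a threshold (default **35 %**, the permissive cut-off appropriate
for low-abundance analytes with cross-class ISTDs). The class→ISTD map is
fully configurable; the shipped default is the third sub-strategy (GM1, GM2,
GM3 on their own deuterated standards; GD3-d3 for GD3, GD2, GD1, GT1b, GQ1b
and, as a cross-class default, the remaining sialylated classes). Neutral
GSLs and sulfatides in fraction 1 are normalized to a single ISTD peak area.

## Calibration and validation

Calibration fits are ordinary least squares of response ratio on
concentration ratio over an 8-point two-fold dilution grid (5 down to
0.039). `LLOD = 3.3σ/s`, `LLOQ = 10σ/s`, so `LLOQ/LLOD = 10/3.3` exactly.
The "standard deviation of responses" σ is ambiguous in bioanalytical
practice; the default is the **residual standard error** of the regression
(the most common ICH-compatible reading), with the intercept standard error
and blank-response SD selectable. A non-positive slope leaves LLOD/LLOQ
undefined with a flag rather than producing negative limits. Linearity
acceptance is `R² ≥ 0.95` by default. Carry-over is
`100 · blank area / preceding standard area`, summarized as the mean across
analytes.

## Statistics

Per-species two-sided Mann–Whitney U tests compare two groups, with
Benjamini–Hochberg adjustment across species and the conventional stars
(* < 0.05, ** < 0.01, *** < 0.001). Tie handling follows
`stats::wilcox.test`: exact distribution for small tie-free groups, normal
approximation with continuity and tie correction otherwise. Optional sex
stratification runs the test within each sex, adjusting within the stratum.
Class totals sum species to subclasses, preserving per-sample sums.
Covariate-adjusted empirical-Bayes modelling is deliberately out of scope;
this module is the nonparametric layer only.

## Synthetic data: what it emulates and what it does not

`simulate_cohort()` reproduces the study design: per-sample true species
amounts from a lognormal law (median 0.05 nmol, biological CV 60 % by
default; CV 0 turns samples into replicate extracts); per-ISTD fraction-2
partitions from a normal truncated to (0, 100) at the measured truths
(means 78.70/80.40/75.99/70.35 %, CVs 5.59/2.94/3.95/7.40 % for GD3-d3,
GM1-d5, GM2-d9, GM3-d5 — the replicate count is a parameter because the
source material reports both n = 4 and n = 6 designs); analytes partition
like their mapped ISTD (response factors default to 1, the semi-quantification
assumption); areas are amounts × detector response with **multiplicative
lognormal** noise (areas are positive and noise is quoted as CV), unit-mean
parameterization; descriptors are library values plus Gaussian jitter scaled
to the tolerance windows. Spectra generators emit the species' own fragment
ions with random intensities plus optional decoys; calibration series are
`y = sx + ε`, `ε ~ N(0, σ²)`.

The generator does **not** emulate: chromatographic peak shapes or
co-elution, isotopologue interference, in-source decay, matrix effects,
class-dependent response factors (configurable but defaulting to 1), or
real CCS/RT physics. Passing tests therefore demonstrate the correctness of
the bookkeeping — parsing, mass arithmetic, window logic, partition algebra,
statistical plumbing — not instrument-level performance on real serum.

Noise-robustness of annotation is asserted as: at zero positional noise,
top-1 recovery is 100 %; under Gaussian jitter with σ equal to half of each
tolerance window, at least 95 % of *annotated* features carry the true
entry at rank 1 (features jittered outside a window are returned as
unknown — an honest miss, not a wrong identification).

## Problem sizes and determinism

All stochastic tests are seeded. The test suite uses cohorts of 3–20 samples
with 8–25 species, 1000-replicate partition simulations, 200-repeat
Monte-Carlo calibration checks, and 200 null cohorts of 100 species for the
type-I-error property (observed false-positive rate ≈ 0.04–0.05, the slight
deficit reflecting the discreteness of the exact U distribution at n = 10
per group). The acceptance script recomputes the reference ion m/z values
and diagnostic nominal masses deterministically and the GD3-d3 partition
mean from 1000 seeded replicate extracts.

## Known limitations

* No linkage-type or anomericity resolution (α2-3 vs α2-6, GalNAc vs
  GlcNAc): beyond the platform; isomer tokens are topology tags resolved by
  CCS/fragments only.
* Raw-data processing (peak picking, recursive feature extraction, TIMS
  calibration) is upstream and out of scope; the package starts at feature
  tables and spectra.
* Fixture descriptors are synthetic; real annotation requires a measured
  library (`build_library()` on replicate standards).
* Placeholder inventory rows ("unidentified sphingoid base") carry counts
  but no mass and are excluded from mass-dependent operations.
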