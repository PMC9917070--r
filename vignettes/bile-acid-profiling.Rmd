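---
title: "Semi-targeted bile-acid profiling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-targeted bile-acid profiling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baprofiler)
```

## The problem

Bile acids are cholesterol-derived steroidal acids whose circulating levels
rise when the enterohepatic circulation is disturbed, for example by
drug-induced liver injury. A targeted assay quantifies only the standards it
was built for; an untargeted one drowns in unidentifiable features. The
*semi-targeted* compromise implemented here anchors annotation to a library
of 46 bile-acid standards (plus 14 deuterated internal standards) and then
extends it by exact-mass arithmetic: isomers share a standard's elemental
formula but elute elsewhere, and phase-II conjugates appear at the formula
plus a fixed mass shift (sulfation +SO3, glucuronidation +C6H8O6).

`baprofiler` implements that workflow for negative-mode LC-HRMS feature
tables, end to end: mass arithmetic, tiered annotation, diagnostic-ion MS/MS
classification, internal-standard normalization, dose-group screening, and
cross-matching against in-vitro S9-incubation metabolites. Because no public
raw data accompany the study design it targets, the package also contains a
first-class synthetic-study generator with planted ground truth; every
quantitative claim in the test suite is made against that truth.

## Mass model

All masses derive from a single table of monoisotopic isotope masses
(C 12 exactly, H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207117,
D 2.01410178), hard-coded to 8 decimals and checked in the tests against two
independent hand summations. The deprotonated ion is

$$ m/z\,[\mathrm{M-H}]^- = M_\text{mono} - 1.00727646 $$

i.e. the proton mass is subtracted, not the hydrogen-atom mass: the electron
stays with the anion. This choice is what makes the reported ppm errors of
the sulfate-conjugate reference table reproducible to better than 0.05 ppm
(the package recomputes all nine rows in its acceptance checks). Mass error
is always expressed as signed ppm, $(obs - theo)/theo \times 10^6$.

Deuterated internal standards are modelled as the parent formula plus
$n \times 1.00627675$ Da (the D$-$H difference), with $n = 4$ or 6 per
standard.

## The packaged library

The 46 analytes and 14 internal standards ship as a versioned CSV
(`inst/extdata/ba_library.csv`). The compound names and conjugation classes
follow the commercial standard mix this workflow assumes; the elemental
formulas were compiled from standard chemical references. Two arithmetic
invariants are enforced at load time and abort on failure:

* every glycine conjugate equals its parent formula + C2H3NO, every taurine
  conjugate parent + C2H5NO2S;
* unconjugated, non-keto, non-nor backbones are C24H40O3/O4/O5 for
  mono-, di-, and tri-hydroxylated species.

The `reference_rt_min` column is **synthetic scenario data**, not
measurement: the study the package emulates prints retention times only for
isomer and conjugate peaks, never a full standards table. The values were
chosen once to respect reversed-phase elution order (taurine conjugates
before glycine conjugates before unconjugated species; tri-OH before di-OH
before mono-OH within a class) and to keep at least 0.5 min between any
standard and any same-formula planted isomer, and are not revisited.
`isomer_group` names the conventional exemplar used to label isomer-tier
features per formula (e.g. all di-OH C24H40O4 isomers report as
"CDCA isomer").

## Tiered annotation

`annotate_features()` assigns each feature its best target by smallest
absolute ppm error, breaking ties by retention-time proximity and then name,
deterministically. Tiers:

| tier | rule |
|------|------|
| `identified` | matches an analyte within `ppm_tol` **and** `rt_tol` |
| `isomer` | matches an analyte formula within `ppm_tol`, outside `rt_tol` |
| `conjugate_tentative` | matches analyte formula + sulfate/glucuronide shift within `ppm_tol` |
| `unassigned` | nothing within `ppm_tol` |

`ppm_tol` defaults to 10 ppm, the tolerance the underlying assay states.
`rt_tol` defaults to 0.30 min; the assay never states an RT window, so this
is a package decision, exposed in `pipeline_params()` and used consistently
everywhere (identified tier, IS matching, cross-matching). Conjugates of
isomeric analytes are collapsed to one target per distinct formula, so a
sulfate of any of the six di-OH standards reports once as "CDCA+SO3".
Glucuronide targets stay in the default search space even though the
emulated study found none significant — they were searched for, and absence
of a finding is itself a result the pipeline must be able to produce.

## MS/MS classification

Conjugate classes leave characteristic low-mass product ions in negative
mode; the steroid nucleus itself fragments weakly (sub-1% intensities), so
these ions carry the class information. The rule table is *computed* from
formulas, never typed in: deprotonated glycine 74.0248, deprotonated taurine
124.0074 with companions C2H3SO3⁻ 106.9808, HSO3⁻ 80.9652 and the SO3
radical anion 79.9574, and HSO4⁻ 96.9601 for sulfate esters. Two decisions:

* **Precedence taurine > sulfate > glycine.** Taurine conjugates shed
  sulfur-containing fragments that overlap the sulfate signature, so the
  more specific call must win. A single low-mass sulfur ion is ambiguous;
  taurine therefore requires either the 124.0074 ion or at least two ions
  of its set.
* **Tolerance 0.01 Da, intensity floor 1%** — suited to TOF MS/MS accuracy
  at low m/z; both are exposed parameters.

Note HSO3⁻ computes to 80.9652, which displays as 80.97 at two decimals even
though such tables are conventionally printed as 80.96; the package always
keeps the computed value and treats two-decimal values as display only.

When the class contradicts the exact-mass assignment,
`reconcile_annotation()` subtracts the observed class's conjugate delta from
the assigned formula; if a valid parent formula remains, the feature is
re-labelled (flag `msms_reassigned`), otherwise flagged `msms_conflict`. The
canonical case: a putative GLCA+SO3 (C26H43NO7S) with a taurine-type
spectrum is isomerically a taurine conjugate of a keto-DCA-type C24H38O5
skeleton.

## Quantification and screening

Analyte areas are normalized to a deuterated internal standard
(ratio = analyte area / IS area per sample). IS assignment is a
deterministic cascade: exact name (`d4-GCA` for GCA), then same conjugation
class with nearest reference RT, then globally nearest RT — a transparent
stand-in for the analyst's per-compound table, which the emulated study does
not print.

The low/high dose contrast (75 vs 600 mg/kg by default) is tested with a
two-sample **Student (pooled-variance) t-test on untransformed ratios**,
matching the behaviour of the vendor statistics software this replaces;
Welch is available by flag, and no multiple-testing correction is applied by
default because the screening rule is the raw-p threshold. Significance
requires $p < 0.05$ **and** fold change $> 2$ (fold change = ratio of group
means, high/low; a direction-agnostic mode also accepts $< 0.5$). Degenerate
inputs are defined, not left to chance: two identical constant groups give
$p = 1$; a zero low-group mean flags the fold change undefined.

Isomeric labels are split into RT clusters before testing (single linkage,
gap 0.25 min). The gap must exceed twice the within-study RT scatter
(truncated at ±0.10 min) and stay below the smallest planted isomer
separation (0.5 min); 0.25 sits in the middle of that admissible interval.

## In-vitro metabolite calling

Each incubation set has a full run (NADPH-regenerating system + PAPS) and
two controls, each lacking one cofactor. A feature at a parent+delta exact
mass is called a metabolite when its area is at least `fold_threshold`
(default 5) times the *minimum* over the controls of the control-window area
(±10 ppm, ±0.2 min). The minimum matters: an oxidative metabolite is fully
present in the no-PAPS control, so comparing against the maximum would never
call anything. Cofactor dependence follows from which single control lacks
the peak. The oxidative delta vocabulary is {+O, +2O, +O−2H, −2H, −O};
sulfation contributes +SO3. The "dehydroxylated" metabolite class is encoded
as −O, the only formula-level reading of that term.

`cross_match()` then pairs called metabolites with plasma annotations of
identical formula within 0.3 min, greedily one-to-one by smallest RT
difference.

## The synthetic-data generator

`make_plasma_study()` emulates a 4-dose × 3-replicate design:

* **Abundance**: lognormal multiplicative noise, median-parameterised,
  analytical CV 10% — peak areas are positive and CV-scaled, which a
  Gaussian model would violate at small means. Dose response is a geometric
  ramp reaching the planted fold change at the top dose.
* **Planted effects**: 13 standards with fold changes ≥ 4 (DCA 6.0 and
  HDCA 6.4 at their reported values, the rest scenario choices; no taurine
  conjugate is affected), the 22 isomer placements and the 9 sulfate
  conjugates of the printed reference tables at their printed RTs and fold
  changes, 4 non-changing sulfates and 6 non-changing glucuronides, and one
  GLCA+SO3-by-mass feature at RT 10.9 whose spectrum is taurine-type.
* **Mass error** N(0, 3 ppm) truncated at ±5 ppm; **RT jitter** N(0, 0.05
  min) truncated at ±0.10 min, so identified-tier matching at ±0.30 min and
  isomer separations of ≥0.5 min are unambiguous by construction for *every*
  seed, not just the default.
* **Decoys**: 15 features drawn uniformly in m/z 350–550, rejected within
  ±25 ppm of any annotatable mass, hence unannotatable at 10 ppm by design.
* **Reproducibility**: one integer seed; identical configurations give
  byte-identical outputs.

What the generator deliberately does **not** emulate: chromatographic drift
between runs (features are generated aligned; alignment is out of scope),
isotopologue envelopes, adducts other than [M−H]⁻, matrix interference, and
missing peaks beyond a simple limit-of-detection cut. Green tests therefore
demonstrate that the pipeline's logic is correct under the stated noise
model — not that the workflow would survive a badly drifting column or
co-eluting isobars, which is exactly the part a vendor peak-picker and an
analyst's eye handle on real data.

`make_invitro_suite()` plants the reported per-parent metabolite inventory
(e.g. GCDCA: seven +O, four +O−2H, one +2O) with four oxidative metabolites
placed to co-elute with plasma isomer placements (DCA+O−2H at 15.8, CDCA+O
at 14.3, UDCA+O at 18.9, GCDCA+O at 9.5) and every sulfate deliberately
placed away from plasma — reproducing the asymmetry that oxidative, but not
sulfated, species could be corroborated in vitro. Controls contain the
cofactor-independent class at full level and the blocked class at a 2%
leakage level.

## Signal module

For raw traces, `extract_xic()` sums centroided points within a ±ppm window
per scan, and `detect_peaks()` integrates peaks with a transparent recipe:
baseline = trace median, noise = 1.4826×MAD (robust, parameter-free),
apexes = local maxima of a 5-point moving average above baseline +
`min_snr`×noise (default 3), boundaries at the nearest persistent valley
(rebound above the running minimum exceeding the noise level) or at 1% of
the baseline-corrected apex height, trapezoidal areas computed on the *raw*
trace so smoothing never biases them, and a minimum of 5 points per peak.
These defaults replace the vendor integrator the emulated workflow used;
none are stated by that workflow, all are exposed arguments. A planted
Gaussian integrates to within 2% of its closed form $A\sigma\sqrt{2\pi}$
(the 1%-of-apex boundary alone forfeits ~0.25%).

## Problem sizes and determinism

The default study is 12 samples × 117 species ≈ 1400 features, 32 MS/MS
spectra, and 27 incubation runs; a full pipeline pass takes about a second.
The statistical operating profile is established with 1000 simulated null
targets (type-I error of the screen at n = 3, CV 10%) and 200 independent
study generations for the fold-change recovery of DCA and HDCA — sizes at
which the binomial/standard errors (±0.007 on the type-I rate, ±0.05 on the
fold-change mean) are well inside the asserted bands. All randomness flows
from explicit integer seeds.

## Known limitations

* Stereochemistry is out of reach by construction: an "isomer" tier names a
  formula group, not a structure, and the package never pretends otherwise.
* The t-test operates on untransformed ratios at n = 3; whether the vendor
  tool log-transforms is unknown, so a log-scale option is left to the user
  (transform the ratios before `differential_test()`).
* mzML input requires the Bioconductor `mzR` package; the long-format TSV
  path is the fully supported route.
* The IS-assignment cascade is a heuristic; with the real per-analyte
  assignment table it should be bypassed by calling `normalize_areas()`
  directly.
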