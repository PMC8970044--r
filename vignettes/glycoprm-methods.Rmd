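---
title: "Methods: glycopeptide annotation and PRM fucosylation-ratio evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycopeptide annotation and PRM fucosylation-ratio evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoPRM)
```

## The problem

Serum glycoproteins are largely liver-derived, and their site-specific
N-glycosylation changes with liver disease. In particular, increased
fucosylation of specific glycosites has been studied as a marker of
progression from cirrhosis to early hepatocellular carcinoma (HCC). The
workflow this package implements follows that study design: discovery-mode
(DDA) stepped-HCD MS/MS identifies intact glycopeptides and profiles their
glycoforms; targeted (PRM) MS/MS then quantifies a panel of glycopeptides —
here, 18 targets on four ceruloplasmin glycosites (N138, N358, N397, N762) —
in individual patient sera, and the *fucosylation ratio* per glycosite is
evaluated as a candidate biomarker, alone and combined with serum AFP.

Because the underlying patient sera and vendor raw files are not available,
every stage runs against synthetic data with known ground truth. The
generators are first-class, tested code: what the tests demonstrate is that
the computational pipeline recovers planted truth under the stated noise
models, not that the clinical effect replicates.

## Mass engine

All masses are monoisotopic (the workflow's 10 ppm MS1 / 20 ppm MS2
tolerances imply monoisotopic arithmetic), with proton 1.007276 Da and water
18.010565 Da. Glycan compositions are counts over four monosaccharides
(HexNAc, Hex, Fuc, NeuAc) with residue masses 203.079373, 162.052824,
146.057909 and 291.095417 Da; `glycan_mass()` is linear in the composition.
Peptide masses are residue sums plus water, with carbamidomethyl-C fixed by
default and explicit positional variable modifications (the engine does not
enumerate modification combinations — that is a search engine's job, out of
scope here).

Eight diagnostic oxonium ions are supported. Six are computed as residue
sums plus a proton (HexNAc 204.09, NeuAc 292.10 and its water loss 274.09,
HexNAcHex 366.14, HexNAcHexFuc 512.20, HexNAcHexNeuAc 657.23). The two
HexNAc secondary fragments at m/z 138.05 and 168.05 are dehydration or
cross-ring products without a simple residue-sum form, so they are stored as
fixed published values in the shipped constants table; the 168.05 entry is
flagged there because the common literature value is 168.066. Keeping the
fixed values in data rather than code leaves the computed path pure.

Glycosidic Y ions retain the peptide plus part of the glycan. The series
emitted is deliberately small — Y0, Y1 (pep+HexNAc), pep+HexNAc+Fuc,
pep+2HexNAc, pep+2HexNAc+Fuc — because these are the ions with
interpretive value: Y1 is the quantification transition, and the
fucose-retaining members that keep at most the chitobiose core are the
core-fucosylation diagnostics. Larger fucosylated Y ions are ambiguous
(the fucose may sit on an antenna) and are not used as topology evidence.

Antennarity is classified from composition by the chitobiose-core
convention: antenna count = HexNAc − 2, so HexNAc 4/5/6 map to
bi/tri/tetra-antennary. Bisecting GlcNAc is not modeled; anything else,
including high-mannose-like compositions, falls into an "other" bucket.
Composition alone can never place a fucose — core versus outer-arm is a
spectral call.

## Annotation and fucose topology

Matching assigns theoretical ions to observed peaks greedily by error, each
ion to at most one peak and each peak to at most one ion, ties toward the
lower-mass ion. Two tolerance regimes exist because the workflow uses both:
ppm (default 20, the MS2 search tolerance) for DDA annotation, and absolute
m/z (default 0.05, the targeted ion-match tolerance) for PRM traces. In the
ppm regime the greedy order is relative error; in the absolute regime,
absolute error.

The topology call is: core-fucosylated iff pep+HexNAc+Fuc or
pep+2HexNAc+Fuc matched at any allowed charge; outer-arm iff the
HexNAcHexFuc oxonium at 512.20 matched; `both` requires at least two
fucoses in the composition (one fucose cannot occupy two positions — a
mono-fucosylated spectrum showing both evidence kinds is `undetermined`
with a conflict flag); a composition without fucose is `non_fucosylated`
regardless of spurious matches. Evidence peaks must reach 1% of the base
peak by default; the source workflow states no intensity floor, but a floor
guards against noise matches and is configurable down to zero.

## Quantification

PRM XICs are extracted per target at the Y1 m/z within ±0.05 m/z, restricted
to spectra acquired for that target's precursor (±0.01 m/z), inside the
expected retention time ±1.5 min. Integration is apex-anchored trapezoidal:
boundaries are the deepest valley between the apex and each window edge
(ties resolved toward the apex), so an isolated peak integrates across its
whole window while co-eluting peaks are cut at the valley between them. No
boundary rule is stated in the source workflow; this one is deterministic
and robust to multiplicative intensity noise, which a strict
first-local-minimum walk is not. The Y1 charge actually quantified is the
one (of 1+ and 2+) with the larger area, recorded per record.

Relative abundance is each target's area over the summed area of all
targets in the sample, so abundances sum to 1; a missing target contributes
area 0 but stays in the denominator to keep denominators comparable across
samples. On the DDA side, areas are first summed over charge states of the
same glycan at the same glycosite, and unique glycopeptides are counted by
the charge-collapsed key (peptide, glycosite, canonical composition).

The fucosylation ratio is the fucosylated target's area divided by its
composition-matched non-fucosylated partner's area (same peptide, site and
HexNAc/Hex/NeuAc counts, zero fucose). Ratios are mostly below 1, so
−log10(ratio) is the plotting and combination scale. A zero denominator
leaves the ratio undefined; undefined ratios are excluded from group
statistics (no imputation rule exists to follow) and the exclusion count is
reported. The shipped 18-target fixture leaves site N358 without
fucosylated partners on purpose, to exercise this path.

## Cohort statistics

Design power uses the noncentral t distribution with noncentrality
d·√(n1·n2/(n1+n2)) and df = n1+n2−2; at the study design (n = 35 vs 27,
d = 0.8, two-sided α = 0.05) this gives 0.87. Group comparisons default to
the pooled-variance two-sided t-test to match that power family (Welch by
flag); the comparison scale defaults to −log10 ratio and is recorded in the
output, since the source reports only "t-test" without stating flavor or
scale. Across markers, raw p-values and Benjamini–Hochberg q-values are both
emitted, labeled.

ROC curves are empirical over all thresholds; the AUC is computed by
midranks (Mann–Whitney with ties counted 0.5), identical to the trapezoidal
area under the empirical curve, and is verified in tests against an
exhaustive concordant-pair oracle and an independent ROC implementation.
Sensitivity at 90% specificity is the maximal sensitivity among thresholds
achieving specificity ≥ 0.90.

How the ratio was "combined" with AFP is not stated in the source; the
standard two-marker combination is used: binary logistic regression on
(log10 AFP, −log10 ratio) fitted by Newton–Raphson with a small ridge
penalty (λ = 1e-6, intercept unpenalized) purely to keep coefficients finite
under complete separation. The combined score is the linear predictor. ROC
evaluation is in-sample, matching the apparent practice of the source; no
cross-validation is applied, so combined AUCs should be read as
procedure-dependent and optimistically biased.

## Synthetic data: what it emulates and what it does not

`make_ms2()` plants peaks at theoretical fragment m/z (with optional ppm
jitter) plus uniform noise peaks constrained to lie more than 3 tolerances
from every theoretical ion of the target, so annotation tests have exact
expected outcomes; an adversarial mode drops that constraint. `make_prm_run()`
generates targeted spectra on a regular time grid with Gaussian elution
profiles (default sd 0.1 min, grid 0.02 min, window ±1 min) whose areas are
the recorded ground truth, with optional multiplicative intensity noise.
`make_cohort()` draws −log10 ratios as Normal(μ_g, σ²) with the disease
group shifted by d·σ (the ratio increases with disease, so its minus-log
decreases) and AFP as log-normal. Cohort defaults mirror the study design —
35 cirrhosis vs 27 early HCC, d = 0.8 — with AFP medians 3.7 and 32.4 ng/mL
and log-scale spreads (sdlog 1.243 and 3.80) derived once from the clinical
interquartile ranges (1.7–9.1 and 2–336 ng/mL). The reference-group ratio
scale (mean −log10 ratio 0.6, sd 0.25) is a realistic choice for
sub-stoichiometric fucosylation, fixed in advance of any testing.

Not emulated: chromatographic tailing, isotope envelopes, co-isolation
interference, retention-time drift across runs, and search-engine score
distributions (identification tables are consumed, not generated from
spectra). Passing tests therefore show that the pipeline's arithmetic,
matching, integration and statistics recover planted truth under these
idealized conditions — not that the method would perform identically on
real serum data.

## Numerical choices and problem sizes

Peaks closer than 1e-5 m/z merge on spectrum construction
(intensity-weighted centroid). The logistic solver iterates Newton steps to
a 1e-10 step norm with at most 100 iterations. Simulation-based checks use
50,000 Monte-Carlo cohorts for the power cross-check, 20,000 null and 5,000
alternative cohorts for test calibration, 1,000 spectra for topology
soundness, and 200 instances (n ≤ 30) for the exhaustive AUC oracle — sizes
chosen so each check's sampling error is well inside its tolerance. The
demo pipeline (`run_pipeline()`) uses 18 targets, 4 PRM runs at 5%
multiplicative noise, and a 35 + 27 cohort, and completes in well under a
minute on one CPU; reruns with the same root seed are bit-identical because
all stage seeds derive from it by fixed offsets.

## Known limitations

Composition-level classification cannot resolve isomers (the 512.20 ion's
Hex may be Gal or Glc; it is labeled HexNAcHexFuc); hybrid and bisected
glycans fall into "other"; O-glycans are out of scope. mzML support is a
centroided-MS2 read subset; synthetic runs are written as MGF plus a
run-index CSV. The command-line entry point is a thin wrapper
(`inst/cli/glycoprm.R`) over `run_pipeline()` and `t_test_power()`; the R
functions are the primary interface.
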