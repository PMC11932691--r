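---
title: "Methods: models, parameters and design choices in pauciquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pauciquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pauciquant)
```

# Scope

`pauciquant` implements the quantitative analysis chain of a systems
glycobiology study of colorectal cancer (CRC): composition-based
N-glycan classification and glycome summarization, TMT reporter-ion
glycopeptide quantitation, cell-of-origin marker correlation,
fluorometric hexosaminidase (Hex) activity assay processing, and
plasma-activity survival stratification. Raw spectral processing and
identification are upstream of this package: inputs are tabular exports
(glycan quantities, glycoPSM tables with reporter intensities,
annotation sets, plate readings, cohort tables). Because the original
cohort data are not redistributable, the package ships synthetic-cohort
generators that emulate each input with known ground truth; every
downstream stage is exercised and tested against that truth.

# Glycan classification

A glycan species is represented by its generic monosaccharide
composition (Hex, HexNAc, dHex, NeuAc). Classification is a total
partition driven by an ordered rule table (`default_rule_table()`,
configurable from TSV):

1. HexNAc ≤ 2 with no Hex → chitobiose core (GlcNAc1(F), GlcNAc2(F));
2. HexNAc = 2, Hex 1–3, no NeuAc → paucimannose (M1–M3, ± core fucose);
3. HexNAc = 2, Hex ≥ 4, no dHex/NeuAc → oligomannose;
4. HexNAc = 3, Hex ≥ 5 → hybrid;
5. HexNAc ≥ 3 otherwise → complex;
6. anything else → other.

Two boundaries are conventions, not biology the composition can decide.
Hex4HexNAc2 is assigned to oligomannose because paucimannose is defined
as Man1–3 only. Fucosylated Hex≥4/HexNAc2 compositions (e.g.
Hex5HexNAc2dHex1) cannot be canonical oligomannose and are classed
`other`; resolving them would require MS/MS structure elucidation,
which is out of scope. The hybrid/complex split from composition alone
is likewise a heuristic — studies resolving structures manually may
adopt a different convention by loading their own rule table.
Non-generic residues (NeuGc, sulfation, phosphorylation) are not
modeled.

Classes map deterministically onto biosynthetic pathways: paucimannose
and chitobiose core are products of the truncation pathway (driven by
the hexosaminidases HEXA/HEXB), hybrid and complex of the elongation
pathway, and oligomannose species are the shared precursors.
Unclassifiable compositions are grouped with the precursors for pathway
accounting, a conservative choice that cannot inflate the
truncation signal.

# Synthetic cohorts

The generators define the study conditions; they are pure functions of
(configuration, seed).

**Discovery design.** 7 donors per CRC stage I–IV plus 8 controls (36
samples) over four TMT-10plex batches, each with the 126 channel
reserved for a pooled reference. Samples are interleaved across groups
before being dealt into plexes, which guarantees every plex carries at
least one sample of each stage and a control.

**Glycomes.** Group-level mean class shares use the reported cohort
values: tissue NAT 6.7% paucimannose rising to 13.5–15.4% across tumor
stages; PBMC controls 14.9% rising to 19.5–27.1%. Only the endpoints of
the stage ranges are reported, so intermediate stages are interpolated
linearly — a package choice, not a reported value. The remaining
glycome is split over chitobiose core / oligomannose / hybrid / complex
in a fixed 3/28/7/62 base mix scaled to the non-paucimannose remainder;
within the paucimannosidic class, the dominant core-fucosylated M2F and
M3F species carry 65% of the weight, the midpoint of the reported
60–70% band. Per-sample noise is logistic-normal: Gaussian perturbation
of log class shares renormalized by softmax, with a single dispersion
parameter (default SD 0.15 on the log scale; 0 reproduces the group
means exactly). Logistic-normal was preferred over Dirichlet for its
direct, single-parameter dispersion control. The generator emulates
compositional class structure and sampling noise only — not
isomer-level heterogeneity, missing species, or batch effects in
glycomics acquisition — so passing round trips demonstrate correctness
of the classification/summarization arithmetic, not robustness to those
real-data features.

**GlycoPSM tables.** Each ground-truth feature (accession, site,
composition) spawns 1–5 PSMs per plex whose intensities sum to the
feature total, with multiplicative per-plex batch factors, per-channel
biases, and log-normal measurement noise; the reference channel carries
the pooled mean of the feature across all samples. A configurable PSM
fraction receives PEP 2D ≥ 0.001, emulating identifications the
confidence filter must remove.

**Plates.** Standard wells follow fluorescence = slope·amount +
intercept + Gaussian noise; blanks read the intercept; sample wells
(technical triplicates, MUG and MUGS) encode planted activities through
the same linear response at the assay's 30 min incubation and 2 µl/µg
input.

**Plasma cohort.** 302 CRC donors plus 78 healthy controls. (Age,
activity) are bivariate normal at the reported means and SDs (63.9 ±
12.7 years; 1.0 ± 0.3 relative activity units) with correlation 0.2 —
the study quantifies neither the age–activity correlation nor the
baseline hazard, so the confounding strength is a package default,
chosen once as a mild positive dependence. Event times are exponential
with hazard `h0·exp(β_act·activity + β_age·age)` under administrative
censoring at 5 years; β defaults are the age-adjusted estimates
(HR 2.04 per activity unit, 1.03 per year). The baseline hazard is
calibrated numerically (quadrature + root finding) so the expected
5-year event fraction equals the cohort's 87/302 nonsurvivor share —
the cohort composition is a stated study condition, the baseline hazard
is derived from it. Because the univariable (2.49) and multivariable
(2.04) activity estimates cannot be produced jointly without knowing
the true confounding structure, recovery simulations treat the two
planted coefficients separately.

# TMT quantitation

Processing follows a two-stage scheme: PSMs are filtered at
PEP 2D < 0.001 (strict inequality), grouped into features by
(accession, site, composition) with channel-wise intensity summation,
divided by the feature's reference-channel intensity within each plex
(placing all batches on the shared reference scale), merged across
plexes (features absent from a plex are missing, never zero), and
finally each sample column is divided by its median ratio over
quantified features. The within-channel statistic is not specified by
the upstream protocol; the median was chosen for outlier robustness and
mean/total are available. Features with a zero or missing reference in
a plex are excluded from that plex and logged rather than erroring.
Missing values propagate as missing — no imputation; downstream
statistics use pairwise-complete observations. By construction the
fully normalized matrix is invariant to per-channel and per-plex
multiplicative perturbations, and zero-noise generator truth is
recovered exactly (relative error < 1e-9 in the test suite). A
`reference = FALSE` mode supports within-sample comparisons (e.g.
relative subunit levels), normalizing only within channels. Search
engine FDR control is an upstream property consumed as-is; only the
PEP 2D threshold is applied here.

# Cell-origin correlation

Annotation sets (bone marrow, NK/B/T cells, monocytes — sizes
534/114/141/262/201 in the synthetic defaults, matching the HPA-derived
sets the study used) are consumed from two-column files; there are no
live resource queries. A set's marker score is the sum of normalized
abundances of its detected members (the aggregation used upstream is
unstated; sum is the default, mean is available). Scores are correlated
with glycan-class shares by Pearson correlation with a t-distribution
test, pairwise-complete, with n reported per cell and cells under
n = 3 flagged rather than computed. Worked overlap percentages
(`overlap_percentage`) reproduce the study's panel arithmetic exactly
(7/51 = 13.7%, 13/51 = 25.5%).

When planting a target score-level correlation in synthetic protein
matrices, the association is placed in a factor common to the set's
members: summing members with independent per-protein correlations
would amplify the aggregate correlation well above the planted value.

# Hex activity assay

The 4-MU standard curve is an OLS line (≥ 3 distinct standards, slope
must be positive, R² < 0.98 warns). Sample activity is blank-corrected
mean replicate fluorescence converted through the curve and divided by
incubation time and input amount; below-blank signals clamp to zero
with a warning (the protocol is silent on below-blank wells). HEXB
activity is proxied as MUG − MUGS, clamped at zero with a warning since
negative values are biologically impossible and signal assay failure.
Activities are normalized within each plate to the mean of the plate's
control samples (median available; the protocol does not state which
was used), yielding the relative activity units used for all
cross-sample comparisons. Cell viability is
100·(treated − blank)/(vehicle − blank).

# Statistics and survival

Pearson r uses the product-moment formula with
`t = r√(n−2)/√(1−r²)` on n − 2 df, two-sided — the implemented p at
(r = 0.57, n = 36), (r = 0.49, n = 35) and (r = 0.52, n = 36) rounds to
the reported 0.0003, 0.0028 and 0.001. Group tests delegate to the
standard machinery (`t.test` pooled/Welch, `aov` + `TukeyHSD`);
survival estimation delegates to the survival package (`survfit`,
`survdiff`, `coxph` with Efron ties — the ties method is unstated
upstream; Efron is the better default). AUC is the exact Mann–Whitney
statistic from midranks, tested against an O(n²) pairwise oracle.
Outlier flagging replaces the proprietary ROUT method with a documented
robust rule — median ± 5·MAD (normal-consistent constant), flagged
never silently removed, k configurable — because ROUT's internals and
its Q setting are not reproducible from the publication. Dichotomization
uses the type-7 (linear interpolation) empirical quantile with strict
">" for the high arm; the study's 81/221 split of 302 donors is not
exactly reproducible from any standard 75th-percentile convention
(tie handling in the raw data presumably differs), so the convention
here is fixed and documented rather than tuned. All tests are
two-sided at α = 0.05.

Replicated hazard-ratio recoveries summarize across simulations with
the geometric mean (exp of the mean log HR): hazard ratios are
log-scale quantities, and an arithmetic mean of `exp(β̂)` would carry a
Jensen bias of about `exp(SE²/2)` that reflects the summary, not the
estimator.

# Problem sizes and numerical choices

The test suite and the acceptance script run the study-scale designs:
36-sample discovery cohorts, 302-donor survival cohorts with 500
simulation replicates, and 2000 replicates for correlation recovery and
type-I-error suites — sizes at which the Monte-Carlo error is
comfortably inside the assertion tolerances while the whole suite runs
in well under a minute. Determinism is enforced by explicit seeds on
every generator (each restores the caller's RNG state), and the
pipeline writes the seed into every output's provenance header.
Degenerate inputs fail loudly: empty truth maps, columns with no
quantified features, zero-variance correlation inputs, constant Cox
covariates, all-equal dichotomization values and missing blanks are
errors naming the offending object.

# Known limitations

Composition-level classification cannot resolve isomers; hybrid vs
complex and fucosylated high-mannose assignments are conventions. The
synthetic generators do not emulate isotope impurity, co-isolation
interference, peptide-level missingness patterns, glycomics batch
effects, or non-proportional hazards, so recovery results bound
arithmetic correctness rather than robustness to those artifacts.
Deconvolution of cell fractions is deliberately absent — the
cell-origin stage is correlation-only, as in the study it reimplements.
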