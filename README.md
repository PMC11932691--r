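# pauciquant

Quantitative analysis of paucimannosidic N-glycosylation in colorectal
cancer (CRC) cohorts.

Paucimannosidic N-glycans (Man1–3GlcNAc2Fuc0–1, short-hand M1–M3F) are
truncated glycans produced by the N-glycan truncation pathway, in which
the hexosaminidases HEXA/HEXB trim the antennae down to the
trimannosylchitobiose core and beyond. They are elevated in CRC tumor
tissue and in patient PBMCs, track immune (monocytic) infiltration of
the tumor microenvironment, and the circulating Hex activity that
produces them stratifies patient survival. `pauciquant` reimplements
the full quantitative chain of such a study as a tested R package plus
a numbered analysis workflow:

- **Glycan classification** (`classify_glycan`, `pathway_of`): ordered,
  file-configurable rule table mapping monosaccharide compositions
  (Hex/HexNAc/dHex/NeuAc) to paucimannose, chitobiose core,
  oligomannose, hybrid, complex or other, and onto
  truncation/elongation/precursor pathways.
- **Glycome summarization** (`type_summary`,
  `species_share_within_class`, `pathway_usage`, `paired_ratio`,
  `compare_groups`): per-sample class shares (percent), within-class
  species dominance, pathway usage, tumor/normal ratios, and group
  tests (t-test / ANOVA + Tukey).
- **TMT glycopeptide quantitation** (`filter_psms`, `group_glycopsms`,
  `normalize_to_reference`, `merge_plexes`,
  `normalize_within_channel`, `quantify_tmt`): PEP 2D < 0.001
  filtering, feature grouping by (accession, site, composition),
  pooled-reference-channel normalization across TMT-10plex batches,
  then per-channel median centering.
- **Cell-origin correlation** (`map_proteins`, `marker_score`,
  `correlate_origin_glycotype`, `overlap_percentage`): HPA-style
  annotation sets, summed marker scores, Pearson correlation against
  glycan-class levels.
- **Hex activity assay** (`fit_standard_curve`, `quantify_activity`,
  `hexb_proxy`, `normalize_plate`, `viability`, `process_plate`):
  4-methylumbelliferone standard curves, MUG/MUGS activities, the
  HEXB proxy MUG − MUGS, control-anchored relative activity units.
- **Survival statistics** (`pearson`, `ttest`, `anova_tukey`, `auc`,
  `flag_outliers`, `km_estimate`, `logrank`, `dichotomize_percentile`,
  `cox_fit`): Kaplan–Meier, log-rank, 75th-percentile risk
  stratification, and univariable/age-adjusted Cox proportional
  hazards (Efron ties).
- **Synthetic cohorts** (`cohort_design`, `generate_glycome_table`,
  `generate_glycopsm_table`, `generate_annotation_sets`,
  `generate_plate_readings`, `generate_survival_cohort`): every
  pipeline input with known ground truth, so all stages are testable
  without access to the original cohort data.

## Worked example

```r
library(pauciquant)

# 36-sample discovery cohort, zero-dispersion tissue glycome
design <- cohort_design()
g <- generate_glycome_table(design, glycome_profile("tissue", dispersion = 0))
shares <- type_summary(g)
shares[shares$class == "paucimannose", c("control_1", "stage_IV_1")]
#>   control_1 stage_IV_1
#> 1       6.7       15.4

# dominant core-fucosylated species within the paucimannosidic class
w <- species_share_within_class(g, "paucimannose")
sum(w[w$label %in% c("M2F", "M3F"), "stage_I_1"])
#> [1] 65

# plasma cohort: age-adjusted Cox model of 5-year mortality
cohort <- generate_survival_cohort(survival_sim_config(), seed = 1)
cox_fit(cohort[cohort$group == "crc", ], c("activity", "age"))
#>   covariate       beta       hr    lower    upper          se            p          mode
#> 1  activity 0.75563529 2.128964 1.101766 4.113836 0.336088149 2.455549e-02 multivariable
#> 2       age 0.03643922 1.037111 1.019012 1.055532 0.008982616 4.978406e-05 multivariable
```

A control (NAT) sample carries 6.7% paucimannose against 15.4% in a
stage IV tumor; M2F + M3F cover 65% of the paucimannosidic signal; and
on one simulated 302-donor plasma cohort the age-adjusted model
estimates a hazard ratio of ≈ 2.1 per relative Hex activity unit
(planted: 2.04) and ≈ 1.04 per year of age (planted: 1.03).

## Analysis workflow

The `analysis/` directory holds the end-to-end workflow as numbered
drivers over the package, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # all synthetic inputs
Rscript analysis/02_quantify.R    # TMT glycopeptide quantitation
Rscript analysis/03_glycotype.R   # glycome classes, stage effects, ratios
Rscript analysis/04_cell_origin.R # marker scores vs glycan classes
Rscript analysis/05_hex_assay.R   # 4-MU plates, activities, viability
Rscript analysis/06_survival.R    # KM, log-rank, Cox stratification
```

`run_pipeline(pipeline_config(...))` runs the same chain in one call.

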