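#!/usr/bin/env Rscript
# Stage 1 — simulate every pipeline input with known ground truth.
#
# Builds the discovery cohort (7 donors per CRC stage I-IV + 8 controls,
# 36 samples over four TMT-10plex batches), tissue and PBMC glycomes with
# stage-dependent paucimannose elevation, a glycoPSM export with batch
# and channel artifacts plus low-confidence decoys, HPA-style annotation
# sets, a 4-MU activity plate, and the 380-donor plasma survival cohort.

library(pauciquant)

seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
prov <- c(seed = seed, stage = "simulate")

design <- cohort_design()
write_table(design, "results/data/design.tsv", prov)
cat(sprintf("cohort design: %d samples, %d plexes, groups: %s\n",
            nrow(design), length(unique(design$plex)),
            paste(names(table(design$group)), table(design$group),
                  sep = "=", collapse = ", ")))

for (mtx in c("tissue", "pbmc")) {
  g <- generate_glycome_table(design, glycome_profile(mtx, dispersion = 0.15),
                              seed = seed + (mtx == "pbmc"))
  write_table(g, sprintf("results/data/glycome_%s.tsv", mtx), prov)
  cat(sprintf("glycome (%s): %d species x %d samples\n",
              mtx, nrow(g), nrow(design)))
}

# glycopeptide ground truth: paucimannosidic features elevated with stage
truth_boost <- c(control = 1, stage_I = 1.6, stage_II = 1.8,
                 stage_III = 2.0, stage_IV = 2.2)
feats <- data.frame(
  accession = sprintf("GP%03d", 1:30),
  site = seq(40, 620, length.out = 30),
  composition = rep(c("Hex3HexNAc2dHex1", "Hex9HexNAc2",
                      "Hex5HexNAc4dHex1NeuAc2"), each = 10))
ab <- matrix(1, 30, 36, dimnames = list(NULL, design$sample_id))
for (s in seq_len(nrow(design)))   # features 1-10 carry the stage effect
  ab[1:10, s] <- truth_boost[[design$group[s]]]
psms <- generate_glycopsm_table(design, list(features = feats, abundance = ab),
                                seed = seed + 2, batch_sd = 0.3,
                                channel_sd = 0.1, noise_sd = 0.05,
                                decoy_fraction = 0.1)
write_table(psms, "results/data/glycopsms.tsv", prov)
cat(sprintf("glycoPSMs: %d rows (%d with PEP 2D >= 0.001 to be filtered)\n",
            nrow(psms), sum(psms$pep2d >= 0.001)))

sets <- generate_annotation_sets(seed = seed + 3)
write_table(data.frame(set = rep(names(sets), lengths(sets)),
                       accession = unlist(sets, use.names = FALSE)),
            "results/data/annotation_sets.tsv", prov)
cat("annotation sets:", paste(names(sets), lengths(sets),
                              sep = "=", collapse = ", "), "\n")

# PBMC Hex activity plate: controls around 1.0, CRC donors elevated,
# with inter-individual spread
set.seed(seed + 6)
mug_true <- pmax(rnorm(36, ifelse(design$group == "control", 1.0, 1.25),
                       0.15), 0.2)
act <- data.frame(sample_id = design$sample_id,
                  mug = mug_true,
                  mugs = pmax(0.4 * mug_true + rnorm(36, 0, 0.03), 0.05),
                  is_control = design$group == "control")
plate <- generate_plate_readings(act, noise_sd = 2, seed = seed + 4)
write_table(plate, "results/data/plate_readings.tsv", prov)
cat(sprintf("activity plate: %d wells (%d standards, %d blanks)\n",
            nrow(plate), sum(plate$role == "standard"),
            sum(plate$role == "blank")))

cohort <- generate_survival_cohort(survival_sim_config(), seed = seed + 5)
write_table(cohort, "results/data/survival_cohort.tsv", prov)
crc <- cohort[cohort$group == "crc", ]
cat(sprintf("plasma cohort: %d donors (%d CRC, %d healthy), %d events in 5 y\n",
            nrow(cohort), nrow(crc), sum(cohort$group == "healthy"),
            sum(crc$event)))
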