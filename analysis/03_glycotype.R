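#!/usr/bin/env Rscript
# Stage 3 — glycome classification and summarization.
#
# Classifies each glycan species by composition, reduces the tissue and
# PBMC glycomes to class shares, tests stage effects on paucimannose,
# summarizes within-class species dominance, pathway usage, and
# tumor/normal paired ratios.

library(pauciquant)

design <- read_table("results/data/design.tsv", "design")
prov <- c(seed = 1, stage = "glycotype")

for (mtx in c("tissue", "pbmc")) {
  g <- read_table(sprintf("results/data/glycome_%s.tsv", mtx), "glycome")
  shares <- type_summary(g)
  write_table(shares, sprintf("results/class_shares_%s.tsv", mtx), prov)
  pauci <- as.numeric(shares[shares$class == "paucimannose",
                             design$sample_id])
  by_group <- tapply(pauci, design$group, mean)
  cat(sprintf("%s paucimannose %% by group: %s\n", mtx,
              paste(names(by_group), sprintf("%.1f", by_group),
                    sep = "=", collapse = ", ")))
  cmp <- compare_groups(shares, design, test = "ttest")
  write_table(cmp, sprintf("results/class_comparisons_%s.tsv", mtx), prov)
  sig <- cmp[cmp$class == "paucimannose" & cmp$p < 0.05, ]
  cat(sprintf("  stages with paucimannose significantly above control: %s\n",
              if (nrow(sig)) paste(sig$group, collapse = ", ") else "none"))
}

g_tissue <- read_table("results/data/glycome_tissue.tsv", "glycome")
within <- species_share_within_class(g_tissue, "paucimannose")
write_table(within, "results/paucimannose_species_shares.tsv", prov)
tum <- design$sample_id[design$group != "control"]
m2f_m3f <- vapply(tum, function(s)
  sum(within[[s]][within$label %in% c("M2F", "M3F")]), numeric(1))
cat(sprintf("M2F+M3F within paucimannose (tumors): mean %.1f%% (range %.1f-%.1f)\n",
            mean(m2f_m3f), min(m2f_m3f), max(m2f_m3f)))

shares_tissue <- type_summary(g_tissue)
usage <- pathway_usage(shares_tissue)
write_table(usage, "results/pathway_usage_tissue.tsv", prov)
tru <- as.numeric(usage[usage$pathway == "truncation", design$sample_id])
cat(sprintf("truncation-pathway usage: control %.1f%%, stage IV %.1f%%\n",
            mean(tru[design$group == "control"]),
            mean(tru[design$group == "stage_IV"])))

# paired tumor/normal ratio on the first stage-II donor vs first control
r <- paired_ratio(g_tissue, design$sample_id[design$group == "stage_II"][1],
                  design$sample_id[design$group == "control"][1])
cls <- classify_glycan(r$composition)
cat(sprintf("TUM/NAT ratio, paucimannosidic species: median %.2f (> 1: %d/%d)\n",
            median(r$ratio[cls == "paucimannose"], na.rm = TRUE),
            sum(r$ratio[cls == "paucimannose"] > 1, na.rm = TRUE),
            sum(cls == "paucimannose")))
write_table(r, "results/paired_ratio_example.tsv", prov)
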