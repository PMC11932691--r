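#!/usr/bin/env Rscript
# Stage 4 — cell-of-origin annotation and marker/glycotype correlation.
#
# Maps detected proteins onto the annotation sets, builds per-sample
# marker scores, and correlates the bone-marrow (immune-origin) score
# with glycan-class levels across the 36 tissue samples. A protein
# abundance matrix is synthesized with a planted score/paucimannose
# correlation of 0.57 so the recovered estimate has a known target;
# the replicated-recovery simulation quantifies the estimator spread.

library(pauciquant)

design <- read_table("results/data/design.tsv", "design")
ann <- read_table("results/data/annotation_sets.tsv", "annotation")
sets <- split(ann$accession, ann$set)
shares <- utils::read.delim("results/class_shares_tissue.tsv",
                            comment.char = "#", check.names = FALSE)

# synthesize a protein matrix whose summed bone-marrow marker score has
# population correlation 0.57 with the paucimannose share: the planted
# association lives in a factor common to the 40 detected members (a
# per-protein association would be amplified by summation), with small
# idiosyncratic noise on top; 60 bystander proteins are independent
set.seed(10)
pauci <- as.numeric(shares[shares$class == "paucimannose", design$sample_id])
zp <- as.numeric(scale(pauci))
members <- sample(sets$bone_marrow, 40)
prot <- matrix(NA_real_, 100, nrow(design),
               dimnames = list(c(members, sprintf("OFF%04d", 1:60)),
                               design$sample_id))
rho <- 0.57
common <- rho * zp + sqrt(1 - rho^2) * rnorm(nrow(design))
for (i in 1:100) {
  base <- if (i <= 40) common + 0.1 * rnorm(nrow(design))
          else rnorm(nrow(design))
  prot[i, ] <- 2^(0.5 * base)
}

mapped <- map_proteins(rownames(prot), sets)
cat("detected members per set:",
    paste(names(mapped$set_counts), mapped$set_counts,
          sep = "=", collapse = ", "), "\n")

score <- marker_score(prot, sets$bone_marrow, set_name = "bone_marrow")
cat(sprintf("bone-marrow marker score built from %d detected proteins\n",
            attr(score, "n_proteins")))

corr <- correlate_origin_glycotype(rbind(bone_marrow = score), shares)
write_table(corr, "results/origin_glycotype_correlation.tsv",
            c(seed = 10, stage = "correlate"))
pc <- corr[corr$class == "paucimannose", ]
cat(sprintf("bone-marrow score vs paucimannose: r = %.2f, p = %.2g, n = %d\n",
            pc$r, pc$p, pc$n))

# estimator calibration at the study size: mean recovered r over 2000
# replicates of n = 36 at planted 0.57
rs <- recover_planted_correlation(36, 0.57, reps = 2000, seed = 11)
cat(sprintf("planted r = 0.57 recovery over 2000 x n=36: mean %.3f (SD %.3f)\n",
            mean(rs), sd(rs)))

# worked overlap percentages of the paucimannosidic protein panel
cat(sprintf("overlap worked examples: 7/51 = %.1f%%, 13/51 = %.1f%%\n",
            overlap_percentage(51, 7), overlap_percentage(51, 13)))
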