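# shared fixture builders; everything is generated in code at test time

# tiny two-plex design: 2 samples per plex
tiny_design <- function() {
  d <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    group = c("control", "stage_I", "control", "stage_I"),
    plex = c(1, 1, 2, 2),
    channel = c("127N", "127C", "127N", "127C"),
    stringsAsFactors = FALSE)
  attr(d, "ref_channel") <- "126"
  d
}

# ground-truth feature map over a design: `flat` features at 1 plus
# `changed` features with the given per-group fold changes
tiny_truth <- function(design, fold = c(control = 1, stage_I = 2),
                       n_flat = 3, n_changed = 1) {
  n <- n_flat + n_changed
  feats <- data.frame(
    accession = sprintf("P%02d", seq_len(n)),
    site = 10 * seq_len(n),
    composition = rep(c("Hex3HexNAc2dHex1", "Hex9HexNAc2"),
                      length.out = n),
    stringsAsFactors = FALSE)
  ab <- matrix(1, n, nrow(design),
               dimnames = list(NULL, design$sample_id))
  if (n_changed > 0)
    for (s in seq_len(nrow(design)))
      ab[n_flat + seq_len(n_changed), s] <- fold[[design$group[s]]]
  list(features = feats, abundance = ab)
}

# paired vectors whose *sample* correlation is exactly r (residual
# orthogonalization), for evaluating the analytic p-value at a given r
pair_with_exact_r <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  z2 <- stats::residuals(stats::lm(z2 ~ z1))
  z1 <- as.numeric(scale(z1))
  z2 <- as.numeric(scale(z2))
  list(x = z1, y = r * z1 + sqrt(1 - r^2) * z2)
}

# O(n^2) pairwise-comparison AUC oracle (ties count one half)
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}
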