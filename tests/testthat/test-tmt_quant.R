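test_that("PEP 2D filtering is strict and reports removals", {
  psms <- data.frame(spectrum_id = c("a", "b", "c"),
                     pep2d = c(0.0005, 0.001, 0.01))
  kept <- filter_psms(psms, 0.001)
  expect_equal(kept$spectrum_id, "a")  # strict inequality at the boundary
  expect_equal(attr(kept, "removed"), 2)
  empty <- filter_psms(psms[0, ], 0.001)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "removed"), 0)
  expect_equal(nrow(filter_psms(psms, 1.0)), 3)
})

test_that("glycoPSM grouping sums channels and conserves intensity", {
  psms <- data.frame(
    spectrum_id = c("s1", "s2", "s3"),
    accession = "P05164", site = c(483, 483, 729),
    composition = "Hex3HexNAc2dHex1", pep2d = 0, plex = 1,
    `126` = c(100, 50, 10), `127N` = c(200, 100, 20),
    check.names = FALSE)
  feats <- group_glycopsms(psms, channels = c("126", "127N"))
  expect_equal(nrow(feats), 2)  # distinct sites stay distinct features
  f483 <- feats[feats$site == 483, ]
  expect_equal(f483[["126"]], 150)
  expect_equal(f483[["127N"]], 300)
  for (ch in c("126", "127N"))
    expect_equal(sum(feats[[ch]]), sum(psms[[ch]]))
})

test_that("reference normalization divides by the plex reference channel", {
  d <- tiny_design()[1:2, ]
  feats <- data.frame(accession = "P1", site = 1, composition = "HexNAc2",
                      plex = 1, `126` = 100, `127N` = 50, `127C` = 200,
                      check.names = FALSE)
  mats <- normalize_to_reference(feats, d)
  expect_equal(as.numeric(mats[["1"]]), c(0.5, 2.0))
  expect_equal(colnames(mats[["1"]]), c("s1", "s2"))
  # all channels equal: all ratios one
  feats2 <- feats
  feats2[c("126", "127N", "127C")] <- 7
  expect_equal(as.numeric(normalize_to_reference(feats2, d)[["1"]]),
               c(1, 1))
  # zero reference: excluded and logged, not an error
  feats$`126` <- 0
  expect_message(mats0 <- normalize_to_reference(feats, d), "excluded")
  expect_equal(nrow(mats0[["1"]]), 0)
  expect_equal(attr(mats0, "excluded")$feature, "P1|1|HexNAc2")
})

test_that("within-channel normalization centers each column median at 1", {
  m <- matrix(c(1, 2, 4, 2, 4, 8, 1, 1, 3), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  out <- normalize_within_channel(m)
  # hand-computed: columns divided by medians 2, 4, 1
  expect_equal(unname(out),
               cbind(c(0.5, 1, 2), c(0.5, 1, 2), c(1, 1, 3)),
               ignore_attr = TRUE)
  expect_true(all(abs(apply(log(out), 2, stats::median)) < 1e-9))
  expect_equal(unname(normalize_within_channel(
    matrix(2, 3, 1, dimnames = list(1:3, "s")))[, 1]), rep(1, 3))
  bad <- matrix(NA_real_, 2, 1, dimnames = list(1:2, "sampleX"))
  expect_error(normalize_within_channel(bad), "sampleX")
})

test_that("plex merging uses missing (not zero) for absent features", {
  m1 <- matrix(1:4, 2, 2, dimnames = list(c("fA", "fB"), c("s1", "s2")))
  m2 <- matrix(5:6, 1, 2, dimnames = list("fA", c("s3", "s4")))
  merged <- merge_plexes(list(m1, m2))
  expect_equal(dim(merged), c(2, 4))
  expect_equal(merged["fA", ], c(s1 = 1, s2 = 3, s3 = 5, s4 = 6))
  expect_true(all(is.na(merged["fB", c("s3", "s4")])))
  m2dup <- m2
  colnames(m2dup) <- c("s1", "s4")
  expect_error(merge_plexes(list(m1, m2dup)), "duplicate sample ids")
})

test_that("full chain is invariant to channel biases and batch factors", {
  d <- cohort_design()
  set.seed(11)
  n <- 12
  feats <- data.frame(accession = sprintf("P%02d", 1:n), site = 1:n,
                      composition = "Hex3HexNAc2", stringsAsFactors = FALSE)
  ab <- matrix(1, n, 36, dimnames = list(NULL, d$sample_id))
  ab[1:3, ] <- matrix(exp(stats::rnorm(3 * 36, 0, 0.5)), 3, 36)
  truth <- list(features = feats, abundance = ab)
  clean <- quantify_tmt(
    generate_glycopsm_table(d, truth, seed = 9, max_psms = 1), d)
  perturbed <- quantify_tmt(
    generate_glycopsm_table(d, truth, seed = 9, max_psms = 1,
                            batch_sd = 0.6, channel_sd = 0.4), d)
  expect_equal(clean, perturbed, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("zero-noise generator truth is recovered exactly", {
  d <- cohort_design()
  truth <- tiny_truth(d, fold = c(control = 1, stage_I = 2, stage_II = 3,
                                  stage_III = 0.5, stage_IV = 1.5),
                      n_flat = 9, n_changed = 1)
  psms <- generate_glycopsm_table(d, truth, seed = 2, max_psms = 5,
                                  batch_sd = 0.3, channel_sd = 0.2)
  mat <- quantify_tmt(psms, d)
  # flat features recover 1 after within-channel centering; the changed
  # feature recovers its fold change relative to its cross-sample mean
  expect_true(all(abs(mat[1:9, ] - 1) < 1e-9))
  changed <- mat[10, d$sample_id]
  truthrow <- truth$abundance[10, d$sample_id]
  expect_lt(max(abs(changed / changed[1] - truthrow / truthrow[1])), 1e-9)
})

test_that("within-sample mode quantifies without the reference stage", {
  d <- tiny_design()
  truth <- tiny_truth(d, n_flat = 3, n_changed = 0)
  psms <- generate_glycopsm_table(d, truth, seed = 1, max_psms = 1)
  mat <- quantify_tmt(psms, d, reference = FALSE)
  expect_equal(dim(mat), c(3L, 4L))
  expect_true(all(abs(mat - 1) < 1e-12))
})
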