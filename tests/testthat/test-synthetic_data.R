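test_that("cohort design fills four balanced plexes covering every group", {
  d <- cohort_design()
  expect_equal(nrow(d), 36)
  expect_equal(as.integer(table(d$plex)), rep(9L, 4))
  expect_equal(sum(d$group == "control"), 8)
  expect_equal(sum(grepl("^stage_", d$group)), 28)
  # every plex holds >= 1 sample of each stage and a control
  expect_true(all(table(d$plex, d$group) >= 1))
  # one sample per channel per plex, reference channel never assigned
  expect_false(any(d$channel == attr(d, "ref_channel")))
  expect_true(all(table(d$plex, d$channel) <= 1))
})

test_that("glycome generator is exact at zero dispersion and normalized", {
  d <- cohort_design()
  prof <- glycome_profile("tissue", dispersion = 0)
  g <- generate_glycome_table(d, prof, seed = 1)
  sums <- colSums(g[, d$sample_id])
  expect_true(all(abs(sums - 1) < 1e-9))
  # zero-noise passthrough of group class shares
  cls <- classify_glycan(g$composition)
  nat <- d$sample_id[d$group == "control"]
  for (s in nat)
    expect_equal(sum(g[[s]][cls == "paucimannose"]), 0.067)
  # determinism and noise
  expect_identical(g, generate_glycome_table(d, prof, seed = 1))
  gn <- generate_glycome_table(d, glycome_profile("tissue", 0.2), seed = 1)
  expect_false(isTRUE(all.equal(g[, nat[1]], gn[, nat[1]])))
  expect_true(all(abs(colSums(gn[, d$sample_id]) - 1) < 1e-9))
})

test_that("glycoPSM generator encodes truth, biases and decoys as designed", {
  d <- tiny_design()
  truth <- tiny_truth(d, n_flat = 1, n_changed = 0)
  # one feature, one PSM, no noise: intensities equal feature totals
  psms <- generate_glycopsm_table(d, truth, seed = 1, max_psms = 1)
  expect_equal(nrow(psms), 2)  # one per plex
  for (p in 1:2) {
    row <- psms[psms$plex == p, ]
    dsub <- d[d$plex == p, ]
    for (i in seq_len(nrow(dsub)))
      expect_equal(row[[dsub$channel[i]]],
                   unname(truth$abundance[1, dsub$sample_id[i]]))
    expect_equal(row[["126"]], mean(truth$abundance[1, ]))
  }
  # channel bias scales raw intensities but not ground-truth ratios
  truth2 <- tiny_truth(d)
  raw <- generate_glycopsm_table(d, truth2, seed = 3, max_psms = 1)
  biased <- generate_glycopsm_table(d, truth2, seed = 3, max_psms = 1,
                                    channel_sd = 0.5)
  m1 <- quantify_tmt(raw, d)
  m2 <- quantify_tmt(biased, d)
  expect_equal(m1, m2, tolerance = 1e-9, ignore_attr = TRUE)
  # decoy fraction behaves binomially
  truth3 <- tiny_truth(d, n_flat = 25, n_changed = 0)
  psms3 <- generate_glycopsm_table(d, truth3, seed = 5, max_psms = 1,
                                   decoy_fraction = 0.1)
  n <- nrow(psms3)
  n_decoy <- sum(psms3$pep2d >= 0.001)
  expect_gt(n_decoy, stats::qbinom(0.0005, n, 0.1) - 1)
  expect_lt(n_decoy, stats::qbinom(0.9995, n, 0.1) + 1)
  expect_error(generate_glycopsm_table(d, list(features = NULL)),
               "at least one feature")
})

test_that("annotation sets honor sizes, overlaps and seeds", {
  sets <- generate_annotation_sets(seed = 2)
  expect_equal(lengths(sets)[c("bone_marrow", "nk_cell", "b_cell",
                               "t_cell", "monocyte")],
               c(bone_marrow = 534L, nk_cell = 114L, b_cell = 141L,
                 t_cell = 262L, monocyte = 201L))
  expect_identical(sets, generate_annotation_sets(seed = 2))
  # planted overlap with the bone-marrow set
  expect_equal(length(intersect(sets$monocyte, sets$bone_marrow)),
               round(0.2 * 201))
  # cell-type sets pairwise disjoint
  cell <- sets[c("nk_cell", "b_cell", "t_cell", "monocyte")]
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(cell[[i]], cell[[j]]), 0)
  disjoint <- generate_annotation_sets(seed = 2, overlap_fraction = 0)
  expect_length(intersect(disjoint$monocyte, disjoint$bone_marrow), 0)
})

test_that("plate generator produces exact linear wells at zero noise", {
  act <- data.frame(sample_id = c("a", "b"), mug = c(1, 0.5),
                    mugs = c(0.4, 0), is_control = c(TRUE, FALSE))
  plate <- generate_plate_readings(act, slope = 100, intercept = 50,
                                   noise_sd = 0, time = 30, amount = 2)
  std <- plate[plate$role == "standard", ]
  expect_equal(std$fluorescence, 100 * std$concentration + 50)
  expect_equal(plate$fluorescence[plate$role == "blank"], rep(50, 3))
  # zero MUGS activity reads as blank
  b_mugs <- plate[plate$role == "sample" & plate$sample_id == "b" &
                    plate$substrate == "MUGS", ]
  expect_equal(b_mugs$fluorescence, rep(50, 3))
  # triplicates for every sample and substrate
  counts <- table(plate$sample_id[plate$role == "sample"],
                  plate$substrate[plate$role == "sample"])
  expect_true(all(counts == 3))
  expect_error(generate_plate_readings(act, slope = 0), "slope")
})

test_that("survival cohort simulator matches the design and the null", {
  cfg <- survival_sim_config()
  coh <- generate_survival_cohort(cfg, seed = 4)
  expect_equal(nrow(coh), 380)
  expect_equal(sum(coh$group == "crc"), 302)
  crc <- coh[coh$group == "crc", ]
  expect_true(all(crc$time <= 5 + 1e-12))
  expect_true(all(crc$time > 0))
  expect_true(all(is.na(coh$time[coh$group == "healthy"])))
  expect_identical(coh, generate_survival_cohort(cfg, seed = 4))
  # covariate moments near the configured distribution
  expect_equal(mean(crc$age), 63.9, tolerance = 0.05)
  expect_equal(stats::cor(crc$age, crc$activity), 0.2, tolerance = 0.35)
  # null model: with zero coefficients event times ignore the covariates
  cfg0 <- survival_sim_config(beta_activity = 0, beta_age = 0,
                              baseline_hazard = 0.1)
  cors <- vapply(1:40, function(r) {
    c0 <- generate_survival_cohort(cfg0, seed = 100 + r)
    c0 <- c0[c0$group == "crc", ]
    stats::cor(c0$activity, c0$time)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("baseline hazard calibration hits the target event fraction", {
  cfg <- survival_sim_config()
  evf <- vapply(1:40, function(r) {
    coh <- generate_survival_cohort(cfg, seed = 200 + r)
    mean(coh$event[coh$group == "crc"])
  }, numeric(1))
  expect_lt(abs(mean(evf) - 87 / 302), 0.015)
})

test_that("correlated-pair generator plants the population correlation", {
  rs <- vapply(1:300, function(r) {
    d <- generate_correlated_pair(200, 0.6, seed = r)
    stats::cor(d$x, d$y)
  }, numeric(1))
  expect_equal(mean(rs), 0.6, tolerance = 0.015)
})
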