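make_glycome <- function(values, compositions, labels = NULL) {
  g <- data.frame(composition = compositions, stringsAsFactors = FALSE)
  if (!is.null(labels)) g$label <- labels
  for (s in names(values)) g[[s]] <- values[[s]]
  g
}

test_that("type summary classifies species and conserves totals", {
  g <- make_glycome(list(s1 = 1), "Hex3HexNAc2dHex1", "M3F")
  expect_equal(type_summary(g)$s1, 100)
  # three-species hand fixture: 0.5 pauci, 0.3 oligo, 0.2 complex
  g3 <- make_glycome(list(s1 = c(0.5, 0.3, 0.2)),
                     c("Hex3HexNAc2dHex1", "Hex9HexNAc2",
                       "Hex5HexNAc4dHex1NeuAc2"))
  ts <- type_summary(g3)
  expect_equal(ts$s1[ts$class == "paucimannose"], 50)
  expect_equal(ts$s1[ts$class == "oligomannose"], 30)
  expect_equal(ts$s1[ts$class == "complex"], 20)
  expect_equal(sum(ts$s1), 100)
  # unclassifiable species land in "other" with a warning
  g4 <- make_glycome(list(s1 = c(0.6, 0.4)),
                     c("Hex3HexNAc2", "Hex6HexNAc2dHex1"))
  expect_warning(ts4 <- type_summary(g4), "other")
  expect_equal(ts4$s1[ts4$class == "other"], 40)
})

test_that("within-class species shares sum to 100 and flag absent classes", {
  g <- make_glycome(list(s1 = c(0.05, 0.05, 0.9), s2 = c(0, 0, 1)),
                    c("Hex2HexNAc2dHex1", "Hex3HexNAc2dHex1", "Hex9HexNAc2"),
                    c("M2F", "M3F", "Man9"))
  w <- species_share_within_class(g, "paucimannose")
  expect_equal(w$s1, c(50, 50))
  expect_true(all(is.na(w$s2)))  # class absent: undefined, not zero
  w2 <- species_share_within_class(g, "oligomannose")
  expect_equal(w2$s1, 100)
  expect_error(species_share_within_class(g, "hybrid"), "no species")
})

test_that("pathway usage aggregates classes and moves with inhibition", {
  shares <- data.frame(class = c("paucimannose", "complex"),
                       s1 = c(100, 0), s2 = c(50, 50))
  u <- pathway_usage(shares)
  expect_equal(u$s1[u$pathway == "truncation"], 100)
  expect_equal(u$s2[u$pathway == "truncation"], 50)
  expect_equal(u$s2[u$pathway == "elongation"], 50)
  expect_equal(colSums(u[, c("s1", "s2")]), c(s1 = 100, s2 = 100))
  # Hex inhibition: paucimannose down, complex up => truncation usage
  # falls and elongation rises
  before <- data.frame(class = c("paucimannose", "oligomannose", "complex"),
                       s = c(30, 20, 50))
  after <- data.frame(class = c("paucimannose", "oligomannose", "complex"),
                      s = c(10, 20, 70))
  ub <- pathway_usage(before)
  ua <- pathway_usage(after)
  expect_lt(ua$s[ua$pathway == "truncation"], ub$s[ub$pathway == "truncation"])
  expect_gt(ua$s[ua$pathway == "elongation"], ub$s[ub$pathway == "elongation"])
})

test_that("paired ratios compare relative abundances and flag zeros", {
  g <- make_glycome(list(tum = c(0.6, 0.4, 0), nat = c(0.3, 0.7, 0)),
                    c("Hex3HexNAc2dHex1", "Hex9HexNAc2", "Hex5HexNAc4"))
  r <- paired_ratio(g, "tum", "nat")
  expect_equal(r$ratio[1:2], c(2, 4 / 7))
  expect_true(is.na(r$ratio[3]) && r$undefined[3])
  same <- paired_ratio(g, "nat", "nat")
  expect_equal(same$ratio[1:2], c(1, 1))
  # elevated paucimannose by construction gives TUM/NAT ratio > 1
  expect_gt(r$ratio[r$composition == "Hex3HexNAc2dHex1"], 1)
})

test_that("group comparisons find planted stage effects and a flat null", {
  d <- cohort_design()
  g <- generate_glycome_table(d, glycome_profile("tissue", 0.08), seed = 21)
  shares <- type_summary(g)
  cmp <- compare_groups(shares, d, test = "ttest")
  pauci <- cmp[cmp$class == "paucimannose", ]
  expect_true(all(pauci$difference > 0))      # stages above control
  expect_true(all(pauci$p[pauci$group %in%
                            c("stage_III", "stage_IV")] < 0.05))
  # identical groups: zero difference, p of 1
  flat <- shares
  set.seed(41)  # identical group means; epsilon noise avoids zero variance
  flat[, d$sample_id] <- matrix(c(60, 30, 5, 3, 2), 5, 36) +
    matrix(rnorm(5 * 36, 0, 1e-8), 5, 36)
  cmp0 <- compare_groups(flat, d, test = "ttest")
  expect_true(all(abs(cmp0$difference) < 1e-6))
  an <- compare_groups(shares, d, test = "anova_tukey")
  expect_true(all(c("class", "F", "p") %in% names(an)))
  expect_true(is.data.frame(attr(an, "tukey")))
  expect_error(compare_groups(shares, d[1:5, ], test = "ttest"), "group")
})

test_that("t-test p-values agree with an exhaustive permutation oracle", {
  set.seed(31)
  x <- rnorm(5, 0.8)
  y <- rnorm(5, 0)
  obs <- ttest(x, y)
  pool <- c(x, y)
  combs <- utils::combn(10, 5)
  tstats <- apply(combs, 2, function(idx)
    abs(ttest(pool[idx], pool[-idx])$t))
  p_perm <- mean(tstats >= abs(obs$t) - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.05)
})
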