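test_that("pearson matches its closed form, cor.test and a permutation oracle", {
  x <- c(1, 2, 4, 3, 6, 5, 8, 9)
  y <- c(2, 1, 3, 5, 4, 7, 6, 9)
  p <- pearson(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(p$r, unname(ct$estimate))
  expect_equal(p$t, unname(ct$statistic))
  expect_equal(p$p, ct$p.value)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, x)$p, 0)
  # pairwise-complete handling
  pm <- pearson(c(x, NA, 3), c(y, 2, NA))
  expect_equal(pm$n, 8)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  # Monte-Carlo permutation oracle on the n = 8 fixture
  set.seed(19)
  robs <- abs(p$r)
  rperm <- replicate(20000, abs(stats::cor(x, sample(y))))
  p_perm <- mean(rperm >= robs - 1e-12)
  expect_lt(abs(p$p - p_perm), 0.03)
})

test_that("t-test reproduces hand-computed pooled statistics", {
  same <- ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  # a = (1,2,3), b = (2,4,6): pooled s^2 = 2.5, t = -2/sqrt(5/3)
  tt <- ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(tt$t, -2 / sqrt(5 / 3))
  expect_equal(tt$df, 4)
  expect_equal(tt$difference, -2)
  expect_error(ttest(1, c(1, 2)), "at least 2")
  # empirical power at d = 1, sd = 1, n = 50/50 matches the closed form
  target <- stats::power.t.test(n = 50, delta = 1, sd = 1,
                                sig.level = 0.05)$power
  set.seed(23)
  rej <- mean(replicate(1000, ttest(rnorm(50, 1), rnorm(50))$p < 0.05))
  expect_lt(abs(rej - target), 0.04)
})

test_that("ANOVA with Tukey reproduces a hand-computed fixture", {
  # groups (1,2,3), (2,3,4), (3,4,5): SSB = 6, SSW = 6, F = 3
  at <- anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(at$F, 3)
  expect_equal(at$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(nrow(at$tukey), 3)
  expect_equal(at$tukey$difference[at$tukey$contrast == "c-a"], 2)
  flat <- anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  expect_error(anova_tukey(list(a = 1:3)), "2 groups")
})

test_that("AUC equals the O(n^2) pairwise oracle, including ties", {
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc(c(5, 6, 7), c(1, 2, 3)), 1)
  set.seed(29)
  for (i in 1:10) {
    pos <- sample(1:6, 8, replace = TRUE)
    neg <- sample(1:6, 5, replace = TRUE)
    expect_equal(auc(pos, neg), auc_oracle(pos, neg))
  }
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("MAD outlier flagging reports planted outliers and nothing else", {
  set.seed(37)
  x <- rnorm(35)
  expect_length(flag_outliers(x), 0)
  x[17] <- median(x) + 10 * mad(x)
  expect_equal(flag_outliers(x), 17L)
  expect_length(flag_outliers(rep(3, 10)), 0)  # zero MAD: no flags
})

test_that("Kaplan-Meier matches closed forms and the empirical survivor", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  cens <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(cens$survival == 1))
  # mixed fixture, hand-computed product limit:
  # event@1 (4 at risk) -> 3/4; censor@2; event@3 (2 at risk) -> 3/8;
  # event@4 (1 at risk) -> 0
  mixed <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(mixed$survival[mixed$n_event > 0], c(0.75, 0.375, 0))
  # without censoring KM equals the empirical survivor function
  set.seed(43)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  emp <- vapply(km2$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$survival, emp)
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank matches a hand-computed two-group fixture", {
  # A: (1, e), (2, e); B: (1.5, e), (3, e)
  # O_A = 2, E_A = 1/2 + 1/3 + 1/2, V = 1/4 + 2/9 + 1/4
  lr <- logrank(c(1, 2, 1.5, 3), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, (2 - 4 / 3)^2 / (13 / 18), tolerance = 1e-9)
  same <- logrank(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_lt(same$chisq, 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-6)
  expect_error(logrank(1:3, rep(1, 3), rep("A", 3)), "2 groups")
})

test_that("percentile dichotomization uses the documented convention", {
  d <- dichotomize_percentile(1:100, 0.75)
  # type-7 quantile of 1..100 at 0.75 is 75.25: 25 values above
  expect_equal(d$threshold, 75.25)
  expect_equal(d$n_high, 25)
  expect_equal(d$n_low, 75)
  expect_equal(dichotomize_percentile(1:10, 1)$n_high, 0)  # all low
  low <- dichotomize_percentile(c(1, 1, 2, 3), 0)
  expect_equal(low$n_high, 2)  # ties at the minimum stay low
  expect_error(dichotomize_percentile(rep(2, 5)), "no split")
})

test_that("Cox fits recover nulls and the exponential closed form", {
  set.seed(47)
  n <- 600
  x <- rnorm(n)
  t <- rexp(n, 0.2)
  null_fit <- cox_fit(data.frame(time = t, event = 1, x = x), "x")
  expect_lt(abs(null_fit$beta), 0.15)
  # two-group exponential: beta approximates log rate ratio
  g <- rep(0:1, each = 1000)
  t2 <- c(rexp(1000, 1), rexp(1000, 2.5))
  fit2 <- cox_fit(data.frame(time = t2, event = 1, g = g), "g")
  expect_equal(fit2$beta, log(2.5), tolerance = 0.08)
  # CI brackets the HR; univariable mode fits separate models
  coh <- generate_survival_cohort(survival_sim_config(), seed = 9)
  crc <- coh[coh$group == "crc", ]
  fit <- cox_fit(crc, c("activity", "age"))
  expect_true(all(fit$lower < fit$hr & fit$hr < fit$upper))
  uni <- cox_fit(crc, c("activity", "age"), mode = "univariable")
  expect_equal(uni$covariate, c("activity", "age"))
  expect_true(all(uni$mode == "univariable"))
  expect_error(cox_fit(data.frame(time = t, event = 1, x = 1), "x"),
               "constant")
  expect_error(cox_fit(data.frame(time = t, event = 0, x = x), "x"),
               "no events")
})
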