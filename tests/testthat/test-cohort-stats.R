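test_that("identical constant values give F = 0 and Tukey p = 1", {
  tab <- toy_cohort(list(LV = list(control = 0.4), RV = list(control = 0.4),
                         OFT = list(control = 0.4)), spread = 0)
  a <- anova_tukey(tab, group = "control", range = 0.4)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_true(all(a$tukey$p_adj == 1))
})

test_that("region ANOVA flags clear separation and Tukey p dominates raw p", {
  set.seed(21)
  tab <- cohort_table(data.frame(
    specimen = paste0("s", 1:18),
    region = rep(c("LV", "RV", "OFT"), each = 6L),
    group = "control", range = 0.4,
    value = c(rnorm(6, 0.42, 0.05), rnorm(6, 0.18, 0.05), rnorm(6, 0.61, 0.05))))
  a <- anova_tukey(tab, "control", 0.4)
  expect_lt(a$p, 0.01)
  # Tukey-adjusted p is never smaller than the unadjusted pairwise p built
  # on the same pooled error term
  d <- as.data.frame(tab)
  fit <- aov(value ~ region, data = d)
  mse <- sum(fit$residuals^2) / fit$df.residual
  for (k in seq_len(nrow(a$tukey))) {
    pr <- strsplit(a$tukey$pair[k], "-")[[1L]]
    n1 <- sum(d$region == pr[1L])
    n2 <- sum(d$region == pr[2L])
    tstat <- a$tukey$diff[k] / sqrt(mse * (1 / n1 + 1 / n2))
    praw <- 2 * pt(-abs(tstat), fit$df.residual)
    expect_gte(a$tukey$p_adj[k] + 1e-12, praw)
  }
})

test_that("Tukey familywise error agrees with a permutation oracle on a fixed dataset", {
  # small fixed three-region dataset; compare the Tukey adjusted p of the
  # extreme pair against a max-|t| permutation reference
  d <- data.frame(
    specimen = paste0("s", 1:12),
    region = rep(c("LV", "RV", "OFT"), each = 4L),
    group = "control", range = 0.4,
    value = c(0.41, 0.37, 0.45, 0.40,  0.22, 0.19, 0.27, 0.24,  0.44, 0.49, 0.40, 0.46))
  tab <- cohort_table(d)
  a <- anova_tukey(tab, "control", 0.4)
  pairt <- function(vals, reg) {
    combn(unique(reg), 2, function(pp) {
      abs(t.test(vals[reg == pp[1L]], vals[reg == pp[2L]], var.equal = TRUE)$statistic)
    })
  }
  tobs <- pairt(d$value, d$region)
  set.seed(5)
  nperm <- 4000
  exceed <- numeric(3)
  for (b in seq_len(nperm)) {
    tb <- pairt(d$value[sample.int(12)], d$region)
    exceed <- exceed + (max(tb) >= tobs - 1e-12)
  }
  p_perm <- exceed / nperm
  # the worst pair is clearly significant under both procedures, and the
  # adjusted p-values agree within Monte-Carlo + distributional tolerance
  expect_lt(max(abs(sort(a$tukey$p_adj) - sort(p_perm))), 0.08)
})

test_that("the genotype t-test matches the textbook pooled formula", {
  x <- c(0.10, 0.14, 0.12)  # control
  y <- c(0.30, 0.26, 0.34)  # mutant
  tab <- cohort_table(data.frame(
    specimen = paste0("s", 1:6), region = "RV",
    group = rep(c("control", "mutant"), each = 3L), range = 0.4,
    value = c(x, y)))
  tt <- genotype_ttest(tab, "RV", 0.4)
  # hand computation: pooled variance, t = (my - mx) / (sp * sqrt(2/3))
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
})

test_that("degenerate genotype comparisons follow the stated conventions", {
  eq <- cohort_table(data.frame(
    specimen = paste0("s", 1:6), region = "RV",
    group = rep(c("control", "mutant"), each = 3L), range = 0.4, value = 0.2))
  tt <- genotype_ttest(eq, "RV", 0.4)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  one <- cohort_table(data.frame(specimen = "a", region = "RV",
                                 group = "control", range = 0.4, value = 1))
  expect_error(genotype_ttest(one, "RV", 0.4), class = "pamech_degenerate_design")
})

test_that("stiffness ratios reproduce the measured cohort table cells", {
  sed <- reference_sed()
  pick <- function(rg, rng, g) sed$mean[sed$region == rg & sed$range == rng & sed$group == g]
  expect_equal(stiffness_ratio(c(pick("LV", 0.2, "control"), pick("LV", 0.2, "mutant"))), 2.2)
  expect_equal(stiffness_ratio(c(pick("LV", 0.4, "control"), pick("LV", 0.4, "mutant"))), 1.7)
  expect_equal(stiffness_ratio(c(pick("RV", 0.4, "control"), pick("RV", 0.4, "mutant"))), 3.7)
  expect_equal(stiffness_ratio(c(0.1, 0.1)), 1.0)
  expect_error(stiffness_ratio(c(0, 1)), class = "pamech_undefined_ratio")
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  set.seed(9)
  for (i in 1:4) {
    tab <- cohort_table(data.frame(
      specimen = paste0("s", 1:12),
      region = rep(c("LV", "RV"), each = 6L), group = "control", range = 0.4,
      value = rnorm(12, rep(c(0.4, 0.25), each = 6L), 0.08)))
    a <- anova_tukey(tab, "control", 0.4)
    d <- as.data.frame(tab)
    tt <- t.test(value ~ region, d, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("simulated control cohorts separate RV from the stiffer sites", {
  # cohorts drawn at the measured control means with per-specimen scatter
  # consistent with the printed standard errors (SD = SE * sqrt(n)).  Under
  # that heteroscedastic independence the clearly separated RV-vs-OFT pair
  # is detected in the majority of replicates; the closer RV-vs-LV pair has
  # only partial power (the study's paired within-heart design, which the
  # independent draws do not model, sharpens it further)
  sed <- reference_sed()
  ctrl <- sed[sed$group == "control" & sed$range == 0.4, ]
  hit_oft <- hit_lv <- 0L
  n_rep <- 30L
  set.seed(31)
  for (b in seq_len(n_rep)) {
    vals <- unlist(lapply(seq_len(nrow(ctrl)), function(k) {
      rnorm(10, ctrl$mean[k], ctrl$se[k] * sqrt(10))
    }))
    tab <- cohort_table(data.frame(
      specimen = paste0("s", seq_along(vals)),
      region = rep(ctrl$region, each = 10L), group = "control", range = 0.4,
      value = vals))
    a <- anova_tukey(tab, "control", 0.4)
    p_oft <- a$tukey$p_adj[a$tukey$pair %in% c("RV-OFT", "OFT-RV")]
    p_lv <- a$tukey$p_adj[a$tukey$pair %in% c("RV-LV", "LV-RV")]
    hit_oft <- hit_oft + (p_oft < 0.05)
    hit_lv <- hit_lv + (p_lv < 0.05)
  }
  expect_gte(hit_oft / n_rep, 0.5)
  expect_gte(hit_lv / n_rep, 0.15)
})
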