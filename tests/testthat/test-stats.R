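test_that("learning curves are ordered, deduplicated and gap-flagged", {
  m <- tibble::tibble(
    subject = rep("s1", 12), group = "g", phase = "acquisition",
    session = sample(1:12), probability = runif(12), percent_cr = 0,
    amplitude = 0.3)
  cv <- build_learning_curves(m)
  expect_equal(cv$session, 1:12)
  # shuffled input gives identical output
  cv2 <- build_learning_curves(m[sample(1:12), ])
  expect_equal(cv, cv2, ignore_attr = TRUE)
  expect_error(build_learning_curves(m[c(1, 1, 2), ]), "duplicate")
  expect_warning(build_learning_curves(m[-3, ]), "missing")
})

test_that("last-four mean is the arithmetic mean of trailing sessions", {
  m <- tibble::tibble(
    subject = "s1", group = "g", phase = "acquisition", session = 1:12,
    probability = c(rep(0.2, 8), 0.4, 0.5, 0.6, 0.7))
  lf <- last_four_mean(m)
  expect_equal(lf$probability, 0.55)
  m2 <- m; m2$probability <- 0.5
  expect_equal(last_four_mean(m2)$probability, 0.5)
  expect_error(last_four_mean(m[1:3, ]), "4 required|required")
})

test_that("Cohen's d matches the pooled-SD formula", {
  # unit effect: means 1 and 0, both SD 1, equal n
  set.seed(51)
  z <- as.numeric(scale(rnorm(10)))
  expect_equal(cohens_dprime(z + 1, z), 1, tolerance = 1e-12)
  # identical group means: effect 0
  expect_equal(cohens_dprime(z, z + 0), 0)
  # brute-force arithmetic oracle on random groups
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
    sp <- sqrt(((length(a) - 1) * sd(a)^2 + (length(b) - 1) * sd(b)^2) /
                 (length(a) + length(b) - 2))
    expect_equal(cohens_dprime(a, b), abs(mean(a) - mean(b)) / sp,
                 tolerance = 1e-12)
  }
  expect_error(cohens_dprime(rep(1, 5), rep(1, 4)), "pooled SD")
  expect_error(cohens_dprime(1, rnorm(5)), "n >= 2")
})

test_that("d' and the unpaired t statistic satisfy t = d' sqrt(n/2)", {
  set.seed(52)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    a <- rnorm(n, 0, runif(1, 0.5, 2)); b <- rnorm(n, runif(1, -1, 1))
    tt <- abs(stats::t.test(a, b, var.equal = TRUE)$statistic)
    expect_equal(unname(tt), cohens_dprime(a, b) * sqrt(n / 2),
                 tolerance = 1e-9)
  }
})

test_that("mixed two-way ANOVA matches the sums-of-squares oracle", {
  set.seed(53)
  d <- expand.grid(subject = sprintf("s%02d", 1:8), session = 1:4)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 4, "wt", "mut")
  d$y <- rnorm(nrow(d)) + 0.5 * (d$group == "mut") + 0.1 * d$session
  res <- rm_anova_2way(d, "y")
  o <- oracle_mixed_anova(d)
  expect_equal(res$statistic[res$effect == "group"], o$F_group,
               tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "session"], o$F_session,
               tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "group:session"], o$F_inter,
               tolerance = 1e-9)
  expect_equal(res$df1, c(1, 3, 3))
  expect_equal(res$df2, c(6, 18, 18))
})

test_that("mixed ANOVA edge cases: identical groups and missing sessions", {
  d <- expand.grid(subject = sprintf("s%02d", 1:6), session = 1:3)
  d$group <- rep(c("a", "b"), each = 3)[as.integer(sub("s", "", d$subject))]
  base <- c(1, 2, 3, 1, 2, 3)
  d$y <- base[as.integer(sub("s", "", d$subject))] + 0.2 * d$session
  # per-subject data identical across groups -> zero genotype F
  res <- rm_anova_2way(d, "y")
  expect_equal(res$statistic[res$effect == "group"], 0, tolerance = 1e-12)
  # subject with a missing session is dropped listwise with a warning
  d2 <- d[-1, ]
  d2$y <- d2$y + rnorm(nrow(d2), 0, 0.01)
  expect_warning(res2 <- rm_anova_2way(d2, "y"), "missing sessions")
  expect_equal(res2$df2[res2$effect == "group"], 3)  # 5 subjects - 2
})

test_that("one-way ANOVA applies Bonferroni to planned comparisons only", {
  set.seed(54)
  v <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- oneway_anova_bonferroni(v, g,
                                 planned_pairs = list(c("a", "b"),
                                                      c("a", "c")))
  expect_equal(nrow(res), 3)  # omnibus + 2 planned
  expect_equal(res$p_value[-1], pmin(1, 2 * res$p_raw[-1]))
  # omnibus F against the brute-force SS arithmetic
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum((v - ave(v, g))^2)
  expect_equal(res$statistic[1], (ssb / 2) / (ssw / 21), tolerance = 1e-9)
  # identical groups: omnibus F = 0, adjusted p = 1
  v0 <- rep(c(1, 2, 3), 3)
  res0 <- oneway_anova_bonferroni(v0, rep(c("a", "b", "c"), each = 3))
  expect_equal(res0$statistic[1], 0)
  expect_true(all(res0$p_value[-1] == 1))
  expect_error(oneway_anova_bonferroni(1:4, rep("a", 4)), "2 groups")
})

test_that("ANCOVA adjusts a shared age slope away", {
  set.seed(55)
  # groups differing only through a shared age slope: adjustment removes
  # the apparent group effect in nearly all replicates
  ns <- 0
  for (i in 1:400) {
    age <- c(rnorm(12, 70, 5), rnorm(12, 110, 5))
    y <- 0.01 * age + rnorm(24, 0, 0.05)
    d <- tibble::tibble(group = rep(c("young", "old"), each = 12),
                        age_days = age, probability = y)
    res <- ancova_age_tukey(d)
    if (res$p_value[1] > 0.05) ns <- ns + 1
  }
  expect_gte(ns / 400, 0.90)
})

test_that("ANCOVA agrees with one-way ANOVA when age is uninformative", {
  set.seed(56)
  d <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                      age_days = rnorm(20, 90, 10),
                      probability = rnorm(20) + rep(c(0, 0.8), each = 10))
  res <- ancova_age_tukey(d)
  p_anova <- summary(stats::aov(probability ~ group, d))[[1]]$`Pr(>F)`[1]
  # with a zero generative age slope the adjusted and unadjusted p agree
  # on average: paired simulation over replicates
  diffs <- replicate(200, {
    dd <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                         age_days = rnorm(20, 90, 10),
                         probability = rnorm(20) + rep(c(0, 0.4), each = 10))
    pa <- ancova_age_tukey(dd)$p_value[1]
    pb <- summary(stats::aov(probability ~ group, dd))[[1]]$`Pr(>F)`[1]
    pa - pb
  })
  expect_lt(abs(mean(diffs)), 0.03)
  # constant age: exact reduction to one-way ANOVA
  d2 <- d; d2$age_days <- 90
  res2 <- ancova_age_tukey(d2)
  expect_equal(res2$p_value[1], p_anova, tolerance = 1e-9)
  # identical groups: adjusted F ~ 0
  d3 <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                       age_days = rep(rnorm(6, 90, 5), 2),
                       probability = rep(rnorm(6), 2))
  expect_lt(ancova_age_tukey(d3)$statistic[1], 1e-12)
  # Tukey rows present
  expect_equal(nrow(res), 2)
})

test_that("savings comparisons detect extinction and reacquisition", {
  # deterministic curves: strong CR at end of acquisition, gone after
  # extinction, back after reacquisition
  set.seed(57)
  mk <- function(subj) {
    dplyr::bind_rows(
      tibble::tibble(subject = subj, group = "wt", phase = "acquisition",
                     session = 1:12,
                     percent_cr = seq(5, 60, length.out = 12) + rnorm(12, 0, 3)),
      tibble::tibble(subject = subj, group = "wt", phase = "extinction",
                     session = 1:4,
                     percent_cr = c(40, 20, 10, 5) + rnorm(4, 0, 2)),
      tibble::tibble(subject = subj, group = "wt", phase = "reacquisition",
                     session = 1:3,
                     percent_cr = c(30, 50, 58) + rnorm(3, 0, 3)))
  }
  curves <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:10), mk))
  sv <- savings_summary(curves)
  acq_ext <- sv[sv$comparison == "acquisition_vs_extinction", ]
  ext_rea <- sv[sv$comparison == "extinction_vs_reacquisition", ]
  expect_lt(acq_ext$p_value, 0.05)
  expect_gt(acq_ext$mean_diff, 0)
  expect_lt(ext_rea$p_value, 0.05)
  expect_lt(ext_rea$mean_diff, 0)
  # identical phase values -> t = 0, p = 1
  flat <- curves
  flat$percent_cr <- 10
  sv0 <- savings_summary(flat)
  expect_true(all(sv0$statistic == 0))
  expect_true(all(sv0$p_value == 1))
  # never-acquired groups are reported but skipped
  sv1 <- savings_summary(curves, skip_groups = "wt")
  expect_true(all(sv1$skipped))
  expect_true(all(is.na(sv1$p_value)))
  # subjects missing a phase are excluded with a warning
  expect_warning(savings_summary(curves[curves$subject != "s01" |
                                          curves$phase != "extinction", ]),
                 "missing a phase")
})

test_that("metrics-level cohort simulator tracks its generative curve", {
  m <- simulate_metrics_cohort(
    list(list(label = "wt", n_subjects = 10, p_max = 0.55)),
    subject_sd = 0, seed = 58)
  lf <- last_four_mean(m)
  truth <- 0.55 * mean(1 - exp(-(9:12) / 4))
  expect_equal(mean(lf$probability), truth, tolerance = 0.05)
  # per-session group means track the closed-form curve
  by_sess <- tapply(m$probability, m$session, mean)
  expect_equal(as.numeric(by_sess), 0.55 * (1 - exp(-(1:12) / 4)),
               tolerance = 0.06)
})
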