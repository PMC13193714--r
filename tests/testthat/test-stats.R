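test_that("paired t matches the closed form and the one-sample identity", {
  s <- paired_sample(c("u1", "u2", "u3"), a = c(2, 4, 6), b = c(1, 2, 3))
  res <- paired_t(s)
  # d = (1, 2, 3): mean 2, sd 1, n 3 -> t = 2 * sqrt(3), df 2
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  # oracle: base t.test, both paired and one-sample-of-differences forms
  ref <- t.test(s$a, s$b, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
  ref1 <- t.test(s$a - s$b, mu = 0)
  expect_equal(res$p_raw, ref1$p.value, tolerance = 1e-12)
})

test_that("degenerate paired samples are handled explicitly", {
  s_eq <- paired_sample(c("u1", "u2"), a = c(3, 5), b = c(3, 5))
  res <- paired_t(s_eq)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)
  s_const <- paired_sample(c("u1", "u2"), a = c(4, 6), b = c(3, 5))
  expect_error(paired_t(s_const), "infinite")
  expect_error(paired_sample("u1", 1, 2), "units")
  expect_error(paired_sample(c("u1", "u1"), 1:2, 3:4), "duplicate")
})

test_that("paired t holds its nominal type-I error rate", {
  n <- 6
  reps <- 10000
  withr::with_seed(77, d <- matrix(rnorm(reps * n), reps, n))
  mu <- rowMeans(d)
  sdv <- sqrt(rowSums((d - mu)^2) / (n - 1))
  tv <- mu / (sdv / sqrt(n))
  rate <- mean(abs(tv) > qt(0.975, n - 1))
  expect_gte(rate, 0.041)
  expect_lte(rate, 0.059)
})

test_that("tail probabilities agree with reference quantiles to 1e-10", {
  # t distribution spot checks at tabulated quantiles
  expect_equal(2 * pt(-abs(qt(0.975, 4)), 4), 0.05, tolerance = 1e-10)
  expect_equal(2 * pt(-abs(qt(0.995, 31)), 31), 0.01, tolerance = 1e-10)
  expect_equal(pf(qf(0.95, 2, 31), 2, 31, lower.tail = FALSE), 0.05,
               tolerance = 1e-10)
})

test_that("mixed ANOVA reproduces a hand-computed 2x2 decomposition", {
  # 2 groups x 2 within levels, 3 units each; small integer data
  d <- data.frame(
    unit = rep(sprintf("u%d", 1:6), each = 2),
    group = rep(c("ctrl", "treat"), each = 6),
    within = rep(c("l1", "l2"), times = 6),
    value = c(3, 5,  4, 6,  5, 9,    # ctrl units
              6, 4,  7, 3,  8, 4))   # treat units
  fit <- mixed_rm_anova(d)
  # oracle: explicit sums over cell/marginal means
  y <- d$value
  grand <- mean(y)
  cellm <- tapply(y, list(d$group, d$within), mean)
  gm <- tapply(y, d$group, mean)
  lm_ <- tapply(y, d$within, mean)
  um <- tapply(y, d$unit, mean)
  ss_group <- 2 * 3 * sum((gm - grand)^2)
  ss_within <- 6 * sum((lm_ - grand)^2)
  ss_cells <- 3 * sum((cellm - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_within
  ss_subj <- 2 * sum((um - rep(gm, each = 3))^2)
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_cells - ss_subj
  got <- setNames(fit$ss, fit$effect)
  expect_equal(got[["group"]], ss_group, tolerance = 1e-8)
  expect_equal(got[["within"]], ss_within, tolerance = 1e-8)
  expect_equal(got[["group:within"]], ss_inter, tolerance = 1e-8)
  expect_equal(got[["subjects_within_groups"]], ss_subj, tolerance = 1e-8)
  expect_equal(got[["error_within"]], ss_err, tolerance = 1e-8)
  expect_equal(fit$df, c(1, 1, 1, 4, 4))
  # F ratios use the matching error strata
  expect_equal(fit$f[1], (ss_group / 1) / (ss_subj / 4), tolerance = 1e-10)
  expect_equal(fit$f[2], (ss_within / 1) / (ss_err / 4), tolerance = 1e-10)
})

test_that("mixed ANOVA agrees with aov's Error() decomposition", {
  cm <- matrix(c(10, 12, 9, 15), 2, 2,
               dimnames = list(c("g1", "g2"), c("w1", "w2")))
  for (npg in list(c(5, 5), c(6, 9))) {  # balanced and unbalanced groups
    d <- make_mixed_data(cm, npg, sd = 2, seed = 42 + npg[2])
    fit <- mixed_rm_anova(d)
    ref <- summary(aov(value ~ group * within + Error(unit),
                       data = transform(d, unit = factor(unit),
                                        group = factor(group),
                                        within = factor(within))))
    ref_between <- ref[["Error: unit"]][[1]]
    ref_within <- ref[["Error: Within"]][[1]]
    got <- setNames(fit$ss, fit$effect)
    expect_equal(got[["group"]], ref_between["group", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(got[["subjects_within_groups"]],
                 ref_between["Residuals", "Sum Sq"], tolerance = 1e-8)
    expect_equal(got[["within"]], ref_within["within", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(got[["group:within"]], ref_within["group:within", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(got[["error_within"]], ref_within["Residuals", "Sum Sq"],
                 tolerance = 1e-8)
    fp <- setNames(fit$p, fit$effect)
    expect_equal(fp[["group"]], ref_between["group", "Pr(>F)"],
                 tolerance = 1e-8)
    expect_equal(fp[["within"]], ref_within["within", "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("ANOVA sums of squares are conserved on random balanced designs", {
  for (k in 1:5) {
    cm <- matrix(rnorm(6, sd = 3), 2, 3,
                 dimnames = list(c("g1", "g2"), c("w1", "w2", "w3")))
    d <- make_mixed_data(cm, c(4, 7), sd = 1.5, seed = k)
    fit <- mixed_rm_anova(d)
    expect_equal(sum(fit$ss), attr(fit, "ss_total"),
                 tolerance = 1e-8 * attr(fit, "ss_total"))
    # dfs partition the total
    expect_equal(sum(fit$df), nrow(d) - 1)
  }
})

test_that("all-equal data gives zero sums of squares and undefined F", {
  d <- data.frame(unit = rep(c("u1", "u2", "u3", "u4"), each = 2),
                  group = rep(c("g1", "g2"), each = 4),
                  within = rep(c("w1", "w2"), 4),
                  value = 7)
  fit <- mixed_rm_anova(d)
  expect_equal(fit$ss, rep(0, 5))
  expect_true(all(is.na(fit$f[1:3])))
})

test_that("incomplete or ill-structured designs are rejected", {
  d <- data.frame(unit = c("u1", "u1", "u2"), group = "g1",
                  within = c("w1", "w2", "w1"), value = 1:3)
  expect_error(mixed_rm_anova(d), "incomplete")
  d2 <- data.frame(unit = rep("u1", 2), group = c("g1", "g2"),
                   within = c("w1", "w2"), value = 1:2)
  expect_error(mixed_rm_anova(d2), "exactly one group")
})

test_that("Sidak adjustment formula and monotonicity", {
  expect_equal(sidak_adjust(0.02, 3), 1 - 0.98^3)
  expect_equal(sidak_adjust(0.02, 3), 0.058808, tolerance = 1e-9)
  expect_equal(sidak_adjust(0.5, 1), 0.5)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(1, 5), 1)
  withr::with_seed(3, p <- runif(50))
  expect_true(all(sidak_adjust(p, 4) >= p))
  expect_error(sidak_adjust(0.5, 0), "m")
  expect_error(sidak_adjust(1.5, 2), "p_raw")
})

test_that("post-hoc contrasts use the shared error term and df", {
  # 3 groups totalling 34 units, 2 within levels -> error df 31
  cm <- matrix(c(10, 6, 11, 10.8, 12, 11), 3, 2,
               dimnames = list(c("ctrl", "rostral", "caudal"), c("on", "off")))
  d <- make_mixed_data(cm, c(10, 13, 11), sd = 1.8, seed = 9)
  fit <- mixed_rm_anova(d)
  expect_equal(attr(fit, "df_error"), 31)
  ph <- sidak_posthoc(fit, levels = c("on", "off"))
  expect_length(ph, 3)
  ms_err <- attr(fit, "ms_error")
  cm_fit <- attr(fit, "cell_means")
  npg <- attr(fit, "units_per_group")
  for (g in names(ph)) {
    expect_equal(ph[[g]]$df, 31)
    # closed form: t = (mean_on - mean_off) / sqrt(2 MS_err / n_g)
    t_hand <- (cm_fit[g, "on"] - cm_fit[g, "off"]) /
      sqrt(2 * ms_err / npg[[g]])
    expect_equal(ph[[g]]$statistic, t_hand, tolerance = 1e-12)
    expect_equal(ph[[g]]$m, 3L)
    expect_gte(ph[[g]]$p_adjusted, ph[[g]]$p_raw)
    expect_equal(ph[[g]]$p_adjusted, sidak_adjust(ph[[g]]$p_raw, 3))
  }
  # the simulated suppression group should carry the significant contrast
  expect_lt(ph[["rostral"]]$p_adjusted, 0.05)
})

test_that("identical level means give t = 0 and adjusted p = 1", {
  # g1's observed level means are exactly equal by construction
  d <- data.frame(
    unit = rep(sprintf("u%d", 1:6), each = 2),
    group = rep(c("g1", "g2"), each = 6),
    within = rep(c("w1", "w2"), 6),
    value = c(4, 6, 6, 4, 5, 5,      # g1: both level means 5
              2, 8, 3, 9, 4, 10))    # g2: consistent +6 shift
  fit <- mixed_rm_anova(d)
  ph <- sidak_posthoc(fit, levels = c("w1", "w2"))
  expect_equal(ph[["g1"]]$statistic, 0)
  expect_equal(ph[["g1"]]$p_raw, 1)
  expect_equal(ph[["g1"]]$p_adjusted, 1)
  expect_gt(abs(ph[["g2"]]$statistic), 3)
})

test_that("pure interaction inflates only the interaction F (Monte Carlo)", {
  f_int <- numeric(20); f_group <- numeric(20)
  for (k in 1:20) {
    eff <- if (k <= 10) 0 else 3
    # both margins flat: a pure crossover interaction
    cm <- matrix(c(-eff / 2, eff / 2, eff / 2, -eff / 2), 2, 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("w1", "w2")))
    d <- make_mixed_data(cm, c(6, 6), sd = 1, seed = 400 + k)
    fit <- mixed_rm_anova(d)
    f_int[k] <- fit$f[3]; f_group[k] <- fit$f[1]
  }
  expect_gt(median(f_int[11:20]), 10 * median(f_int[1:10]))
  # group F stays near its null scale
  expect_lt(median(f_group[11:20]), 6)
})
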