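test_that("Holm adjustment matches the hand-worked step-down example", {
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.1, 1.2)), "p")
  p <- c(0.04, 0.001, 0.2, 0.9)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("Holm adjustment equals brute-force enumeration of the step-down
           rule", {
  set.seed(3)
  grids <- c(list(c(0.012, 0.03, 0.04, 0.2, 0.8),
                  c(0.5, 0.5, 0.5), c(0.001, 0.9)),
             replicate(20, runif(sample(1:5, 1)), simplify = FALSE))
  for (p in grids)
    expect_equal(holm_adjust(p), holm_brute_force(p), tolerance = 1e-12)
})

test_that("effect sizes from contrast estimates behave at the origin and
           reject bad inputs", {
  d0 <- cohens_d_from_emm(0, 2, 20, 20)
  expect_equal(d0$d, 0)
  expect_equal(d0$lower, -d0$upper)
  expect_error(cohens_d_from_emm(1, 0, 20, 20), "se")
  expect_error(cohens_d_from_emm(1, 1, 1, 20), "n1")
  g <- hedges_g_from_emm(21.3, 4.71, 24, 26)
  d <- cohens_d_from_emm(21.3, 4.71, 24, 26)
  expect_equal(g$g, d$d * (1 - 3 / (4 * 50 - 9)))
  expect_lt(abs(g$g), abs(d$d))
})

test_that("partial eta-squared follows its definition, monotonicity and CI
           bounds", {
  expect_equal(partial_eta_sq(0, 1, 50)$eta_sq, 0)
  e1 <- partial_eta_sq(3, 1, 50)
  e2 <- partial_eta_sq(6, 1, 50)
  expect_lt(e1$eta_sq, e2$eta_sq)
  expect_equal(e2$eta_sq, 6 / (6 + 50))
  expect_gte(e1$lower, 0)
  expect_lte(e1$lower, e1$eta_sq)
  expect_gte(e1$upper, e1$eta_sq)
  expect_error(partial_eta_sq(2, 0, 10), "df")
})

test_that("chi-square independence test matches hand computation and is
           permutation invariant", {
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(chisq_independence(prop)$chisq, 0, tolerance = 1e-10)
  tab <- matrix(c(10, 20, 20, 10), 2)
  r <- chisq_independence(tab)
  expect_equal(r$chisq, 20 / 3, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_equal(chisq_independence(tab[2:1, ])$chisq, r$chisq)
  expect_error(chisq_independence(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(chisq_independence(matrix(c(1.5, 2, 1, 2), 2)), "integer")
})

test_that("single-condition ANCOVA reduces to least squares with the
           closed-form adjusted-mean contrast", {
  tab <- toy_outcome_table(n_per_group = 12, effect = 3, seed = 2)
  fit <- fit_baseline_ancova(tab, "y")
  expect_identical(fit$type, "lm")
  expect_equal(emm_contrast(fit)$estimate, adjusted_mean_contrast(fit$data),
               tolerance = 1e-8)
  ft <- ancova_f_test(fit, "group")
  expect_equal(ft$df2, 2 * 12 - 3)   # residual df N - 3
})

test_that("mixed ANCOVA EMMs equal closed-form adjusted means per condition
           on balanced data", {
  tab <- toy_outcome_table(n_per_group = 10,
                           conditions = c("c1", "c2", "c3"),
                           effect = 2, seed = 4)
  fit <- fit_baseline_ancova(tab, "y")
  expect_identical(fit$type, "lme")
  ct <- emm_contrast(fit)
  # reference: pooled-slope adjusted means computed from the model's own
  # coefficients, per condition, at the grand-mean baseline
  bhat <- nlme::fixef(fit$model)["baseline"]
  for (cn in c("c1", "c2", "c3")) {
    d <- fit$data[fit$data$condition == cn, ]
    adj <- tapply(d$followup, d$group, mean) -
      bhat * (tapply(d$baseline, d$group, mean) - mean(fit$data$baseline))
    expect_equal(ct$estimate[ct$condition == cn],
                 unname(adj["active"] - adj["placebo"]), tolerance = 1e-8)
  }
  expect_error(emm_contrast(fit, condition = "nope"), "condition")
})

test_that("contrasts are equivariant under constant shifts and group
           relabelling", {
  tab <- toy_outcome_table(n_per_group = 10, effect = 2, seed = 5)
  fit <- fit_baseline_ancova(tab, "y")
  shifted <- tab
  shifted$value[shifted$visit == "followup"] <-
    shifted$value[shifted$visit == "followup"] + 7
  fit2 <- fit_baseline_ancova(shifted, "y")
  expect_equal(ancova_f_test(fit2, "group")$F, ancova_f_test(fit, "group")$F,
               tolerance = 1e-8)
  expect_equal(emm_contrast(fit2)$estimate, emm_contrast(fit)$estimate,
               tolerance = 1e-8)
  swapped <- tab
  swapped$group <- ifelse(tab$group == "active", "placebo", "active")
  fit3 <- fit_baseline_ancova(swapped, "y")
  expect_equal(emm_contrast(fit3)$estimate, -emm_contrast(fit)$estimate,
               tolerance = 1e-8)
  expect_equal(emm_contrast(fit3)$se, emm_contrast(fit)$se, tolerance = 1e-8)
})

test_that("contrast tables Holm-correct across conditions and attach effect
           sizes with the contrast's observation counts", {
  tab <- toy_outcome_table(n_per_group = 9, conditions = c("c1", "c2", "c3"),
                           effect = 2, seed = 6)
  fit <- fit_baseline_ancova(tab, "y")
  ct <- ancova_contrasts(fit)
  percond <- ct[ct$condition != "overall", ]
  expect_equal(percond$p_holm, holm_adjust(percond$p))
  expect_equal(unique(percond$n1), 9)
  ov <- ct[ct$condition == "overall", ]
  expect_equal(ov$n1, 27)   # subjects x conditions for the pooled contrast
  expect_equal(ov$d,
               cohens_d_from_emm(ov$estimate, ov$se, 27, 27)$d)
})

test_that("log transform policy is applied and recorded", {
  tab <- toy_outcome_table(n_per_group = 8, seed = 7)
  tab$value <- exp(tab$value / 20)
  fit <- fit_baseline_ancova(tab, "y", transform = "log")
  expect_identical(fit$transform, "log")
  neg <- tab; neg$value[1] <- -1
  expect_error(fit_baseline_ancova(neg, "y", transform = "log"), "positive")
})

test_that("longitudinal mixed model recovers injected daily group offsets", {
  set.seed(9)
  n <- 30; days <- 10
  mk <- function(delta) {
    subj <- rep(sprintf("S%02d", 1:(2 * n)), each = days)
    grp <- rep(rep(c("active", "placebo"), each = n), each = days)
    day <- rep(1:days, 2 * n)
    b <- rep(rnorm(2 * n, 0, 1), each = days)
    data.frame(subject = subj, group = grp, day = day, item = "it",
               value = 10 + 0.2 * day + b +
                 ifelse(grp == "active", delta, 0) + rnorm(2 * n * days, 0, 1))
  }
  r0 <- longitudinal_lmm(mk(0), "it")
  expect_lt(abs(r0$estimate), 0.6)
  r2 <- longitudinal_lmm(mk(2), "it")
  expect_equal(r2$estimate, 2, tolerance = 0.6)
  expect_true(r2$lower < r2$estimate && r2$estimate < r2$upper)
  one_day <- mk(0)[rep(seq(1, nrow(mk(0)), days)), ]
  expect_error(longitudinal_lmm(one_day, "it"), "time point|ANCOVA")
})

test_that("balanced complete daily data gives the time-detrended group mean
           difference", {
  set.seed(10)
  n <- 12; days <- 8
  subj <- rep(sprintf("S%02d", 1:(2 * n)), each = days)
  grp <- rep(rep(c("active", "placebo"), each = n), each = days)
  day <- rep(1:days, 2 * n)
  val <- 5 + 0.3 * day + ifelse(grp == "active", 1.5, 0) +
    rnorm(2 * n * days, 0, 0.5)
  daily <- data.frame(subject = subj, group = grp, day = day, item = "x",
                      value = val)
  r <- longitudinal_lmm(daily, "x")
  # balanced design: group effect equals the raw difference of group means
  raw <- mean(val[grp == "active"]) - mean(val[grp == "placebo"])
  expect_equal(r$estimate, raw, tolerance = 1e-6)
})
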