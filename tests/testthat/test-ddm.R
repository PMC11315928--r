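test_that("parameter constructor enforces domains and bias is the z*a product", {
  expect_error(ddm_params(-1, 0.5, 0.2, 1, 0), "a")
  expect_error(ddm_params(1, 1.2, 0.2, 1, 0), "z")
  expect_error(ddm_params(1, 0.5, -0.1, 1, 0), "ter")
  p <- ddm_params(2, 0.5, 0.2, 1, 0)
  expect_equal(summarise_bias(p), 1.0)
  expect_equal(summarise_bias(ddm_params(1.5, 0.4, 0.2, 1, 0)), 0.6)
  expect_lt(summarise_bias(p), p$a)
})

test_that("defective CDF limits: nothing before ter, symmetry at zero drift,
           conservation at infinity", {
  p <- ddm_params(1, 0.5, 0.2, 0, 0)
  expect_equal(fpt_defective_cdf(p, c(0, 0.1, 0.2), "upper", "go"),
               c(0, 0, 0))
  expect_equal(fpt_defective_cdf(p, 100, "upper", "go"), 0.5,
               tolerance = 1e-8)
  expect_equal(fpt_defective_cdf(p, 100, "lower", "go"), 0.5,
               tolerance = 1e-8)
  # conservation across a parameter grid
  for (a in c(0.6, 1.0, 1.8)) for (z in c(0.3, 0.5, 0.7))
    for (v in c(-2, 0.5, 3)) {
      pp <- ddm_params(a, z, 0.15, v, 0)
      tot <- fpt_defective_cdf(pp, 60, "upper", "go") +
        fpt_defective_cdf(pp, 60, "lower", "go")
      expect_equal(tot, 1, tolerance = 1e-6)
    }
  expect_error(fpt_defective_cdf(p, -1, "upper", "go"), "t")
})

test_that("stimulus class selects the effective drift", {
  p <- ddm_params(1, 0.5, 0.15, 2, 0.5)
  # go drift v+dc = 2.5; nogo drift -v+dc = -1.5
  ref_go <- ddm_params(1, 0.5, 0.15, 2.5, 0)
  ref_ng <- ddm_params(1, 0.5, 0.15, -1.5, 0)
  expect_equal(fpt_defective_cdf(p, 0.5, "upper", "go"),
               fpt_defective_cdf(ref_go, 0.5, "upper", "go"))
  expect_equal(fpt_defective_cdf(p, 0.5, "upper", "nogo"),
               fpt_defective_cdf(ref_ng, 0.5, "upper", "go"))
})

test_that("analytic CDF matches an independent pure-R Euler oracle", {
  p <- ddm_params(1, 0.5, 0.2, 1, 0)
  set.seed(14)
  sim <- euler_fpt_r(20000, 1, 0.5, 1, 0.001, 1.0)
  for (tt in c(0.3, 0.5, 1.0)) {
    emp <- mean(sim$outcome == 1 & (0.2 + sim$dtime) <= tt + 1e-12,
                na.rm = TRUE)
    expect_equal(fpt_defective_cdf(p, tt, "upper", "go"), emp,
                 tolerance = 0.015)
  }
})

test_that("trial sampler is deterministic, censors at the deadline and
           matches the analytic press mass", {
  p <- ddm_params(0.9, 0.62, 0.17, 2.5, 0.5)
  tt <- rep(c("go", "nogo"), c(80, 20))
  s1 <- with_seed_local(5, sample_gng_trials(p, tt))
  s2 <- with_seed_local(5, sample_gng_trials(p, tt))
  expect_identical(s1, s2)
  rts <- s1$rt_ms[!is.na(s1$rt_ms)]
  expect_true(all(rts <= 400 + 1e-9))
  expect_true(all(rts >= p$ter * 1000))
  expect_true(all(is.na(s1$rt_ms[s1$response == "none"])))
  # empirical press fraction vs analytic defective mass at the deadline
  set.seed(6)
  big <- sample_gng_trials(p, rep("go", 1e5))
  expect_equal(mean(big$response == "press"),
               fpt_defective_cdf(p, 0.4, "upper", "go"), tolerance = 0.01)
  # boundary-start limit: z near 1 with strong positive drift presses
  pz <- ddm_params(0.9, 0.995, 0.1, 6, 0)
  set.seed(7)
  pr <- sample_gng_trials(pz, rep("go", 2000))
  expect_gt(mean(pr$response == "press"), 0.99)
})

test_that("quantile binning reproduces the definitional counts", {
  # 100 continuous press RTs -> (10, 20, 20, 20, 20, 10)
  set.seed(9)
  tr <- data.frame(trial_type = "go", response = "press",
                   rt_ms = 150 + 200 * runif(100))
  b <- bin_observed(tr)
  expect_equal(b$go$counts, c(10, 20, 20, 20, 20, 10, 0))
  # conservation with non-responses
  tr2 <- data.frame(trial_type = "go",
                    response = rep(c("press", "none"), c(15, 5)),
                    rt_ms = c(150 + 200 * runif(15), rep(NA, 5)))
  b2 <- bin_observed(tr2)
  expect_equal(sum(b2$go$counts), 20)
  expect_equal(b2$go$counts[length(b2$go$counts)], 5)
  expect_false(b2$go$collapsed)
  # below the floor the cell collapses to a median split and is flagged
  b3 <- bin_observed(tr2[c(1:6, 16:20), ])
  expect_true(b3$go$collapsed)
  expect_equal(length(b3$go$counts), 3L)
})

test_that("tie handling on a printed 10-value list matches the hand
           computation (type-7 quantiles, ties to the lower bin)", {
  rts <- c(210, 220, 230, 240, 250, 260, 270, 280, 290, 300)
  tr <- data.frame(trial_type = "go", response = "press", rt_ms = rts)
  b <- bin_observed(tr, min_press = 10)
  expect_equal(b$go$edges_ms, c(219, 237, 255, 273, 291))
  expect_equal(b$go$counts, c(1, 2, 2, 2, 2, 1, 0))
})

test_that("G-squared is zero at perfect fit, positive elsewhere, and matches
           direct evaluation", {
  bs <- structure(list(go = list(edges_ms = c(200, 300), counts = c(30, 70, 0),
                                 n = 100, n_press = 100, collapsed = FALSE)),
                  class = "gng_binset")
  expect_equal(gsquare(bs, list(go = c(0.3, 0.7, 0))), 0)
  g <- gsquare(bs, list(go = c(0.5, 0.5, 0)))
  expect_equal(g, 2 * (30 * log(30 / 50) + 70 * log(70 / 50)),
               tolerance = 1e-10)
  expect_equal(g, 16.4566, tolerance = 1e-4)
  expect_error(gsquare(bs, list(go = c(0.4, 0.4, 0))), "sum to 1")
  # non-negativity over random tables
  set.seed(15)
  for (i in 1:20) {
    O <- rmultinom(1, 50, runif(4) + 0.1)[, 1]
    p <- runif(4) + 0.1; p <- p / sum(p)
    bsr <- structure(list(go = list(counts = O, n = 50)), class = "gng_binset")
    expect_gte(gsquare(bsr, list(go = p)), -1e-10)
  }
})

test_that("expected bin probabilities sum to one per trial type", {
  p <- ddm_params(0.9, 0.62, 0.17, 2.5, 0.5)
  set.seed(16)
  tr <- sample_gng_trials(p, rep(c("go", "nogo"), c(128, 32)))
  b <- bin_observed(tr)
  ex <- ddm_expected_probs(p, b)
  for (st in names(ex)) expect_equal(sum(ex[[st]]), 1, tolerance = 1e-8)
})

test_that("cell fits are deterministic, recover plausible values and flag
           pathological responders", {
  p <- ddm_params(0.9, 0.62, 0.17, 2.5, 0.5)
  set.seed(17)
  tr <- sample_gng_trials(p, sample(rep(c("go", "nogo"), c(128, 32))))
  f1 <- fit_ddm_cell(tr, seed = 3, restarts = 4)
  f2 <- fit_ddm_cell(tr, seed = 3, restarts = 4)
  expect_identical(f1, f2)
  expect_true(f1$convergence)
  expect_lt(abs(f1$params$ter - p$ter), 0.08)
  # all-press subject: z is pushed toward the go boundary and flagged
  allp <- tr
  allp$response <- "press"
  allp$rt_ms[is.na(allp$rt_ms)] <- 250
  fp <- fit_ddm_cell(allp, seed = 2, restarts = 4)
  expect_gt(fp$params$z, 0.8)
  expect_true(length(fp$flags) > 0)
})
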