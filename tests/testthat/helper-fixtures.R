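# Shared fixtures and independent oracles used across the test files.

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# small cohort spec for fast structural tests
small_spec <- function(seed = 7, ...) {
  cohort_spec(n_active = 4, n_placebo = 4, seed = seed, ...)
}

# balanced two-visit outcome table with a known injected effect
toy_outcome_table <- function(n_per_group = 10, conditions = "c1",
                              effect = 0, seed = 1) {
  set.seed(seed)
  subj <- sprintf("P%02d", seq_len(2 * n_per_group))
  grp <- rep(c("active", "placebo"), each = n_per_group)
  do.call(rbind, lapply(conditions, function(cn) {
    base <- rnorm(2 * n_per_group, 50, 5)
    foll <- 0.5 * base + rnorm(2 * n_per_group, 25, 3) +
      ifelse(grp == "active", effect, 0)
    rbind(data.frame(subject = subj, group = grp, visit = "baseline",
                     condition = cn, outcome = "y", value = base),
          data.frame(subject = subj, group = grp, visit = "followup",
                     condition = cn, outcome = "y", value = foll))
  }))
}

# brute-force step-down Holm: literal definition, adjusted p_(i) =
# max over j <= i of min(1, (m - j + 1) * p_(j)) in the sorted order
holm_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(i), function(j) min(1, (m - j + 1) * p[o][j]),
                   numeric(1))
    adj_sorted[i] <- max(cand)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# closed-form baseline-adjusted means for a single-condition ANCOVA
adjusted_mean_contrast <- function(dat) {
  b <- coef(lm(followup ~ group + baseline, data = dat))["baseline"]
  adj <- tapply(dat$followup, dat$group, mean) -
    b * (tapply(dat$baseline, dat$group, mean) - mean(dat$baseline))
  unname(adj["active"] - adj["placebo"])
}

# pure-R Euler-Maruyama first-passage sampler with bridge correction,
# independent of the compiled path (used to validate the package sampler)
euler_fpt_r <- function(n, a, w0, mu, dt, tmax) {
  out <- integer(n); rt <- rep(NA_real_, n)
  sdt <- sqrt(dt)
  for (i in seq_len(n)) {
    x <- w0; t <- 0; res <- 0L; tt <- NA_real_
    while (t < tmax - 1e-12) {
      xn <- x + mu * dt + sdt * rnorm(1)
      t <- t + dt
      if (xn >= a) { res <- 1L; tt <- t; break }
      if (xn <= 0) { res <- -1L; tt <- t; break }
      pu <- exp(-2 * (a - x) * (a - xn) / dt)
      pl <- exp(-2 * x * xn / dt)
      u <- runif(1)
      if (u < pu) { res <- 1L; tt <- t - dt / 2; break }
      if (u < pu + pl) { res <- -1L; tt <- t - dt / 2; break }
      x <- xn
    }
    out[i] <- res; rt[i] <- tt
  }
  list(outcome = out, dtime = rt)
}

# hand-built go/no-go cell: 12 go (9 press with known RTs, 3 none),
# 8 no-go (3 press, 5 none)
handmade_gng_cell <- function() {
  data.frame(
    subject = "S1", group = "active", visit = "followup",
    condition = "control",
    trial_type = c(rep("go", 12), rep("nogo", 8)),
    response = c(rep("press", 9), rep("none", 3), rep("press", 3),
                 rep("none", 5)),
    rt_ms = c(210, 250, 260, 280, 300, 310, 320, 350, 390, NA, NA, NA,
              240, 290, 330, NA, NA, NA, NA, NA))
}
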