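#' Specification of a synthetic two-visit, two-group study cohort
#'
#' Defines the population from which subject-level generative parameters are
#' drawn, the between-group effects injected at follow-up, and the task
#' dimensions. Population means are given on the natural scale of each
#' parameter and dispersions on its transformed (analysis) scale: logit for
#' learning rates and the DDM start point, log for outcome sensitivities,
#' boundary separation and non-decision time, identity for drift terms.
#' Group effects (`group_shift`) are additive on the transformed scale and
#' applied only to the active group at follow-up; a DDM shift can be
#' restricted to one interference condition by suffixing its name (e.g.
#' `z_aversive`).
#'
#' @param n_active,n_placebo group sizes (default 26 and 27)
#' @param rl named list of `c(mean, sd)` for alpha_win, alpha_loss,
#'   rho_win, rho_loss
#' @param ddm named list of `c(mean, sd)` for a, z, ter, v, dc
#' @param v_condition_offset fixed drift-rate decrements per interference
#'   condition (emotional distractors slow evidence accumulation)
#' @param memory named list of generative settings for the n-back, verbal
#'   learning and daily-rating tables
#' @param group_shift named numeric vector of transformed-scale shifts for
#'   the active group at follow-up
#' @param baseline_followup_corr within-subject correlation of transformed
#'   parameters across visits, in \[0, 1)
#' @param deadline_s go/no-go response deadline in seconds
#' @param n_days days of daily ratings
#' @param seed root seed; every stream derives from it
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_active = 26, n_placebo = 27,
                        rl = list(alpha_win = c(0.30, 0.8),
                                  alpha_loss = c(0.30, 0.8),
                                  rho_win = c(3.0, 0.4),
                                  rho_loss = c(3.0, 0.4)),
                        ddm = list(a = c(0.90, 0.25),
                                   z = c(0.62, 0.50),
                                   ter = c(0.17, 0.15),
                                   v = c(2.5, 1.0),
                                   dc = c(0.5, 0.6)),
                        v_condition_offset = c(control = 0, positive = -0.2,
                                               aversive = -0.4),
                        memory = list(nback_acc = c(0.95, 0.90, 0.82, 0.72),
                                      nback_rt_ms = c(500, 600, 750, 900),
                                      avlt_learning = c(0.45, 0.60, 0.70, 0.78, 0.84),
                                      avlt_distraction = 0.40,
                                      avlt_delayed = 0.80,
                                      ability_sd = 0.5,
                                      speed_sd = 0.15),
                        group_shift = c(rho_loss = -0.4, z_aversive = -0.5),
                        baseline_followup_corr = 0.7,
                        deadline_s = 0.4, n_days = 14, seed = 101L) {
  if (!is.numeric(n_active) || n_active < 1) stop_field("n_active", "must be >= 1")
  if (!is.numeric(n_placebo) || n_placebo < 1) stop_field("n_placebo", "must be >= 1")
  check_scalar(baseline_followup_corr, "baseline_followup_corr", 0, 1,
               open_upper = TRUE)
  check_scalar(deadline_s, "deadline_s", 0, Inf, open_lower = TRUE)
  for (nm in names(rl)) {
    if (length(rl[[nm]]) != 2 || any(!is.finite(rl[[nm]])))
      stop_field(paste0("rl$", nm), "must be c(mean, sd)")
    if (rl[[nm]][2] <= 0) stop_field(paste0("rl$", nm), "dispersion must be > 0")
  }
  for (nm in names(ddm)) {
    if (length(ddm[[nm]]) != 2 || any(!is.finite(ddm[[nm]])))
      stop_field(paste0("ddm$", nm), "must be c(mean, sd)")
    if (ddm[[nm]][2] <= 0) stop_field(paste0("ddm$", nm), "dispersion must be > 0")
  }
  if (length(group_shift) && is.null(names(group_shift)))
    stop_field("group_shift", "must be a named numeric vector")
  structure(list(n_active = as.integer(n_active),
                 n_placebo = as.integer(n_placebo),
                 rl = rl, ddm = ddm, v_condition_offset = v_condition_offset,
                 memory = memory, group_shift = group_shift,
                 baseline_followup_corr = baseline_followup_corr,
                 deadline_s = deadline_s, n_days = as.integer(n_days),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# transform registry for generative parameters
param_transform <- function(name) {
  switch(name,
         alpha_win = , alpha_loss = , z = list(fwd = qlogis, inv = plogis),
         rho_win = , rho_loss = , a = , ter = list(fwd = log, inv = exp),
         list(fwd = identity, inv = identity))
}

gng_conditions <- c("control", "positive", "aversive")

#' Sample a population of subjects with known ground-truth parameters
#'
#' Each subject's transformed parameter values at baseline and follow-up are
#' a bivariate normal with the spec's population mean, dispersion and
#' cross-visit correlation; active-group follow-up values then receive the
#' spec's additive `group_shift` on the transformed scale. DDM parameters
#' are shared across interference conditions up to the spec's fixed drift
#' offsets and any condition-restricted shift. Per-subject child seeds for
#' the task generators are drawn once from the root seed so downstream
#' streams do not depend on iteration order.
#'
#' @param spec a [cohort_spec]
#' @return data frame of class `subject_truth`, one row per subject, with
#'   `<param>_<visit>` columns (DDM: `<param>_<condition>_<visit>`)
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_active + spec$n_placebo
  r <- spec$baseline_followup_corr
  with_seed(spec$seed, {
    truth <- data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      group = rep(c("active", "placebo"), c(spec$n_active, spec$n_placebo)))
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * 5L), n, 5L)
    colnames(seeds) <- c("seed_pilt_baseline", "seed_pilt_followup",
                         "seed_gng_baseline", "seed_gng_followup", "seed_summary")
    truth <- cbind(truth, as.data.frame(seeds))
    active <- truth$group == "active"

    draw_pair <- function(mean_nat, sd_t, tf, shift = 0) {
      m <- tf$fwd(mean_nat)
      e1 <- rnorm(n); e2 <- rnorm(n)
      xb <- m + sd_t * e1
      xf <- m + sd_t * (r * e1 + sqrt(1 - r^2) * e2)
      xf[active] <- xf[active] + shift
      list(baseline = xb, followup = xf)
    }
    get_shift <- function(key) {
      s <- spec$group_shift[key]
      if (length(s) == 1 && !is.na(s)) unname(s) else 0
    }

    for (nm in names(spec$rl)) {
      tf <- param_transform(nm)
      pr <- draw_pair(spec$rl[[nm]][1], spec$rl[[nm]][2], tf, get_shift(nm))
      truth[[paste0(nm, "_baseline")]] <- tf$inv(pr$baseline)
      truth[[paste0(nm, "_followup")]] <- tf$inv(pr$followup)
    }

    for (nm in names(spec$ddm)) {
      tf <- param_transform(nm)
      pr <- draw_pair(spec$ddm[[nm]][1], spec$ddm[[nm]][2], tf, get_shift(nm))
      for (cond in gng_conditions) {
        off <- if (nm == "v") spec$v_condition_offset[[cond]] else 0
        csh <- get_shift(paste0(nm, "_", cond))
        xb <- pr$baseline + off
        xf <- pr$followup + off
        xf[active] <- xf[active] + csh
        truth[[paste0(nm, "_", cond, "_baseline")]] <- tf$inv(xb)
        truth[[paste0(nm, "_", cond, "_followup")]] <- tf$inv(xf)
      }
    }

    for (nm in c("nback_ability", "avlt_ability")) {
      pr <- draw_pair(0, spec$memory$ability_sd,
                      list(fwd = identity, inv = identity), get_shift(nm))
      truth[[paste0(nm, "_baseline")]] <- pr$baseline
      truth[[paste0(nm, "_followup")]] <- pr$followup
    }
    pr <- draw_pair(0, spec$memory$speed_sd,
                    list(fwd = identity, inv = identity), get_shift("nback_speed"))
    truth$nback_speed_baseline <- pr$baseline
    truth$nback_speed_followup <- pr$followup

    # stable person-level rating dispositions for the daily tables
    truth$vas_positive_level <- rnorm(n, 700, 80)
    truth$vas_negative_level <- pmax(rnorm(n, 160, 60), 0)
    truth$side_effect_level <- pmax(rnorm(n, 0.3, 0.15), 0)
    class(truth) <- c("subject_truth", "data.frame")
    truth
  })
}

# per-subject generative parameter accessors
truth_rl_params <- function(truth, i, visit) {
  rl_params(truth[[paste0("alpha_win_", visit)]][i],
            truth[[paste0("alpha_loss_", visit)]][i],
            truth[[paste0("rho_win_", visit)]][i],
            truth[[paste0("rho_loss_", visit)]][i])
}

truth_ddm_params <- function(truth, i, cond, visit) {
  g <- function(p) truth[[paste0(p, "_", cond, "_", visit)]][i]
  ddm_params(g("a"), g("z"), g("ter"), g("v"), g("dc"))
}

#' Generate probabilistic instrumental learning task trials for a cohort
#'
#' Per subject and visit: 3 blocks of 30 win + 30 loss trials with
#' reciprocal 70/30 outcome probabilities; choices are produced by the RL
#' agent under the subject's true parameters for that visit.
#'
#' @param truth a `subject_truth` data frame from [sample_population()]
#' @return trial table: subject, group, visit, block, trial, condition,
#'   choice, outcome, rt_ms
#' @export
generate_pilt <- function(truth) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (visit in c("baseline", "followup")) {
      sim <- with_seed(truth[[paste0("seed_pilt_", visit)]][i], {
        sched <- pilt_schedule()
        simulate_pilt_agent(truth_rl_params(truth, i, visit), sched)
      })
      sim$p_good <- NULL
      rows[[length(rows) + 1L]] <- data.frame(
        subject = truth$subject[i], group = truth$group[i], visit = visit,
        sim, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Generate affective go/no-go task trials for a cohort
#'
#' Per subject and visit: 6 blocks of 80 trials (two blocks per
#' interference condition, order randomised per visit), 80% go / 20% no-go,
#' with each trial's response and RT drawn from the subject's
#' condition-specific diffusion under a 400 ms deadline. Go-boundary
#' absorptions after the deadline are non-responses.
#'
#' @param truth a `subject_truth` data frame
#' @param deadline_s response deadline in seconds
#' @param dt Euler step for the trial sampler
#' @return trial table: subject, group, visit, block, condition, trial,
#'   trial_type, response, rt_ms, correct
#' @export
generate_gng <- function(truth, deadline_s = 0.4, dt = 0.001) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (visit in c("baseline", "followup")) {
      sim <- with_seed(truth[[paste0("seed_gng_", visit)]][i], {
        block_cond <- sample(rep(gng_conditions, 2))
        blocks <- lapply(seq_along(block_cond), function(b) {
          tt <- sample(rep(c("go", "nogo"), c(64, 16)))
          pars <- truth_ddm_params(truth, i, block_cond[b], visit)
          tr <- sample_gng_trials(pars, tt, deadline_s, dt)
          data.frame(block = b, condition = block_cond[b],
                     trial = seq_along(tt), tr)
        })
        do.call(rbind, blocks)
      })
      sim$correct <- (sim$trial_type == "go" & sim$response == "press") |
        (sim$trial_type == "nogo" & sim$response == "none")
      rows[[length(rows) + 1L]] <- data.frame(
        subject = truth$subject[i], group = truth$group[i], visit = visit,
        sim, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Generate summary-level memory-task and daily-rating tables
#'
#' N-back: loads 0-3, 4 blocks of 10 stimuli per load; accuracy counts are
#' binomial in the subject's load-specific success probability and correct
#' RTs log-normal around the load mean. Verbal list learning (AVLT-style):
#' 5 learning lists of 15 items, one distraction list, two delayed recalls,
#' binomial recall counts. Daily ratings: one row per subject, day and item,
#' rounded non-negative normals around person-level dispositions.
#'
#' @param truth a `subject_truth` data frame
#' @param spec the generating [cohort_spec] (task dimensions and means)
#' @return list with `outcomes` (subject, group, visit, condition, outcome,
#'   value) and `daily` (subject, group, day, item, value)
#' @export
generate_summary_outcomes <- function(truth, spec) {
  mem <- spec$memory
  out_rows <- list()
  daily_rows <- list()
  for (i in seq_len(nrow(truth))) {
    res <- with_seed(truth$seed_summary[i], {
      rows <- list()
      for (visit in c("baseline", "followup")) {
        abil <- truth[[paste0("nback_ability_", visit)]][i]
        speed <- truth[[paste0("nback_speed_", visit)]][i]
        for (load in 0:3) {
          p <- plogis(qlogis(mem$nback_acc[load + 1]) + abil)
          n_correct <- rbinom(1, 40, p)
          rt <- mean(rlnorm(max(n_correct, 1),
                            log(mem$nback_rt_ms[load + 1]) + speed, 0.12))
          lc <- paste0("load", load)
          rows[[length(rows) + 1L]] <- data.frame(
            visit = visit, condition = lc,
            outcome = c("nback_correct", "nback_rt"),
            value = c(n_correct, rt))
        }
        av <- truth[[paste0("avlt_ability_", visit)]][i]
        ps <- c(mem$avlt_learning, mem$avlt_distraction,
                mem$avlt_delayed, mem$avlt_delayed)
        labs <- c(paste0("learning", 1:5), "distraction",
                  "delayed1", "delayed2")
        counts <- rbinom(length(ps), 15, plogis(qlogis(ps) + av))
        rows[[length(rows) + 1L]] <- data.frame(
          visit = visit, condition = labs, outcome = "avlt_recall",
          value = counts)
      }
      items <- c(vas_positive = truth$vas_positive_level[i],
                 vas_negative = truth$vas_negative_level[i],
                 se_nausea = truth$side_effect_level[i],
                 se_insomnia = truth$side_effect_level[i],
                 se_appetite = truth$side_effect_level[i])
      isd <- c(60, 40, 0.4, 0.4, 0.4)
      dl <- do.call(rbind, lapply(seq_len(spec$n_days), function(d) {
        data.frame(day = d, item = names(items),
                   value = pmax(round(rnorm(length(items), items, isd), 1), 0))
      }))
      list(outcomes = do.call(rbind, rows), daily = dl)
    })
    out_rows[[i]] <- data.frame(subject = truth$subject[i],
                                group = truth$group[i], res$outcomes,
                                row.names = NULL)
    daily_rows[[i]] <- data.frame(subject = truth$subject[i],
                                  group = truth$group[i], res$daily,
                                  row.names = NULL)
  }
  list(outcomes = do.call(rbind, out_rows),
       daily = do.call(rbind, daily_rows))
}

#' Simulate a complete synthetic study cohort
#'
#' @param spec a [cohort_spec]
#' @param tasks character vector of tables to generate
#' @return list with elements truth, pilt, gng, outcomes, daily (those
#'   requested)
#' @export
simulate_cohort <- function(spec,
                            tasks = c("pilt", "gng", "summary")) {
  truth <- sample_population(spec)
  out <- list(truth = truth)
  if ("pilt" %in% tasks) out$pilt <- generate_pilt(truth)
  if ("gng" %in% tasks) out$gng <- generate_gng(truth, spec$deadline_s)
  if ("summary" %in% tasks) {
    so <- generate_summary_outcomes(truth, spec)
    out$outcomes <- so$outcomes
    out$daily <- so$daily
  }
  out
}

#' Write cohort tables as delimited text
#'
#' Comma-separated, header row, UTF-8, "NA" for missing values.
#'
#' @param cohort list from [simulate_cohort()]
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(cohort)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- cohort[[nm]]
    class(df) <- "data.frame"
    write.csv(df, p, row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read a cohort table written by [write_cohort()]
#' @param path file path
#' @return data frame
#' @export
read_trial_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
           fileEncoding = "UTF-8")
}
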