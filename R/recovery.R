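# true-vs-recovered Pearson correlations on each parameter's analysis
# (transformed) scale: logit for rates/start points, log for positive
# magnitudes, identity for drifts
recovery_cors <- function(tab, pnames) {
  vapply(pnames, function(nm) {
    tf <- param_transform(sub("^bias$", "a", nm))
    if (nm == "bias") tf <- list(fwd = log)
    cor(tf$fwd(tab[[paste0("true_", nm)]]), tf$fwd(tab[[paste0("est_", nm)]]))
  }, numeric(1))
}

#' Parameter-recovery study for the RL model
#'
#' Draws subject-level true parameters from the cohort population, simulates
#' each subject's full task (3 blocks, 180 trials), refits by maximum
#' likelihood and reports true-versus-recovered Pearson correlations on the
#' analysis (transformed) scale of each parameter.
#'
#' @param n_subjects number of simulated subjects
#' @param spec a [cohort_spec] providing the population
#' @param restarts optimiser restarts per fit
#' @param seed root seed
#' @param prior [pilt_prior()] used to stabilise the fits (NULL for plain
#'   maximum likelihood)
#' @return data frame with true_/est_ columns; attribute `correlations`
#'   holds the per-parameter Pearson correlations
#' @export
rl_recovery <- function(n_subjects = 200, spec = cohort_spec(),
                        restarts = 20, seed = 1L, prior = pilt_prior()) {
  seeds <- child_seeds(seed, 2L * n_subjects)
  pnames <- c("alpha_win", "alpha_loss", "rho_win", "rho_loss")
  rows <- lapply(seq_len(n_subjects), function(i) {
    true <- with_seed(seeds[i], {
      vals <- lapply(pnames, function(nm) {
        tf <- param_transform(nm)
        tf$inv(tf$fwd(spec$rl[[nm]][1]) + spec$rl[[nm]][2] * rnorm(1))
      })
      do.call(rl_params, setNames(vals, pnames))
    })
    trials <- with_seed(seeds[n_subjects + i],
                        simulate_pilt_agent(true, pilt_schedule()))
    fit <- fit_pilt_subject(trials, restarts = restarts, seed = seeds[i],
                            prior = prior)
    out <- c(setNames(unlist(true), paste0("true_", pnames)),
             setNames(unlist(fit$params), paste0("est_", pnames)))
    as.data.frame(as.list(out))
  })
  tab <- do.call(rbind, rows)
  attr(tab, "correlations") <- recovery_cors(tab, pnames)
  tab
}

#' Parameter-recovery study for the go/no-go DDM
#'
#' Draws subject-level true parameters from the cohort population, simulates
#' one fitting cell at the task's full trial count (480 trials, 80% go)
#' under the response deadline, refits by quantile G-squared and reports
#' true-versus-recovered Pearson correlations on each parameter's analysis
#' (transformed) scale. Besides the five parameters the
#' table carries the derived initial choice bias `z * a` (the quantity the
#' group contrasts are run on).
#'
#' @param n_subjects number of simulated subjects
#' @param spec a [cohort_spec]
#' @param n_trials trials per fitting cell (80% go)
#' @param restarts optimiser restarts per cell fit
#' @param seed root seed
#' @param prior [ddm_prior()] used to stabilise the fits (NULL for plain
#'   G-squared)
#' @return data frame with one row per subject; attribute `correlations`
#'   holds per-parameter correlations (including `bias`)
#' @export
ddm_recovery <- function(n_subjects = 100, spec = cohort_spec(),
                         n_trials = 480, restarts = 8, seed = 1L,
                         prior = ddm_prior()) {
  seeds <- child_seeds(seed, 2L * n_subjects)
  pnames <- c("a", "z", "ter", "v", "dc")
  n_go <- round(0.8 * n_trials)
  rows <- lapply(seq_len(n_subjects), function(i) {
    true <- with_seed(seeds[i], {
      tv <- vapply(pnames, function(nm) {
        tf <- param_transform(nm)
        tf$fwd(spec$ddm[[nm]][1]) + spec$ddm[[nm]][2] * rnorm(1)
      }, numeric(1))
      ddm_params(exp(tv["a"]), plogis(tv["z"]), exp(tv["ter"]),
                 tv["v"], tv["dc"])
    })
    trials <- with_seed(seeds[n_subjects + i], {
      tt <- sample(rep(c("go", "nogo"), c(n_go, n_trials - n_go)))
      sample_gng_trials(true, tt, spec$deadline_s)
    })
    fit <- fit_ddm_cell(trials, deadline_s = spec$deadline_s,
                        restarts = restarts, seed = seeds[i], prior = prior)
    data.frame(subject = i,
               as.list(setNames(unlist(true), paste0("true_", pnames))),
               true_bias = summarise_bias(true),
               as.list(setNames(unlist(fit$params), paste0("est_", pnames))),
               est_bias = summarise_bias(fit$params))
  })
  tab <- do.call(rbind, rows)
  attr(tab, "correlations") <- recovery_cors(tab, c(pnames, "bias"))
  tab
}

#' Sign recovery of an injected loss outcome-sensitivity group effect
#'
#' Repeatedly simulates full study cohorts with the spec's `rho_loss` shift,
#' fits the RL model to every subject-visit, runs the baseline-adjusted
#' ANCOVA on fitted `rho_loss`, and records whether the active-minus-placebo
#' contrast carries the injected sign.
#'
#' @param n_replicates cohort replicates
#' @param spec a [cohort_spec]; its `group_shift["rho_loss"]` must be nonzero
#' @param restarts optimiser restarts per subject fit
#' @param seed root seed
#' @return logical vector, one entry per replicate (contrast sign correct)
#' @export
rl_group_sign_recovery <- function(n_replicates = 10, spec = cohort_spec(),
                                   restarts = 6, seed = 1L) {
  shift <- spec$group_shift["rho_loss"]
  if (is.na(shift) || shift == 0)
    stop_field("spec", "group_shift must include a nonzero rho_loss entry")
  rep_seeds <- child_seeds(seed, n_replicates)
  vapply(seq_len(n_replicates), function(rix) {
    sp <- spec
    sp$seed <- rep_seeds[rix]
    truth <- sample_population(sp)
    trials <- generate_pilt(truth)
    fits <- fit_pilt(trials, restarts = restarts, seed = rep_seeds[rix],
                     prior = pilt_prior())
    tab <- data.frame(subject = rep(fits$subject, 1), group = fits$group,
                      visit = fits$visit, condition = "loss",
                      outcome = "rho_loss", value = fits$rho_loss)
    fit <- fit_baseline_ancova(tab, "rho_loss", transform = "log")
    ct <- emm_contrast(fit)
    sign(ct$estimate) == sign(shift)
  }, logical(1))
}

#' Sign recovery of an injected aversive-condition start-point group effect
#'
#' Repeatedly simulates cohorts with the spec's `z_aversive` shift, fits the
#' DDM to every subject-visit cell of the aversive condition, runs the
#' baseline-adjusted ANCOVA on the fitted start point (logit z, the
#' parameter the shift is injected on), and records whether the group
#' contrast carries the injected sign. The derived bias `z * a` inherits
#' boundary-separation estimation noise and is contrasted in the main
#' pipeline instead.
#'
#' @inheritParams rl_group_sign_recovery
#' @return logical vector, one entry per replicate
#' @export
ddm_group_sign_recovery <- function(n_replicates = 10, spec = cohort_spec(),
                                    restarts = 5, seed = 1L) {
  shift <- spec$group_shift["z_aversive"]
  if (is.na(shift) || shift == 0)
    stop_field("spec", "group_shift must include a nonzero z_aversive entry")
  rep_seeds <- child_seeds(seed, n_replicates)
  vapply(seq_len(n_replicates), function(rix) {
    sp <- spec
    sp$seed <- rep_seeds[rix]
    truth <- sample_population(sp)
    trials <- generate_gng(truth, sp$deadline_s)
    trials <- trials[trials$condition == "aversive", , drop = FALSE]
    fits <- fit_ddm(trials, deadline_s = sp$deadline_s, restarts = restarts,
                    seed = rep_seeds[rix], prior = ddm_prior())
    tab <- data.frame(subject = fits$subject, group = fits$group,
                      visit = fits$visit, condition = fits$condition,
                      outcome = "z_logit", value = qlogis(fits$z))
    fit <- fit_baseline_ancova(tab, "z_logit")
    ct <- emm_contrast(fit)
    sign(ct$estimate) == sign(shift)
  }, logical(1))
}

#' Run the full parameter-recovery study
#'
#' @param config list with optional entries n_rl, n_ddm, restarts_rl,
#'   restarts_ddm, spec, seed
#' @return list: rl (table + correlations), ddm (table + correlations)
#' @export
run_recovery <- function(config = list()) {
  spec <- config$spec %||% cohort_spec()
  seed <- config$seed %||% 1L
  n_rl <- config$n_rl %||% 200L
  n_ddm <- config$n_ddm %||% 100L
  if (n_rl < 1 || n_ddm < 1)
    stop_field("config", "subject counts must be >= 1")
  rl <- rl_recovery(n_rl, spec, restarts = config$restarts_rl %||% 20L,
                    seed = seed)
  ddm <- ddm_recovery(n_ddm, spec, restarts = config$restarts_ddm %||% 8L,
                      seed = seed + 1L)
  list(rl = list(table = rl, correlations = attr(rl, "correlations")),
       ddm = list(table = ddm, correlations = attr(ddm, "correlations")))
}
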