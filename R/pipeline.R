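#' Behavioural summaries of the probabilistic instrumental learning task
#'
#' Per subject-visit-condition: percentage of high-probability (optimal)
#' choices and mean response time.
#'
#' @param trials PILT trial table
#' @return long-format outcome table (subject, group, visit, condition,
#'   outcome, value)
#' @export
summarise_pilt <- function(trials) {
  oc <- optimal_choice_rate(trials)
  oc_long <- data.frame(oc[c("subject", "group", "visit", "condition")],
                        outcome = "optimal_choice", value = oc$optimal_pct)
  valid <- trials[!is.na(trials$rt_ms), , drop = FALSE]
  rt <- aggregate(list(value = valid$rt_ms),
                  valid[c("subject", "group", "visit", "condition")], mean)
  rt$outcome <- "pilt_rt"
  out <- rbind(oc_long, rt[names(oc_long)])
  out[order(out$subject, out$visit, out$condition, out$outcome), ]
}

#' Run the full study analysis pipeline on a synthetic cohort
#'
#' Simulate -> (optionally) fit the computational models -> summarise ->
#' baseline-adjusted group inference, writing delimited-text tables and a
#' plain-text log under `out_dir`. Every random stream derives from
#' `config$seed`.
#'
#' @param config list: `seed` (root seed), `out_dir` (optional output
#'   directory), `spec` (a [cohort_spec]; built from `seed` if absent),
#'   `fit_models` (fit RL and DDM parameters; default TRUE),
#'   `restarts_rl`, `restarts_ddm`, `transforms` (named character vector
#'   outcome -> "log" for outcomes analysed on the log scale)
#' @return (invisibly) list: cohort, summaries, fits, inference tables
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  spec <- config$spec %||% cohort_spec(seed = seed)
  fit_models <- config$fit_models %||% TRUE
  out_dir <- config$out_dir

  cohort <- simulate_cohort(spec)
  summaries <- rbind(summarise_pilt(cohort$pilt),
                     summarise_gng(cohort$gng))
  outcomes <- rbind(summaries, cohort$outcomes)

  fits <- list()
  if (fit_models) {
    fits$rl <- fit_pilt(cohort$pilt,
                        restarts = config$restarts_rl %||% 20L, seed = seed,
                        prior = config$rl_prior %||% pilt_prior())
    fits$ddm <- fit_ddm(cohort$gng, deadline_s = spec$deadline_s,
                        restarts = config$restarts_ddm %||% 8L, seed = seed,
                        prior = config$ddm_prior %||% ddm_prior())
    rl_long <- do.call(rbind, lapply(
      c("alpha_win", "alpha_loss", "rho_win", "rho_loss"), function(nm) {
        data.frame(subject = fits$rl$subject, group = fits$rl$group,
                   visit = fits$rl$visit,
                   condition = if (grepl("win", nm)) "win" else "loss",
                   outcome = nm, value = fits$rl[[nm]])
      }))
    ddm_long <- do.call(rbind, lapply(
      c("a", "z", "ter_s", "v", "dc", "bias"), function(nm) {
        data.frame(subject = fits$ddm$subject, group = fits$ddm$group,
                   visit = fits$ddm$visit, condition = fits$ddm$condition,
                   outcome = nm, value = fits$ddm[[nm]])
      }))
    outcomes <- rbind(outcomes, rl_long, ddm_long)
  }

  transforms <- config$transforms %||%
    c(rho_win = "log", rho_loss = "log", a = "log", ter_s = "log")
  infer_one <- function(nm) {
    tr <- if (!is.na(transforms[nm])) transforms[[nm]] else "identity"
    fit <- tryCatch(fit_baseline_ancova(outcomes, nm, transform = tr),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("inference skipped for '%s': %s", nm,
                      conditionMessage(fit)))
      return(NULL)
    }
    ct <- ancova_contrasts(fit)
    gf <- tryCatch(ancova_f_test(fit, "group"), error = function(e) NULL)
    cbind(outcome = nm, transform = tr, ct,
          group_F = gf$F %||% NA_real_, group_df1 = gf$df1 %||% NA_real_,
          group_df2 = gf$df2 %||% NA_real_, group_p = gf$p %||% NA_real_)
  }
  target_outcomes <- setdiff(unique(outcomes$outcome),
                             c("hit_rate", "fa_rate"))
  inference <- do.call(rbind, lapply(target_outcomes, infer_one))

  daily_items <- unique(cohort$daily$item)
  daily_res <- do.call(rbind, lapply(daily_items, function(it) {
    r <- longitudinal_lmm(cohort$daily, it)
    data.frame(item = it, estimate = r$estimate, lower = r$lower,
               upper = r$upper, t = r$t, p = r$p)
  }))

  result <- list(cohort = cohort, summaries = summaries, fits = fits,
                 inference = inference, daily = daily_res)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort[setdiff(names(cohort), "truth")],
                 file.path(out_dir, "tables"))
    write.csv(cohort$truth, file.path(out_dir, "tables", "truth.csv"),
              row.names = FALSE, na = "NA")
    write.csv(summaries, file.path(out_dir, "summaries.csv"),
              row.names = FALSE, na = "NA")
    if (fit_models) {
      write.csv(fits$rl, file.path(out_dir, "rl_params.csv"), row.names = FALSE)
      write.csv(fits$ddm, file.path(out_dir, "ddm_params.csv"), row.names = FALSE)
    }
    write.csv(inference, file.path(out_dir, "inference.csv"), row.names = FALSE)
    write.csv(daily_res, file.path(out_dir, "daily_lmm.csv"), row.names = FALSE)
    writeLines(c(sprintf("serocog %s", as.character(utils::packageVersion("serocog"))),
                 sprintf("seed: %d", seed),
                 sprintf("n_active: %d  n_placebo: %d", spec$n_active, spec$n_placebo),
                 sprintf("group_shift: %s",
                         paste(names(spec$group_shift), spec$group_shift,
                               sep = "=", collapse = ", ")),
                 sprintf("fit_models: %s", fit_models),
                 sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}
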