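#' Reinforcement-learning model for the probabilistic instrumental learning task
#'
#' The task presents two interleaved symbol pairs per block, one pair per
#' valence condition. In win trials the better symbol pays +1 with
#' probability 0.7 (else 0); in loss trials the better symbol avoids a -1
#' outcome with probability 0.7. The model learns a value expectation Q for
#' each symbol with a delta rule scaled by an outcome sensitivity, and
#' chooses between the pair's two symbols by a unit-temperature softmax:
#'
#'   Q <- Q + alpha * (rho * r - Q)
#'   p(choose c) = exp(Qc) / (exp(Qc) + exp(Qo))
#'
#' Learning rate `alpha` and outcome sensitivity `rho` are estimated
#' separately for win and loss trials. The softmax temperature is fixed at 1:
#' it is not jointly identifiable with `rho` in this parameterisation, so
#' `rho` carries the effective outcome magnitude.
#'
#' @param alpha_win,alpha_loss learning rates in (0, 1)
#' @param rho_win,rho_loss outcome sensitivities, > 0
#' @return an object of class `rl_params` (named list)
#' @export
rl_params <- function(alpha_win, alpha_loss, rho_win, rho_loss) {
  check_scalar(alpha_win, "alpha_win", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(alpha_loss, "alpha_loss", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(rho_win, "rho_win", 0, Inf, open_lower = TRUE)
  check_scalar(rho_loss, "rho_loss", 0, Inf, open_lower = TRUE)
  structure(list(alpha_win = alpha_win, alpha_loss = alpha_loss,
                 rho_win = rho_win, rho_loss = rho_loss),
            class = "rl_params")
}

#' Delta-rule value update for the chosen option
#'
#' @param q current value expectation of the chosen option
#' @param alpha learning rate in (0, 1]
#' @param rho outcome sensitivity, > 0
#' @param r observed outcome, one of -1, 0, +1
#' @return the updated value expectation `q + alpha * (rho * r - q)`
#' @export
q_update <- function(q, alpha, rho, r) {
  if (!is.numeric(q) || !all(is.finite(q))) stop_field("q", "must be finite")
  check_scalar(alpha, "alpha", 0, 1, open_lower = TRUE)
  check_scalar(rho, "rho", 0, Inf, open_lower = TRUE)
  if (!all(r %in% c(-1, 0, 1))) stop_field("r", "must be -1, 0 or +1")
  q + alpha * (rho * r - q)
}

#' Softmax choice probability over a symbol pair (unit temperature)
#'
#' @param q_chosen,q_other value expectations of the chosen and unchosen symbol
#' @return `exp(q_chosen) / (exp(q_chosen) + exp(q_other))`, evaluated stably
#' @export
choice_prob <- function(q_chosen, q_other) {
  if (!all(is.finite(q_chosen), is.finite(q_other)))
    stop_field("q", "Q values must be finite")
  plogis(q_chosen - q_other)
}

# validate and order a PILT trial table for one subject-visit
pilt_prepare_trials <- function(trials) {
  need <- c("block", "trial", "condition", "choice", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_field("trials", paste("missing columns:", paste(miss, collapse = ", ")))
  trials <- trials[order(trials$block, trials$trial), , drop = FALSE]
  if (!all(trials$condition %in% c("win", "loss")))
    stop_field("condition", "must be 'win' or 'loss'")
  ok_win <- trials$condition == "win" & trials$outcome %in% c(0, 1)
  ok_loss <- trials$condition == "loss" & trials$outcome %in% c(-1, 0)
  valid <- !is.na(trials$choice)
  if (!all((ok_win | ok_loss)[valid]))
    stop_field("outcome", "win outcomes must be {0,+1}, loss outcomes {-1,0}")
  trials
}

#' Negative log-likelihood of a PILT trial sequence
#'
#' Q values are initialised to 0 at the start of the visit and, by default,
#' carried across blocks (the symbol pairs persist across blocks within a
#' visit). Trials with a missing choice (timeouts) are excluded from the
#' likelihood; their count is returned as an attribute.
#'
#' @param params an [rl_params] object
#' @param trials data frame with columns block, trial, condition
#'   ("win"/"loss"), choice ("high"/"low", NA for missing) and outcome
#' @param reset_per_block reset Q to 0 at each block boundary
#' @return negative log-likelihood (scalar) with attribute `n_excluded`
#' @export
pilt_nll <- function(params, trials, reset_per_block = FALSE) {
  stopifnot(inherits(params, "rl_params"))
  trials <- pilt_prepare_trials(trials)
  if (nrow(trials) == 0L) stop_field("trials", "no trials supplied")
  valid <- !is.na(trials$choice)
  tr <- trials[valid, , drop = FALSE]
  if (nrow(tr) == 0L) stop_field("trials", "no valid (non-missing) trials")
  nll <- pilt_nll_core(
    cond = as.integer(tr$condition == "loss"),
    choice = as.integer(tr$choice == "high"),
    outcome = as.numeric(tr$outcome),
    block = as.integer(tr$block),
    alpha_win = params$alpha_win, alpha_loss = params$alpha_loss,
    rho_win = params$rho_win, rho_loss = params$rho_loss,
    reset_per_block = reset_per_block)
  structure(nll, n_excluded = sum(!valid))
}

#' Trial schedule for the probabilistic instrumental learning task
#'
#' 3 blocks of 30 win and 30 loss trials each (interleaved at random within
#' block); the better symbol of each pair leads to the favourable outcome
#' with probability `p_good` (0.7, reciprocal within the pair).
#'
#' @param n_blocks,n_per_type blocks and trials per trial type per block
#' @param p_good probability that the high-probability symbol yields the
#'   favourable outcome
#' @return data frame with columns block, trial, condition, p_good
#' @export
pilt_schedule <- function(n_blocks = 3, n_per_type = 30, p_good = 0.7) {
  blocks <- lapply(seq_len(n_blocks), function(b) {
    cond <- sample(rep(c("win", "loss"), each = n_per_type))
    data.frame(block = b, trial = seq_along(cond), condition = cond,
               p_good = p_good)
  })
  do.call(rbind, blocks)
}

#' Simulate a PILT agent over a schedule
#'
#' Choices are sampled from the softmax decision rule and Q values updated
#' by the delta rule, trial by trial. Outcomes follow the schedule's
#' reciprocal 70/30 probabilities: in win trials the favourable outcome is
#' +1 (else 0); in loss trials it is 0 (else -1).
#'
#' @param params an [rl_params] object
#' @param schedule output of [pilt_schedule()]
#' @param reset_per_block reset Q at block boundaries
#' @return the schedule with columns choice ("high"/"low"), outcome and rt_ms
#' @export
simulate_pilt_agent <- function(params, schedule, reset_per_block = FALSE) {
  stopifnot(inherits(params, "rl_params"))
  n <- nrow(schedule)
  Q <- c(wh = 0, wl = 0, lh = 0, ll = 0)
  choice <- character(n)
  outcome <- numeric(n)
  cur_block <- schedule$block[1]
  for (i in seq_len(n)) {
    if (reset_per_block && schedule$block[i] != cur_block) {
      Q[] <- 0
      cur_block <- schedule$block[i]
    }
    win <- schedule$condition[i] == "win"
    ih <- if (win) 1L else 3L
    p_high <- plogis(Q[ih] - Q[ih + 1L])
    ch_high <- runif(1) < p_high
    choice[i] <- if (ch_high) "high" else "low"
    p_fav <- if (ch_high) schedule$p_good[i] else 1 - schedule$p_good[i]
    fav <- runif(1) < p_fav
    outcome[i] <- if (win) as.numeric(fav) else -as.numeric(!fav)
    alpha <- if (win) params$alpha_win else params$alpha_loss
    rho <- if (win) params$rho_win else params$rho_loss
    ic <- ih + if (ch_high) 0L else 1L
    Q[ic] <- Q[ic] + alpha * (rho * outcome[i] - Q[ic])
  }
  schedule$choice <- choice
  schedule$outcome <- outcome
  schedule$rt_ms <- round(rlnorm(n, log(650), 0.25))
  schedule
}

#' Weakly-informative prior for boundary-stable RL fitting
#'
#' Quadratic penalties on the transformed parameter scale: logit learning
#' rates shrink toward 0 (alpha = 0.5) and log outcome sensitivities toward
#' `rho_log_mean` (default `exp(1) ~ 2.7`, the magnitude scale of outcome
#' sensitivities in this model family). Used to stabilise maximum-likelihood
#' fits against the learning-rate/outcome-sensitivity trade-off ridge; the
#' default fit remains unpenalised.
#'
#' @param alpha_logit_sd prior SD of logit learning rates
#' @param rho_log_mean,rho_log_sd prior mean and SD of log outcome
#'   sensitivities
#' @return list of class `pilt_prior`
#' @export
pilt_prior <- function(alpha_logit_sd = 1.0, rho_log_mean = 1.0,
                       rho_log_sd = 0.5) {
  structure(list(alpha_logit_sd = alpha_logit_sd,
                 rho_log_mean = rho_log_mean, rho_log_sd = rho_log_sd),
            class = "pilt_prior")
}

#' Maximum-likelihood fit of the RL model for one subject-visit
#'
#' Minimises the negative log-likelihood over transformed parameters
#' (logit alpha, log rho) with multi-restart quasi-Newton optimisation.
#' Restart start points are drawn uniformly on the transformed scale within
#' `[logit 0.05, logit 0.95]` for alphas and `[log 0.1, log 20]` for rhos;
#' ties are broken by lowest NLL then lowest restart index. Supplying a
#' [pilt_prior()] switches to maximum a posteriori estimation.
#'
#' @param trials PILT trial table for one subject-visit
#' @param restarts number of random restarts (default 20)
#' @param reset_per_block reset Q at block boundaries
#' @param min_trials minimum valid trials required per condition
#' @param seed optional seed making the restart draw reproducible
#' @param prior optional [pilt_prior()]; NULL fits by plain maximum
#'   likelihood
#' @return list of class `rl_fit`: params ([rl_params]), nll, convergence,
#'   restarts, best_restart, n_excluded, boundary flag
#' @export
fit_pilt_subject <- function(trials, restarts = 20, reset_per_block = FALSE,
                             min_trials = 30, seed = NULL, prior = NULL) {
  trials <- pilt_prepare_trials(trials)
  valid <- trials[!is.na(trials$choice), , drop = FALSE]
  n_win <- sum(valid$condition == "win")
  n_loss <- sum(valid$condition == "loss")
  if (n_win < min_trials || n_loss < min_trials)
    stop(sprintf("too few valid trials (win %d, loss %d; need >= %d per condition)",
                 n_win, n_loss, min_trials), call. = FALSE)
  cond <- as.integer(valid$condition == "loss")
  ch <- as.integer(valid$choice == "high")
  out <- as.numeric(valid$outcome)
  blk <- as.integer(valid$block)
  penalty <- if (is.null(prior)) function(theta) 0 else {
    stopifnot(inherits(prior, "pilt_prior"))
    function(theta)
      sum(theta[1:2]^2) / (2 * prior$alpha_logit_sd^2) +
      sum((theta[3:4] - prior$rho_log_mean)^2) / (2 * prior$rho_log_sd^2)
  }
  obj <- function(theta) {
    pilt_nll_core(cond, ch, out, blk,
                  plogis(theta[1]), plogis(theta[2]),
                  exp(theta[3]), exp(theta[4]), reset_per_block) +
      penalty(theta)
  }
  draw_starts <- function() cbind(
    runif(restarts, qlogis(0.05), qlogis(0.95)),
    runif(restarts, qlogis(0.05), qlogis(0.95)),
    runif(restarts, log(0.1), log(20)),
    runif(restarts, log(0.1), log(20)))
  starts <- if (is.null(seed)) draw_starts() else with_seed(seed, draw_starts())
  fits <- vector("list", restarts)
  for (k in seq_len(restarts)) {
    fits[[k]] <- tryCatch(
      optim(starts[k, ], obj, method = "L-BFGS-B",
            lower = c(-8, -8, log(1e-3), log(1e-3)),
            upper = c(8, 8, log(100), log(100)),
            control = list(maxit = 500)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all restarts failed in fit_pilt_subject", call. = FALSE)
  nlls <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
  best <- which.min(nlls)
  f <- fits[[best]]
  th <- f$par
  pars <- rl_params(plogis(th[1]), plogis(th[2]), exp(th[3]), exp(th[4]))
  at_boundary <- any(abs(th[1:2]) > 7.5) || any(th[3:4] < log(1e-3) + 0.05) ||
    any(th[3:4] > log(100) - 0.05)
  nll_pure <- obj(th) - penalty(th)
  structure(list(params = pars, nll = nll_pure, objective = f$value,
                 convergence = f$convergence == 0L,
                 restarts = restarts, best_restart = best,
                 n_excluded = nrow(trials) - nrow(valid),
                 at_boundary = at_boundary),
            class = "rl_fit")
}

#' Fit the RL model for every subject-visit in a cohort trial table
#'
#' @param trials full PILT trial table (columns subject, group, visit plus
#'   the per-trial schema)
#' @param ... passed to [fit_pilt_subject()]
#' @param seed root seed; per-fit restart seeds are derived from it
#' @return data frame, one row per subject-visit, with fitted parameters
#'   and diagnostics
#' @export
fit_pilt <- function(trials, ..., seed = 1L) {
  cells <- unique(trials[c("subject", "group", "visit")])
  seeds <- child_seeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- trials[trials$subject == cells$subject[i] &
                   trials$visit == cells$visit[i], , drop = FALSE]
    fit <- fit_pilt_subject(tr, seed = seeds[i], ...)
    data.frame(cells[i, , drop = FALSE],
               alpha_win = fit$params$alpha_win,
               alpha_loss = fit$params$alpha_loss,
               rho_win = fit$params$rho_win,
               rho_loss = fit$params$rho_loss,
               nll = fit$nll, converged = fit$convergence,
               at_boundary = fit$at_boundary,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Percentage of high-probability (optimal) choices per condition
#'
#' @param trials PILT trial table; may span subjects and visits
#' @return data frame with one row per subject-visit-condition and column
#'   `optimal_pct` = 100 * high-probability choices / valid trials (NA with
#'   a warning for empty cells)
#' @export
optimal_choice_rate <- function(trials) {
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  if (!nrow(trials)) {
    warning("no valid trials; returning empty summary")
    return(data.frame(subject = character(), visit = character(),
                      condition = character(), optimal_pct = numeric()))
  }
  key <- c(intersect(c("subject", "group", "visit"), names(trials)), "condition")
  agg <- aggregate(list(optimal_pct = trials$choice == "high"),
                   trials[key], function(x) 100 * mean(x))
  agg[do.call(order, agg[key]), , drop = FALSE]
}
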