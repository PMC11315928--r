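#' Drift-diffusion model parameters for the affective go/no-go task
#'
#' A Wiener diffusion between absorbing boundaries 0 (no-go) and `a` (go),
#' diffusion coefficient fixed at 1 (scaling convention). Evidence starts at
#' `z * a`; the reported initial choice bias is the product `z * a`.
#' Accumulation begins after non-decision time `ter` (seconds). The
#' effective drift is stimulus dependent: `v + dc` for go stimuli and
#' `-v + dc` for no-go stimuli, where `dc` is an evidence-independent drift
#' criterion.
#'
#' @param a boundary separation, > 0 (evidence units)
#' @param z relative start point in (0, 1)
#' @param ter non-decision time in seconds, >= 0
#' @param v drift rate (evidence/s)
#' @param dc drift criterion (evidence/s)
#' @return object of class `ddm_params`
#' @export
ddm_params <- function(a, z, ter, v, dc) {
  check_scalar(a, "a", 0, Inf, open_lower = TRUE)
  check_scalar(z, "z", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar(ter, "ter", 0, Inf)
  check_scalar(v, "v")
  check_scalar(dc, "dc")
  structure(list(a = a, z = z, ter = ter, v = v, dc = dc),
            class = "ddm_params")
}

#' Effective drift for a stimulus class
#' @noRd
ddm_effective_drift <- function(params, stimulus = c("go", "nogo")) {
  stimulus <- match.arg(stimulus)
  if (stimulus == "go") params$v + params$dc else -params$v + params$dc
}

#' Defective first-passage CDF of the go/no-go diffusion
#'
#' Probability mass absorbed at the named boundary by observed time `t`
#' (seconds, including non-decision time). Evaluated by the large-time
#' series expansion of the two-boundary Wiener first-passage distribution,
#' truncated when three consecutive terms fall below `tol`. Before `ter` the
#' mass is exactly 0; as `t` grows the upper and lower masses sum to 1.
#'
#' @param params a [ddm_params] object
#' @param t observed time(s) in seconds
#' @param boundary "upper" (go/press) or "lower" (no-go)
#' @param stimulus "go" or "nogo": selects the effective drift `v + dc` or
#'   `-v + dc`
#' @param tol series truncation tolerance
#' @return vector of absorbed probability masses
#' @export
fpt_defective_cdf <- function(params, t, boundary = c("upper", "lower"),
                              stimulus = c("go", "nogo"), tol = 1e-10) {
  stopifnot(inherits(params, "ddm_params"))
  boundary <- match.arg(boundary)
  stimulus <- match.arg(stimulus)
  if (!all(is.finite(t)) || any(t < 0)) stop_field("t", "must be finite and >= 0")
  mu <- ddm_effective_drift(params, stimulus)
  td <- pmax(t - params$ter, 0)
  wfpt_cdf_core(td, mu, params$a, params$z * params$a,
                upper = boundary == "upper", tol = tol, kmax = 100000L)
}

#' Sample go/no-go trials from the diffusion by Euler-Maruyama simulation
#'
#' Paths start at `z * a` and are integrated with step `dt`, with a
#' Brownian-bridge correction for boundary crossings inside a step. Upper
#' absorption with `ter + decision time <= deadline` is recorded as a press
#' with that RT; lower absorptions and paths unabsorbed at the deadline are
#' non-responses (observationally identical under the 400 ms deadline).
#'
#' @param params a [ddm_params] object
#' @param trial_type character vector, "go"/"nogo", one entry per trial
#' @param deadline_s response deadline in seconds
#' @param dt Euler step in seconds (default 0.001)
#' @return data frame with columns trial_type, response ("press"/"none"),
#'   rt_ms (NA unless press)
#' @export
sample_gng_trials <- function(params, trial_type, deadline_s = 0.4, dt = 0.001) {
  stopifnot(inherits(params, "ddm_params"))
  if (deadline_s <= params$ter)
    stop_field("deadline_s", "must exceed non-decision time")
  if (!all(trial_type %in% c("go", "nogo")))
    stop_field("trial_type", "entries must be 'go' or 'nogo'")
  tmax <- deadline_s - params$ter
  response <- character(length(trial_type))
  rt <- rep(NA_real_, length(trial_type))
  for (st in unique(trial_type)) {
    idx <- which(trial_type == st)
    mu <- ddm_effective_drift(params, st)
    sim <- ddm_sample_core(length(idx), params$a, params$z * params$a,
                           mu, dt, tmax)
    press <- sim$outcome == 1L
    response[idx] <- ifelse(press, "press", "none")
    rt[idx[press]] <- (params$ter + sim$dtime[press]) * 1000
  }
  data.frame(trial_type = trial_type, response = response, rt_ms = rt)
}

#' Quantile-bin observed go/no-go trials for G-squared fitting
#'
#' Press RTs in each trial-type cell are divided at their 10th/30th/50th/
#' 70th/90th percentiles (type-7 linear-interpolation quantiles) into 6 bins;
#' non-responses form a 7th bin. Cells with fewer than `min_press` presses
#' collapse to a median split (2 RT bins) and are flagged.
#'
#' @param trials data frame with trial_type, response, rt_ms for one
#'   subject-visit-condition cell
#' @param probs quantile probabilities for the bin boundaries
#' @param min_press minimum presses for the full quantile grid
#' @param min_rt_ms press RTs below this are treated as anticipations and
#'   dropped from the press bins (they remain excluded from counts)
#' @return list of class `gng_binset`: per trial type, the bin edges (ms),
#'   observed counts (press bins then no-press), n, and a `collapsed` flag
#' @export
bin_observed <- function(trials, probs = c(.1, .3, .5, .7, .9),
                         min_press = 10, min_rt_ms = 100) {
  out <- list()
  for (st in intersect(c("go", "nogo"), unique(trials$trial_type))) {
    cell <- trials[trials$trial_type == st, , drop = FALSE]
    anticip <- cell$response == "press" & !is.na(cell$rt_ms) &
      cell$rt_ms < min_rt_ms
    cell <- cell[!anticip, , drop = FALSE]
    rts <- cell$rt_ms[cell$response == "press"]
    n_press <- length(rts)
    n_none <- sum(cell$response == "none")
    collapsed <- n_press < min_press
    p_use <- if (collapsed) 0.5 else probs
    if (n_press >= 2) {
      edges <- as.numeric(quantile(rts, p_use, type = 7, names = FALSE))
      # discrete RTs can tie at quantile boundaries: merge duplicate edges
      edges <- unique(edges)
      counts <- as.vector(table(cut(rts, c(-Inf, edges, Inf), right = TRUE)))
    } else {
      edges <- numeric(0)
      counts <- n_press
    }
    out[[st]] <- list(edges_ms = edges, counts = c(counts, n_none),
                      n = n_press + n_none, n_press = n_press,
                      collapsed = collapsed)
  }
  structure(out, class = "gng_binset")
}

#' Expected bin probabilities under a DDM parameter set
#'
#' Press-RT bin probabilities are increments of the upper-boundary defective
#' CDF between the observed bin edges, with the deadline closing the last
#' press bin; the no-press bin receives all remaining mass (no-go decisions
#' plus deadline-censored paths).
#'
#' @param params a [ddm_params] object
#' @param binset a `gng_binset` from [bin_observed()]
#' @param deadline_s response deadline in seconds
#' @return list per trial type of probabilities aligned with the observed
#'   counts (summing to 1)
#' @export
ddm_expected_probs <- function(params, binset, deadline_s = 0.4) {
  stopifnot(inherits(binset, "gng_binset"))
  lapply_named <- function(nms, f) setNames(lapply(nms, f), nms)
  lapply_named(names(binset), function(st) {
    b <- binset[[st]]
    t_edges <- c(b$edges_ms / 1000, deadline_s)
    cdf <- fpt_defective_cdf(params, c(0, t_edges), boundary = "upper",
                             stimulus = st)
    press_p <- diff(cdf)
    c(press_p, 1 - cdf[length(cdf)])
  })
}

#' G-squared statistic over quantile bins
#'
#' `G2 = 2 * sum O * log(O / (N p))` over every bin of every trial-type
#' cell; zero observed counts contribute 0 and expected probabilities are
#' floored at 1e-10 inside the log.
#'
#' @param binset observed `gng_binset`
#' @param expected list of expected probability vectors as returned by
#'   [ddm_expected_probs()]
#' @return scalar G-squared
#' @export
gsquare <- function(binset, expected) {
  g2 <- 0
  for (st in names(binset)) {
    O <- binset[[st]]$counts
    p <- expected[[st]]
    if (length(O) != length(p))
      stop_field("expected", "probabilities not aligned with observed bins")
    if (abs(sum(p) - 1) > 1e-8)
      stop_field("expected", "probabilities must sum to 1")
    N <- sum(O)
    pos <- O > 0
    g2 <- g2 + 2 * sum(O[pos] * log(O[pos] / (N * pmax(p[pos], 1e-10))))
  }
  g2
}

#' Reported initial choice bias
#'
#' @param params a [ddm_params] object
#' @return the product `z * a`
#' @export
summarise_bias <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  params$z * params$a
}

# G2 objective on the transformed parameter scale. Works from precomputed
# per-trial-type edge times and counts so each evaluation costs two series
# calls; equivalent to gsquare(binset, ddm_expected_probs(...)).
ddm_g2_objective <- function(theta, cells, deadline_s) {
  a <- exp(theta[1]); z <- plogis(theta[2]); ter <- exp(theta[3])
  v <- theta[4]; dc <- theta[5]
  if (ter >= deadline_s) return(1e10)
  g2 <- 0
  for (cell in cells) {
    mu <- if (cell$go) v + dc else -v + dc
    td <- pmax(c(cell$t_edges, deadline_s) - ter, 0)
    cdf <- wfpt_cdf_core(td, mu, a, z * a, upper = TRUE,
                         tol = 1e-10, kmax = 100000L)
    p <- c(cdf[1], diff(cdf), 1 - cdf[length(cdf)])
    O <- cell$counts
    N <- cell$n
    pos <- O > 0
    g2 <- g2 + 2 * sum(O[pos] * log(O[pos] / (N * pmax(p[pos], 1e-10))))
  }
  g2
}

#' Weakly-informative prior for boundary-stable DDM fitting
#'
#' Quadratic penalties on the transformed parameter scale (log a, logit z,
#' log ter, v, dc), added to the G-squared objective (equivalent to maximum
#' a posteriori estimation, since G-squared is twice the multinomial
#' negative log-likelihood up to a constant). Breaks the boundary/start-
#' point/non-decision-time trade-off ridge that deadline censoring induces;
#' the default fit remains unpenalised.
#'
#' @param mu prior means on the transformed scale, order (log a, logit z,
#'   log ter, v, dc)
#' @param sd prior SDs on the transformed scale
#' @return list of class `ddm_prior`
#' @export
ddm_prior <- function(mu = c(log(1), qlogis(0.6), log(0.18), 2.5, 0.5),
                      sd = c(0.5, 1.0, 0.4, 3.0, 2.0)) {
  stopifnot(length(mu) == 5, length(sd) == 5, all(sd > 0))
  structure(list(mu = mu, sd = sd), class = "ddm_prior")
}

#' Fit the DDM to one subject-visit-condition cell by quantile G-squared
#'
#' Observed press-RT distributions (per trial type) are quantile-binned and
#' the five parameters minimise the G-squared discrepancy between observed
#' and model-expected bin counts, with the deadline-censored mass pooled
#' into the no-press bin. Optimisation runs on transformed scales (log a,
#' logit z, log ter, raw v and dc) from `restarts` random start points.
#'
#' @param trials one cell's trial table (both trial types)
#' @param deadline_s response deadline in seconds
#' @param restarts number of random restarts
#' @param seed optional seed for the restart draw
#' @param min_press passed to [bin_observed()]
#' @param prior optional [ddm_prior()]; NULL minimises plain G-squared
#' @return list of class `ddm_fit`: params, g2, convergence, best_restart,
#'   flags (collapsed cells, boundary estimates)
#' @export
fit_ddm_cell <- function(trials, deadline_s = 0.4, restarts = 8,
                         seed = NULL, min_press = 10, prior = NULL) {
  binset <- bin_observed(trials, min_press = min_press)
  if (!("go" %in% names(binset)) || !("nogo" %in% names(binset)))
    stop_field("trials", "cell must contain both go and no-go trials")
  cells <- lapply(names(binset), function(st) {
    b <- binset[[st]]
    list(go = st == "go", t_edges = b$edges_ms / 1000,
         counts = b$counts, n = b$n)
  })
  min_rt_s <- min(c(binset$go$edges_ms, binset$nogo$edges_ms,
                    deadline_s * 1000)) / 1000
  draw_starts <- function() cbind(
    runif(restarts, log(0.4), log(2.5)),
    runif(restarts, qlogis(0.2), qlogis(0.8)),
    runif(restarts, log(0.05), log(max(0.06, 0.95 * min_rt_s))),
    runif(restarts, 0, 6),
    runif(restarts, -2, 2))
  starts <- if (is.null(seed)) draw_starts() else with_seed(seed, draw_starts())
  lower <- c(log(0.1), -4, log(0.02), -2, -5)
  upper <- c(log(5), 4, log(deadline_s * 0.95), 10, 5)
  obj <- if (is.null(prior)) {
    function(theta) ddm_g2_objective(theta, cells, deadline_s)
  } else {
    stopifnot(inherits(prior, "ddm_prior"))
    function(theta) ddm_g2_objective(theta, cells, deadline_s) +
      sum(((theta - prior$mu) / prior$sd)^2)
  }
  fits <- vector("list", restarts)
  for (k in seq_len(restarts)) {
    fits[[k]] <- tryCatch(
      optim(starts[k, ], obj, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
  }
  g2s <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
  if (!any(is.finite(g2s)))
    stop("all restarts failed in fit_ddm_cell", call. = FALSE)
  best <- which.min(g2s)
  f <- fits[[best]]
  th <- f$par
  pars <- ddm_params(exp(th[1]), plogis(th[2]), exp(th[3]), th[4], th[5])
  g2_pure <- ddm_g2_objective(th, cells, deadline_s)
  flags <- character(0)
  if (any(vapply(binset, `[[`, logical(1), "collapsed")))
    flags <- c(flags, "collapsed_bins")
  if (abs(th[2]) > 3.5) flags <- c(flags, "z_at_boundary")
  at_box <- any(abs(th - lower) < 0.02) || any(abs(th - upper) < 0.02)
  if (at_box) flags <- c(flags, "box_boundary")
  structure(list(params = pars, g2 = g2_pure, objective = f$value,
                 convergence = f$convergence == 0L,
                 best_restart = best, restarts = restarts, flags = flags),
            class = "ddm_fit")
}

#' Fit the DDM for every subject-visit-condition cell in a cohort table
#'
#' @param trials full go/no-go trial table (columns subject, group, visit,
#'   condition plus the per-trial schema); the two blocks per condition are
#'   pooled
#' @param ... passed to [fit_ddm_cell()]
#' @param seed root seed for restart draws
#' @return data frame with one row per cell: fitted a, z, ter_s, v, dc,
#'   bias (`z * a`), g2 and flags
#' @export
fit_ddm <- function(trials, ..., seed = 1L) {
  cells <- unique(trials[c("subject", "group", "visit", "condition")])
  seeds <- child_seeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- trials[trials$subject == cells$subject[i] &
                   trials$visit == cells$visit[i] &
                   trials$condition == cells$condition[i], , drop = FALSE]
    fit <- fit_ddm_cell(tr, seed = seeds[i], ...)
    data.frame(cells[i, , drop = FALSE],
               a = fit$params$a, z = fit$params$z, ter_s = fit$params$ter,
               v = fit$params$v, dc = fit$params$dc,
               bias = summarise_bias(fit$params),
               g2 = fit$g2, converged = fit$convergence,
               flags = paste(fit$flags, collapse = ";"),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
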