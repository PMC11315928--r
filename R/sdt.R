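#' Hit and false-alarm rates for a go/no-go cell
#'
#' Hits are presses on go trials, false alarms presses on no-go trials.
#' Extreme rates (0 or 1) are corrected so that the inverse-normal indices
#' stay finite: by default 0 is replaced with `1/(2N)` and 1 with
#' `1 - 1/(2N)` per cell (N = trials of that type); the log-linear
#' alternative adds 0.5 to both counts and 1 to both denominators.
#' Response inhibition, `100 * (1 - raw fa_rate)`, uses the uncorrected
#' rate.
#'
#' @param trials trial table for one cell with trial_type and response
#' @param correction "half_trial" (default) or "loglinear"
#' @return list: hit_rate, fa_rate (corrected), hit_raw, fa_raw,
#'   inhibition_pct, n_go, n_nogo
#' @export
response_rates <- function(trials, correction = c("half_trial", "loglinear")) {
  correction <- match.arg(correction)
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  nogo <- trials[trials$trial_type == "nogo", , drop = FALSE]
  if (nrow(go) == 0L || nrow(nogo) == 0L)
    stop("cell must contain at least one go and one no-go trial", call. = FALSE)
  n_go <- nrow(go); n_nogo <- nrow(nogo)
  hits <- sum(go$response == "press")
  fas <- sum(nogo$response == "press")
  hit_raw <- hits / n_go
  fa_raw <- fas / n_nogo
  if (correction == "half_trial") {
    fix <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
    hit <- fix(hit_raw, n_go)
    fa <- fix(fa_raw, n_nogo)
  } else {
    hit <- (hits + 0.5) / (n_go + 1)
    fa <- (fas + 0.5) / (n_nogo + 1)
  }
  list(hit_rate = hit, fa_rate = fa, hit_raw = hit_raw, fa_raw = fa_raw,
       inhibition_pct = 100 * (1 - fa_raw), n_go = n_go, n_nogo = n_nogo)
}

#' Signal-detection sensitivity d'
#'
#' @param hit_rate,fa_rate rates strictly inside (0, 1) (pre-corrected)
#' @return `qnorm(hit_rate) - qnorm(fa_rate)`
#' @export
d_prime <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1 | fa_rate <= 0 | fa_rate >= 1))
    stop("rates must lie strictly inside (0, 1); apply an extreme-rate correction first",
         call. = FALSE)
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' Signal-detection criterion c
#'
#' `c = -(qnorm(hit) + qnorm(fa)) / 2`. Larger c means fewer presses, i.e.
#' more conservative responding.
#'
#' @inheritParams d_prime
#' @return criterion c
#' @export
criterion_c <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1 | fa_rate <= 0 | fa_rate >= 1))
    stop("rates must lie strictly inside (0, 1); apply an extreme-rate correction first",
         call. = FALSE)
  -(qnorm(hit_rate) + qnorm(fa_rate)) / 2
}

#' Behavioural and signal-detection summaries of a go/no-go trial table
#'
#' Per subject-visit-condition (the two blocks per condition pooled):
#' response inhibition %, go accuracy %, mean correct-go RT (ms), hit and
#' false-alarm rates, d' and criterion c.
#'
#' @param trials full go/no-go trial table
#' @param correction extreme-rate correction passed to [response_rates()]
#' @return long-format outcome table: subject, group, visit, condition,
#'   outcome, value
#' @export
summarise_gng <- function(trials, correction = "half_trial") {
  cells <- unique(trials[c("subject", "group", "visit", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    tr <- trials[trials$subject == cells$subject[i] &
                   trials$visit == cells$visit[i] &
                   trials$condition == cells$condition[i], , drop = FALSE]
    rr <- response_rates(tr, correction)
    go_rt <- tr$rt_ms[tr$trial_type == "go" & tr$response == "press"]
    mean_rt <- if (length(go_rt)) mean(go_rt) else {
      warning(sprintf("no correct go responses for subject %s %s %s",
                      cells$subject[i], cells$visit[i], cells$condition[i]))
      NA_real_
    }
    vals <- c(response_inhibition = rr$inhibition_pct,
              go_accuracy = 100 * rr$hit_raw,
              go_rt = mean_rt,
              hit_rate = rr$hit_rate, fa_rate = rr$fa_rate,
              d_prime = d_prime(rr$hit_rate, rr$fa_rate),
              criterion_c = criterion_c(rr$hit_rate, rr$fa_rate))
    data.frame(cells[i, , drop = FALSE], outcome = names(vals),
               value = unname(vals), row.names = NULL)
  })
  do.call(rbind, rows)
}
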