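#' Baseline-adjusted (mixed) ANCOVA for a study outcome
#'
#' Models follow-up values with the subject's baseline value as a covariate
#' to isolate the group effect. With more than one condition row per
#' subject the model is `followup ~ group * condition + baseline` with a
#' random intercept per subject, fitted by REML ([nlme::lme]) with sum
#' contrasts and containment-style denominator degrees of freedom; with a
#' single condition it reduces to an ordinary least-squares ANCOVA
#' (`followup ~ group + baseline`). Outcomes flagged for transformation are
#' analysed on the log scale.
#'
#' @param table long-format outcome table: subject, group, visit
#'   ("baseline"/"followup"), condition, outcome, value
#' @param outcome name of the outcome to analyse
#' @param transform "identity" or "log" (applied to the values before
#'   modelling; recorded in the result)
#' @return object of class `ancova_fit`: model, data (one row per subject
#'   by condition with baseline and followup columns), anova table, type
#'   ("lm"/"lme"), transform, group sizes
#' @export
fit_baseline_ancova <- function(table, outcome,
                                transform = c("identity", "log")) {
  transform <- match.arg(transform)
  tab <- table[table$outcome == outcome, , drop = FALSE]
  if (!nrow(tab)) stop(sprintf("outcome '%s' not present", outcome), call. = FALSE)
  if (transform == "log") {
    if (any(tab$value <= 0, na.rm = TRUE))
      stop("log transform requested but values are not strictly positive",
           call. = FALSE)
    tab$value <- log(tab$value)
  }
  base <- tab[tab$visit == "baseline", c("subject", "condition", "value")]
  names(base)[3] <- "baseline"
  foll <- tab[tab$visit == "followup",
              c("subject", "group", "condition", "value")]
  names(foll)[4] <- "followup"
  dat <- merge(foll, base, by = c("subject", "condition"))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (!nrow(dat))
    stop("no follow-up rows with matched baseline values", call. = FALSE)
  n_dropped <- nrow(foll) - nrow(dat)
  if (n_dropped > 0)
    warning(sprintf("%d follow-up rows without matched baseline excluded",
                    n_dropped))
  dat$group <- factor(dat$group, levels = c("active", "placebo"))
  if (any(table(dat$group[!duplicated(dat$subject)]) < 2))
    stop("need at least 2 subjects per group", call. = FALSE)
  dat$condition <- factor(dat$condition)
  dat$subject <- factor(dat$subject)
  multi <- nlevels(dat$condition) > 1L
  if (multi) {
    model <- nlme::lme(
      followup ~ group * condition + baseline,
      random = ~ 1 | subject, data = dat, method = "REML",
      contrasts = list(group = "contr.sum", condition = "contr.sum"))
    atab <- anova(model, type = "marginal")
  } else {
    model <- lm(followup ~ group + baseline, data = dat,
                contrasts = list(group = "contr.sum"))
    atab <- anova(lm(followup ~ baseline + group, data = dat))
  }
  ns <- table(dat$group[!duplicated(dat$subject)])
  structure(list(model = model, data = dat, anova = atab,
                 type = if (multi) "lme" else "lm",
                 transform = transform, outcome = outcome,
                 n_active = unname(ns["active"]),
                 n_placebo = unname(ns["placebo"])),
            class = "ancova_fit")
}

#' F test for a term of a baseline-adjusted ANCOVA
#'
#' @param fit an `ancova_fit`
#' @param term row name in the model's ANOVA table (e.g. "group",
#'   "group:condition")
#' @return list: F, df1, df2, p
#' @export
ancova_f_test <- function(fit, term = "group") {
  stopifnot(inherits(fit, "ancova_fit"))
  atab <- fit$anova
  if (!(term %in% rownames(atab)))
    stop(sprintf("term '%s' not in the model (have: %s)", term,
                 paste(rownames(atab), collapse = ", ")), call. = FALSE)
  if (fit$type == "lme") {
    list(F = atab[term, "F-value"], df1 = atab[term, "numDF"],
         df2 = atab[term, "denDF"], p = atab[term, "p-value"])
  } else {
    list(F = atab[term, "F value"], df1 = atab[term, "Df"],
         df2 = atab["Residuals", "Df"], p = atab[term, "Pr(>F)"])
  }
}

#' Estimated-marginal-mean group contrast (active minus placebo)
#'
#' The marginal means are evaluated at the mean of the baseline covariate.
#' With `condition = NULL` and a multi-condition model the contrast is
#' returned for every condition; `scope = "overall"` averages over
#' conditions first (the "all conditions" contrast of the study reports).
#' P values are unadjusted; use [holm_adjust()] or [ancova_contrasts()].
#'
#' @param fit an `ancova_fit`
#' @param condition optional condition label to restrict to
#' @param scope "by_condition" or "overall"
#' @return data frame: condition, estimate, se, df, t, p
#' @export
emm_contrast <- function(fit, condition = NULL,
                         scope = c("by_condition", "overall")) {
  stopifnot(inherits(fit, "ancova_fit"))
  scope <- match.arg(scope)
  multi <- fit$type == "lme"
  if (scope == "overall" || !multi) {
    em <- emmeans::emmeans(fit$model, ~ group, data = fit$data)
    ct <- summary(emmeans::contrast(em, "pairwise"), infer = c(FALSE, TRUE))
    res <- data.frame(condition = "overall", estimate = ct$estimate,
                      se = ct$SE, df = ct$df, t = ct$t.ratio,
                      p = ct$p.value)
  } else {
    em <- emmeans::emmeans(fit$model, ~ group | condition, data = fit$data)
    ct <- summary(emmeans::contrast(em, "pairwise", by = "condition"),
                  infer = c(FALSE, TRUE))
    res <- data.frame(condition = as.character(ct$condition),
                      estimate = ct$estimate, se = ct$SE, df = ct$df,
                      t = ct$t.ratio, p = ct$p.value)
  }
  if (!is.null(condition)) {
    if (!(condition %in% res$condition))
      stop(sprintf("condition '%s' not in the model", condition), call. = FALSE)
    res <- res[res$condition == condition, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Planned contrast table with Holm correction and effect sizes
#'
#' Runs the per-condition EMM contrasts of an ANCOVA fit, Holm-adjusts the
#' p values across conditions, and attaches Cohen's d with its 95% CI. The
#' d calculation counts the observations entering each contrast: subjects
#' per group for per-condition contrasts, subjects times conditions for the
#' pooled "overall" contrast.
#'
#' @param fit an `ancova_fit`
#' @param include_overall also include the pooled-across-conditions contrast
#'   (not part of the Holm family)
#' @return data frame: condition, estimate, se, t, df, p, p_holm, n1, n2,
#'   d, d_lo, d_hi
#' @export
ancova_contrasts <- function(fit, include_overall = TRUE) {
  percond <- emm_contrast(fit)
  percond$p_holm <- holm_adjust(percond$p)
  k <- if (fit$type == "lme") nlevels(fit$data$condition) else 1L
  add_d <- function(df, mult) {
    n1 <- fit$n_active * mult
    n2 <- fit$n_placebo * mult
    ds <- t(mapply(function(e, s) unlist(cohens_d_from_emm(e, s, n1, n2)),
                   df$estimate, df$se))
    df$n1 <- n1; df$n2 <- n2
    df$d <- ds[, "d"]; df$d_lo <- ds[, "lower"]; df$d_hi <- ds[, "upper"]
    df
  }
  percond <- add_d(percond, 1L)
  if (include_overall && fit$type == "lme") {
    ov <- emm_contrast(fit, scope = "overall")
    ov$p_holm <- ov$p
    ov <- add_d(ov, k)
    percond <- rbind(percond, ov)
  }
  rownames(percond) <- NULL
  percond
}

#' Holm (step-down Bonferroni) adjustment of p values
#'
#' @param p vector of p values in \[0, 1\]
#' @return adjusted p values (monotone, capped at 1)
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_field("p", "p values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Cohen's d from an EMM contrast estimate and its standard error
#'
#' `d = (estimate / SE) * sqrt(1/n1 + 1/n2)`, where n1 and n2 count the
#' observations entering the contrast. The 95% CI is
#' `d +/- 1.96 * sqrt((n1+n2)/(n1*n2) + d^2 / (2*(n1+n2)))`.
#'
#' @param estimate EMM contrast estimate
#' @param se its standard error (> 0)
#' @param n1,n2 observation counts per group in the contrast (>= 2)
#' @param conf confidence level
#' @return list: d, lower, upper
#' @export
cohens_d_from_emm <- function(estimate, se, n1, n2, conf = 0.95) {
  if (!is.numeric(se) || se <= 0) stop_field("se", "must be > 0")
  if (n1 < 2 || n2 < 2) stop_field("n1/n2", "must be >= 2")
  d <- (estimate / se) * sqrt(1 / n1 + 1 / n2)
  zc <- qnorm(1 - (1 - conf) / 2)
  sd_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(d = d, lower = d - zc * sd_d, upper = d + zc * sd_d)
}

#' Hedges' g: small-sample-corrected Cohen's d
#'
#' Applies the correction factor `1 - 3 / (4*(n1+n2) - 9)` to
#' [cohens_d_from_emm()].
#'
#' @inheritParams cohens_d_from_emm
#' @return list: g, lower, upper
#' @export
hedges_g_from_emm <- function(estimate, se, n1, n2, conf = 0.95) {
  d <- cohens_d_from_emm(estimate, se, n1, n2, conf)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  list(g = d$d * J, lower = d$lower * J, upper = d$upper * J)
}

#' Partial eta-squared from an F statistic, with confidence interval
#'
#' `eta_p^2 = F*df1 / (F*df1 + df2)`. The CI inverts the noncentral-F
#' distribution for the noncentrality parameter (lower bound floored at 0)
#' and maps it through `lambda / (lambda + df1 + df2 + 1)`.
#'
#' @param f observed F statistic (>= 0)
#' @param df1,df2 numerator and denominator degrees of freedom
#' @param conf confidence level
#' @return list: eta_sq, lower, upper
#' @export
partial_eta_sq <- function(f, df1, df2, conf = 0.95) {
  if (!is.numeric(f) || f < 0) stop_field("f", "must be >= 0")
  if (df1 < 1 || df2 < 1) stop_field("df", "degrees of freedom must be >= 1")
  eta <- f * df1 / (f * df1 + df2)
  alpha <- 1 - conf
  ncp_bound <- function(target) {
    # largest lambda with P(F(df1,df2,lambda) <= f) >= target is the root
    g <- function(l) pf(f, df1, df2, ncp = l) - target
    if (g(0) < 0) return(0)
    hi <- 1
    while (g(hi) > 0 && hi < 1e7) hi <- hi * 2
    uniroot(g, c(0, hi))$root
  }
  lo <- ncp_bound(1 - alpha / 2)
  hi <- ncp_bound(alpha / 2)
  to_eta <- function(l) l / (l + df1 + df2 + 1)
  list(eta_sq = eta, lower = max(to_eta(lo), 0), upper = to_eta(hi))
}

#' Longitudinal mixed model for daily ratings
#'
#' `value ~ group + day` with a random intercept per subject, REML. Returns
#' the time-adjusted main effect of group (active minus placebo coding via
#' treatment contrasts on levels active, placebo means the reported
#' estimate is placebo-relative; the sign convention used here is
#' active minus placebo).
#'
#' @param daily data frame: subject, group, day, item, value
#' @param item rating item to model
#' @param conf confidence level for the group-effect CI
#' @return list: estimate, lower, upper, t, p, model
#' @export
longitudinal_lmm <- function(daily, item, conf = 0.95) {
  dat <- daily[daily$item == item, , drop = FALSE]
  if (!nrow(dat)) stop(sprintf("item '%s' not present", item), call. = FALSE)
  if (length(unique(dat$day)) < 2L)
    stop("only one time point: use the baseline-adjusted ANCOVA path",
         call. = FALSE)
  dat$group <- factor(dat$group, levels = c("placebo", "active"))
  dat$subject <- factor(dat$subject)
  model <- nlme::lme(value ~ group + day, random = ~ 1 | subject,
                     data = dat, method = "REML")
  tt <- summary(model)$tTable
  est <- tt["groupactive", "Value"]
  se <- tt["groupactive", "Std.Error"]
  df <- tt["groupactive", "DF"]
  zc <- qt_safe(conf, df)
  list(estimate = est, lower = est - zc * se, upper = est + zc * se,
       t = tt["groupactive", "t-value"], p = tt["groupactive", "p-value"],
       model = model)
}

qt_safe <- function(conf, df) stats::qt(1 - (1 - conf) / 2, df)

#' Pearson chi-square test of independence
#'
#' @param tab contingency table or matrix of non-negative integer counts
#' @param correct apply Yates continuity correction (default FALSE)
#' @return list: chisq, df, p
#' @export
chisq_independence <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_field("tab", "counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_field("tab", "margins must be positive")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
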