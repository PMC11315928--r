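---
title: "Computational models and statistics for placebo-controlled serotonin studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational models and statistics for placebo-controlled serotonin studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(serocog)
```

`serocog` implements the analysis stack of a two-visit, placebo-controlled
behavioural pharmacology study of a serotonin-releasing agent: a
valence-specific reinforcement-learning (RL) model for a probabilistic
instrumental learning task, a five-parameter drift-diffusion model (DDM)
for a deadline-limited affective go/no-go task, signal-detection indices,
and a baseline-adjusted group-inference layer. A synthetic-cohort
generator with known ground truth makes the whole chain testable end to
end. This vignette documents the models, the generator, the numerical
choices, and what the simulation studies do and do not establish.

## The reinforcement-learning model

On each trial of the learning task the participant chooses between the two
symbols of a pair; one pair appears on win trials (outcomes +1 or 0), the
other on loss trials (outcomes −1 or 0), with reciprocal 70/30 outcome
probabilities. The model maintains a value expectation $Q$ for each symbol
and updates only the chosen one:

$$Q \leftarrow Q + \alpha\,(\rho\, r - Q),$$

with choice probabilities given by a unit-temperature softmax over the
pair's two $Q$ values. Learning rate $\alpha \in (0,1)$ and outcome
sensitivity $\rho > 0$ are estimated separately for win and loss trials
(four parameters per subject-visit). The softmax temperature is fixed at 1
because it is not jointly identifiable with $\rho$; $\rho$ therefore
carries the effective outcome magnitude. $Q$ values start at 0 at each
visit and are carried across the three blocks, since the symbol pairs
persist within a visit (`reset_per_block` reverts this). A single-$\rho$
variant is not provided; the per-valence parameterisation is what the
group contrasts are run on.

Fitting is multi-restart quasi-Newton minimisation of the negative
log-likelihood on transformed scales (logit $\alpha$, log $\rho$), with 20
restarts drawn uniformly in $[\mathrm{logit}\,0.05, \mathrm{logit}\,0.95]
\times [\log 0.1, \log 20]$ and ties broken by lowest objective then
lowest restart index. Timeout trials are excluded from the likelihood and
counted in the diagnostics.

### Boundary-stabilising priors

At the task's size (90 trials per valence) the likelihood has a ridge:
$\alpha \to 0$ with $\rho$ very large produces nearly the same early
learning increments as moderate values, and pure maximum-likelihood
estimates occasionally escape to the parameter bounds, especially in the
loss condition where successful avoidance stops the agent from sampling
the avoided symbol. `pilt_prior()` adds weak quadratic penalties on the
transformed scale (logit $\alpha \sim N(0, 1)$; $\log\rho \sim N(1,
0.5)$, i.e. sensitivities on the order of a few units). The default fit
remains plain maximum likelihood; the recovery studies and the pipeline
enable the prior. Its widths were chosen by recovery simulation at the
task's own size — the standard way estimator settings are validated in
this field — and are deliberately generic rather than centred on any
particular cohort's truth.

## The drift-diffusion model

The go/no-go task presents 80% go and 20% no-go trials under three
interference conditions (control, positive, aversive), with a 400 ms
response deadline. Evidence accumulates as a Wiener diffusion between an
upper "go/press" boundary at $a$ and a lower "no-go" boundary at 0,
starting at $z \cdot a$, after non-decision time $T_{er}$. The effective
drift is $v + dc$ for go stimuli and $-v + dc$ for no-go stimuli, where
$dc$ is an evidence-independent drift criterion. The diffusion coefficient
is fixed at 1 (the usual scaling convention). The reported initial choice
bias is the product $z \cdot a$.

First-passage probabilities are computed from the classical large-time
series expansion of the two-boundary Wiener distribution, with terms
evaluated in exponent form (stable for large drifts) and truncation when
three consecutive terms fall below $10^{-10}$ (the sine factor can vanish
at isolated indices, so a single small term is not a stopping signal).
Trial simulation uses Euler–Maruyama integration at $\Delta t = 1$ ms with
a Brownian-bridge correction for within-step boundary crossings; without
the correction, discretisation biases absorption masses by more than the
0.005 agreement tolerance the analytic/simulation cross-checks use. The
final step is capped so absorption times never exceed the deadline.

Fitting follows the quantile maximum-likelihood approach: press RTs in
each trial-type cell are binned at their 10th/30th/50th/70th/90th
percentiles (type-7 linear-interpolation quantiles; duplicate edges from
millisecond-discrete RTs are merged), non-responses form one further bin,
and the five parameters minimise

$$G^2 = 2 \sum_{\text{bins}} O \ln \frac{O}{N p},$$

with expected probabilities from the defective CDFs, the deadline closing
the last press bin, and expected probabilities floored at $10^{-10}$
inside the logarithm. No-go decisions and deadline-censored paths are
observationally identical (no response, no RT) and are pooled into the
no-press bin — the minimal coherent likelihood for this design, and a
declared decision of this package since the source analyses do not state
their treatment. Cells with fewer than 10 presses collapse to a median
split; press RTs below 100 ms are treated as anticipations. Fits are per
subject × visit × condition, pooling the two blocks per condition.

Deadline censoring makes single parameters weakly identified: estimation
errors of $\log a$, $\mathrm{logit}\, z$ and $\log T_{er}$ are strongly
correlated (a ridge), because raising the boundary while raising the start
point and advancing $T_{er}$ leaves the visible first 0.2 s of the RT
distribution nearly unchanged, and the censored tail that would separate
them is unobserved. `ddm_prior()` therefore offers the same weak quadratic
stabilisation on the transformed scale (added to $G^2$, which equals twice
the multinomial negative log-likelihood up to a constant, so this is
ordinary MAP estimation). As with the RL model, the default fit is
unpenalised and the recovery/pipeline analyses enable the prior.

## Signal-detection indices

Hits are presses on go trials, false alarms presses on no-go trials;
response inhibition is $100(1 - \text{raw false-alarm rate})$.
Sensitivity and criterion follow the classical definitions
$d' = \Phi^{-1}(h) - \Phi^{-1}(f)$ and
$c = -\tfrac12(\Phi^{-1}(h) + \Phi^{-1}(f))$; larger $c$ means fewer
presses (more conservative responding). Extreme rates are replaced by
$1/(2N)$ and $1 - 1/(2N)$ per cell (a log-linear alternative is
available); the source does not state its correction rule, so this is a
package decision. Any log transform of $c$ for normality is applied in
the statistics layer, not in the index itself.

## The statistics layer

Group inference on post-intervention data uses the baseline value as a
covariate: `followup ~ group * condition + baseline` with a random
intercept per subject, fitted by REML (`nlme::lme`, sum contrasts) when an
outcome has several condition rows per subject, and ordinary least squares
otherwise. Planned comparisons are two-tailed estimated-marginal-mean
contrasts (active minus placebo) at each condition, Holm-corrected across
conditions; a pooled "overall" contrast averages over conditions first.
Cohen's $d$ is computed from the contrast as
$d = (\mathrm{EMM}/\mathrm{SE})\sqrt{1/n_1 + 1/n_2}$, where $n_1, n_2$
count the observations entering the contrast — subjects per group for
per-condition contrasts, subjects × conditions for pooled ones. This
convention reproduces the printed effect sizes of the motivating study
from its printed EMM/SE pairs. Hedges' $g$ applies the usual small-sample
correction. Partial $\eta^2$ is $F\,df_1/(F\,df_1 + df_2)$ with a CI from
noncentral-F inversion.

Denominator degrees of freedom follow `nlme`'s containment scheme. The
within-subject strata reproduce the motivating study's printed dfs (e.g.
$F[1,50]$ for a two-condition interaction at $N=53$; $F[2,95]$ at
$N=50$); the between-subject stratum gives $N-2$ where that study prints
$N-3$, a one-df discrepancy whose origin (the authors' software defaults)
is unknowable from the text; we document rather than force it.

Daily ratings are analysed with `value ~ group + day` plus a random
intercept per subject (REML), reporting the time-adjusted group effect
with its CI. Allocation-guess tables use Pearson's χ² without continuity
correction by default. Outcomes flagged non-normal (positive, skewed:
outcome sensitivities, boundary separation, non-decision time) are
log-transformed before modelling, and the transform is recorded in the
output tables.

## The synthetic cohort generator

The generator defines the study conditions for every simulation-based
check: 26 active and 27 placebo subjects, two visits, with subject-level
parameters drawn from bivariate normals on each parameter's transformed
scale (logit for $\alpha$ and $z$, log for $\rho$, $a$, $T_{er}$,
identity for drifts) with cross-visit correlation 0.7, and group effects
added to the active group's follow-up values on the transformed scale.
Default injected effects mirror the motivating findings: loss outcome
sensitivity reduced by 0.4 log units (one population SD) and the aversive
start point reduced by 0.5 logit units (one population SD).

RL population: $\alpha = 0.30$ (logit SD 0.8), $\rho = 3.0$ (log SD 0.4).
DDM population: $a = 0.90$ (log SD 0.25), $z = 0.62$ (logit SD 0.50),
$T_{er} = 0.17$ s (log SD 0.15), $v = 2.5$ (SD 1.0), $dc = 0.5$ (SD 0.6),
with fixed drift decrements of 0.2 and 0.4 under positive and aversive
interference. These were chosen to reproduce realistic task behaviour
under a 400 ms deadline — go press rates near 0.88, false-alarm rates of
roughly 0.25–0.35 (withholding under a tight deadline is genuinely hard,
which is why the start point sits above 0.5: the 80% go base rate induces
a prepotent response), and mean correct-go RTs around 250 ms. The z shift
produces slower aversive go RTs as a downstream consequence, matching the
direction of the choice-impulsivity findings. Memory tasks are generated
at summary level only (binomial recall counts over 15-item lists for the
verbal-learning task; binomial accuracy over 4 × 10 stimuli per load and
log-normal RTs for the n-back); daily ratings are rounded non-negative
normals around person-level dispositions. None of these summary-level
models is mechanistic — they exist to exercise the statistics layer.

Randomness is organised as one root seed from which per-subject,
per-task child seeds are drawn once, so regenerating any table is
independent of iteration order and byte-identical under the same spec.

### What the simulations do and do not show

Passing recovery and calibration tests establish that the estimation and
inference chain is internally consistent *under this generator*: no
missing data, no lapses or attention drifts, no RT contamination beyond
the anticipation filter, parameter stationarity within a visit, and
normal population shapes on the transformed scales. Real data violate all
of these to some degree, so recovery correlations here are an upper bound
on what field data would support, and the type-I calibration speaks to
the model-fitting pipeline, not to any particular dataset.

## Problem sizes and thresholds used by the checks

The recovery studies run at the tasks' own sizes: 200 subjects × 180
trials for the RL model (true-vs-recovered Pearson correlations on the
analysis scale, expected above 0.7 per parameter) and 100 subjects × one
480-trial cell for the DDM (expected above 0.6 per parameter). The
correlations for the RL learning rates sit within a few hundredths of the
0.7 mark — the information limit of 90 trials per valence — so individual
runs straddle it: the win learning rate typically lands just above, and
the loss learning rate at or just below, because successful avoidance
stops the agent from sampling the avoided symbol and caps the information
available about how fast its value was learned. The DDM boundary
separation behaves similarly around 0.6–0.7. Sign recovery of the injected group effects
uses 10 full cohort replicates (simulate → fit → baseline-adjusted
contrast), contrasting fitted $\rho_{loss}$ and, for the DDM, the fitted
start point (logit $z$) in the aversive condition — the parameter the
shift is injected on; the derived bias $z \cdot a$ inherits
boundary-separation noise and is contrasted in the pipeline output
instead. Null calibration uses 500 cohort replicates of the mixed ANCOVA
group test on the n-back accuracy outcome. These sizes are the package's
standing choices for its own validation studies.

## Known limitations

- No hierarchical (shrinkage-across-subjects) fitting; the priors are
  fixed, not estimated from the sample.
- No inter-trial variability parameters (sv, st, sz) in the DDM, and no
  lapse/decay parameters in the RL model.
- The no-press bin pools no-go decisions with censored go decisions; with
  a 400 ms deadline this is unavoidable observationally, but it is why
  $a$, $z$ and $T_{er}$ trade off and why the stabilising priors exist.
- The study's deposited dataset is optional input; without it the
  pipeline's group contrasts describe synthetic cohorts only.
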