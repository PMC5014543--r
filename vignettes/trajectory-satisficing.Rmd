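---
title: "Identifying survey satisficers from response-speed trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying survey satisficers from response-speed trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajsat)
library(dplyr)
```

## Motivation and model

Participants in long-running cohorts answer near-identical questionnaires
every visit, and some learn to race through them. Because single-survey
satisficing indicators (straightlining, attention checks, fixed latency
thresholds) ignore the longitudinal dimension, `trajsat` instead asks
whether a participant's *response speed trajectory* accelerates over recent
visits.

The observable is per-visit response speed

$$y_{it} = N_{it} / T_{it} \quad \text{(words per second)},$$

where $N_{it}$ is the word count of the variables participant $i$ responded
to at visit $t$ and $T_{it}$ the survey duration in seconds from the
recorded start/end timestamps. Coded time maps the first scheduled visit to
$t = 0$ (here visits 50–58 map to 0–8); this is the single time convention
used throughout the package.

Speeds are modelled with a group-based trajectory model (GBTM): a finite
mixture in which each latent group $j$ follows a polynomial mean trajectory

$$y_{it} \mid (i \in j) \sim
  \mathcal{N}\!\left(\textstyle\sum_{m=0}^{p} \beta_{jm} t^{m},\, \sigma^2\right),$$

with mixing proportions $\pi_j$ and, by default, one shared residual SD. The
per-participant likelihood is the mixture over groups of the product of
normal densities across that participant's observed visits, so unbalanced
panels (missed visits) need no special handling. We use a plain normal
outcome density rather than the censored normal of the classic SAS
implementation: response speeds here are strictly positive and uncensored,
so censoring would add parameters without changing the fit.

### Estimation and model selection

Estimation is by EM with multiple restarts. The first initialisation is
deterministic — participants are ranked by mean speed and split into $K$
quantile blocks — and later restarts perturb the ranking with seeded noise,
so a fixed seed gives a fully reproducible fit. The M-step is weighted
polynomial least squares per group, responsibility means for $\pi$, and a
pooled weighted residual SD; convergence is declared when the relative
log-likelihood change falls below `tol` (default 1e-8, capped at 500
iterations). Mixing proportions are floored at 1e-6; a floored component is
reported via the `collapsed` flag rather than silently dropped. Fitted
groups are relabelled by ascending intercept so reported labels are
deterministic, and the log-likelihood sequence of the winning start is kept
on the object so EM monotonicity can be verified.

$K$ is selected by the Bayesian information criterion in the trajectory
modelling convention, $\mathrm{BIC} = \log L - \tfrac{1}{2} k \ln n$ with
$n$ the number of participants, under which the best model has the largest
(least negative) BIC. Because the literature is ambiguous about whether $n$
should count participants or observations, the observation-count variant is
available behind a flag (`gbtm_bic(model, "observations")`); ties in the
selection go to the smaller $K$.

### Two-step classification

The classifier mirrors how trajectory solutions are read in practice, but
replaces the visual judgement "speed increased over recent visits" with an
explicit rule. For each fitted group we evaluate the trajectory on the
integer time grid and compute the end derivative
$\mu_j'(t_{\max})$ and the trailing rise
$\mu_j(t_{\max}) - \min_{t \in \text{last } w+1 \text{ visits}} \mu_j(t)$.
A group is *recently increasing* when the end derivative is positive **and**
the trailing rise exceeds $\delta = \texttt{margin} \cdot \hat\sigma$. A
group whose net change $\mu_j(t_{\max}) - \mu_j(0)$ falls below $-\delta$
and that is not a recent riser is *overall decreasing* — this is what
excludes a group that rose early and declined since, even though part of its
curve increases.

Defaults: `window = 2` (the last three visits enter the rise), `margin =
0.1` residual SDs. There is no field-standard numeric threshold separating a
"nearly constant" from a "slightly rising" trajectory, so the margin is this
package's operational choice; `reclassify()` re-derives labels from the
stored fits under other margins without refitting, and raising the margin
can only shrink the satisficer set.

Step 1 fits the whole cohort over `k_range` (default 1–5 at both steps) and
hard-assigns participants by maximum posterior (ties to the lowest group
index). Step 2 refits each recently-increasing group on its own members and
labels the members of its recently-increasing subgroups as satisficers. All
candidates are processed, not just the first. A candidate group smaller than
`10 * max(k_range_step2)` participants is labelled satisficer wholesale with
a warning: mixture fits on tiny groups are unstable, and a group already
flagged as rising is better taken as-is than refitted unreliably.

### Association models

Satisficer status (constant within participant) is related to covariates
with a marginal logistic model for repeated measures: generalized estimating
equations with an exchangeable working correlation and robust sandwich
standard errors clustered by participant. No GEE solver dependency is used;
the exchangeable structure has a closed-form inverse, so the scoring update
and the sandwich are computed in a handful of vectorised cross-products.
Baseline age enters as $(\text{age} - \bar{\text{age}})/10$, so its OR is
per 10-year increase (centering does not affect it); reference levels are
race = white, education = college, HIV = negative, sexual activity = none,
drug use = none. Wald 95% CIs and two-sided p-values are reported without
multiplicity adjustment, and rows with missing covariates are dropped
listwise with a message.

Two numerical notes. First, when the outcome is constant within participant
the moment estimator of the working correlation tends to 1; it is capped at
0.95. Any working correlation leaves the coefficient estimates consistent
and the sandwich variance valid, but a near-unit exchangeable correlation
down-weights between-participant contrasts, so coefficients of covariates
that vary *within* participant (sexual activity, drug use) are estimated
mainly from within-participant information and are attenuated when the
outcome cannot vary within a participant. This is inherent to the marginal
model, not an implementation artefact; cluster-level covariate effects are
unaffected. Second, `or_from_2x2()` provides the crude Woolf odds ratio
(with the Haldane–Anscombe 0.5 correction for zero cells) as an independent
oracle: with one visit per participant the GEE reduces to ordinary logistic
regression and must reproduce it, which the tests assert to 1e-4.

## What the synthetic cohorts emulate

`synth_config()` defaults encode the study conditions the pipeline is meant
for: 2138 participants over 9 semiannual visits; three latent speed groups
near 2, 4 and 6 words/s with shares 37.84/49.01/13.14% — a slow group flat
early and rising late (the satisficer reservoir), a middle group declining
then flat, and a fast group rising early but declining overall; residual SD
0.5 words/s; about 23% of scheduled visits unattended; record corruption at
rates 14/14722, 1887/14722 and 34/14722 for missing start, missing end and
illogical times, applied by *without-replacement quota sampling* so fixtures
reproduce exclusion arithmetic exactly; and a word-count drop of 225 around
a base of 1500 from coded time 6 onward, mimicking a questionnaire shortened
by roughly 30 questions. Durations are derived as $T = N/(\mu_j(t) +
\varepsilon)$ with $\varepsilon \sim \mathcal{N}(0, \sigma)$ resampled on
the rare non-positive draws, so observed speed recovers $\mu_j(t) +
\varepsilon$ exactly and, with $\sigma = 0$, the planted trajectory to
machine precision.

Free choices the data do not pin down, made once and documented here: word
counts are Poisson around the base (the real instrument's word count arises
from skip logic, which is out of scope — the analysis only consumes $N$ and
$T$); baseline age is normal (mean 51.5, SD 9, clamped to 20–90), roughly
matching a median of 51 with IQR 45–58; visit-level behavioural categories
repeat a participant-level latent category with probability 0.8 and are
redrawn otherwise. Covariate effects on satisficer-group membership are
specified as log-odds tilts in a multinomial logit; with a single satisficer
group this collapses to an exactly logistic marginal model, so planted
effects are recoverable on the log-OR scale by the GEE stage. The default
tilt is zero, which keeps the group shares exactly at `true_pi`.

What the generator does **not** emulate: question-level latencies, skip
logic and its effect on word counts, panel attrition that depends on speed,
drift in interview hardware, or measurement error in the timestamps beyond
the three corruption modes. Passing tests therefore show that the method
recovers structure *of the planted kind* under realistic sizes and noise —
not that real cohorts contain such structure.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: the mixture
log-likelihood against an explicit loop-based summation on 3-participant
instances (1e-9); $K = 1$ EM against ordinary polynomial least squares
(1e-6); posterior rows against direct summation and symmetry cases; the
cleaning report against hand-built records and exact corruption quotas
(a 14,722-record fixture leaves exactly 12,787); reported percentages
against half-up two-decimal arithmetic (543/2138 → 25.40); the GEE against
`glm()` and the crude 2×2 OR in the one-visit case and against the reference
clustered sandwich estimator.

Statistical guarantees are checked at sizes chosen to keep the full suite
under a few minutes while leaving comfortable margins: BIC selects the
planted $K = 3$ (groups at 2/4/6 words/s, $\sigma = 0.3$, $n = 600$) in at
least 80% of 20 seeded replicates; a planted accelerating subpopulation (15%
prevalence, ≥3σ separation, $n = 2000$) is recovered with sensitivity and
specificity ≥ 0.9; null simulations give 90–99% CI coverage of OR = 1 over
200 replicates; and a planted log-OR of 0.8 is recovered within ±0.15 at
$n = 2000$.

## Known limitations

- The recency margin δ is an operational stand-in for a visual judgement;
  sensitivity to it should be reported (`reclassify()` makes this cheap).
- BIC selection among mixtures with well-separated flat groups is easy; with
  genuinely overlapping trajectories the selected $K$ — and hence who is
  labelled — can be unstable across seeds.
- Exchangeable-GEE attenuation of within-participant covariate effects when
  the outcome is participant-constant (discussed above).
- Speeds are treated as conditionally normal; with very small word counts
  the ratio N/T is discrete and skewed, which the model ignores.
- The classifier labels whole subgroups: an individual's idiosyncratic
  acceleration inside a non-rising group is not detected.
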