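---
title: "A response-time-based mixture model for careless and insufficient effort responding"
author: "carelessRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A response-time-based mixture model for careless and insufficient effort responding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carelessRT)
```

## The problem

Careless and insufficient effort responding (C/IER) — answering questionnaire
items without regard to their content — contaminates survey data in ways that
range from added noise to systematically distorted trait correlations and
factor structures. C/IER takes many shapes: uniform random responding,
random alternation between the extreme response options, straight lining,
and diagonal lining. Indicator-based screens (long string index, even–odd
consistency, Mahalanobis distance, response-time thresholds) each detect only
some of these shapes and require cutoffs whose choice drives the outcome.

`carelessRT` implements a model-based alternative: a latent response mixture
model in which every respondent–screen unit is, with some probability,
generated by an *attentive* process (responses reflect the trait, response
times reflect speed and item time intensity) or by a *C/IER* process
(content-free category choices, short content-free response times).
Identification comes almost entirely from response times, which makes the
approach agnostic about the specific C/IER response pattern.

## The item-level model

Respondents $i = 1,\dots,N$ answer $J_s$ ordinal items ($x_{ijs} \in
\{0,\dots,K\}$) on screens $s = 1,\dots,S$; one screen measures one trait.
A binary latent state $\Delta_{is}$ says whether the unit was answered
attentively.

**Attentive responses** follow a generalized partial credit model (GPCM)
with discrimination $v_{js}$ and step difficulties $b_{js1..K}$:
$$
p(x_{ijs}=k \mid \Delta_{is}=1) =
\frac{\exp \sum_{l=0}^{k} (v_{js}\eta_{is} - b_{jsl})}
     {\sum_{r=0}^{K}\exp \sum_{l=0}^{r} (v_{js}\eta_{is} - b_{jsl})},
\qquad \sum_{l=0}^{0}(\cdot) \equiv 0 .
$$

**Attentive response times** are lognormal with
$$
\ln t_{ijs} \mid \Delta_{is}=1 \sim
\mathcal N\!\big(\beta_{js} - \tau_i - \gamma\,
|v_{js}\eta_{is} - o_{js}|,\ \sigma_A^2\big),
$$
where $\tau_i$ is the respondent's speed, $o_{js}$ the item's middle step
difficulty, and $\gamma$ the distance–difficulty coefficient: items far from
the respondent's trait level are endorsed (or rejected) faster, by the factor
$e^{-\gamma}$ per unit of absolute weighted distance. For an odd number of
steps $o_{js}$ is the middle step (for four response categories, $b_{js2}$);
for an even number we take the mean of the two central steps, which reduces
to the same rule.

**C/IER responses** are content-free: category probabilities $\kappa_k$
shared by all items and persons (the marginal over whatever mixture of
C/IER patterns is present — the model detects the patterns collectively but
does not label them), and
$$
\ln t_{ijs} \mid \Delta_{is}=0 \sim \mathcal N(\beta_C,\ \sigma_C^2),
\qquad
\beta_{js} = \beta_C + \beta^*_{js},\ \ \beta^*_{js} \ge 0 ,
$$
so attentive responding is never faster *in expectation* than C/IER on the
same item, while the two RT distributions may overlap freely.

**Attentiveness** follows a Rasch model,
$P(\Delta_{is}=1) = \operatorname{logistic}(\psi_i - \iota_s)$, with
respondent attentiveness $\psi_i$ and screen attentiveness difficulty
$\iota_s$. Person parameters $(\psi_i, \tau_i, \eta_{i1},\dots,\eta_{iS})$
are multivariate normal with zero means; trait variances are fixed at one
for identification. The likelihood of a respondent–screen unit is the
two-component mixture with $\Delta_{is}$ marginalized; missing responses and
missing RTs enter through indicators and contribute a factor of one.

## The screen-level variant

When only aggregated timing is available, the mean time per item
$\bar t_{is}$ replaces the item-level RTs, and the model simplifies: the
respondent is either attentive on *all* screens or careless on all of them,
with a respondent-specific probability $\pi_i$ that is constant across
screens and distinct from the traits. The attentive timing model uses a
screen-level time intensity $\beta_s = \beta_C + \beta^*_s$ and the
screen aggregates $v_{\cdot s}$ (geometric mean of discriminations) and
$o_{\cdot s}$ (arithmetic mean of middle step difficulties). $\psi$ is
dropped from the person-parameter distribution. The mixture is at the person
level: $\pi_i$ multiplies the product of attentive factors over all screens
against the product of C/IER factors.

Which aggregate feeds $\bar t_{is}$ is the caller's choice
(`timing_measure`): the plain mean of item RTs, total screen time per item
(TT/J), TTFRT, or AAT — see `compute_timing_measures()`.

## Priors and estimation

Priors follow the originating modeling tradition: LKJ(1) on the
person-parameter correlation matrix (uniform over positive-definite
correlation matrices), half-Cauchy(0, 5) on all standard deviations and on
discriminations, Normal(0, 10) on step difficulties, $\beta^*$, $\gamma$,
$\beta_C$ and $\iota_s$, Dirichlet(1) on $\kappa$. In the screen-level
variant, $(\pi_i, 1-\pi_i) \sim \mathrm{Dir}(\lambda \pi_P, \lambda(1-\pi_P))$
with $(\pi_P, 1-\pi_P) \sim \mathrm{Dir}(1,1)$ and
$\lambda \sim$ half-Cauchy(0, 5). The prior for $\iota_s$ is our reading of
"diffuse normal priors" for location-type fixed effects.

Estimation is by an adaptive Metropolis-within-Gibbs sampler written in
C++, with the discrete $\Delta$ marginalized analytically (posterior
state probabilities are recovered per draw from the component
responsibilities). Because random-walk updates carry more autocorrelation
than the gradient-based samplers often used for such models, each recorded
iteration comprises `thin` full update sweeps (default 10), and the sampler
adds dedicated moves for the model's weakly identified directions:

* a joint shift of all $\psi_i$ and all $\iota_s$ (the likelihood depends on
  $\psi - \iota$ only);
* a joint rescaling of $\psi$ with $\sigma_\psi$, with $\iota$ adjusted to
  hold the implied marginal C/IER rate approximately fixed (the
  attentiveness variance and the screen difficulties form a ridge);
* shifts of $\beta_C$ against the non-negative offsets $\beta^*$ (all
  attentive time intensities fixed) and against all speeds $\tau_i$
  (attentive RT means fixed);
* interweaved (non-centered) updates of the $\psi$-correlations that move
  the imputed $\psi_i$ together with the correlation, holding the
  standardized residuals fixed;
* an independence refresh of $\psi_i$ from its conditional prior, which is
  near-global for the many respondents whose data carry little
  attentiveness information.

Ridge-type moves use a heavy-tailed (two-component normal) proposal so that
occasional large jumps can cross flat stretches of the posterior. Proposal
scales adapt by Robbins–Monro during warmup only. Convergence is assessed by
the split potential scale reduction factor (`psrf()`), with the conventional
1.10 threshold; `fit_cier()` warns when any parameter exceeds it.

`iterations` counts recorded iterations including warmup (the first half by
default), mirroring common practice of running four chains of 4,000
iterations with the first half as warmup.

## Classification and C/IER rates

`classify_attentiveness()` returns posterior C/IER probabilities — per
person–screen for the item-level variant (the posterior mean of the C/IER
component responsibility), per person for the screen-level variant.
`cier_rate()` reports the posterior-mean rate: per screen, and overall with
screens weighted by their item counts (a response-level rate). A hard
classification count is available through its `threshold` argument; the
posterior-mean definition is the default because fractional responsibilities
are the model's native output and avoid an arbitrary cutoff. A fully missing
person–screen reproduces its prior: its posterior C/IER probability equals
the posterior mean of $1-\operatorname{logistic}(\psi_i - \iota_s)$.

`marginal_cier_rate()` maps a screen difficulty $\iota$ and attentiveness
SD $\sigma_\psi$ to the population-level C/IER probability of that screen by
Gauss–Hermite quadrature (64 nodes); `iota_for_rate()` inverts it, and is
how the simulator chooses $\iota$ for a target rate.

## The synthetic-data generator

`simulate_cier_data()` draws from exactly the item-level model above, plus
plumbing that makes screen-level timing measures derivable. Defaults are
the study conditions used throughout the package's tests: $N = 300$
respondents, two screens of 7 and 5 four-point items ($K = 3$), a 5%
marginal C/IER rate, and global parameters resembling the estimates of the
motivating large-scale questionnaire analysis — attentiveness variance
1.98, speed variance 0.11, trait correlation .43, small positive
correlations of attentiveness with the traits (.24, .17), $\gamma = 0.04$,
$\beta_C = 0.74$, $\sigma_C^2 = 0.78$. Two values those analyses do not
print were fixed once here: the attentive residual SD $\sigma_A = 0.5$
(log-seconds; chosen so that total log-RT spread, combining speed variance,
the distance term and the residual, matches the reported overall RT
quartiles), and the time-intensity offsets of the middle items of each
screen, interpolated linearly between the printed first and last pairs
(screen 1: 0.46, 0.68, …, 0.13, 0.00; screen 2: 0.04, 0.24, …, 0.51, 0.29).

C/IER units draw one of four patterns (equal mix by default): uniform
random over $0..K$; endpoint random over $\{0, K\}$; straight line (one
uniformly drawn category repeated); diagonal line (uniform start,
incremented by one per item, wrapping modulo $K+1$; a descending option
exists). The pattern is drawn per C/IE person–screen — the weaker
assumption; `pattern_per_person = TRUE` fixes it per respondent. C/IER RTs
are iid lognormal$(\beta_C, \sigma_C)$ regardless of pattern. A per-screen
stem-reading time (lognormal, default median 8 s) is generated so TT and
FRT are well defined; it is plumbing, not part of the response model.

What the generator does **not** emulate: reconstruction of item RTs from
time-stamped log events (items are answered in presentation order, so AAT's
"first answered item" is simply the first item), respondent-varying speed
trajectories, attentiveness switching *within* a screen, and C/IER that
partially reflects the trait. Passing tests therefore show that the
estimator recovers the generating process under these idealized conditions,
not that it is robust to violations of them on real data.

## Timing measures and trimming

From item RTs plus reading time, `compute_timing_measures()` returns per
person–screen: TT (reading plus all item RTs), FRT (reading plus the first
item RT), TT/J, TTFRT $=(\mathrm{TT}-\mathrm{FRT})/(J-1)$, and AAT (mean of
item RTs excluding the first answered item, mirroring that the first item's
RT cannot be separated from stem reading when RTs are reconstructed from
logs). On complete data TTFRT and AAT coincide; both are undefined for
single-item screens. `trim_rts()` sets RTs above a threshold (default 90 s)
to missing; trimming applies to item RTs, AAT and TTFRT but never to TT,
and every exclusion is counted and reported.

## Indicator-based screening

`long_string()` (longest constant run; missing entries break runs),
`even_odd()` (correlation between odd-half and even-half scale scores
across scales — the one-sentence textbook definition is ambiguous; we use
half scores and return missing when either half has no variance across
scales), `mahalanobis_flags()` (squared distances vs. a $\chi^2$ quantile,
listwise deletion with counts reported), and `multiple_hurdle()` — the
sequential screen: RT threshold (on AAT by default), then long string,
then Mahalanobis distance recomputed on the survivors, so each flagged
respondent is attributed to exactly one hurdle. The conservative preset
uses 1 s, a run spanning all items, and the .99 quantile; the liberal
preset 2 s, per-scale run thresholds (default $\lceil 0.7 J_s \rceil$,
i.e. 5 of 7 and 4 of 5), and the .95 quantile.

## Numerical choices

All mixtures are computed in log space via log-sum-exp; the logistic and
its logarithm are evaluated branch-wise so $P(\Delta = 1)$ is stable for
large $|\psi - \iota|$. C/IER screen factors use sufficient statistics
(category counts, $\sum \ln t$, $\sum (\ln t)^2$), so global-parameter
updates cost $O(NS)$ rather than $O(NJ)$. The LKJ prior is implemented by
pairwise correlation proposals with rejection outside the positive-definite
set plus the $\det(\Omega)^{\eta-1}$ factor — exact for any shape $\eta$,
and uniform over the PD set at the default $\eta = 1$ (whose marginal on a
single correlation of a $4 \times 4$ matrix is Beta(2,2) on $(-1,1)$, not
uniform — the tests check those moments). $\beta^* \ge 0$ is maintained by
reflecting proposals at zero. Degenerate inputs are defined rather than
special-cased: a fully missing person–screen contributes zero log
likelihood, $\pi_i \in \{0, 1\}$ reduce the person mixture to a single
component, and single-step items use the only step as the middle step.

## Problem sizes and what the tests compute

The package's acceptance-style tests run the full pipeline at the default
study conditions: one item-level recovery fit at $N = 300$ with two chains
of 1,000 recorded iterations, and ten screen-level fits (one chain of 800)
to item-level-generated data to measure the aggregation-induced
overestimation of the C/IER rate. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in
minutes. Monte-Carlo oracles in the unit tests use $10^4$–$10^6$ draws with
3-standard-error tolerances.

## Known limitations

* With rare C/IER (5% of units at $N = 300$, roughly 25–30 events), the
  posterior is genuinely diffuse along the $(\sigma_\psi, \iota)$ ridge,
  $\kappa$ is estimated from few responses and adapts to whichever patterns
  happened to be drawn, and the estimated rate inherits noticeable
  seed-to-seed variability; an unlucky pattern draw can concentrate
  $\kappa$ on the extreme categories and halve the detection rate of
  mid-category C/IER screens.
* The posterior median of the trait correlation carries mild shrinkage
  toward zero at small $N$ (about $-0.03$ to $-0.05$ at $N = 300$ with 12
  four-point items), vanishing as information grows.
* Aggregating RTs to the screen level discards the information that
  separates the components best: the screen-level model overestimates the
  population C/IER rate and drives the attentive residual variance toward
  zero. Trait correlations remain essentially unbiased, which is the
  variant's intended use: screening and structural conclusions, not rate
  estimation.
* Very long RTs are outside both component models; trim before fitting
  (`trim_rts()`), as untrimmed extreme outliers can stall convergence.
* The sampler treats one recorded iteration as `thin` sweeps; comparisons
  with samplers that count leapfrog trajectories differently should be made
  on effective sample size, not iteration counts.
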