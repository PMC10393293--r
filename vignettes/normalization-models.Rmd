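---
title: "Context-dependent outcome normalization: models, simulation and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent outcome normalization: models, simulation and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditnorm)
```

## The problem

When people learn option values by trial and error, the subjective value
assigned to an outcome depends on the context in which it is experienced: 50
points feels like a jackpot when the alternative pays 14, and like a
consolation prize when the alternative pays 86. `banditnorm` implements a
family of reinforcement-learning models that formalize competing accounts of
this context dependence, a factorial bandit task able to discriminate among
them, and the estimation and comparison machinery needed to decide which
account a choice dataset supports.

The task crosses the amplitude of the outcome range in a learning context
(narrow vs wide) with either the number of options (binary vs trinary) or,
in the third experiment family, the availability of the best option. Because
options from different contexts are later pitted against each other in a
transfer phase without feedback, the transfer choice rates reveal the scale
on which values were stored during learning.

## Models

All models share a delta-rule core. On each trial $t$ in context $s$, every
presented option $i$ is updated

$$Q_{t}^{s,i} = Q_{t-1}^{s,i} + \alpha_X\,\delta_t^i, \qquad
  \delta_t^i = u(R_i) - Q_{t-1}^{s,i},$$

with learning rate $\alpha_C$ for the obtained (chosen or forced) outcome
and $\alpha_U$ for forgone outcomes, including outcomes of options displayed
but not selectable. Free choices follow a softmax with inverse temperature
$\beta$ over the options selectable on that trial.

The models differ only in the subjective encoding $u(\cdot)$ of the raw
outcomes $R_1,\dots,R_n$ presented on a trial (and in $Q_0$):

* **UNBIASED** — $u(R_i) = R_i$; values live on the objective 0–100 point
  scale, $Q_0 = 50$.
* **RANGE** — $u(R_i) = (R_i - \min R)/(\max R - \min R)$; values live on a
  within-context 0–1 scale, $Q_0 = 0.5$.
* **DIVISIVE** — $u(R_i) = R_i / \sum_k R_k$; the denominator grows with the
  set size, $Q_0 = 0.5$.
* **RANGE$^\omega$** — the range value raised to a power $\omega \in
  (0,\infty)$, one free exponent for all outcomes.
* **RANGE$^{\omega+}$** — separate exponents for obtained ($\omega_c$) and
  forgone ($\omega_u$) outcomes.

These rules make sharply different transfer-phase predictions. Under range
normalization every context's best option converges to $u \approx 1$, so all
high-value options are chosen at similar rates when they meet in transfer.
Under divisive normalization a trinary context's best option is diluted by
the extra denominator term, so binary-context favourites beat trinary ones.
Under unbiased coding the 86-point options beat the 50-point options
regardless of context.

In the transfer phase, simulated agents choose greedily (argmax on final
values, ties split by a fair coin); this mirrors the idea that transfer
preferences read out learned values rather than continue exploration. For
*likelihood evaluation* of transfer choices we use the softmax with the
fitted $\beta$ instead: an argmax likelihood assigns probability zero to a
single inconsistent choice, which makes out-of-sample log-likelihoods
degenerate, whereas the softmax keeps them finite while preserving the
ranking structure.

## Task designs

`bandit_design()` registers eight designs. Experiments 1–2 use four contexts
of 2–3 options with mean outcomes drawn from {14, 32, 50, 68, 86} points;
each context is presented 45 times (180 free learning trials). Versions b/c
add five forced-choice trials per option (230 learning trials), with
complete (b) or partial (c) feedback on the forced trials. The transfer
phase presents all $\binom{10}{2} = 45$ cue pairs 4 times (180 trials) and
the explicit phase elicits 4 ratings per cue (40 trials). Experiment 3 uses
four trinary contexts; in two of them the highest-mean option is displayed
but not selectable on 50 % (3a) or 75 % (3b) of trials, and transfer/explicit
reps halve ($\binom{12}{2} = 66$ pairs $\times$ 2 = 132 trials; 24 ratings).

Realized outcomes are normal draws around the option mean with variance 4.
We read the dispersion statement in the source protocols as a *variance* of
4 (SD 2) — the more precise of the two available statements — and expose
`outcome_sd` as a per-context field so either reading can be configured;
with means at least 18 points apart the choice is immaterial for model
ranking. Outcomes are rounded to integer points and clipped to [0, 100],
matching the payoff scale participants are shown. Two consequences are
handled explicitly: a trial on which rounding collapses the range
($\max R = \min R$, probability negligible at SD 2) maps all outcomes to
0.5, and divisive normalization raises an error if outcomes sum to zero
(impossible in the built-in designs).

Fractional unavailable-trial counts are resolved deterministically: 50 % of
45 trials is realized as 22 and 23 trials in the two affected contexts (the
assignment alternates with the seed so neither context is systematically
favoured), and 75 % of 45 rounds to 34. Forced trials are uniformly
interleaved with free trials, as no block structure is specified for them.

## The synthetic cohort generator

`simulate_cohort()` stands in for a human dataset. Agent parameters are
drawn from the priors used for ex ante prediction: learning rates from
Beta(1.1, 1.1) (near-uniform, mean 0.5) and the inverse temperature from
Gamma(1.2, 5). We read Gamma(1.2, 5) in the shape–scale parametrization
(mean 6): the shape–rate reading would put the prior mass at $\beta \approx
0.24$, an implausibly noisy regime for agents that demonstrably learn. For
the exponent models, recovery studies draw $\omega$ from log-normal(0, 0.5),
centred on the linear case $\omega = 1$.

Explicit-phase ratings need a generative stand-in, since humans produce them
directly: the simulator reports the final learned value mapped to the 0–100
slider (raw $Q$ for UNBIASED, $100\,Q$ otherwise) plus Gaussian noise
(SD 5 rating points, configurable), clipped to the scale. This preserves
exactly the monotone value-to-rating link that the downstream
rating-based choice simulation (`simulate_choices_from_ratings()`) assumes,
and nothing more.

What passing simulation-based tests shows, therefore, is that the *pipeline*
(design → learning → transfer → metrics → fitting → comparison) behaves as
the theory says it must on data whose generative process is known. It does
not show that human data obey any of these models: real datasets bring
sequential effects, attention lapses, and rating biases that the generator
deliberately omits.

## Fitting

`fit_bandit()` maximizes the likelihood of the learning-phase free choices
by replaying the recorded trial sequence: observed choices and displayed
outcomes drive the updates, forced trials contribute updates but no
likelihood term, and on trials with a restricted choice set the softmax runs
over the selectable options only. Under partial feedback, hidden outcomes
are replaced by the last outcome seen for that option; an option never yet
observed falls back to 50 points (the raw-outcome counterpart of the neutral
initialization — a context-free raw value whose normalization is exactly 0.5
does not exist, so the fallback is normalized within the trial like any
outcome). This fallback is only ever exercised in version-c forced trials.

Optimization runs on transformed coordinates — logit for learning rates, log
for $\beta$ and the exponents — with L-BFGS-B inside a box wide enough to be
effectively unconstrained (|logit $\alpha$| ≤ 10, |log $\beta$| ≤ 5) except
for the exponents, which are searched in $[e^{-3}, e^3]$, generously
covering the empirically plausible range. Twenty restarts are used by
default: the first from the prior means, the rest from prior draws, all
reproducible from the fit seed. The replay itself is compiled (C++), which
is what makes 450-fit recovery studies routine; the test suite checks it
against an independently written R replay to $10^{-9}$.

Model comparison uses the out-of-sample log-likelihood of the transfer
choices under the fitted parameters (`transfer_oos_loglik()`,
`compare_models()`). No complexity penalty is applied: evaluating on choices
the optimizer never saw already penalizes overfitting. The per-subject
best model is likewise the one with the highest out-of-sample
log-likelihood.

`ex_post_simulate()` re-simulates fitted subjects with fresh outcome draws
(the generative check); it defaults to the argmax transfer rule to mirror
the ex ante simulations, with softmax available. Whether ex post simulation
should resample outcomes or replay the observed ones is underdetermined;
resampling is the stricter test and is what the implementation does.

## Problem sizes and reproducibility

The validation suites use the study's own scale: 50-agent cohorts for the ex
ante signatures and parameter recovery, and 3 × 50 agents (UNBIASED,
DIVISIVE, RANGE generators, each fit under all three candidates) for model
recovery. All randomness flows from a single integer seed through derived
per-subject substreams, so cohorts, fits, and recovery tables are
bit-reproducible. Smoke-level variants (2–4 agents, 2 restarts) cover the
same code paths cheaply in the unit tests.

## Known limitations

* **Learning rates are weakly identified in this task family.** Outcomes
  are nearly deterministic (SD 2 against 36–72-point ranges), so the
  range-normalized outcome of a binary context is constant at 0/1 on every
  trial; values converge within a handful of trials; and under complete
  feedback every presented option is updated on every trial, so the chosen
  and unchosen learning rates trade off along a likelihood ridge (moving
  $\alpha_C$ from its true value to a bound typically costs about one
  log-likelihood unit over 180 trials). In recovery studies on 50-agent
  cohorts, $\beta$ recovers with rank correlations around 0.9 while the
  learning rates recover around 0.2 — stably across seeds, and not due to
  the optimizer, which in diagnostic runs never returned a likelihood worse
  than the truth's. Analyses of such designs should therefore lean on the
  out-of-sample model comparison, which is well behaved, rather than on
  point estimates of the learning rates.
* The fully parameterized divisive-normalization variants (with additional
  saturation/weight constants) are not implemented; only the five models
  above are.
* Inferential statistics (ANOVAs, t tests) are out of scope by design: the
  package emits per-subject summary tables (`cohort_summary()`, CSV
  writers) for consumption by standard statistical tooling.
* Whether free-choice trials in version c also had partial feedback is
  ambiguous in the source protocols; the schedule encodes partial feedback
  on forced trials only, and the `feedback` field lets users configure the
  other reading.
* The argmax transfer rule makes simulated transfer choices insensitive to
  $\beta$; fitted $\beta$ therefore reflects learning-phase decisiveness
  only. This is a property of the modelling choices, not of the code.
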