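---
title: "The quad-negative-binomial model for differential RNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quad-negative-binomial model for differential RNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadnb)
library(ggplot2)
```

## The problem

MeRIP-seq (m6A-seq) measures transcriptome-wide RNA methylation through two
paired libraries per biological replicate: an antibody-enriched IP library
whose reads track methylated fragments, and an input-control library that
tracks overall transcript abundance. For a feature (a called methylation
site, or a gene) with IP count $t$ and input count $c$, the naive
methylation level is $\hat p = t/(t+c)$. That single number hides the
information content of the counts: $(t, c) = (100, 0)$ and $(1, 0)$ both
report 100% methylation, yet only the first is a confident estimate. With
typically no more than three replicates per condition, deciding whether a
rate difference between two conditions exceeds biological noise needs a
count-based model that borrows variance information across features —
the same pressure that produced DESeq-style inference for RNA-seq.

A second complication is specific to RNA: expression itself changes between
conditions, so the absolute amount of methylated material can move in the
opposite direction from the methylation *rate*. The input library must
therefore enter the model as a measured quantity with its own noise, not
merely as a plug-in background.

## The model

For feature $i$ in replicate $j$ under condition $\rho(j) \in \{A, B\}$,
IP and input counts are modelled as negative binomial,

$$ t_{i,j} \sim \mathrm{NB}(\mu_{t,i,j}, \sigma^2_{t,i,j}), \qquad
   c_{i,j} \sim \mathrm{NB}(\mu_{c,i,j}, \sigma^2_{c,i,j}), $$

with means factorised as

$$ \mu_{t,i,j} = q_i\, p_{i,\rho(j)}\, e_{i,\rho(j)}\, s_{t,j}, \qquad
   \mu_{c,i,j} = q_i\, (1 - p_{i,\rho(j)})\, e_{i,\rho(j)}\, s_{c,j}. $$

Here $q_i$ is the feature's abundance in a standard library, $p$ the
methylation rate on the common scale, $e$ a condition-specific expression
factor and $s$ a per-library size factor (estimated separately for IP and
input libraries, which are differently constructed and not directly
comparable). The variance decomposes into shot noise plus a raw
(extra-Poisson) component,

$$ \sigma^2_{t,i,j} = \mu_{t,i,j} + (e_{i,\rho(j)} s_{t,j})^2\,
   \upsilon_{t,i,\rho(j)}, $$

and the raw variance $\upsilon$ is assumed to be a smooth function of the
methylation rate and abundance, shared across features. Abundance is
estimated from IP *and* input reads together,
$\hat q_i = \mathrm{mean}_j (t_{ij}/s_{t,j} + c_{ij}/s_{c,j})$, which keeps
the background estimate usable for lowly expressed features whose input
library alone is thin.

The test conditions on the observed totals. Under the null of one common
rate $p_{i,O}$, the four group sums $t_{i,A}, t_{i,B}, c_{i,A}, c_{i,B}$
follow four cross-linked NB laws with means such as
$\hat\mu_{t,i,A} = \hat p_{i,O} \hat q_i \hat e_{i,A} \sum_{j \in A}
\hat s_{t,j}$ and variances adding
$\upsilon_A(\hat p_{i,O}, \hat q_i)\, \hat e^2_{i,A} \sum_{j\in A}
\hat s^2_{t,j}$. Holding $t_i = t_{i,A} + t_{i,B}$ and the per-condition
totals $n_{i,A}, n_{i,B}$ fixed, the probability of a split
$t_{i,A} = t$ is the product of the four masses, and the two-sided p-value
sums, over the bounded support
$t \in [\max(0, t_i - n_{i,B}),\ \min(t_i, n_{i,A})]$, all splits no more
probable than the observed one, normalised by the total mass. Effect sizes
are reported as the risk ratio $\hat p_{i,A}/\hat p_{i,B}$ (second condition
= control) and the depth-normalised odds ratio.

## Estimating the raw variance

For each sample type and fitting group, counts are brought to the common
scale ($t_{ij}/(\hat s_{t,j}\hat e_{i,\rho})$) and their unbiased sample
variance $\hat w$ computed across replicates. $\hat w$ overstates the raw
variance by a shot-noise term
$z = \hat q \hat p\, |\rho|^{-1} \sum_j 1/(\hat s_{t,j} \hat e_{i,\rho})$;
$\hat w - z$ is unbiased for $\upsilon$ but far too noisy per feature at
2–3 replicates, so $\hat w$ is smoothed over $(\hat p, \log \hat q)$ and
the bias term subtracted at evaluation time. Four fitting modes mirror the
usual dispersion-sharing strategies: `per-condition` (one surface per
condition; needs two replicates everywhere), `pooled` (one surface per
sample type from all replicated conditions), `blind` (all samples of a type
treated as replicates of one condition — works without biological
replicates but is conservative, since real between-condition signal
inflates the variance), and `auto` (per-condition when every condition is
replicated, else blind; the default).

Numerical choices, made where the method description leaves them open:

* **Smoother.** The response $\hat w$ is a scaled sum of squares, hence
  positive and right-skewed, so the smoother is a gamma-family model with
  log link. We fit a penalized tensor-product spline over
  $(\hat p, \log\hat q)$ with `mgcv::gam` (REML smoothness selection,
  basis dimension grown slowly with the number of features). This plays
  the same role as a local gamma-likelihood regression; penalized splines
  make the fit deterministic and cheap at tens of thousands of features.
  A log-scale loess (`engine = "loess"`, response $\log(\hat w +
  10^{-8})$, span = the `smooth` argument, default 0.7) is available as an
  alternative and is used automatically if the gamma fit fails; the engine
  actually used is recorded in the model object.
* **Predictor space.** Abundance spans orders of magnitude, so the
  smoother works in $\log \hat q$.
* **Zero spread.** Features with identical replicates ($\hat w = 0$) stay
  in the fit with the response floored at $10^{-8}$ (a gamma response must
  be positive).
* **Extrapolation.** Evaluation clamps covariates to the fitted range
  rather than trusting the smoother's tails.
* **Clamping.** $\hat\upsilon = \max(0, w(\cdot) - z)$: the unbiased
  estimator can dip below zero, but at evaluation a variance below shot
  noise is not meaningful.
* **Under-dispersion guard.** If a group's fitted variance falls at or
  below its mean, the Poisson limit is used (the NB law is undefined
  there).
* **Ties.** The p-value comparison $P(t) \le P(t_{\mathrm{obs}})$ uses a
  relative tolerance of $10^{-8}$, which includes floating-point ties and
  errs on the conservative side. All mass computations run on the log
  scale, so extreme observations do not underflow.
* **Degenerate features.** Features with no reads at all (or zero total IP
  count) are flagged `skipped-zero` and retained in the output with
  missing statistics; a feature whose conditional law has no numerically
  positive mass is flagged `skipped-degenerate` with p-value 1.

## Size factors

`size_factors()` estimates sequencing-depth factors per sample type:
`"geometric"` is the median-of-ratios estimator (per-feature geometric-mean
reference over features positive in all columns of that type) and
`"total"` rescales column sums. IP and input factors are never pooled
across types. If fewer than 50 features support the geometric reference a
warning suggests `"total"`. Counts must be integers; fractional values are
rejected rather than rounded, because the exact test conditions on integer
sums.

## The simulator

`simulate_merip()` draws datasets from exactly the generative model above,
with ground truth attached: $\log q_i \sim U(\log 10, \log 10^4)$,
$p_{i,A} \sim U(0,1)$ with $p_{i,B} = p_{i,A}$ for the non-differential
half and redrawn independently otherwise, lognormal expression and size
factors ($\mathrm{sd} = 0.25$ on the log scale), and raw variance
$\upsilon = d / (e_{i,\rho} s_j)$ so a single constant $d$ tunes the
over-dispersion ($d = 1$ by default; counts are Poisson at $d = 0$). The
uniform abundance range, the lognormal spreads and the redraw rule for
differential rates are the package's choices where the model description
is silent; they produce realistic 10–10,000-read features with mild
replicate-to-replicate depth variation, and each is a single exposed
argument so sweeps vary one knob. The NB draw uses the same
(mean, variance) → (size, mu) conversion as the test's pmf, so simulator
and test share one model — which is precisely what the moment-matching
and calibration tests exploit.

What the simulator does *not* emulate: positional read structure within a
peak, isoform ambiguity, immunoprecipitation-efficiency differences
between IP libraries, and correlated features. Passing tests on simulated
data therefore demonstrate correctness of the inference machinery under
the model's own assumptions, not robustness to those real-data effects.

## What the checks show, at what scale

The test suite verifies, among others: exactness of the conditional
p-value against brute-force enumeration (200 random small instances,
totals ≤ 50); elementwise agreement of every moment estimator with direct
formula evaluation (1,000 simulated features); unbiasedness of
$\hat w - z$ against a known constant raw variance (2,000 features, 3
Monte-Carlo standard errors); type-I error on a fully null simulation
(5,000 features, 3+3 replicates, $d = 1$) within $[0.02, 0.10]$ at
$\alpha = 0.05$; and benchmark trends at reduced scale — mean AUC over 20
simulation repeats of 2,000 features, non-decreasing in replicate count
over $\{2, 3, 4, 6\}$ and non-increasing in dispersion over
$\{0.5, 2, 8\}$, with AUC above 0.9 at the easiest setting. The trend
repeats share one seed per repeat across grid settings, so the
comparisons are paired and the small dispersion effect is not drowned by
between-dataset noise. These problem sizes keep the full suite fast while
leaving every Monte-Carlo margin at 2–3 standard errors.

The dispersion effect deserves a note: with $\upsilon = d/(e s)$ the
extra count variance is roughly $d$ per observation, so at abundances of
thousands of reads moderate $d$ barely moves the test, and the AUC cost
of dispersion is concentrated in low-abundance features. That matches the
model's intent — dispersion hurts exactly where coverage is thin.

## A worked run

```{r example, fig.width = 6, fig.height = 4}
sim <- simulate_merip(n_features = 1000, d = 1, seed = 42)
fit <- qnb_test(sim$dataset)
glance(fit)
head(tidy(fit))
roc_auc(tidy(fit)$p_value, sim$truth$is_differential)
autoplot(fit)
```

The sample-swop protocol builds label-exchanged negative controls for real
data, where no ground truth exists:

```{r swop}
pairs <- make_swop_pairs(sim$dataset)
genuine_p <- tidy(fit)$p_value
mock_p <- lapply(pairs, function(sp) tidy(qnb_test(sp$mock))$p_value)
curve <- swop_curve(rep(list(genuine_p), 3), mock_p,
                    fractions = c(0.01, 0.05, 0.1))
curve
```

Each mock exchanges one replicate (its IP and input columns together —
they are one paired library) between the conditions, so mock calls
estimate the no-signal background; `implied_fdr` is the mock/genuine
calling ratio at matched thresholds.

## Known limitations

* With a single replicate per condition only `blind` mode is available,
  and its variance estimate absorbs true between-condition differences:
  power is substantially reduced by design.
* The smooth-surface assumption trades per-feature variance fidelity for
  stability; with many replicates, direct per-feature dispersion
  estimation would be preferable, and no empirical-Bayes moderation
  beyond the smoothing is attempted.
* The conditional support is bounded by the observed totals, so features
  with enormous counts enumerate long supports; computation stays exact
  rather than truncated, at linear cost in the total count.
* Isoform-specific testing and IP-efficiency correction are out of scope.
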