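---
title: "Empirical Bayes differential expression from FPKM point estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical Bayes differential expression from FPKM point estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebfpkm)
```

## The problem

RNA-seq quantification pipelines such as Tophat–Cufflinks return, for each
transcript $t$ in each condition, a single FPKM point estimate
$\hat A_t$ together with a confidence interval — not replicate
measurements. Differential expression testing, however, needs a variance
for every transcript, and with one (or zero) biological replicates that
variance cannot be estimated per transcript from the data alone.
`ebfpkm` addresses this by (i) treating the quantifier's interval as a
normal sampling distribution for each transcript and expanding it into
synthesized pseudo-replicates, and (ii) fitting a hierarchical empirical
Bayes mixture model that shares information across all transcripts, so
that even data-poor transcripts borrow strength from the transcriptome as
a whole. The same machinery handles more than two conditions through
user-declared *expression patterns*.

The justification for the normality assumption is asymptotic: the FPKM
estimate is a product of two jointly asymptotically normal maximum
likelihood estimates (a gene-level fragment count and a transcript
fraction). If $\sqrt n(\hat\theta_n-\theta,\hat\eta_n-\eta)$ converges to
a bivariate normal with SDs $\sigma_1,\sigma_2$ and correlation $\rho$,
then $\sqrt n(\hat\theta_n\hat\eta_n - \theta\eta) \to N(0,\gamma^2)$ with

$$\gamma^2=\eta^2\sigma_1^2+\theta^2\sigma_2^2
  +2\eta\theta\sigma_1\sigma_2\rho,$$

implemented as `product_delta_variance()` and verified by Monte Carlo in
the test suite.

## The hierarchical model

For transcript $j$, let $x_j=(x_{j1},\dots,x_{jI})$ collect its expression
values over all samples. Within a group of samples assumed to share one
underlying mean,

$$X_{ji}\mid\mu_j \sim N(\mu_j,\sigma_j^2),\qquad
  \mu_j \sim N(\mu_0,\tau_0^2).$$

Integrating $\mu_j$ out gives an $n$-dimensional normal with mean
$(\mu_0,\dots,\mu_0)$ and compound-symmetric covariance
$\Sigma_j=\sigma_j^2 I_n+\tau_0^2 J_n$ ($J_n$ the all-ones matrix). Its
determinant, $\sigma_j^{2(n-1)}(\sigma_j^2+n\tau_0^2)$, and inverse
(rank-one update) are closed-form, so `marginal_log_density()` evaluates
the log-density directly from two sufficient statistics per group —
no matrix algebra, stable in the log domain. The test suite checks this
closed form against adaptive one-dimensional quadrature of the defining
integral to a relative error below $10^{-8}$.

An *expression pattern* is a partition of the samples into equal-mean
groups; groups are independent given the hyperparameters, so a pattern's
density is the product of its group marginals (`pattern_log_density()`).
Pattern 0 is always the null — all samples in one group (equivalent
expression). A two-condition analysis uses the two patterns
`null = (1,1,...,1)` and `DE = (1,...,1,2,...,2)`; with four samples,
say a genotype-by-treatment design, one can declare e.g.
treatment-specific `(1,2,1,2)` and genotype-specific `(1,2,1,1)`
alternatives next to the null and test all three simultaneously.

Transcripts belong to pattern $k$ with prior probability $p_k$, giving
the marginal mixture $f(x_j)=\sum_k p_k f_k(x_j)$ and the posterior

$$P(H_k \mid x_j)=\frac{p_k f_k(x_j)}{\sum_l p_l f_l(x_j)},$$

computed by log-sum-exp in `posterior_probabilities()`. A common
selection rule keeps transcripts with posterior above 0.99 for a pattern
of interest; `rank_by_pattern()` orders transcripts by decreasing
posterior, breaking ties lexicographically by id so rankings are
deterministic.

## EM fitting and its numerical choices

`eb_fit()` maximises the marginal log-likelihood
$\sum_j\log\sum_k p_k f_k(x_j)$ by EM:

* **E-step** — posterior pattern responsibilities per transcript.
* **M-step, mixing proportions** — the posterior average per pattern,
  kept above a floor of $10^{-6}$ (exact KKT projection onto the floored
  simplex) so no pattern becomes an absorbing zero state; the reported
  `mix` is the unfloored posterior average.
* **M-step, $(\mu_0,\tau_0^2)$** — no closed form exists with
  heterogeneous $\sigma_j^2$, so the expected complete-data
  log-likelihood is maximised by bounded quasi-Newton (L-BFGS-B) on
  $(\mu_0,\log\tau_0^2)$, started at the current iterate. Because the
  M-step can only improve the objective from that start, the generalized
  EM ascent property holds; the test suite asserts the log-likelihood
  trace never decreases by more than $10^{-8}$ on every fitted dataset.

Initialization is $\mu_0=$ grand mean, $\tau_0^2=$ variance of
per-transcript means, mix $=(0.95, 0.05/m, \dots)$. Convergence is a
relative log-likelihood change below $10^{-6}$ (at most 1000 iterations);
both are settable through `eb_control()`. Non-convergence is returned as
`converged = FALSE` with a warning, never silently.

**Observation variances.** Each transcript's $\sigma_j^2$ is a plug-in:
by default the pooled within-condition sample variance, *moderated* by
shrinkage toward a common prior variance (`limma::squeezeVar`, with
$\sum_c(n_c-1)$ degrees of freedom). The moderation matters: raw
per-transcript variances estimated from a handful of samples are noisy,
and that noise is asymmetric in its effect — transcripts whose variance
happens to be underestimated produce spuriously large likelihood ratios
in favour of differential expression, which inflates the fitted DE
proportion (we observe roughly +0.03 at five replicates per condition in
simulation, removed entirely by moderation or by supplying the true
variances). `moderate_var = FALSE` restores the raw plug-in; `sigma_sq`
accepts externally derived variances, e.g. interval-derived quantifier
variances, directly. Variances are floored at $10^{-8}$ to keep
$\Sigma_j$ non-singular. Data are modelled on the raw FPKM scale; a
`log_transform` flag (off by default) applies `log1p` first.

One structural note: because the prior on group means is shared across
the transcriptome, $\tau_0^2$ reflects *between-transcript* spread, which
is typically much larger than measurement noise — exactly the property
that lets a DE pattern gain likelihood only when group means separate by
more than $\sigma_j$ noise would explain.

## From point estimates to pseudo-replicates

`ci_to_variance()` reads the quantifier's interval as a symmetric
two-sided normal interval, $\mathrm{sd}=(\text{hi}-\text{lo})/(2z)$ with
$z=1.96$ at the default 0.95 level (the level is configurable; the
quantifier's actual level is assumed, not checked). `synthesize_replicates()`
then draws $M$ independent values from $N(\hat A_t,\hat V_{A_t})$ per
transcript per condition. Defaults and choices:

* $M$ is a model parameter expressing confidence in the quantifier's
  variance, not a count of real replicates. Around 1000 suits clean
  (noise-free) data and around 100 noisy data; the package default is
  100 and the value is always the user's to set.
* Negative draws are kept by default — the normal model permits them and
  truncation would bias the synthesized moments; `clamp_negative = TRUE`
  truncates at zero for users who require non-negative FPKM.
* Transcripts absent from any condition are dropped (inner join) and
  reported, rather than zero-filled: zero-filling fabricates certainty
  about absence.

Before fitting, `filter_extremes()` removes the 1% most lowly and 0.1%
most highly expressed transcripts (grand mean across samples,
`floor(fraction * G)` per tail, ties broken by id). Transcripts at the
extremes are poorly described by a single shared prior and destabilise
the mixture; both fractions are configurable and `0` disables the filter.
Pooled (not per-condition) ranking is used so that a transcript's
filtering status cannot itself depend on condition.

## The read-level benchmark

To compare DE methods one needs data where truth is known *at the level
of reads*, so that both FPKM-based and count-based pipelines can consume
it. Two generators provide this:

* **Rank-proportional spike-in** (`select_spike_reads()`,
  `apply_spike()`): sample $K$ (default 100) uniquely mapping reads
  (`NH:i:1`) uniformly without replacement; the read drawn $i$-th gains
  $i$ additional copies. A transcript's unique-read count therefore rises
  by exactly the sum of its selected reads' ranks, and `spike_truth()`
  tabulates `treatment = control + added` per transcript — an identity
  the suite checks exactly, alongside `count_reads()`, the package's
  unique-read counter.
* **Negative-binomial copy noise** (`apply_read_noise()`): each uniquely
  mapping read of gene $g$ is replicated $y\sim NB(r_g,p_g)$ additional
  times ($y$ counts successes before $r_g$ failures at success
  probability $p_g$; mean $pr/(1-p)$). Summing per-read draws, a gene
  with $N$ original reads ends with
  $E(X)=N+pNr/(1-p)$ and $\mathrm{Var}(X)=pNr/(1-p)^2$. Setting
  $\mathrm{Var}(X)=E(X)$ gives the critical dispersion
  $r_c=((1-p)/p)^2$ (`critical_dispersion()`), at which both moments
  equal $N/p$: noise is Poisson-like at $r_c$, overdispersed above it.
  `draw_noise_params()` draws $p_g\sim U(0.9,1)$ and
  $r_g = c\,r_c(p_g)$ with $c\sim U(1.2,2)$, guaranteeing
  overdispersion, as observed in real technical replicates.

SAM handling is deliberately line-based and minimal: records round-trip
byte-for-byte (header included), only the `NH` tag is interpreted, and
duplicated reads keep their `QNAME` verbatim (naive line replication).
Positions follow the 1-based SAM convention. BAM/CRAM are out of scope —
plain SAM suffices for benchmark construction, and `samtools` converts
either way.

`fano_regression()` provides the companion diagnostic: per-gene Fano
factors (variance/mean across technical replicates) with an OLS line of
Fano on mean, optionally over the first $k$ genes by increasing mean.
Poisson-simulated counts give mean Fano ≈ 1 and slope ≈ 0; counts from
the copy-noise model give Fano > 1 growing with the mean.

## The simulation study and its generator

`simulate_expression()` reproduces the evaluation design: a
$1000\times n$ control matrix from per-transcript normals at baseline
(mean, variance) pairs; a treatment matrix in which a random 10% of
transcripts are over-expressed, half by $+x$ and half by $+2x$; and
optionally $+v$ added to every treatment variance. Only over-expression
is simulated. `simulation_auc()` runs the full loop — simulate, fit the
two-pattern model, score by posterior DE probability, return the ROC AUC
(`roc_curve()`, trapezoid rule, tied scores grouped into one step).

The baseline pairs stand in for a real quantified transcriptome, which
this package does not ship: `base_expression_params()` draws means
log-normally (median 60 FPKM, $\mathrm{sdlog}=1$, so roughly 8–450 FPKM
across the central range) with $\mathrm{sd}=2+0.15\,\mathrm{mean}$,
mimicking the mean-variance coupling of FPKM estimates. These values were
fixed once, on the grounds that shifts of 5–50 FPKM should span the range
from undetectable to easy at ten replicates — and the resulting AUC
surface indeed rises from 0.5 (null) toward ~0.95 over $x\in[0,50]$. A
user table of `mean`/`variance` columns can replace the synthetic pairs.
What these simulations do *not* emulate: skewness of FPKM sampling
distributions near transcript-fraction boundaries, correlated transcripts
within genes, or library-size effects; conclusions from them are about
model behaviour under its own assumptions, not about any real dataset.

Problem sizes in the tests and the acceptance script (1000 transcripts,
five seeds per setting for AUC curves; 5000 transcripts for parameter
recovery; $10^3$–$3\times10^3$ Monte Carlo repetitions for noise moments)
were chosen as the smallest sizes at which the Monte Carlo error bands
quoted alongside each check are meaningful.

## Known limitations

* The normal-normal model operates on raw FPKM; strongly skewed
  transcripts (fractions near 1, very low expression) violate it, which
  is precisely why extreme-abundance filtering and a tunable replicate
  count exist. Choosing $M$ by a self-consistency criterion such as
  cross-validation is recommended for real data.
* Posterior probabilities are reported as-is; no FDR calibration beyond
  posterior thresholding is provided.
* Log-normal and gamma-gamma mixture variants, and count-based empirical
  Bayes models, are out of scope.
* The spike-in generator assumes single-end semantics: records are
  duplicated independently, with no attempt to keep mate pairs together.
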