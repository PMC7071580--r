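---
title: "Assessing 16S rRNA count tables with two-sample titration mixtures"
author: "titrassess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing 16S rRNA count tables with two-sample titration mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titrassess)
```

## The measurement problem

A 16S rRNA marker-gene survey turns a community of microbes into a
feature-by-sample count table, through DNA extraction, PCR, sequencing and
a bioinformatic pipeline (clustering, denoising, chimera removal). Every
step injects artifacts: spurious features that are not in the sample
(false positives) and real community members missing from the table
(false negatives), as well as bias and noise in the abundance values
themselves. Different pipelines make very different trade-offs, and
without expected values there is no way to score them on real data.

Two-sample titration mixtures supply those expected values. DNA from two
stool samples of the same subject — collected before (PRE) and after
(POST) exposure to enterotoxigenic *E. coli* — is mixed along a log2
dilution series. A titration with factor $t$ contains a POST DNA
proportion $\theta = 2^{-t}$, so for every feature $j$ the mixture design
fixes its expected relative abundance in titration $i$:

$$q_{ij} = \theta_i\, q_{\mathrm{post},j} + (1 - \theta_i)\, q_{\mathrm{pre},j}$$

where $q_{\mathrm{pre},j}$ and $q_{\mathrm{post},j}$ are measured in the
unmixed samples. Everything in this package derives from that one
equation: expected proportions, expected log fold-changes between
titrations, detection floors for presence/absence tests, and the ground
truth of the synthetic generator.

The reference design has 5 subjects, titration factors
$\{1,2,3,4,5,10,15\}$ (POST proportions $1/2 \dots 1/32768$), unmixed PRE
and POST samples, 4 PCR replicates per sample and 12 no-template controls:
45 samples, and 45 × 4 + 12 = 192 PCR assays. `defaultDesign()` encodes
it; the unmixed PRE is encoded with an absent titration factor and
$\theta = 0$, and factor 0 denotes unmixed POST.

## Qualitative assessment: can sampling explain it?

Features observed *only* in unmixed samples (unmixed-specific) or *only*
in titrations (titration-specific) are candidate artifacts — but a rare
feature can legitimately disappear from a finite sequencing sample. The
qualitative assessment asks, per feature and titration PCR replicate,
whether random sampling at the replicate's depth explains the observation.

**Unmixed-specific features** have a known mixture expectation $q$, so a
one-sided binomial test applies: $p = P(X \le C_{obs})$,
$X \sim \mathrm{Binomial}(N, q)$, which is $(1-q)^N$ at $C_{obs} = 0$.

**Titration-specific features** have $q_{\mathrm{pre}} = q_{\mathrm{post}}
= 0$, so the binomial test degenerates. Instead we use the posterior
probability that the true proportion $\pi$ lies below the detection floor
$\pi_{\min}$ — the mixture expectation of the *minimum* observed nonzero
PRE and POST proportions for that subject — given that at least $C_{obs}$
counts appeared:

$$p = \frac{P(C \ge C_{obs} \mid \pi < \pi_{\min})\,w}
  {P(C \ge C_{obs} \mid \pi < \pi_{\min})\,w +
   P(C \ge C_{obs} \mid \pi \ge \pi_{\min})\,(1-w)}$$

with prior null mass $w$ (default $1/2$), $\pi \sim U(0, \pi_{\min})$
under the null and $\pi \sim \pi_{\min} + (1-\pi_{\min})
\mathrm{Beta}(\alpha,\beta)$ under the alternative. Two implementation
choices deserve note:

* We evaluate the full two-term posterior rather than the simplified
  equal-prior ratio, because only the full form satisfies the sanity
  identity $C_{obs} = 0 \Rightarrow p = w$ (nothing observed is fully
  explained up to the prior).
* The Monte Carlo integrates over $\pi$ only; the binomial tail
  $P(C \ge C_{obs} \mid \pi)$ is computed exactly for each draw rather
  than sampling $C$. This Rao-Blackwellized estimator has lower variance,
  is deterministic given the seed, and is *provably* monotone
  non-increasing in $C_{obs}$ under common random numbers (the binomial
  tail family has a monotone likelihood ratio in $\pi$). Per-test RNG
  substreams are derived by hashing the (feature, sample) ids so results
  do not depend on iteration order.

P-values are Benjamini-Hochberg adjusted within each (subject, test kind)
family — the unit at which results are reported. The **artifactual
feature proportion (AFP)** is the fraction of tests (or features, both
units are emitted) with adjusted $p < 0.05$. AFP is interpreted jointly
with **sparsity** (fraction of zero cells): high AFP with high sparsity
suggests false negatives; low AFP with high sparsity suggests false
positives.

```{r qual-demo}
# absence of a 1-in-1000 feature from a depth-1000 replicate: unsurprising
binomialAbsenceTest(0, 1000, 0.001)
# 50 counts against a detection floor of 1e-4 at depth 1e4: artifactual
as.numeric(bayesTitrationTest(50, 1e4, 1e-4, seed = 1))
```

## Inferring the realized mixture proportion

Stool DNA is a mix of prokaryotic and (mostly human) eukaryotic DNA. If
the PRE and POST extracts carry different prokaryotic proportions
$\gamma_{\mathrm{pre}}, \gamma_{\mathrm{post}}$, the POST fraction
*visible to 16S sequencing* is not the design $\theta$ but

$$\theta_{\mathrm{eff}} = \frac{\theta\gamma_{\mathrm{post}}}
  {\theta\gamma_{\mathrm{post}} + (1-\theta)\gamma_{\mathrm{pre}}}.$$

`inferTheta()` estimates the realized proportion from the count data by
constrained least squares: over features whose unmixed proportions differ
(the informative features), the mixture equation gives
$q_{obs,j} - q_{\mathrm{pre},j} = \theta\,(q_{\mathrm{post},j} -
q_{\mathrm{pre},j})$, a regression through the origin solved on
pooled-replicate proportions and clamped to $[0,1]$. The estimator is
exact on noiseless mixtures, scale-invariant, and recovers
$\theta_{\mathrm{eff}}$ (not the design value) under $\gamma$ distortion —
which is precisely what the downstream expectations need. No uncertainty
interval is attached, only the residual SSE; with fewer than 3 informative
features or a degenerate regressor the design value is used and flagged.

Inferred $\theta$ feeds the *relative abundance* expectations only. The
*log fold-change* expectations always use design $\theta$: inferred values
for the most dilute titrations are not reliably monotone, and plugging
them into ratio expectations produces unrealistic values (e.g. negative
expected log fold-changes for PRE-specific features).

## Quantitative assessment

**Relative abundance.** The observed value per feature and titration is
the PCR-replicate average computed from an intercept-only negative
binomial regression with log link and log-depth offset (robust to
replicate outliers); it falls back to the pooled proportion
$\sum c/\sum d$ for all-zero, non-integer or near-constant replicates and
on non-convergence — the NB parameterization is not prescribed by the
framework, so the fallback hierarchy is this package's documented choice.
Eligible features are those observed in *all* PRE and POST replicates
plus the PRE-/POST-specific features. The error rate is
$|exp - obs|/exp$ (records with $exp = 0$ are skipped and flagged), and
per feature the **bias** is the median error rate and the **variance**
the robust coefficient of variation $\mathrm{RCOV} = \mathrm{IQR}/|\mathrm
{median}|$. All quantiles use linear interpolation (R type 7) — RCOV is
convention-sensitive, so the convention is fixed and tested against a
first-principles oracle.

**Differential abundance.** Log fold-changes between every pair of
mixture levels (all $\binom{9}{2} = 36$ pairs for the reference design,
oriented higher-$\theta$ first) are estimated by a transparent moderated
proportion ratio on replicate-pooled counts:
$\log_2\frac{(c_l+p)/(d_l+2p)}{(c_m+p)/(d_m+2p)}$ with prior count $p =
0.5$. TMM normalization and empirical-Bayes dispersion moderation of
dedicated differential-abundance packages are deliberately *not*
re-implemented: the test suite verifies that the median feature-level
bias moves by well under 20% across prior counts 0.1–2, and
`assessLogFC(external_logfc=)` accepts externally computed tables for
anyone who wants a specific estimator. Eligible features are PRE-specific
(expected value $\log_2\frac{1-\theta_l}{1-\theta_m}$, independent of
counts; undefined against unmixed POST, so those pairs are dropped) and
PRE-dominant (full mixture ratio). POST-specific features are excluded:
they are rarely observed in more than one titration. A per-feature OLS of
estimated on expected log fold-change yields the bias $|1-\mathrm{slope}|$
and variance $R^2$ metrics; a subject with no eligible features is
reported, not an error.

The feature-catalog routing is a fixed precedence over presence patterns
("observed" = count $\ge 1$ in a replicate, the weakest defensible
threshold): all-zero, titration-only, unmixed-only, then the
PRE/POST-specific, -dominant and shared rules, with a catch-all OTHER.
The typology is a proper partition of presence patterns: the POST-side
specific/dominance rules mirror the PRE-side ones by symmetry, and OTHER
completes the partition. The dominance log fold-change uses the same
moderated estimator (prior 0.5, threshold 5).

## Cross-pipeline comparison

Feature-level metrics from several pipelines are compared with the mixed
effects model $e_{ijk} = b + b_i + z_j + \epsilon_{ijk}$ (fixed pipeline
effect $b_i$, random subject intercept $z_j$, REML via lme4), after
removing outliers more than $1.5 \times \mathrm{IQR}$ *from the median* —
the rule is implemented literally as stated even though the conventional
fence is anchored at the quartiles (available via `rule = "quartile"`).
Note the literal rule is not idempotent on heavy-tailed data: trimming
shrinks the IQR, so re-application can remove more. Pairwise contrasts
use Tukey's HSD via the studentized range distribution on the REML
fixed-effect covariance, with containment residual degrees of freedom
($n - k - (J-1)$; the df method is not prescribed). The one-sided
alternative is "smaller metric is better"; the one-sided adjusted p is
half the two-sided Tukey p in the alternative's direction. Singular fits
(zero subject variance, or a single subject) fall back to a fixed-effects
model with a flag.

## The synthetic generator: what it emulates, what it does not

`simulateDataset()` is the package's test bed: it draws per-subject
PRE/POST compositions from a log-normal abundance model
(`meanlog = 0, sdlog = 2` by default — a long-tailed community in which
the rarest features sit near the detection limit, as real 16S data do),
imposes the class structure, computes titration proportions at
$\theta_{\mathrm{eff}}$, and samples counts multinomially per PCR
replicate at negative-binomial depths (mean $10^5$, matching the
reference dataset's per-sample read counts; an optional
Dirichlet-multinomial layer adds PCR replicate overdispersion). Artifacts
are injected afterwards and recorded in a truth registry: false positives
as novel features with counts 1-5 in one sample (default rate 1 per
sample), false negatives as zeroed cells (default probability 0.01).

Class structure is built so truth labels are *recoverable in principle*:
shared features get a POST:PRE log2 ratio within $\pm 3$, dominant
features within $[7, 10]$ — margins on either side of the classification
threshold of 5 that absorb the PRE/POST normalization shift and sampling
noise. (Independent PRE and POST draws would place a fifth of "shared"
features beyond the dominance threshold by chance, making any recovery
test meaningless.) The optional `minProportion` floor produces
*detection-safe* datasets — every true feature expected in every
replicate — used by the exact-recovery tests; realistic long-tailed
configurations are used by the calibration tests, where
sampling-generated unmixed-/titration-specific features must appear. A
`noiselessDataset()` oracle mode replaces sampling with exact expected
intensities; by default its cells are fractional, because rounding to
integers at finite depth would put a $1/\mathrm{depth}$ floor under every
"exact recovery" tolerance. The count-table *readers* still enforce
integer cells; only the in-memory container tolerates fractional oracle
data.

What a green test on simulated data does **not** establish: the generator
has no chimeras, no taxonomy, no primer or extraction bias, no
correlation between artifacts and abundance, and multinomial noise only
(unless the DM layer is enabled). It validates the *assessment
machinery* — that the metrics recover known distortions — not any claim
about real pipelines.

## Numerical and design choices

* Quantiles: linear interpolation (type 7) everywhere; tested against a
  sort-based oracle.
* Bayesian test: defaults $\alpha = \beta = 1$, $w = 1/2$, $10^5$ draws;
  rejections are stable (<10% change) across $(\alpha,\beta) \in
  \{(1,1),(2,5),(5,2)\}$.
* Replicate zero depths are dropped with a warning; an all-zero depth
  vector is an error.
* RCOV with zero median and positive IQR is reported as `Inf`; all-zero
  errors give 0. On noiseless data, errors at float-noise level
  ($\sim 10^{-15}$) make the IQR/median ratio meaningless noise — the
  tests assert the bias there, not the RCOV.
* Test granularity: one test per (feature, titration PCR replicate), the
  expected proportion varying by titration; both replicate- and
  feature-level AFP aggregations are reported since either can be the
  unit of interest.
* Sample ordering is fixed (subject, descending $\theta$, replicate; NTCs
  last) so all outputs are byte-stable; `runFullAssessment()` re-runs are
  byte-identical given the seed.

## Worked example

```{r example}
design <- TitrationDesign(paste0("S", 1:2), c(1, 2, 3, 4))
sim <- simulateDataset(design, SimulationConfig(depthMean = 1e4, seed = 7))
te <- sim$te
te

catalog <- buildCatalog(te)
catalogSummary(catalog)[catalogSummary(catalog)$n > 0, ][1:6, ]

theta <- inferThetaAll(te, catalog)
head(theta[, c("subject", "titration_factor", "theta_design",
               "theta_hat", "n_features_used")], 4)

qual <- assessQualitative(te, catalog, n_draws = 2000, seed = 3)
afp <- artifactualFeatureProportion(qual)
afp[afp$subject == "all", ]

ra <- assessRelativeAbundance(te, catalog, theta = theta)
summary(ra$features$bias)

lfc <- assessLogFC(te, catalog)
summary(lfc$features$bias)
```

## Known limitations

* The $\theta$ inference substitutes a documented least-squares estimator
  for the original (supplementary-only) procedure; its uncertainty is not
  quantified.
* The log fold-change estimator is a moderated proportion ratio, not a
  full GLM with normalization; use `external_logfc` to plug one in.
* The per-feature mixed-model comparison supports per-feature summaries
  (default) or per-(feature, titration) errors; the appropriate
  granularity depends on the question.
* Headline numbers of the reference study (per-pipeline feature counts,
  bias distributions, F statistics) require its raw sequence data and
  external pipeline runs; they are out of scope here.
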