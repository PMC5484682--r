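---
title: "Deriving and benchmarking miRNA-regulated severity signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and benchmarking miRNA-regulated severity signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcoSig)
library(SummarizedExperiment)
```

# The problem

Sarcoidosis spans a severity continuum: most patients remit
(uncomplicated disease), while a minority progress to cardiac,
neurologic, or severe pulmonary involvement (complicated disease). A
blood-based expression signature that tracks this continuum would support
both diagnosis and risk stratification. sarcoSig implements a
regulation-anchored way of building one: instead of taking the top
differentially expressed genes wholesale, it keeps only the genes that
are plausibly *regulated* by severity-associated miRNAs — predicted
binding (mirSVR), both partners differentially expressed, and
anti-correlated expression — on the premise that a mechanistic filter
lowers the false-positive rate of purely statistical signatures.

# The model, stage by stage

## Severity screen

Severity is coded HC = 0, US = 1, CS = 2. The code is ordinal; Spearman's
correlation uses only rank order, so the equal spacing is irrelevant (any
strictly monotone coding gives identical results — a property the test
suite checks). For each feature the package computes the mid-rank Pearson
correlation with severity and the asymptotic two-sided p-value from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. Two
numerical choices matter here:

* **Mid-ranks, not the $1 - 6\sum d^2/(n^3-n)$ shortcut.** The severity
  vector has only three distinct values, so ties dominate; the shortcut
  formula is invalid under ties, while the mid-rank Pearson formulation
  is exact. `stats::cor.test(..., method = "spearman", exact = FALSE)`
  implements precisely this, and a hand-written brute-force oracle
  confirms it across a thousand random tied instances in the tests.
* **Asymptotic p-values for all n.** The screens run at n ≈ 65–74
  samples, where the t approximation is standard; no exact permutation
  option is offered.

P-values are Benjamini–Hochberg adjusted over *all* features surviving
the presence filter on that platform — not just nominally significant
candidates — and thresholds are strict (`<`), at 0.05 for the miRNA
platform and 0.0005 for the gene platform. Whether the adjustment family
should be the pre- or post-presence-filter set is ambiguous in the field;
this package documents and uses the post-filter set, since undetected
features were never tested. The presence filter keeps features detected
in at least two-thirds of samples, with an inclusive boundary (2 of 3
passes). Constant features cannot be ranked: they are assigned
$\rho = 0$, kept in the BH family with $p = 1$ (deterministic and
conservative), and excluded from the returned records with a warning
rather than failing the whole screen. `alpha = 1` is accepted as an
explicit "no filtering" mode and returns every non-constant feature;
adjusted p-values can equal 1 exactly, so a strict threshold alone could
not express that.

## Pair integration

Predicted miRNA→target interactions enter with a mirSVR score (more
negative = stronger predicted repression). The filter retains scores
$\le -1.2$, *inclusive*: reference tables print scores such as −1.201 at
the cutoff's resolution, and an exclusive rule at coarser print precision
could drop genuine pairs. Duplicate predictions keep the most negative
score, the conservative choice for a $\le$ filter. Candidates are the
filtered predictions whose miRNA and gene both passed their screens; each
candidate is then tested for expression anti-correlation across the
samples shared by the two platforms. The two platforms profile
overlapping but unequal cohorts (13 vs 22 complicated cases in the
emulated design); the sample intersection is the only well-defined
substrate for a paired correlation, and that is what the package uses.
The BH family for these p-values is the post-intersection candidate set.
Pairs with $\rho < 0$ and adjusted $P < 0.005$ (strict) survive.

The unique miRNAs and unique genes of the surviving pairs form the two
signatures, ordered by first appearance. Each signature entry carries its
**severity**-correlation ρ from the screen — not the pair correlation —
because the score weights by the direction of differential expression
with severity.

## The severity score

For signature features $i = 1 \dots N$ with severity correlations
$\rho_i$ and expression $e_i$:

$$S = \sum_{i=1}^{N} \mathrm{sgn}(\rho_i)\,\frac{e_i - \mu_i}{\tau_i}$$

* Weights are $\mathrm{sgn}(\rho_i) \in \{-1, +1\}$, not $\rho_i$ itself:
  the score is deliberately untrained, with no magnitude weighting and no
  regression coefficients to overfit.
* $\mu_i, \tau_i$ are computed on the cohort being scored, across **all**
  of its samples, cases included. This is a transductive design: applying
  the signature to a new cohort requires no frozen training constants,
  but it also means a sample's score depends on its cohort's composition.
  Computing constants on controls only would be a defensible alternative;
  the all-samples convention is fixed here and stated openly.
* $\tau_i$ is the sample standard deviation (denominator $n-1$).

Consequences worth knowing: scores are invariant under positive affine
transforms of any feature (so per-feature normalization offsets cannot
matter), each cohort's scores sum to zero, and a constant feature is a
hard error (its z-score is undefined). Cross-platform application drops
missing signature features with a warning by default and records
coverage; a strict mode errors instead.

## Evaluation

AUC uses the rank (Mann–Whitney) formulation with half-credit for ties,
cases positive, higher score more disease-like; the ROC curve is a
threshold sweep over unique scores. The two-group test is Welch's by
default (the unequal-variance-safe choice when only "t-test" is
specified; pooled-variance Student is available). The severity trend
reuses the screen's Spearman machinery. PCA standardizes features before
decomposition — the signature mixes features of different scales — and
fixes each component's sign so the first signature feature loads
non-negatively, making sample scores reproducible across runs and feature
orderings.

## Resampling benchmarks

A signature should outperform random signatures of its own size. The
package draws size-matched feature sets from either the whole measured
universe ("genome" pool: every feature present in all validation
matrices) or the severity-associated pool (features passing the gene
screen), evaluates each by its summed AUC over the validation cohorts,
and reports the add-one right-tailed empirical p,
$(\#\{\text{draws} \ge \text{observed}\} + 1)/(n+1)$. Ties count toward
the right tail and the add-one correction keeps $p > 0$; at 1,000
resamples the floor is $1/1001 \approx 0.001$.

Random signatures need an orientation per feature to be scorable — a
point on which signature-benchmarking practice is silent. The package's
convention: use the feature's screen ρ sign when screen records are
supplied; otherwise orient each feature on the fly by the sign of its
Spearman correlation with the cohort's own labels. On-the-fly orientation
gives random signatures their *best-case* direction, biasing the null
upward and making the benchmark conservative — a real signature that
still wins has cleared the harder bar. The flip side is calibration:
against a fixed-sign observed signature, favorably oriented null draws
are stochastically larger, so under a true null the p-value is
right-skewed, not uniform. Calibration studies (and the package's own
null-calibration test) therefore fix orientations a priori through the
screen-records route, which restores exchangeability between the observed
signature and the draws.

# The synthetic generator

`generateDiscovery()` emulates the assumed discovery design: 35 HC, 17
US, and 13 (miRNA platform) / 22 (mRNA platform) CS samples, with the
first 13 CS samples shared. Signal miRNA $i$ follows
$\text{baseline} + d_i \cdot \text{effect} \cdot \text{severity} +
\mathcal{N}(0, \sigma)$; one signal miRNA points down and the rest up,
mirroring the 7-up/1-down split of the reference signature. Each planted
target gene is generated *conditionally on its miRNA's realized
expression* (baseline − coupling × miRNA + noise), which guarantees the
negative-correlation structure the pair filter tests, rather than merely
making it likely. A configurable number of "direct" genes (default 150)
carry a severity trend with no miRNA coupling: they emulate the bulk of
severity-associated genes that are *not* regulated by screened miRNAs —
the realistic situation in which the severity-related resampling pool is
much larger than the signature. Without them the pool would collapse to
the signature itself and the second benchmark would be vacuous ($p = 1$
by construction). The matched prediction table gives planted pairs
mirSVR-like scores uniform in $[-2.0, -1.2]$ and decoys scores in
$(-1.2, -0.1)$, so the cutoff separates them by construction; decoy
*pairs* are random non-planted combinations.

Defaults (severity effect 1.5 SD per step, coupling 1, noise SD 1,
300 miRNA / 2,000 gene features, 8 signal miRNAs × 2 targets, 200
decoys) were chosen once as a plausible, clearly recoverable regime — the
emulated study publishes no effect sizes, so these are testability
choices, not biological estimates. What the generator does **not**
emulate: probe-level effects, batch structure, count-based noise,
platform-specific identifier mismatches, or correlated background genes.
Passing tests on this generator therefore demonstrate that the
*algorithms* are correct and recover planted structure at realistic
sample sizes; they do not certify performance on real microarray data.

`generateValidation()` builds binary cohorts in which case samples are
shifted by $\mathrm{sgn}(\rho_i)\cdot\text{shift}$ on each signature
feature. Background features are pure noise and can be given the
discovery platform's feature names (`backgroundIds`), so that
screen-defined resampling pools remain scorable on validation data, as
they are on real whole-genome validation platforms.

# Problem sizes and determinism

All generators and resampling routines draw from a single seeded
generator in documented order, and the orchestrated pipeline writes a
manifest free of timestamps, so a rerun with the same configuration is
bitwise-identical — the test suite asserts this. The packaged test suite
exercises the oracle-equivalence checks at 1,000 random instances per
statistic, planted-pair recovery at full study scale over 25 seeds,
resampling power over 25 seeds at 200 resamples, and null calibration
over 100 seeds; these sizes were chosen to give stable Monte-Carlo
estimates while keeping a full test run in minutes.

# Known limitations

* Identifier mapping across platforms is assumed solved upstream: the
  score matches signature features to matrix rownames by exact symbol
  and reports coverage. No probe-annotation machinery is included.
* The asymptotic Spearman p-value is slightly anti-conservative at very
  small n; screens at n < 20 should be interpreted cautiously.
* The transductive score is cohort-composition dependent; single-sample
  scoring is undefined by design.
* The anti-correlation test, run on the platform sample intersection,
  loses the complicated-case samples profiled on only one platform.
* Real-cohort results depend on public expression repositories and are
  out of scope for the offline test suite; the acceptance script reports
  synthetic analogues of every headline quantity instead.
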