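---
title: "hashmix: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hashmix: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hashmix)
```

## The demultiplexing problem

In cell hashing, every sample is tagged with a hashtag oligonucleotide
(HTO) before pooling, and each sequenced droplet carries a count vector
over the $n$ HTOs alongside its RNA library. Demultiplexing means
recovering, for droplet $i$, the unobserved indicator vector
$C_i \in \{0,1\}^n$ whose $j$-th entry says whether the droplet contains a
cell tagged with HTO $j$: exactly one positive entry is a single-sample
droplet (SSD), two or more a multi-sample multiplet (MSM), none a negative
droplet. The difficulty is ambient background: every droplet shows some
reads of every HTO, so "positive" and "negative" are overlapping count
distributions, not presence/absence.

`hashmix` assumes empty droplets and low-quality cells were already removed
by transcriptome-based filtering. Droplets with zero detected genes are
rejected at construction (their covariate would enter a logarithm).

## Per-HTO mixture model

For each HTO $j$ independently, the counts $y_{\cdot,j}$ are modelled as a
two-component negative binomial mixture,

$$ f(y_{i,j}) = \pi_1\, h(y_{i,j} \mid \mu_{i,1}, \nu_1)
             + \pi_2\, h(y_{i,j} \mid \mu_{i,2}, \nu_2), $$

where $h$ is the NB pmf in mean/size form (variance
$\mu + \mu^2/\nu$), component 1 is background and component 2 the tagged
population. The key modelling idea is that HTO counts co-vary with droplet
"size": the number of detected genes $x_i$ predicts each component mean
through an NB regression with log link,

$$ \mu_{i,k} = \exp(\alpha_k + \beta_k \log x_i). $$

The log link is used throughout; the strictly canonical NB link is
numerically pathological and never used in practice for NB regression.

Three variants are fitted per HTO:

* `full` — regression in both components;
* `pos_only` — $\beta_1 = 0$ (background counts are often too low to carry
  a usable association);
* `naive` — $\beta_1 = \beta_2 = 0$, a plain NB mixture.

Which variant is best is data-dependent: heterogeneous pools (mixed cell
types) show strong gene/HTO associations, homogeneous pools often do not.
The selected model is the one minimizing the expected number of MAP
classification errors $\sum_i \min(p_i, 1 - p_i)$, where $p_i$ is the
posterior probability of being positive; the sum runs over non-outlier
droplets, since outliers are excluded from all model fitting.

## Fitting

**Initialization.** k-means with $k = 2$ on $\log(y + 1)$ (10 restarts,
caller-supplied seed; the pseudocount keeps zeros admissible — the choice
is documented because any monotone log transform would do). The cluster
with the larger mean count initializes the positive component. Droplets in
the positive cluster above Q3 + 1.5 IQR of positive-cluster counts, and
droplets (either cluster) above Q3 + 1.5 IQR of detected genes, are
flagged as outliers: excluded from fitting, still classified. Quantiles
use the linear-interpolation convention (R type 7).

**EM.** The E-step computes responsibilities by Bayes' rule with
log-sum-exp stabilization; the M-step re-estimates $\pi_2$ as the mean
responsibility and refits each component by weighted maximum likelihood
with the responsibilities as weights. Each weighted NB fit alternates
Fisher-scoring IRLS for $(\alpha, \beta)$ at fixed $\nu$ with a univariate
ML search for $\nu$ on the log scale (inner tolerance $10^{-8}$, at most
50 alternations, $\nu$ capped at $10^6$ with a flag — data at the cap are
effectively Poisson). EM stops when the relative change of the
observed-data log-likelihood falls below $10^{-6}$ (at most 100
iterations); every step increases a minorant, so the likelihood trace is
non-decreasing up to numerical slack, which the test suite asserts at
$10^{-8}$.

**Identifiability and degeneracy.** Components are ordered by the
initialization (component 2 = positive); if label switching occurs, the
components are re-ordered after convergence by their fitted mean at the
average detected-gene count. Two failure modes raise a "component
collapse" error naming the HTO: a mixing proportion below $10^{-4}$, and —
the subtler case — data that are genuinely one NB population. EM on
one-population data converges happily to two heavily overlapping
components, so a proportion floor cannot detect it; instead the fitted
mixture must beat a single-component NB fit by the BIC margin
$\tfrac{1}{2} k_\text{extra} \log m$ ($k_\text{extra}$ = the mixing weight
plus the negative component's parameters). On real two-population HTO data
the likelihood gain is orders of magnitude larger than the penalty, so the
check only fires when the second component is unsupported. In automatic
model selection, variants that collapse or do not converge are simply
excluded; only if all three fail does the HTO error out.

## Classification

Per HTO, the MAP call is positive iff the posterior exceeds 0.5; a tie at
exactly 0.5 is called negative, keeping ambiguous droplets out of singlet
calls. Assuming independence across HTOs, the probability that the whole
estimated vector $\hat c_i$ is correct is the product over HTOs of $p_j$
or $1 - p_j$ (computed in log space). Droplets whose joint probability
falls below the acceptance threshold $p_\text{acpt}$ are labelled
`uncertain`; the default is $0.9^n$, so the per-HTO error budget does not
tighten as more samples are pooled, and it can be overridden (e.g. 0.99
for high-precision designs). Lowering the threshold can only convert
uncertain droplets into classified ones, never flip a classified droplet —
the suite checks this monotonicity.

A single-HTO design ($n = 1$, one tagged sample pooled with untagged
cells) is supported as a first-class case: the classifier reduces to
positive/negative with rejection at $\max(p, 1-p) < p_\text{acpt}$.

## Overlap score

The per-HTO quality metric is the shared probability mass of the two
fitted components,
$\mathrm{ovs} = \sum_{z \ge 0} \min\{h(z \mid \theta_1, \bar x_1),
h(z \mid \theta_2, \bar x_2)\}$, each component evaluated at its
posterior-weighted mean detected-gene count (outliers removed from the
averages; for `naive` models the means play no role). It lies in
$(0, 1]$ — 1 means indistinguishable components — and does not depend on
the mixing proportions, so it compares HTO quality across experiments with
different positive fractions. The infinite sum is truncated where both
component tails hold less than $10^{-9}$ mass; the residual is reported
and asserted below $10^{-8}$.

## Synthetic data

`generate_dataset()` is the package's stated world for testing, not a
tuning dial. Defaults, chosen once:

* detected genes: log-normal, median 1800 (`sdlog` 0.45) — the scale of a
  filtered 10x run;
* tagged counts: NB with $\beta = 0.6$ and median ~1450 reads at the
  median droplet, $\nu = 10$ — a high-quality hashing library with the
  strong positive gene/HTO association seen in heterogeneous pools;
* background counts: $\beta = 0.1$, median ~25 reads, $\nu = 5$ — low
  counts with the correspondingly weak association;
* classes: 5% two-sample multiplets, 5% negatives, singlets uniform over
  samples.

The benchmark transforms mirror the attenuation/doublet design used to
stress demultiplexers: `attenuate_signal()` multiplies only the tagging
HTO's counts by $s \in (0,1]$ (rounded to integers — counts must stay
integral for the NB pmf), and `merge_doublets()` appends artificial
multiplets whose counts and detected genes are the rounded average of two
singlets from different samples (truth row = union; sources kept).
Averaged counts are rounded to nearest rather than floored; the choice is
arbitrary and documented.

What the generator does **not** emulate: ambient-contamination structure
correlated across HTOs, cell-type clusters with distinct tagging
efficiency, same-sample multiplets, or empty-droplet tails. A green
end-to-end test therefore establishes correctness of the algorithmic
chain under the model's own assumptions, not performance on any real
dataset.

The scoring functions follow the standard definitions: precision over
predicted SSDs requires the exact sample to be right; sensitivity over
true SSDs counts any SSD call (uncertain/negative/MSM predictions count
against it); `f_ssd` is their harmonic mean; `precision_msm` and the
predicted MSM proportion are the natural multiplet analogues. With no
predicted SSDs the precision is reported as `NA`, never 0.

## Numerical choices, in one place

* NB pmf via `stats::dnbinom` in log space; posteriors via log-sum-exp.
* IRLS working weights $w \mu \nu / (\mu + \nu)$; linear predictor clamped
  to $[-30, 30]$; a singular design (constant covariate) is an error for
  slope variants, which model selection treats as that variant failing.
* Dispersion search interval $[10^{-4}, 10^6]$ on the log scale.
* Effective-sample-size floor 10 for any weighted component fit.
* Joint probabilities and likelihoods in log space throughout.
* Deterministic given seeds: k-means restarts, the simulator and doublet
  injection take explicit seeds and restore the caller's RNG state.

## Known limitations

* Independence of HTO classifications is an approximation; joint
  probabilities are slightly optimistic when HTO errors are correlated
  (shared ambient contamination).
* Same-sample multiplets are invisible to HTO data and not modelled.
* One covariate only (log detected genes); no offsets or multi-covariate
  designs.
* The expected-error selection criterion is computed on non-outlier
  droplets; with very few droplets per component the criterion is noisy
  and the naive variant tends to win by parsimony of fit, which is the
  conservative direction.
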