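---
title: "immunoscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{immunoscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoscape)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters with
their defaults and units, what the synthetic generators do and do not
emulate, and the decisions taken where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. Random-effects meta-analysis

Each study contributes a standardized mean difference per gene or feature:

$$\mathrm{SMD} = \frac{\bar x_1 - \bar x_2}{s_\mathrm{pooled}}, \qquad
s_\mathrm{pooled} = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}},$$

bias-corrected to Hedges' g with the factor $1 - 3/(4n-9)$, $n = n_1+n_2$
(the bare $n$ in the correction is read as the total sample size — the
standard small-sample form). The standard error

$$\mathrm{SE}^2 = \frac{n_1+n_2}{n_1 n_2} + \frac{g^2}{2(n_1+n_2)}$$

is evaluated at the corrected $g$ (the usual Hedges-g SE convention; the
source formula is printed in terms of the SMD only).

Across $k$ studies the observed effects follow
$\hat\theta_k = \mu + \zeta_k + \varepsilon_k$ with between-study variance
$\tau^2 = \mathrm{Var}(\zeta_k)$ estimated by the DerSimonian–Laird moment
method,

$$\hat\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}
 {\sum w_k - \sum w_k^2 / \sum w_k}\right), \qquad
Q = \sum_k w_k (g_k - \bar g_\mathrm{FE})^2,\; w_k = 1/\mathrm{se}_k^2,$$

and studies pooled with weights $w^*_k = 1/(\mathrm{se}_k^2 + \hat\tau^2)$:
estimate $\sum w^* g / \sum w^*$, SE $\sqrt{1/\sum w^*}$, two-sided normal
p-value (sidedness was unstated; two-sided is the conservative default).
The $Q$ statistic is not printed in the source; the standard DL form above
is used. $k=1$ is allowed (the pooled row reduces to the single study's
g/SE, $\tau^2 := 0$ with a warning).

**Multiple testing.** The correction behind "FDR < 0.05" is not named in
the source; Benjamini–Hochberg step-up is used (the convention of the
meta-analysis framework the source builds on) and applied across all rows
of one (disease, compartment) stratum. Genes absent from some studies are
pooled over the studies that carry them, with `k` recorded per row; the
minimum-k threshold is configurable (`min_studies`, default 1).

**Known behavior of the Wald-DL interval.** The 95% CI
`estimate ± 1.96·se` with DL $\tau^2$ is known to undercover slightly at
small $k$; at $k=8$, $\tau^2 = 0.1$, $n = 50+50$ the acceptance suite
measures coverage near 91%, inside the accepted 90–98% band but close to
its lower edge. A Hartung–Knapp adjustment would improve coverage but
would change the SE definition away from $\sqrt{1/\sum w^*}$, so it is not
used.

## 2. Higher-order features

**ssGSEA.** For one sample, genes are ranked by expression (descending;
ties broken by input order, which keeps the statistic well-defined and
deterministic). Walking down the ranking, an in-set CDF weighted by
$\mathrm{rank}^\alpha$ (the gene at position $i$ of $N$ has weight
$(N-i+1)^\alpha$) is compared with the unweighted out-of-set CDF; the
score is the signed maximum deviation between the two running
distributions. Because both CDFs end at 1, the maximum-deviation statistic
is already normalized to $[-1, 1]$: a set occupying the top $|S|$ ranks
attains exactly $+1$ for any set size and $\alpha$, so the "divide by the
maximum attainable deviation" normalization is the identity. The source
describes the method abstractly and implementations differ, so both the
exponent (`alpha`, default 0.25 — a mild rank weighting between the
unweighted ECDF at 0 and the steep weighting at 1) and a
"sum of the running difference" aggregation variant are exposed; the sum
variant *is* normalized, by the value the sum attains in the top-ranks
configuration. Scores are invariant under strictly monotone transforms of
the expression vector, which is what makes them comparable across
platforms. Sets with fewer than `min_overlap = 5` genes present are
dropped: below that, the running-sum statistic is dominated by single
genes.

**Cell-mixture deconvolution.** The source states only a "linear modeling
framework" against a reference basis matrix. We solve non-negative least
squares (Lawson–Hanson active set, implemented in the package — base R has
no NNLS) of the sample against the basis on shared genes, then clip at 0
and renormalize to proportions summing to 1. Mixing is linear in
abundance, so log2-scale studies are de-logged ($2^x - 1$) before
fitting; the basis itself is a linear-scale user input. A rank-deficient
basis makes proportions unidentifiable and triggers a warning at
construction.

**Cytokine panel.** A plain row subset of the expression matrix restricted
to a user-supplied panel (the source used a curated list of 275
cytokine/chemokine/receptor genes); missing panel genes are counted and
logged, and gene identifiers are matched as case-sensitive strings with no
alias resolution.

## 3. Landscape and modules

Pooled per-disease tables are aligned into a features × diseases effect
matrix with a parallel FDR matrix; cells absent from a disease are
explicitly missing, never silently zero. The significance filter keeps
features with minimum FDR across diseases below the threshold
("significant in at least one disease", default 0.05).

Feature–feature similarity is the Spearman correlation of the per-disease
pooled-effect profiles (pairwise-complete; pairs sharing fewer than 3
diseases are zeroed and flagged). Correlation across the *disease* axis is
the documented reading of the source's "correlations between features
across diseases"; with 10 diseases each correlation rests on 10 points,
which bounds how sharply modules can be resolved.

**Linkage.** The source does not state the clustering distance or linkage.
We cluster on $d = 1 - \rho$ and default to **Ward (ward.D2)** linkage,
with average and complete as options. This is a deliberate deviation from
the more common average-linkage default: on planted-module benchmarks
(15 modules of 20 features, within-module correlation 0.9, 10 diseases,
run by the acceptance suite) Ward recovers the planted partition with mean
adjusted Rand index above 0.9 while average linkage stays near 0.85, and an
independent scipy replication reproduces the gap. Ward's preference for
compact, balanced groups matches what a k-cut of a feature correlogram is
meant to produce. The dendrogram is cut into exactly `k` groups
(default 15).

**Cluster-number robustness.** The source reports a perturbation analysis
without specifying it; ours is an explicit stand-in and fully
parameterized. The landscape is perturbed `n_perturbations` times with
additive Gaussian noise at `noise_sd_fraction` (default 0.1) of the
effect-matrix SD; stability is the mean ARI between the re-clustered and
original partitions. The null shuffles each feature's profile across
diseases independently (destroying inter-feature correlation, preserving
margins) and recomputes the same stability; `p = (1 + #null ≥ obs)/(1 +
n_null)`. Because the permutation p is discrete with granularity
$1/(n_\mathrm{null}+1)$, `n_null` should be chosen so the attainable
p-values straddle the intended threshold sensibly; the acceptance suite
uses `n_null = 40`, where the only attainable value below 0.05 is
$1/41 \approx 0.024$.

Module labels are free-text metadata: the source's 15 module names came
from manual literature curation, which is out of scope; the package emits
membership and accepts user labels.

## 4. Module scoring and validation

Module activity per sample is the sum of the module's feature rows after
per-feature z-scaling across the dataset's samples ("scaled across
samples" is read as z-scaling; zero-variance features contribute 0 rather
than NaN). Missing features are skipped with per-module coverage recorded.

Discrimination is the Mann–Whitney AUC, $P(\text{case} > \text{control}) +
\tfrac12 P(\text{tie})$, with the rank-sum p-value. Per (module, disease,
compartment), AUCs are aggregated as mean, SD across studies, stability
$1/\mathrm{SD}$ capped at $1/0.01$ (an uncapped zero-SD group would be
infinite; the cap is documented, the source prints dot sizes only), and a
Fisher-combined p over per-study p-values (clipped below at 1e-300). With
a single study the stability is flagged `NA` rather than invented.

The permutation test draws `n_perm` random modules of the target's size
from the features of the *other* modules (without replacement within a
draw), scores each the same way, and z-transforms the observed Hedges' g
of the target against the null; `p` is the two-sided normal tail as in the
source, with the empirical tail reported alongside because at
`n_perm = 1000` the empirical p cannot go below ~1e-3.

Treatment-response AUC reports its direction explicitly
(`lower_in_responders` vs `higher_in_responders`) instead of silently
flipping — the biologically expected signal for an inflammation module
under an anti-inflammatory is *lower* baseline activity in responders.
Severity association is a Spearman correlation with pairwise-complete
handling of missing clinical scores (≥ 4 pairs required).

## 5. The synthetic world

`generate_study` plants effects on the standardized scale: control samples
are $N(b_g, \sigma^2)$, cases $N(b_g + \theta_{kg}\sigma, \sigma^2)$ with
$\theta_{kg} = \mu_g + \zeta_{kg}$, $\zeta_{kg} \sim N(0, \tau^2)$ — the
generative inverse of the analysis model, so the true Cohen's d is
$\theta_{kg}$ by construction. Baselines default to Uniform(4, 10) log2
units (a typical microarray log-intensity range) with $\sigma = 1$;
generated values are truncated at 0 and flagged as already log-scale so
generator tests stay orthogonal to the harmonization path. Every generator
is a pure function of its seed, with per-study substreams derived from
(seed, study index).

`generate_planted_landscape` gives features of module $m$ the profile
$\sqrt{\rho}\, z_m + \sqrt{1-\rho}\, e_f$ over diseases, so any two
same-module features have correlation exactly $\rho$
(`within_module_correlation`) and different modules are independent. At
the benchmark setting ($\rho = 0.9$, 10 diseases) the *sample* Spearman
correlation per pair rests on 10 points, which is why per-seed recovery
hovers around ARI 0.85–0.97 and the acceptance criterion is asserted on
the mean across seeds.

`generate_mixture_study` produces linear-scale expression
$B p + N(0, \sigma^2)$ truncated at 0, with the true proportions stored as
ground truth.

What the generators do **not** emulate: platform/probe effects,
library-size gradients, correlated gene–gene noise within a study,
missing-not-at-random metadata, or single-cell structure. A green test
therefore establishes correctness of the statistical machinery under its
own model assumptions — not robustness to the full messiness of repository
data.

## 6. Data handling conventions

- Matrices with a maximum above 50 are treated as linear-scale and
  log2(x+1)-transformed; at or below 50, as already log (no log2
  expression reaches 50; the threshold is configurable). Raw counts go
  through TPM (gene lengths required) before the log.
- Duplicate gene rows are collapsed by mean (platform-agnostic and
  symmetric; the source delegates probe summarization to its upstream
  framework).
- Inclusion filters: ≥ 4 subjects per study, baseline samples only where a
  timepoint column distinguishes visits, treated samples dropped where a
  treatment column exists. Missing optional metadata passes the filter
  with a logged warning — exclusion only applies "when such information
  was available". Studies left without both classes are dropped.
- Compartment overlap is reported as intersection-over-union *and* as
  per-compartment fractions, since the source's pie charts do not pin the
  denominator.

## 7. Numerical and degenerate-input conventions

- Zero pooled SD in one study makes that study's effect undefined for that
  gene; the row is pooled over the remaining studies (scalar `hedges_g`
  raises a degeneracy error instead).
- All-tied AUC inputs give AUC 0.5 and p 1 without calling the rank-sum
  machinery (its normal approximation degenerates under total ties).
- Fisher's combination rejects p = 0 (callers clip; the aggregation step
  clips at 1e-300).
- ssGSEA ties in expression are broken by gene order; the statistic is
  otherwise rank-based and scale-free.
- Seeds derived from a master seed stay below $2^{31}$.

## 8. Known limitations

- No REML/Paule–Mandel τ² estimators, no leave-one-study-out diagnostics,
  no Hartung–Knapp CI (see §1).
- No probe-level microarray handling, no batch correction (the
  meta-analysis weighting is the source's answer to cohort effects).
- The perturbation design for cluster-number robustness is a documented
  stand-in for an unspecified procedure; its p-value is meaningful
  relative to its own shuffled null, not as a test of the "true" number of
  modules.
- Module discovery needs ≥ 4 diseases; with few diseases the Spearman
  profiles are too short to cluster meaningfully.
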