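---
title: "Bayesian models for protein-truncating variant association"
author: "ptvbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian models for protein-truncating variant association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptvbayes)
```

# The problem

Protein-truncating variants (PTVs) — stop-gains, frameshifts and
splice-disrupting variants — are individually too rare to test against a
quantitative trait, but share a predictable consequence: loss of function
of one gene copy. `ptvbayes` aggregates the PTVs of a gene into a single
Bayesian model comparison on the carriers' trait values, producing a Bayes
factor (BF) that can be read as evidence directly, used to rank genes for
follow-up, or calibrated into a frequentist test statistic.

# Model and assumptions

Let N individuals have standardized trait values, of which n carry one of
the gene's k PTVs (z denotes the carriers' values). The framework assumes:

* **Standard-normal cohort.** Traits are quantile-normalized: the value at
  rank r maps to $\Phi^{-1}((r-0.5)/N)$. This bounds the influence of
  phenotype outliers — an extreme raw measurement, whatever its cause, is
  compressed to the grid extreme $\Phi^{-1}((N-0.5)/N)$ — at a small cost
  in power when a PTV truly causes extreme values. Without it, individuals
  with artifactual outlier measurements would generate false signals at
  whichever genes they happen to carry a PTV in.
* **At most one PTV per individual.** PTVs are rare; individuals carrying
  two PTVs in the same gene are excluded by default (configurable to
  attribute them to their first variant). Homozygous carriers are kept in
  the single carrier class (dominant coding) or optionally excluded.
* **Unit carrier variance.** Carrier values are modelled N(μ, s²) with
  s = 1 fixed; with the handful of carriers typical for PTVs there is
  little information to estimate a variance change.

**Similar effects model (SEM).** All carriers share one mean shift μ with
prior $\mu \sim \tfrac12 N(+\mu_0,\sigma_0^2)+\tfrac12 N(-\mu_0,\sigma_0^2)$,
symmetric because the direction of a loss-of-function effect is rarely
predictable. Non-carriers have the same distribution under both
hypotheses, so they cancel from the BF, which reduces to a closed-form
function of (n, z̄): each mixture component contributes
$-\tfrac12\log(1+n\sigma_0^2) + B^2/2A - \mu_0^2/2\sigma_0^2$ in log
space, with $A = n + 1/\sigma_0^2$ and $B = n\bar z \pm \mu_0/\sigma_0^2$.
The posterior of μ is the exact two-component conjugate mixture with
component variances $1/A$.

**Grouped effects model, NMD-informed (GEM-NMD).** Some PTVs escape
nonsense-mediated decay — canonically those whose premature termination
codon lies within 50 bases of the final exon–exon junction or in the final
exon — and may act as loss of function, gain of function, or not at all.
GEM assigns variants to two groups with independent priors
$\mu_+ \sim N(+\mu_0, \sigma_0^2)$, $\mu_- \sim N(-\mu_0, \sigma_0^2)$;
the BF of one grouping factorizes over the groups, and the model BF is the
weighted average $\sum_g w_g BF_g$. Averaging over all $2^k$ groupings
costs power when n is small, so the supported default concentrates the
weight on the NMD-informed groupings.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mu0` | 1.5 | trait SD | prior effect-size magnitude for a truncating variant |
| `sigma0Sq` | 0.5 | SD² | prior spread around ±`mu0` |
| `s` | 1 | SD | carrier sampling SD (fixed) |
| GEM-NMD weights | ¼ each | — | all+, all−, triggers+/escapers−, mirror |
| NMD boundary | 50 | transcript bases | distance-to-junction rule threshold |
| Bonferroni denominator | 20000 | genes | default exome-wide α = 2.5×10⁻⁶ |

The legible published record of the hyperparameters is the table of
analytic SEM critical values; `mu0 = 1.5`, `sigma0Sq = 0.5` reproduce all
twelve tabulated cells to better than 0.5%, and the acceptance suite
asserts exactly that. The same reasoning fixes the default GEM-NMD weights
at ¼ per NMD-informed grouping: they are the natural uniform choice over
the four groupings, they collapse exactly to the SEM when the NMD
partition is degenerate (duplicate groupings are merged, weights summed),
and the published GEM-NMD critical values — which were Monte-Carlo
estimates under unpublished weights — are deliberately *not* asserted.
Both the prior and the weights are arguments everywhere
(`modelHyper()`, `groupingScheme()`).

Two conventions are fixed package-wide after deliberate choice:

* **Two-sided tails.** The prior is symmetric, the Collapse p-value is
  two-sided, and the carrier-count arithmetic (8/14/31 carriers for
  effects 2/1.5/1 SD at α = 0.05/20000, 80% power) only reproduces under
  two-sided α.
* **Boundary of the 50-bp rule.** A termination codon *exactly* 50 bases
  upstream of the final junction is classified *escape*: the rule is
  stated as "more than 50 bp upstream triggers", and observed escape
  within 50 bp motivates grouping; `classifyNmd(..., boundary = )`
  exposes the threshold. Splice-disrupting variants default to *trigger*
  (their mis-spliced product is assumed degraded) and can be overridden
  per variant via the annotation's `nmd_override` column. Frameshifts use
  the variant position as a proxy for the termination position —
  computing the true downstream stop would require sequence translation,
  which is out of scope; the override column is the escape hatch.

# Calibration

Used as a frequentist statistic, the SEM BF is strictly increasing in
|z̄| for fixed n while $\sqrt n\,\bar z$ is standard normal under the
null, so critical values are analytic
(`semCriticalValue`) and p-values come from inverting the BF by monotone
bisection on z̄ ∈ [0, 20] to 10⁻¹² relative tolerance
(`semPvalueFromBF`); they equal the Collapse p-values on the same data.
GEM-NMD mixes groupings of both signs, so its null distribution is
simulated (`gemCriticalValueMC`): carrier values i.i.d. N(0,1), default
10⁶ replicates (published tables used 10⁷; the desk-scale default is
documented and the replicate count is always recorded in the output), the
critical value is the order statistic at ⌈(1−α)R⌉, and the 95% CI uses
the order-statistics form of the empirical-quantile bootstrap (bootstrap
ranks drawn from Binomial(R, 1−α)), which is exact for this functional
and avoids resampling cost. Seeds are mandatory and recorded.

Although SEM and Collapse are frequentist-identical at fixed n, the BF
and the p-value rank genes *differently* across n. At a fixed p-value of
0.001 the SEM BF, as a function of n, rises and then falls
(`bfAtFixedPvalue`): tiny n needs implausibly large carrier means that
the prior discounts, while large n corresponds to small shifts that the
alternative also finds unlikely — Lindley's paradox. This is why ranking
discovery genes by BF, which self-adjusts for carrier count, is
preferred.

# What the simulator emulates — and what it does not

`simulateCohort` draws the stated world of the power studies: N = 2000
individuals, 3–5 PTVs each carried by one individual, carrier values
mean-shifted normals with unit variance (trigger +2 SD, escape −2 SD by
default — consistent with the 2/1.5/1 SD design grid; the generating
parameters behind the published power percentages are not legible, so
those percentages are not asserted), one variant escaping NMD in the
grouped scenario, and an `artifact` scenario in which one labelled PTV is
spurious and its carrier's value is standard normal. Optional quantile
normalization after drawing is supported in both power paths; whether the
published simulations normalized is unknown, so both modes are exposed
and the analytic cross-checks run on the un-normalized path.

The generator does **not** emulate: linkage between variants, covariate
structure (age, sex, ancestry), genotype uncertainty or call errors
beyond the single-artifact scenario, between-gene sharing of carriers, or
non-normal trait tails after normalization. A green power test therefore
establishes the statistical machinery under the stated sampling model,
not robustness to cohort artefacts beyond phenotype outliers.

Fixture emission (`generateFixture`) is synthetic by construction: each
gene gets its own contig and a two-exon transcript (600 + 300 nt), with
trigger variants placed >50 bases upstream of the junction and escape
variants in the final exon, so the readers reconstruct the configured
ground truth exactly — on either strand, via the shared transcript
coordinate mapping.

# Numerical choices

* All BF arithmetic is in natural-log space with log-sum-exp; outputs are
  reported in log10 in tables (published magnitudes span 10⁰–10³) and
  natural log in JSON.
* Full grouping enumeration is capped at k ≤ 20 (2²⁰ groupings); larger
  genes require sparse schemes.
* Ties under quantile normalization receive the mean of their tied ranks'
  transformed values, computed by cumulative sums over the quantile grid.
* Empty groups in a GEM grouping contribute a factor of 1 to the BF and
  the prior as their posterior.
* Degenerate inputs: zero carriers give BF = 1 with a warning and the
  prior as posterior; a BF below the minimum attainable inverts to
  p = 1; missing genotypes count as non-carriers (tallied); multiallelic
  VCF records are rejected with instructions to pre-split.
* `cohortSizeForCarriers` uses exact binomial tails with bisection over
  N — no normal approximation, since carrier fractions of 10⁻³ at small
  target counts are deep in the skewed regime.

# Known limitations

* Only two effect groups are modelled; more groups (e.g. separating
  gain-of-function final-exon variants from neutral ones) would be a
  natural extension of the grouping scheme.
* The per-variant effect posteriors under GEM-NMD are model-averaged
  group posteriors; with one carrier per variant they are weakly
  identified and lean on the prior.
* No consequence annotation is performed: the annotation table (or an
  upstream annotator) must already designate stop-gain / frameshift /
  splice-disrupting status and the affected transcript.
* Normality checking of normalized traits in the test suite uses
  Shapiro–Wilk (no Anderson–Darling implementation is available in the
  dependency set); for the exact-grid output of quantile normalization
  the distinction is immaterial.
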