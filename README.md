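# ptvbayes

Gene-based Bayesian association testing between **protein-truncating
variants** (PTVs — stop-gain, frameshift and splice-disrupting variants,
often called loss-of-function variants) and **quantitative traits**.

PTVs are rare, so single-variant tests are underpowered; evidence must be
aggregated across the PTVs of a gene. Unlike arbitrary missense variants,
PTVs have a near-uniform predicted consequence — loss of that gene copy —
which motivates a model in which all carriers share one effect, refined by
whether each variant is predicted to trigger or escape nonsense-mediated
decay (NMD). `ptvbayes` is aimed at analysts of exome/genome sequencing or
exome-array cohorts with measured quantitative phenotypes (lipids,
anthropometrics, biomarkers) who want per-gene evidence that is comparable
across genes with different carrier counts.

## The models

Traits are quantile-normalized so the cohort is standard normal. For a gene
with k PTVs carried by n individuals with trait values z = (z₁..zₙ) (at
most one PTV per individual):

* **Null model** — z_i ~ N(0, 1).
* **SEM** (similar effects model) — z_i ~ N(μ, 1) with prior
  μ ~ ½N(+μ₀, σ₀²) + ½N(−μ₀, σ₀²); defaults μ₀ = 1.5, σ₀² = 0.5.
  The Bayes factor BF = m(z)/∏φ(z_i) has a closed form depending on the
  data only through (n, z̄).
* **GEM-NMD** (grouped effects model) — variants are assigned to two
  groups with means μ₊ ~ N(+μ₀, σ₀²) and μ₋ ~ N(−μ₀, σ₀²); the BF averages
  over groupings g with weights w_g (Σw_g = 1), by default ¼ on each of:
  all +, all −, NMD-triggers +/escapers −, and its mirror. A premature
  termination codon more than 50 bases upstream of the final exon–exon
  junction is predicted to trigger NMD; otherwise it escapes.
* **Collapse** — the frequentist baseline T = √n·z̄ ~ N(0, 1) under the
  null. The SEM BF used as a test statistic has exactly the same power and
  p-values for fixed n, but BF-based and p-value-based *rankings across
  genes* differ, and the BF ranking accounts for each gene's carrier count.

Calibration utilities turn the BFs into frequentist tests (analytic
critical values and p-values for SEM, Monte-Carlo for GEM-NMD), and power
calculators answer design questions such as how many carriers are needed
for exome-wide significance.

## Worked example

A synthetic 2760-sample cohort with one gene carrying two PTVs (allele
counts 1 and 8, carriers' triglyceride-like trait lowered by 1.3 SD):

```r
library(ptvbayes)
fx <- generateFixture(
  list(fixtureGene("APOC3", nTrigger = 2, nEscape = 0,
                   carriersPerVariant = c(1L, 8L), effectTrigger = -1.3,
                   consequence = c("stop_gain", "splice_disrupting"))),
  nSamples = 2760, dir = tempfile(), seed = 42)
cohort <- quantileNormalize(readPhenotypes(fx$phenotypes))
ext <- extractGeneCarriers(fx$vcf, readPtvAnnotation(fx$annotation),
                           cohort, readExonModel(fx$exons))
geneAssociation(ext$genes, cohort)
#>   gene_id k n mean_carrier_trait log10_bf_sem log10_bf_gem_nmd  p_sem
#> 1   APOC3 2 9             -0.678      0.00265          0.00265 0.0419
#>   p_collapse posterior_effect_mean rank_by_bf rank_by_p
#> 1     0.0419                -0.809          1         1
```

The gene's 9 carriers average 0.68 SD below the cohort mean; the SEM Bayes
factor is ~1 (log10 ≈ 0.003, weak evidence at this effect size and carrier
count), the BF-derived p-value equals the Collapse p-value (0.042), and
the posterior mean carrier effect is −0.81 SD:

```r
z <- carrierValues(geneCarrierTraits(ext$genes$APOC3, cohort))
post <- semPosteriorMu(z)
posteriorMean(post)      # -0.81
credibleInterval(post)   # -1.41 -0.16
```

Critical values for using the BF as a frequentist test statistic:

```r
calibrationTable(alphas = c(0.01, 0.001), ns = 3:5, models = "SEM")
#>   model alpha nptv critical_bf ...   method
#> 1   SEM 0.010    3       8.765 ... analytic
#> 2   SEM 0.010    4       7.774 ... analytic
#> 3   SEM 0.010    5       6.811 ... analytic
#> 4   SEM 0.001    3      64.564 ... analytic
#> 5   SEM 0.001    4      63.985 ... analytic
#> 6   SEM 0.001    5      60.069 ... analytic
```

And the study-design arithmetic: at exome-wide Bonferroni significance
(α = 0.05/20000) and 80% power, carrier mean shifts of 2, 1.5 and 1 SD
need `minCarriersForPower(2)` = 8, `minCarriersForPower(1.5)` = 14 and
`minCarriersForPower(1)` = 31 PTV carriers;
`cohortSizeForCarriers(8, f = 0.001)` gives the cohort size at which a
gene with carrier frequency 0.1% yields 8 carriers with 80% probability.

## Command line

A thin wrapper lives at `inst/cli/ptvbayes` (on the installed package:
`system.file("cli", "ptvbayes", package = "ptvbayes")`):

```sh
ptvbayes assoc     --config run.json          # VCF + TSVs -> association table
ptvbayes calibrate --alpha 0.01 --nptv 3 --model sem
ptvbayes power     --scenario grouped_nmd --n-carriers 4
ptvbayes simulate  --dir fixture_dir
```

Configs are JSON; flags override config fields; every `assoc` run writes
its resolved config next to its outputs.

## Acceptance script

`scripts/acceptance.R` recomputes, with the installed package, the minimum
PTV carrier counts for 80% power at the exome-wide Bonferroni level for
carrier effects of 2, 1.5 and 1 SD, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
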