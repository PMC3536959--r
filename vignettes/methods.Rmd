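---
title: "Models and methods behind exomassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind exomassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomassoc)
```

`exomassoc` implements the statistical core of a multi-stage
sequencing-based association study: read-level discovery and testing in a
medium-depth (≈8×) exome-sequenced case–control panel, genotype-based
association in a larger follow-up panel, and fixed-effects meta-analysis
across replication cohorts. This vignette describes the models, the
defaults and why they were chosen, what the synthetic-data generator does
and does not emulate, and the numerical decisions that matter.

## The read-count data model

The unit of stage-1 data is the quality-filtered base count: for site $s$
and individual $i$, the number of sequenced bases read as A, C, G and T.
Per-base qualities are used **only** to filter (Phred ≥ 20 by default,
`quality_filter()`); after filtering, read errors are described by a
single global 4×4 type-specific substitution matrix $e(a \to b)$ rather
than per-base qualities. This replaces thousands of per-read nuisance
parameters with 12 rates that can be estimated extremely precisely from
the data themselves, and it is robust to miscalibrated quality strings.
The matrix is strand-free and shared across individuals; batch-specific
matrices can be obtained by running `estimate_error_model()` on subsets.

Given major allele $M$, candidate minor allele $m$, and genotype $g \in
\{0,1,2\}$ copies of $m$, each read is minor-derived with probability
$g/2$, so

$$P(D_i \mid g) = \prod_{\text{reads } b}
  \left[\tfrac{g}{2}\,P(b \mid m) + \left(1-\tfrac{g}{2}\right) P(b \mid M)\right],$$

computed in log space as a sum of $n_b \log p_b(g)$ terms
(`genotype_likelihoods()`). The contract is exactness to 1e-12 relative
at depths up to 10⁴; a zero-depth individual has the flat triple
$(1,1,1)$. Likelihoods are stored rescaled so the per-individual maximum
is 1, which leaves every downstream quantity (EM weights, likelihood
ratios) unchanged.

## EM allele-frequency estimation with minor-allele uncertainty

Under Hardy–Weinberg proportions $\{(1-f)^2,\,2f(1-f),\,f^2\}$ the site
likelihood is $L(f)=\prod_i \sum_g P(D_i\mid g)\,\mathrm{HWE}(g;f)$,
maximised by EM (`ml_maf()`): weights $w_i(g)\propto P(D_i\mid
g)\,\mathrm{HWE}(g;f)$ and update $f' = \frac{1}{2N}\sum_i\sum_g g\,
w_i(g)$. The log-likelihood is non-decreasing every step (tested);
iteration stops at $|\Delta f| < 10^{-6}$ or 200 iterations. The EM is
initialised at the naive read-fraction estimate floored at $10^{-4}$ —
fast, and it avoids stalling at the $f=0$ boundary. $f$ is the frequency
of the *designated* candidate allele and may exceed 0.5 during
estimation; relabelling ($f \to 1-f$, swap alleles, flag) happens post
hoc, which avoids constrained optimisation.

At low depth the identity of the minor allele is itself uncertain, so
`ml_maf_minor_sum()` fixes the major allele at the most-supported pooled
base and sums the likelihood over the three candidate minors with a
uniform 1/3 prior (no evidence was available to prefer other weights),
each component evaluated at its own EM optimum. Evaluating at per-minor
optima (rather than one shared $f$) is one of two defensible readings of
the construction; it upper-bounds the shared-optimum version and is
simpler to reason about, and the reported $\hat f$/minor come from the
maximal component either way. Exact ties between minors are broken
deterministically in allele order A < C < G < T and flagged.

## Error-rate estimation from putative polymorphic sites

Discovery is two-pass (`discover_snps()`): a fast pass with a uniform
0.25% error matrix flags putative polymorphic sites (estimated frequency
above 0.25%); those sites then feed an EM for the error matrix
(`estimate_error_model()`), and the final pass re-estimates all
frequencies with the learned matrix.

The error EM iterates: (i) genotype likelihoods and per-site frequencies
under the current matrix; (ii) each observed base gets a posterior over
its true allele — 0 for genotype 0, $P(b|m)/(P(b|m)+P(b|M))$ for
heterozygotes, 1 for genotype 2, mixed over the genotype posterior;
(iii) expected true-vs-observed counts are tabulated with a +1
pseudocount per cell (keeping all rates positive and log-likelihoods
finite) and row-normalised. Iteration stops when no off-diagonal rate
moves by more than $10^{-6}$. Whether putative heterozygotes should be
excluded from error tabulation is not a settled question; the soft
posterior weighting used here neither excludes nor fully trusts them,
and simulation recovery (±20% relative at the 2,000 × 500 × 8× design;
typically within a few percent) supports it. Alleles never observed as a
true allele keep their current rates instead of a flat pseudocount row.

## Stage-1 association: the read-level LRT

`lrt_case_control()` tests $f_\text{case} = f_\text{control}$ directly on
likelihoods, with no genotype calls and no covariates:
$T = 2[\ell(\hat f_\text{case}) + \ell(\hat f_\text{control}) -
\ell(\hat f_\text{all})] \sim \chi^2_1$. Asymptotic $\chi^2_1$ is assumed
(no permutation fallback in the core path); tiny negative $T$ from the
finite EM tolerance is clamped to 0, and non-identifiable sites (flat
likelihoods throughout) report $p = 1$ with a flag. Sites enter the test
only if $\hat f > 1\%$ and mean depth exceeds 0.5× per individual
(strict inequalities, so reported counts are exactly reproducible).

Because sequencing batches can correlate with case–control status, three
switchable per-site bias filters (`bias_filters()`, default flag at
$p < 10^{-4}$) operationalise pre-association artefact screening: a
tie-corrected rank-sum test of per-individual depth between groups, a
chi-squared test of zero-depth status against group, and a chi-squared
test of *error-like* read support (bases matching neither site allele)
across batch labels. The batch test deliberately uses off-allele rather
than minor-allele reads: minor-allele counts cluster within individuals
through their genotypes, which overdisperses a read-level test, while
off-allele reads are independent at read level and respond directly to a
batch error-rate shift. These filters are this package's
operationalisation of an under-specified screening step, and each can be
switched off.

Genomic control (`genomic_control()`) uses
$\lambda = \mathrm{median}(\chi^2)/\mathrm{qchisq}(0.5, 1)$ — the exact
χ²₁ median 0.45494, rather than the rounded 0.4549 constant — deflating
statistics only when $\lambda > 1$.

## Stage 2: genotype-based association

Genotype QC (`snp_qc()`) applies MAF > 0.5%, call rate > 95% and exact
Hardy–Weinberg $p > 10^{-7}$, all strict. The HWE test is the exact
conditional test (heterozygote count given allele counts,
$P(h) \propto n!\,2^h / (n_{AA}!\,n_{Aa}!\,n_{aa}!)$), the field
standard for QC where the χ² approximation misbehaves at low MAF.

Quantitative traits are rank-inverse-normal transformed
(`rank_inverse_normal()`): $\Phi^{-1}((r - 0.5)/n)$ with average ranks
for ties; the $0.5$ offset is the standard symmetric choice. Association
on the transformed scale is invariant to any monotone transform of the
raw trait that preserves ties. `assoc_additive()` fits additive linear
or log-additive logistic regressions per SNP (complete-case; missing
genotypes are never mean-imputed), Wald-tested, with the first principal
component of the individual×individual genotype covariance
(`pca_first_component()`, pairwise-complete over missing calls, sign
fixed by the largest-magnitude loading, optionally on a seeded 10,000-SNP
subset for scalability) and sex as default covariates. Conditioning
SNPs enter as extra dosage covariates; a SNP conditioned on itself is
collinear and flagged rather than silently dropped. Separated or
non-converged logistic fits report a missing p-value with a flag.

Enrichment of true associations among a selected SNP set uses a
Storey-type estimator at $\lambda^\ast = 0.5$:
$\pi_0 = \#\{p > 0.5\}/(0.5\,m)$ clipped to $[0,1]$, $\pi_1 = 1 - \pi_0$,
expected true count $\mathrm{round}(\pi_1 m)$. The specific estimator
behind published enrichment fractions is rarely stated; the Storey form
at $\lambda^\ast=0.5$ is the simplest standard choice and the reported
count identity ($\pi_1 = 3.1\%$, $m = 1{,}681 \Rightarrow 52$) holds for
any estimator of the fraction.

## Stage 3 and meta-analysis

`select_stage3()` keeps per-trait hits below 10⁻³ (type 2 diabetes,
obesity, BMI, waist circumference, fasting glucose/insulin) or 10⁻⁴
(all other traits, including the lipids), prunes SNPs in LD
($r^2 > 0.2$ on a phased haplotype panel) with a same-trait known lead
SNP, and for lipid traits additionally removes anything within ±250 kb
of a known SNP. A SNP absent from the panel is kept with a warning —
follow-up is a selection step, and silently dropping unverifiable SNPs
would bias it conservative.

Meta-analysis is fixed-effects in both flavours (`meta_samplesize()`,
`meta_inverse_variance()`). The z-construction is two-sided p plus
direction ($z_i = \Phi^{-1}(1-p_i/2)\,\mathrm{sign}_i$, combined
$Z = \sum\sqrt{n_i} z_i / \sqrt{\sum n_i}$), the convention of the
standard GWAS meta-analysis tools; this is stated explicitly because the
scheme name alone does not pin it down. Inverse-variance pooling reports
$\mathrm{OR} = e^{\hat\beta}$ with a 95% Wald CI. Cochran's Q is computed
and reported but never used to exclude: no heterogeneity filtering is
applied. A discovery cohort enters the combined meta-analysis exactly
like a replication cohort. The final threshold is Bonferroni,
$\alpha/(n_\text{SNPs} \times n_\text{traits})$
(`bonferroni_threshold()`), reported at 2 significant figures alongside
full precision.

## The synthetic cohort generator

`simulate_genotypes()` draws diallelic sites with minor-allele
frequencies uniform on [1%, 50%] by default — the common-variant
discovery floor of the design — and genotypes i.i.d. from HWE. The
default panel is 1,000 cases and 1,000 controls, the discovery-stage
scale. Case status follows a logistic liability
$\mathrm{logit}\,P(\text{case}) = \alpha + \sum_j \log(\mathrm{OR}_j) g_j$
with $\alpha$ solved (by Monte-Carlo root-finding) so the population
prevalence matches the configured value; 8% is the default, a realistic
adult type-2-diabetes-scale prevalence. The cohort is then ascertained by
rejection sampling until the case/control quotas are filled. Extreme
ascertainment of this kind inflates observed case–control frequency
differences relative to the population odds ratios — intentionally, as
that is the design being emulated; logistic effect estimates remain
consistent under case–control sampling. The real study selected cases on
a joint phenotype (disease, adiposity, blood pressure); a single binary
liability is simulated because the joint ascertainment model is not
quantitatively specified anywhere, and inventing one would suggest
false fidelity.

Quantitative traits are additive, $y = \sum_j \beta_j g_j + \varepsilon$,
with noise scaled to hit a target narrow-sense heritability
(`trait_config()`); a zero heritability target with nonzero effects is
rejected as inconsistent. Sex is Bernoulli(0.5) and carried only as a
covariate — no X-chromosome dosage is simulated.

`simulate_reads()` draws per-cell depth Poisson with mean
`mean_depth * q_pass_rate` (a fixed-depth mode exists for exact oracle
tests), picks each read's true allele from the genotype, and corrupts it
through the error matrix. `mean_depth = 8` is interpreted as
*post-quality-filter* depth, so `q_pass_rate` defaults to 1; setting it
below 1 models the raw-to-filtered loss (a raw 11× design filtered at
Q20 loses roughly 20–27% of bases). The default error matrix is uniform
0.25% per substitution type, matching the canonical initialisation rate;
real post-filter mismatch rates spread over roughly 0.25–1% and tests
exercise that range explicitly. Missing genotypes are injected only on
request (default 0%): the sequencing data model represents absent data
as depth-0 cells, which arise naturally from the Poisson.

What the generator does **not** emulate: linkage disequilibrium within
the simulated panel (sites are independent; LD enters only through the
separate phased-panel utilities), sequence-level artefacts (no reads, no
alignment, no strand effects), related individuals, population
structure beyond what PCA tests construct explicitly, and X-linked
inheritance. Passing tests therefore demonstrate correctness of the
estimators under their assumed model, not robustness to every artefact
of real sequencing data.

## Numerical choices and degenerate inputs

* All likelihood accumulation is in log space with max-rescaling;
  `0 * log(0)` terms are defined as 0.
* EM tolerances: $10^{-6}$ on frequencies (200 iterations max) and on
  error rates (100 outer iterations); LRT statistics below 0 are clamped.
* Strict inequalities at every published threshold (discovery,
  QC, selection), so filter counts reproduce exactly.
* Ties: allele order A < C < G < T everywhere a tie must break
  (major assignment, minor candidates); average ranks in the
  rank-normal transform.
* Degenerate inputs have defined behaviour rather than errors where a
  value is meaningful: depth-0 → flat likelihoods; zero minor alleles →
  HWE $p = 1$; empty cohort configurations return empty objects;
  constant traits and rank-0 genotype matrices are errors.
* Coordinates are 1-based and fully closed throughout, and all alleles
  are on the forward strand; the VCF writer emits 1-based positions
  unchanged.
* Every stochastic function is driven by an explicit seed in its config;
  `run_pipeline()` derives all stage seeds from the single config seed.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to keep the full suite in
minutes while leaving the statistical assertions well-powered: null
calibration of the read-level LRT at 2,000 sites × 400 individuals × 8×;
frequency recovery at 100 sites × 1,000 individuals; error-matrix
recovery at 2,000 sites × 500 individuals; regression calibration at
2,000 SNPs × 2,000 individuals and effect recovery at n = 5,000 × 100
replicates; the end-to-end meta-analysis rescue with one discovery
(n = 1,000) plus four replication cohorts (n = 5,000 each). The
estimators are vectorised across sites, so these scale linearly to
study-sized panels.

## Known limitations

* The error model is global; systematic per-individual or per-cycle
  error structure is only addressed through the bias filters.
* The LRT relies on χ²₁ asymptotics; at MAF near the 1% floor with few
  hundred individuals the null is slightly conservative.
* π₁ estimation at $\lambda^\ast = 0.5$ is simple and can be noisy for
  small SNP sets.
* The minor-sum likelihood uses per-minor EM optima (see above); with
  depth ≳ 2× the best component dominates and the distinction is
  numerically irrelevant.
* No burden or aggregation tests are provided: single-variant biases
  accumulate in burden statistics, and the stage-1 data model cannot
  support them safely — this mirrors the design the package implements.
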