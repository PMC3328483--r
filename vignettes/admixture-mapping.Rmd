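---
title: "Admixture mapping and ancestry-aware association: models and design"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture mapping and ancestry-aware association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

# The scientific problem

In populations formed by recent admixture between Native American and Old
World ancestors, a disease allele that is more frequent on one ancestral
background leaves a footprint: affected individuals carry an excess of that
ancestry *at the locus*, beyond their genome-wide average. Admixture mapping
scans for this excess using a modest panel of ancestry-informative markers
(AIMs) rather than a dense genome-wide association panel. The catch, for a
disease like type 2 diabetes in Latin America, is that genetic ancestry is
also entangled with socioeconomic status (SES): individuals with higher
Native ancestry tend to live in lower SES strata, and SES itself predicts
disease. Any analysis of ancestry and disease in such a population must
treat SES as a first-class confounder.

`admixscan` implements the full analysis chain for a two-way admixed
case-control study on an AIM panel -- global- and local-ancestry inference,
an admixture-mapping LOD scan, risk-ratio exclusion mapping, and
covariate-adjusted candidate-marker association -- together with a
synthetic-cohort generator that reproduces the statistical structure the
inference assumes, so that every stage can be validated by parameter
recovery without access to individual-level study data.

# The hidden Markov model of local ancestry

Each individual has a global Native ancestry proportion $\theta \in [0,1]$.
At any genomic position an individual carries $j \in \{0,1,2\}$ haplotypes
of Native ancestry; under random mating within the admixed population
(Hardy-Weinberg in ancestry) the genome-wide prior is

$$\pi(\theta) = \bigl((1-\theta)^2,\; 2\theta(1-\theta),\; \theta^2\bigr).$$

Along a chromosome, each haplotype's ancestry is a two-state Markov chain in
genetic distance: over $d$ Morgans it retains its state with probability
$e^{-\lambda d}$ and otherwise redraws from the stationary law
$\mathrm{Bernoulli}(\theta)$. The intensity $\lambda$ (switches per Morgan)
corresponds to the number of generations since admixture; mean tract length
is $1/\lambda$ Morgans. The diploid hidden state is the unordered pair of
haplotype ancestries, with transition matrix equal to the product of the two
independent haplotype kernels.

A marker with counted-allele frequency $f_1$ in the Native and $f_2$ in the
Old World parental population emits a genotype $g \in \{0,1,2\}$ as a sum of
two Bernoulli draws, each haplotype using its own ancestry's frequency. AIMs
are assumed conditionally independent given the ancestry state (the panels
are designed for ancestry information, not for within-population linkage
disequilibrium). Missing genotypes emit probability 1 in every state.
Parental frequencies are taken from the panel file as known constants and
clamped to $[10^{-4}, 1-10^{-4}]$, so a genotype that conflicts with a fixed
difference can never produce a zero-probability observation.

`estimate_theta()` maximises the independent-marker likelihood
$\prod_m \sum_j \pi_j(\theta)\, P(g_m \mid j)$ per individual by bounded
one-dimensional optimisation, with an explicit endpoint check so boundary
maxima are exact. `forward_backward()` returns exact smoothed posteriors
$q = (q_0, q_1, q_2)$ by the scaled forward-backward algorithm; its
correctness is pinned by a test that enumerates *all pairs of haplotype
paths* on short chains and agrees to $10^{-10}$.

# The scan statistic

The admixture-mapping statistic is cases-only; controls inform the global
ancestry estimates. For a case with locus posterior $q$ and genome-wide
prior $\pi = \pi(\hat\theta)$, a disease model with ancestry risk ratio $R$
per Native copy multiplies risk by $R^j$. The per-case evidence at a locus
is the Bayes factor

$$\mathrm{BF}(R) = \frac{\sum_j q_j R^j}{\sum_j \pi_j R^j},$$

and the locus statistic sums $\log_{10} \mathrm{BF}$ over cases. The main
scan LOD averages the *likelihood* over a small set of plausible disease
models before taking logs:
$\mathrm{LOD} = \log_{10}\bigl(\tfrac1K \sum_{r} 10^{\mathrm{lod}(r)}\bigr)$.
The default model set $\{0.5, 2/3, 0.8, 1.25, 1.5, 2\}$ is symmetric on the
log scale around the null $R = 1$; it is configuration, not a claim, and can
be replaced. The genome-wide LOD averages the per-point likelihood ratios
across all evaluation points the same way. Conventional decision thresholds
are reported alongside: suggestive/significant at LOD 4/5 for a single locus
and 1/2 genome-wide.

Evaluation points are placed every 1 cM between the first and last marker of
each chromosome (the spacing is configurable). Rather than interpolating
posteriors after the fact, the points are inserted into the chain as
pseudo-markers with uninformative emissions, so the smoothed posterior at a
point is *exactly* the model's conditional law given the flanking markers.

# Exclusion mapping

For each evaluation point the single-model LOD is computed over the grid
$R = 0.2$ to $3.00$ in steps of $0.02$ (141 models; $R = 1$ is the null and
its LOD is identically zero). The maximum-likelihood ratio $R_{ML}$ is the
grid argmax, ties broken toward 1 (conservative), and the 95% confidence
interval is every grid model within 0.834 LOD of the maximum: a two-point
likelihood-ratio test at $\alpha$ corresponds to a drop of
$\chi^2_{1,1-\alpha} / (2\ln 10)$, and $3.84 / (2\ln 10) = 0.834$.
A point *excludes* risk ratios above $T$ when the upper bound of its
interval falls below $T$; the genome-wide excluded fraction weights each
point by the genetic length it represents (half the gap to each neighbour),
so uneven maps are not distorted. Whether to weight by genetic or physical
length was an open choice; genetic length matches the scale on which the
chain -- and hence the scan's resolution -- lives.

# Candidate-marker association

Single markers are tested by additive logistic regression of case status on
risk-allele dosage with any of SES, BMI and global ancestry as covariates,
via iteratively reweighted least squares with Wald inference. Design
choices, each with its reason:

* **SES enters as a linear 1-6 band score** -- the analysis this package
  reproduces reports a single SES coefficient, implying linear coding.
* **Additive genotype coding** -- standard for loci selected from
  genome-wide association reports; dominance models are out of scope.
* **Per-marker complete-case analysis** -- no imputation rule is assumed;
  dropped counts are reported.
* **Likely separation is flagged, not silently estimated** (a standardized
  coefficient above 15), and singular designs fail naming the columns.
* **The sign test is one-sided**: risk-allele direction is predicted a
  priori by the previous reports, and the exact binomial tail
  $P(X \ge k)$, $X \sim \mathrm{Bin}(n, 1/2)$ is used. For 14 of 20 the
  exact value is 0.05766 -- marginally above 0.05 even though the count is
  conventionally described as significant at 5%; the package reports the
  exact value and leaves the interpretation to the analyst.
* **Analytic power** uses the normal approximation on the allelic log odds
  ratio with variance from expected allele counts; it agrees with a
  10,000-replicate simulation oracle within 0.02 at study-scale sizes.

`covariate_analysis()` fits the nested models `status ~ ancestry`,
`status ~ SES`, `status ~ ancestry + SES` and
`status ~ ancestry + SES + BMI`, plus the Pearson correlation of ancestry
with SES -- the confounding diagnostic that decides whether an apparent
ancestry effect survives adjustment.

# What the synthetic cohort emulates

`simulate_cohort()` generates data from *exactly* the model the inference
assumes, which is what makes parameter-recovery testing meaningful:

| parameter | default | meaning / rationale |
|---|---|---|
| `n_case`, `n_control` | 876 / 399 | the study design being emulated |
| `n_markers` | 1,536 | genome-wide AIM panel size |
| `theta_mean` | 0.30 | mean Native ancestry of the admixed population |
| `theta_concentration` | 20 | Beta spread (sd $\approx$ 0.10), consistent with a 3-percentage-point case-control ancestry contrast being strongly significant at these sample sizes |
| `lambda_gens` | 10 | generations since admixture; ~10 cM mean tracts |
| `freq_diff_mean` | 0.50 | mean AIM frequency differential between parental populations |
| `ses_ancestry_slope` | $-2$ | latent-SES slope on ancestry; yields cor(ancestry, SES) $\approx -0.2$ |
| `ses_disease_effect` | $-0.4$ | log-odds of disease per SES band |
| `bmi_params` | mean 27.1, sd 4.6, slope $-0.4$/band | case BMI distribution; the control distribution is unreported in the emulated study, so one distribution is shared |
| `base_prevalence_logit` | $-1.5$ | keeps baseline prevalence at a few percent, the regime where the generating odds ratio per Native copy approximates the ancestry risk ratio the scan estimates -- at high prevalence the logistic link saturates and the two are no longer comparable |

SES is a latent Gaussian decreasing in ancestry, cut into six
equal-probability bands (the banding depth of the real SES variable is
administrative and unspecified; equal-probability cuts are the neutral
choice). Disease is Bernoulli with logit linear in SES band and, optionally,
$\log R$ per Native copy at one risk locus; individuals are drawn until the
case and control quotas fill (retention sampling, mimicking clinic-based
ascertainment), with a bounded number of attempts. Ancestry tracts are
simulated haplotype-wise with the same exponential-switch kernel the HMM
assumes; when a risk locus is present, the locus copy count that generated
disease status anchors the simulated tracks, which is valid because the
kernel is reversible with respect to its stationary law.

**What it deliberately does not emulate:** linkage disequilibrium within the
parental populations, three-way (e.g. African) admixture, age or sex effects
on disease, genotyping error, and uncertainty in the parental allele
frequencies. Passing recovery tests therefore demonstrates correctness of
the inference *under its own assumptions*, not robustness to their
violation on real data.

# Numerical choices and degenerate inputs

* Scaled (per-step renormalised) forward-backward; posteriors are identical
  to the unscaled recursion but immune to underflow on long chromosomes.
* LOD sums and averages use a log-sum-exp in base 10, so per-point
  likelihood ratios spanning hundreds of LOD units do not overflow.
* Frequency clamping at $10^{-4}$; `theta` clamped to $(0.001, 0.999)$
  inside the chain so the state prior stays proper even for individuals
  estimated at an ancestry boundary.
* Grid argmax ties resolve toward $R = 1$; a single-model grid is rejected
  because a likelihood-ratio interval is undefined on it.
* Markers with all genotypes missing are rejected at cohort construction;
  individuals with no observed genotypes get an undefined ancestry estimate
  and a warning rather than an arbitrary number.
* One seed drives the whole generator; a configuration plus seed reproduces
  every downstream table bit-for-bit.

# Test and validation design

The test suite validates each stage against an independent oracle:
exhaustive path enumeration for the HMM; closed forms for Bayes factors,
genome LOD, the chi-square LOD offset and logistic special cases (the
intercept-only logit, the 2x2 cross-product odds ratio); exact binomial
enumeration for the sign test; and a Monte-Carlo oracle for analytic power.
Statistical behaviour is checked by simulation at deliberately chosen sizes
that keep the suite fast while leaving adequate Monte-Carlo headroom: global
ancestry RMSE on the full 1,536-AIM panel (200 individuals), localization of
an $R = 2$ locus within 10 cM (20 replicates of 500 cases on an 800-AIM
panel), exclusion-interval coverage (500 simulated loci of 300 cases),
type-I error of the adjusted marker test (1,000 null markers), and null-scan
genome-wide LOD (20 replicates of 200 cases on 400 AIMs).

The confounding demonstration uses `ses_ancestry_slope = -3` and
`ses_disease_effect = -0.6`, stronger than the generator defaults. The
reason is arithmetic: a six-band SES score is a coarse proxy of the latent
confounder, and the marginal coefficients measured on such a proxy
(correlation near $-0.2$, a fifth of a log-odds unit per band) are too weak,
through that path alone, to produce a strongly significant marginal ancestry
association in a one-and-a-quarter-thousand-person cohort. The demonstration
scenario makes the latent confounding strong enough that the qualitative
signature -- ancestry significant marginally, not after SES adjustment -- is
recoverable in most replicates, which is the property being tested.

# Known limitations

* Local-ancestry resolution is information-limited: with a panel
  differential of 0.5, ~2 cM marker spacing and 10 cM tracts, the posterior
  mean Native dosage correlates with the true copy count at roughly 0.81;
  pushing beyond 0.9 requires a more informative or denser panel. This is a
  property of the design, not of the algorithm (which is exact).
* Parental allele frequencies are treated as known; their sampling
  uncertainty is not propagated.
* Two-way admixture only; no phasing; no within-ancestry LD model.
* Genome-wide significance thresholds are taken as the conventional
  constants (4/5 locus, 1/2 genome), not recalibrated by permutation.
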