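# admixscan

Admixture mapping and ancestry-aware case-control association for two-way
admixed populations genotyped on ancestry-informative marker (AIM) panels.

The package is aimed at studies of the kind run on Latin American *mestizo*
cohorts (Native American x Old World admixture), where disease-gene signals
must be separated from two entangled backgrounds: locus-specific ancestry
(the signal admixture mapping exploits) and socioeconomic status, which
correlates with genome-wide ancestry and independently predicts diseases
such as type 2 diabetes.

## What it computes

Given a genotype triplet (EIGENSTRAT-style `geno`/`snp`/`ind`), a marker
panel with parental allele frequencies, and a covariate table:

* **Global ancestry** `estimate_theta()`: per-individual Native ancestry
  proportion by maximum likelihood over the Hardy-Weinberg-in-ancestry
  marker mixture.
* **Local ancestry** `forward_backward()` / `local_ancestry_field()`:
  exact smoothed posteriors over Native copy counts j = 0, 1, 2 from a
  two-haplotype hidden Markov model along the genetic map (ancestry
  switches at intensity lambda per Morgan into the stationary law).
* **Admixture-mapping scan** `admixture_scan()`: at evaluation points every
  centimorgan, the cases-only LOD

      lod_by_R = sum over cases of log10 [ (sum_j q_j R^j) / (sum_j pi_j R^j) ]

  with `q` the locus posterior and `pi` the individual's genome-wide prior;
  the scan LOD averages the likelihood over a configurable set of disease
  models, and the genome-wide LOD averages likelihood ratios over all
  points.
* **Exclusion mapping** `exclusion_map()` / `excluded_fraction()`: per
  point, the maximum-likelihood ancestry risk ratio over the grid
  R = 0.2, ..., 3.00 (step 0.02; 141 models) and the 95% likelihood-ratio
  interval (all models within 0.834 LOD of the maximum, from
  chi-square(1): 3.84 / (2 ln 10)); the genetic-length-weighted fraction of
  the genome excluding risk ratios above a threshold.
* **Candidate association** `marker_association()` / `association_table()`
  / `covariate_analysis()`: additive logistic regression with SES, BMI and
  ancestry covariates; odds ratios oriented to the previously reported risk
  allele; Bonferroni bookkeeping; the exact one-sided binomial sign test on
  OR direction; BMI-trend tests; analytic power.
* **Synthetic cohorts** `simulate_cohort()`: admixed case-control cohorts
  with Beta-distributed ancestry, haplotype-wise ancestry tracts, SES bands
  negatively correlated with ancestry, BMI, and a logistic disease model
  with an optional ancestry risk locus -- the ground-truthed test bed for
  everything above.
* **Pipeline** `run_pipeline()` (and the `inst/scripts/admixcl` front end):
  simulate -> ancestry -> scan -> assoc with a reproducibility manifest.

## Worked example

```r
library(admixscan)

cfg <- sim_config(n_case = 500, n_control = 200, n_markers = 800,
                  risk_locus = list(marker = 200, R = 2), seed = 42)
sim <- simulate_cohort(cfg)

theta_hat <- estimate_theta(sim$cohort, sim$panel)
mean(theta_hat[sim$cohort$ind$status == "case"])     # 0.331
mean(theta_hat[sim$cohort$ind$status == "control"])  # 0.298

scan <- admixture_scan(sim$cohort, sim$panel, theta_hat = theta_hat)
scan
#> <scan_result> 2750 evaluation points, 500 cases
#>   max locus LOD 13.200 (chr4, 45.2 Mb), genome-wide LOD 10.431
#>   excluded fraction at R > 1.22: 0.471
sim$panel[200, c("chromosome", "position_bp")]       # chr4, 47.6 Mb
```

The simulated risk locus (risk ratio 2 per Native copy, chr4 at 47.6 Mb) is
found 2.4 Mb from its true position with a locus LOD of 13.2, far above the
conventional significance threshold of 5; cases carry visibly higher
estimated ancestry than controls because ascertainment at a risk locus
drags global ancestry with it.

Bookkeeping on a published candidate-marker table (shipped with the
package) works directly from printed P-values and odds ratios:

```r
tab <- t2d_candidate_summary()
sign_test_or(tab$or[tab$gwas_selected])
#> 14 of 20 ORs above 1, exact one-sided binomial P = 0.05766
fl <- bonferroni_flags(tab$p_value)
sum(fl$nominal); sum(fl$corrected)    # 6 nominal, 2 Bonferroni hits
```

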