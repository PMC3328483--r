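#' Published candidate-marker association summary
#'
#' The per-marker association summary published for the Antioquian type-2
#' diabetes case-control sample: 21 candidate SNPs (20 selected from
#' genome-wide association reports in Old World populations plus the
#' Native-American-specific *ABCA1* variant rs9282541), each with the
#' previously reported risk allele, the covariate-adjusted P-value and the
#' odds ratio with its 95% confidence interval, oriented to the risk
#' allele. Used as the printed input for multiple-testing and sign-test
#' bookkeeping; the underlying genotypes were never deposited.
#'
#' @return data.frame with columns `marker_id`, `chromosome`, `gene`,
#'   `risk_allele`, `nonrisk_allele`, `p_value`, `or`, `ci_low`, `ci_high`,
#'   `gwas_selected`.
#' @export
t2d_candidate_summary <- function() {
  path <- system.file("extdata", "t2d_candidate_summary.tsv",
                      package = "admixscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
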