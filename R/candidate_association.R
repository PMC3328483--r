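#' Logistic regression with Wald inference
#'
#' Fits case-control status on a design of covariate columns (an intercept
#' is added) by iteratively reweighted least squares, and returns
#' coefficient estimates, their asymptotic covariance and two-sided Wald
#' P-values. Likely complete separation is flagged per term (a coefficient
#' exceeding 15 on a standardised column) rather than silently reported;
#' singular designs fail naming the offending columns.
#'
#' @param status 0/1 vector (1 = case) or a "case"/"control" factor.
#' @param design data.frame or matrix of covariates, no intercept column.
#' @return list with `coef`, `se`, `p`, `vcov`, `converged`, `separation`
#'   (logical per term).
#' @export
fit_logistic <- function(status, design) {
  y <- if (is.numeric(status)) status else as.integer(tolower(as.character(status)) == "case")
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (length(y) <= ncol(X) + 1) {
    stop_adx("more model terms than observations", "adx_model_error")
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qrX$pivot[(qrX$rank + 1):ncol(Xi)]]
    stop_adx(sprintf("singular design: column(s) %s are constant or collinear",
                     paste(dropped, collapse = ", ")), "adx_singular_error")
  }
  # separation / convergence are diagnosed below, so glm.fit's own
  # fitted-probability warnings are redundant here
  fit <- suppressWarnings(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  beta <- fit$coefficients
  W <- fit$weights
  XtWX <- crossprod(Xi * sqrt(W))
  vcov <- solve(XtWX)
  se <- sqrt(diag(vcov))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  sds <- apply(X, 2, stats::sd)
  std_beta <- c(FALSE, abs(beta[-1] * sds) > 15)
  list(coef = beta, se = se, p = p, vcov = vcov,
       converged = fit$converged, separation = std_beta)
}

# Risk-allele dosage: genotypes count the panel's counted allele; flip when
# the previously reported risk allele is the other one.
risk_dosage <- function(g, counted, other, risk_allele) {
  if (risk_allele == counted) return(g)
  if (risk_allele == other) return(2L - g)
  stop_adx(sprintf("risk allele '%s' is neither panel allele (%s/%s)",
                   risk_allele, counted, other), "adx_validation_error")
}

#' Covariate-adjusted single-marker association
#'
#' Additive logistic association of disease with risk-allele dosage at one
#' marker, adjusting for any of SES (linear 1-6 band score), BMI and global
#' Native ancestry. Individuals missing the genotype or any requested
#' covariate are dropped (per-marker complete-case analysis, with the count
#' reported). The odds ratio and Wald confidence interval are oriented to
#' the stated risk allele.
#'
#' @param chrt a `cohort`.
#' @param panel the matching `marker_panel`.
#' @param marker marker identifier.
#' @param risk_allele allele the odds ratio is oriented to.
#' @param covariates subset of `c("ses", "bmi", "ancestry")`.
#' @param theta_hat global ancestry estimates (required when `"ancestry"`
#'   is a covariate).
#' @return one-row data.frame: marker, n used, counts, OR with 95% CI,
#'   Wald P, plus flags `low_information` (minor allele count < 5) and
#'   `separation`.
#' @export
marker_association <- function(chrt, panel, marker, risk_allele,
                               covariates = c("ses", "bmi", "ancestry"),
                               theta_hat = NULL) {
  j <- match(marker, panel$marker_id)
  if (is.na(j)) stop_adx(sprintf("marker '%s' not in panel", marker),
                         "adx_validation_error")
  if (length(covariates) > 0) {
    covariates <- match.arg(covariates, c("ses", "bmi", "ancestry"),
                            several.ok = TRUE)
  }
  g <- risk_dosage(chrt$genotypes[, j], panel$counted_allele[j],
                   panel$other_allele[j], risk_allele)
  df <- data.frame(y = as.integer(chrt$ind$status == "case"), dosage = g)
  if ("ses" %in% covariates) df$ses <- chrt$ind$ses
  if ("bmi" %in% covariates) df$bmi <- chrt$ind$bmi
  if ("ancestry" %in% covariates) {
    if (is.null(theta_hat)) {
      stop_adx("theta_hat is required when adjusting for ancestry",
               "adx_config_error")
    }
    df$ancestry <- as.numeric(theta_hat)
  }
  cc <- stats::complete.cases(df)
  dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < 50) {
    stop_adx(sprintf("only %d complete-case rows for marker %s (need >= 50)",
                     nrow(df), marker), "adx_model_error")
  }
  mac <- min(sum(df$dosage), sum(2 - df$dosage))
  fit <- fit_logistic(df$y, df[, -1, drop = FALSE])
  b <- fit$coef["dosage"]
  se <- fit$se["dosage"]
  data.frame(marker = marker, risk_allele = risk_allele, n = nrow(df),
             n_dropped = dropped, beta = unname(b), se = unname(se),
             or = exp(unname(b)),
             or_ci_low = exp(unname(b - 1.96 * se)),
             or_ci_high = exp(unname(b + 1.96 * se)),
             p = unname(fit$p["dosage"]),
             low_information = mac < 5,
             separation = unname(fit$separation["dosage"]),
             stringsAsFactors = FALSE)
}

#' Association table over a candidate-marker set
#'
#' Runs [marker_association()] for each candidate, then attaches the
#' multiple-testing bookkeeping: nominal and Bonferroni-corrected
#' significance flags and the one-sided binomial sign test on the number of
#' odds ratios above 1 among markers selected from prior reports
#' (`sign_set`, defaulting to all candidates).
#'
#' @param chrt a `cohort`.
#' @param panel the matching `marker_panel`.
#' @param candidates data.frame with columns `marker_id`, `risk_allele`.
#' @param covariates,theta_hat passed to [marker_association()].
#' @param alpha significance level for the flags.
#' @param sign_set marker ids entering the sign test.
#' @return list with `table` (per-marker rows plus flags),
#'   `bonferroni_alpha`, and `sign_test`.
#' @export
association_table <- function(chrt, panel, candidates,
                              covariates = c("ses", "bmi", "ancestry"),
                              theta_hat = NULL, alpha = 0.05,
                              sign_set = candidates$marker_id) {
  if (("ancestry" %in% covariates) && is.null(theta_hat)) {
    theta_hat <- estimate_theta(chrt, panel)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    marker_association(chrt, panel, candidates$marker_id[i],
                       candidates$risk_allele[i], covariates, theta_hat)
  })
  tab <- do.call(rbind, rows)
  flags <- bonferroni_flags(tab$p, alpha)
  tab$nominal <- flags$nominal
  tab$bonferroni <- flags$corrected
  st <- sign_test_or(tab$or[tab$marker %in% sign_set])
  list(table = tab, bonferroni_alpha = flags$threshold, sign_test = st)
}

#' Ancestry / SES / BMI covariate models
#'
#' Fits the nested logistic models `status ~ ancestry`, `status ~ SES`,
#' `status ~ ancestry + SES` and `status ~ ancestry + SES + BMI`, reporting
#' each coefficient with its Wald P-value, together with the Pearson
#' correlation between ancestry and SES band (the genetic-socioeconomic
#' confounding diagnostic) and per-band BMI summaries. This is the analysis
#' that shows whether an ancestry-disease association survives adjustment
#' for socioeconomic status.
#'
#' @param chrt a `cohort`.
#' @param theta_hat global ancestry estimates.
#' @return list of class `covariate_analysis`: `models` (named list of
#'   [fit_logistic()] results), `ancestry_ses_cor` (estimate and P),
#'   `bmi_by_ses` (band means), `n_used`, `n_dropped`.
#' @export
covariate_analysis <- function(chrt, theta_hat) {
  df <- data.frame(y = as.integer(chrt$ind$status == "case"),
                   ancestry = as.numeric(theta_hat),
                   ses = chrt$ind$ses, bmi = chrt$ind$bmi)
  cc <- stats::complete.cases(df)
  dropped <- sum(!cc)
  if (dropped > 0) {
    message(sprintf("covariate_analysis: dropping %d individuals with missing covariates",
                    dropped))
  }
  df <- df[cc, , drop = FALSE]
  models <- list(
    ancestry = fit_logistic(df$y, df["ancestry"]),
    ses = fit_logistic(df$y, df["ses"]),
    ancestry_ses = fit_logistic(df$y, df[c("ancestry", "ses")]),
    ancestry_ses_bmi = fit_logistic(df$y, df[c("ancestry", "ses", "bmi")]))
  ct <- stats::cor.test(df$ancestry, df$ses)
  bmi_by_ses <- tapply(df$bmi, factor(df$ses, levels = 1:6), mean)
  structure(list(models = models,
                 ancestry_ses_cor = list(estimate = unname(ct$estimate),
                                         p = ct$p.value),
                 bmi_by_ses = bmi_by_ses,
                 n_used = nrow(df), n_dropped = dropped),
            class = "covariate_analysis")
}

#' @export
print.covariate_analysis <- function(x, ...) {
  cat(sprintf("<covariate_analysis> n = %d (%d dropped)\n", x$n_used, x$n_dropped))
  for (nm in names(x$models)) {
    f <- x$models[[nm]]
    terms <- names(f$coef)[-1]
    cat(sprintf("  status ~ %s\n", paste(terms, collapse = " + ")))
    for (tm in terms) {
      cat(sprintf("    c_%-9s = %8.4f  P = %.3g\n", tm, f$coef[tm], f$p[tm]))
    }
  }
  cat(sprintf("  cor(ancestry, SES) = %.3f  P = %.3g\n",
              x$ancestry_ses_cor$estimate, x$ancestry_ses_cor$p))
  invisible(x)
}

#' BMI trend over genotype copies
#'
#' Linear regression of BMI on the additive count of the effect allele,
#' with per-genotype-class means; the trend P-value is the two-sided test
#' of zero slope. A BMI column with no variance returns slope 0 and P = 1.
#'
#' @param chrt a `cohort`.
#' @param panel the matching `marker_panel`.
#' @param marker marker identifier.
#' @param effect_allele allele whose copy count is the regressor.
#' @return list: `means` (named by copies 0/1/2, `NA` for empty classes),
#'   `slope`, `p`, `n`.
#' @export
bmi_trend_test <- function(chrt, panel, marker, effect_allele) {
  j <- match(marker, panel$marker_id)
  if (is.na(j)) stop_adx(sprintf("marker '%s' not in panel", marker),
                         "adx_validation_error")
  g <- risk_dosage(chrt$genotypes[, j], panel$counted_allele[j],
                   panel$other_allele[j], effect_allele)
  ok <- !is.na(g) & !is.na(chrt$ind$bmi)
  g <- g[ok]
  bmi <- chrt$ind$bmi[ok]
  means <- tapply(bmi, factor(g, levels = 0:2), mean)
  if (stats::sd(bmi) < 1e-12 || stats::sd(g) < 1e-12) {
    return(list(means = means, slope = 0, p = 1, n = length(g)))
  }
  fit <- stats::lm(bmi ~ g)
  sm <- summary(fit)$coefficients
  list(means = means, slope = unname(sm["g", "Estimate"]),
       p = unname(sm["g", "Pr(>|t|)"]), n = length(g))
}

#' Exact binomial sign test on odds-ratio direction
#'
#' With risk alleles oriented a priori from previous reports, tests whether
#' more odds ratios exceed 1 than chance would give: the one-sided exact
#' tail `P(X >= count)` for `X ~ Binomial(n, 1/2)`. ORs equal to 1 count as
#' not above 1.
#'
#' @param ors vector of positive oriented odds ratios.
#' @return list: `count_gt_1`, `n`, `p`.
#' @export
sign_test_or <- function(ors) {
  if (length(ors) < 1) stop_adx("need at least one odds ratio", "adx_domain_error")
  if (any(ors <= 0)) stop_adx("odds ratios must be > 0", "adx_domain_error")
  k <- sum(ors > 1)
  n <- length(ors)
  list(count_gt_1 = k, n = n,
       p = stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Nominal and Bonferroni-corrected significance flags
#'
#' @param pvals per-marker P-values in (0, 1].
#' @param alpha family-wise level.
#' @return list: `nominal` (`p < alpha`), `corrected`
#'   (`p < alpha / n_tests`), `threshold` (the corrected cutoff).
#' @export
bonferroni_flags <- function(pvals, alpha = 0.05) {
  if (any(pvals <= 0 | pvals > 1)) {
    stop_adx("P-values must lie in (0, 1]", "adx_domain_error")
  }
  list(nominal = pvals < alpha,
       corrected = pvals < alpha / length(pvals),
       threshold = alpha / length(pvals))
}

#' Analytic power for a single-marker additive test
#'
#' Normal approximation on the allelic log odds ratio: the case allele
#' frequency implied by the control frequency and the odds ratio, the
#' Wald variance from expected allele counts (2 alleles per subject), and
#' the two-sided rejection region at `alpha`.
#'
#' @param freq_ctrl risk-allele frequency in controls, in (0, 1).
#' @param or allelic odds ratio, > 0.
#' @param n_case,n_control subject counts.
#' @param alpha significance level.
#' @return estimated power.
#' @export
power_single_marker <- function(freq_ctrl, or, n_case, n_control,
                                alpha = 0.05) {
  if (freq_ctrl <= 0 || freq_ctrl >= 1) {
    stop_adx("control frequency must lie strictly inside (0, 1)", "adx_domain_error")
  }
  if (or <= 0) stop_adx("odds ratio must be > 0", "adx_domain_error")
  p0 <- freq_ctrl
  p1 <- or * p0 / (1 - p0 + or * p0)
  if (p1 < FREQ_EPS || p1 > 1 - FREQ_EPS) {
    warn_adx("implied case frequency is degenerate; clamping", "adx_clamp_warning")
    p1 <- min(max(p1, FREQ_EPS), 1 - FREQ_EPS)
  }
  se <- sqrt(1 / (2 * n_case * p1) + 1 / (2 * n_case * (1 - p1)) +
               1 / (2 * n_control * p0) + 1 / (2 * n_control * (1 - p0)))
  z <- stats::qnorm(1 - alpha / 2)
  delta <- abs(log(or)) / se
  stats::pnorm(delta - z) + stats::pnorm(-delta - z)
}
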