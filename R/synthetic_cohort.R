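# Approximate autosome physical lengths in Mb; with the constant 1 cM/Mb
# map used throughout, genetic length in Morgans is Mb/100 (~28.8 M total).
CHROM_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
              134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Simulation configuration for synthetic admixed cohorts
#'
#' Defaults emulate the Antioquia type-2-diabetes study design: 876 cases
#' and 399 controls on a 1,536-AIM genome-wide panel, mean Native American
#' ancestry 0.30, admixture roughly 10 generations old, socioeconomic bands
#' 1-6 negatively correlated with Native ancestry, and disease risk driven
#' by SES (plus an optional ancestry risk ratio R at one locus).
#'
#' @param n_case,n_control cohort sizes.
#' @param n_markers panel size, spread over 22 autosomes.
#' @param lambda_gens generations since admixture = expected ancestry
#'   switches per Morgan per haplotype.
#' @param theta_mean,theta_concentration Beta distribution of individual
#'   Native ancestry proportions (mean/concentration parameterisation).
#' @param freq_diff_mean mean absolute counted-allele frequency
#'   differential between the parental populations (AIM informativeness).
#' @param risk_locus `NULL` for a null genome, or `list(marker =, R =)`:
#'   marker index (or id) carrying an ancestry risk ratio R per Native copy.
#' @param ses_ancestry_slope slope of the latent socioeconomic variable on
#'   Native ancestry (negative = higher ancestry, lower SES); -2 yields an
#'   ancestry-SES correlation near -0.19 at the default Beta spread.
#' @param ses_disease_effect log-odds of disease per SES band.
#' @param bmi_params `list(mean, sd, ses_slope)`: BMI in kg/m^2, linear in
#'   SES band.
#' @param base_prevalence_logit disease-model intercept. The default keeps
#'   baseline prevalence low (a few percent once SES effects apply), where
#'   the logistic odds ratio per Native copy approximates a risk ratio --
#'   the regime in which the generating R is comparable to the ancestry
#'   risk ratio the scan estimates.
#' @param seed integer seed; the entire cohort is a deterministic function
#'   of the configuration.
#' @return validated configuration list of class `sim_config`.
#' @export
sim_config <- function(n_case = 876, n_control = 399, n_markers = 1536,
                       lambda_gens = 10, theta_mean = 0.3,
                       theta_concentration = 20, freq_diff_mean = 0.5,
                       risk_locus = NULL, ses_ancestry_slope = -2,
                       ses_disease_effect = -0.4,
                       bmi_params = list(mean = 27.1, sd = 4.6, ses_slope = -0.4),
                       base_prevalence_logit = -1.5, seed = 1) {
  if (!is_count(n_case) || !is_count(n_control) || n_case < 1 || n_control < 0) {
    stop_adx("cohort sizes must be positive integers", "adx_config_error")
  }
  if (!is_count(n_markers) || n_markers < 1) {
    stop_adx("n_markers must be a positive integer", "adx_config_error")
  }
  if (lambda_gens <= 0) stop_adx("lambda_gens must be > 0", "adx_config_error")
  if (theta_mean <= 0 || theta_mean >= 1) {
    stop_adx("theta_mean must lie strictly inside (0, 1)", "adx_config_error")
  }
  if (theta_concentration <= 0) {
    stop_adx("theta_concentration must be > 0", "adx_config_error")
  }
  if (freq_diff_mean <= 0 || freq_diff_mean >= 1) {
    stop_adx("freq_diff_mean must lie strictly inside (0, 1)", "adx_config_error")
  }
  if (!is.null(risk_locus)) {
    if (is.null(risk_locus$marker) || is.null(risk_locus$R) || risk_locus$R < 0) {
      stop_adx("risk_locus needs a marker and an ancestry risk ratio R >= 0",
               "adx_config_error")
    }
  }
  structure(list(n_case = n_case, n_control = n_control, n_markers = n_markers,
                 lambda_gens = lambda_gens, theta_mean = theta_mean,
                 theta_concentration = theta_concentration,
                 freq_diff_mean = freq_diff_mean, risk_locus = risk_locus,
                 ses_ancestry_slope = ses_ancestry_slope,
                 ses_disease_effect = ses_disease_effect,
                 bmi_params = bmi_params,
                 base_prevalence_logit = base_prevalence_logit,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ancestry-informative marker panel
#'
#' Markers are spread over the 22 autosomes proportionally to genetic
#' length, with physical positions uniform per chromosome and genetic
#' positions from a constant 1 cM/Mb map. Per-marker parental frequencies
#' are drawn so the absolute differential has mean `freq_diff_mean`
#' (Beta-distributed differential, uniform midpoint, random sign).
#'
#' @param config a [sim_config()].
#' @return a `marker_panel`.
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  simulate_panel_impl(config)
}

simulate_panel_impl <- function(config) {
  m <- config$n_markers
  # deterministic largest-remainder allocation across chromosomes
  share <- CHROM_MB / sum(CHROM_MB) * m
  n_chr <- floor(share)
  rem <- m - sum(n_chr)
  if (rem > 0) {
    extra <- order(share - n_chr, decreasing = TRUE)[seq_len(rem)]
    n_chr[extra] <- n_chr[extra] + 1L
  }
  chrom <- rep(1:22, n_chr)
  pos <- unlist(lapply(1:22, function(ch) {
    k <- n_chr[ch]
    if (k == 0) return(integer(0))
    p <- sort(sample.int(CHROM_MB[ch] * 1e6 - 1L, k))
    p
  }))
  conc <- 20
  d <- stats::rbeta(m, config$freq_diff_mean * conc,
                    (1 - config$freq_diff_mean) * conc)
  mid <- stats::runif(m, d / 2, 1 - d / 2)
  sgn <- sample(c(-1, 1), m, replace = TRUE)
  f1 <- mid + sgn * d / 2
  f2 <- mid - sgn * d / 2
  alle <- t(replicate(m, sample(c("A", "C", "G", "T"), 2)))
  as_marker_panel(data.frame(
    marker_id = sprintf("aim_%05d", seq_len(m)),
    chromosome = chrom, position_bp = pos, genetic_pos = pos / 1e8,
    freq_pop1 = f1, freq_pop2 = f2,
    counted_allele = alle[, 1], other_allele = alle[, 2],
    stringsAsFactors = FALSE))
}

# Two-state (Native / Old World) haplotype chains along the genetic map for
# n individuals at once. At each marker-to-marker step of genetic distance d
# the haplotype keeps its ancestry with probability exp(-lambda * d) and
# otherwise redraws from the stationary law Bernoulli(theta) -- so theta is
# the stationary Native probability and lambda the switch intensity per
# Morgan. `anchor` optionally fixes both haplotype states at one marker
# index; the chain is then propagated outwards in both directions, which is
# valid because the kernel is reversible with respect to its stationary law.
sim_tracks_chrom <- function(gpos, theta, anchor_idx = NULL, h1 = NULL,
                             h2 = NULL, lambda) {
  m <- length(gpos)
  n <- length(theta)
  s <- exp(-lambda * diff(gpos))
  one_hap <- function(anchor_state) {
    H <- matrix(0L, n, m)
    if (is.null(anchor_idx)) {
      H[, 1] <- stats::rbinom(n, 1, theta)
      for (k in seq_len(m - 1L)) {
        stay <- stats::runif(n) < s[k]
        H[, k + 1L] <- ifelse(stay, H[, k], stats::rbinom(n, 1, theta))
      }
    } else {
      H[, anchor_idx] <- anchor_state
      if (anchor_idx < m) for (k in anchor_idx:(m - 1L)) {
        stay <- stats::runif(n) < s[k]
        H[, k + 1L] <- ifelse(stay, H[, k], stats::rbinom(n, 1, theta))
      }
      if (anchor_idx > 1) for (k in anchor_idx:2L) {
        stay <- stats::runif(n) < s[k - 1L]
        H[, k - 1L] <- ifelse(stay, H[, k], stats::rbinom(n, 1, theta))
      }
    }
    H
  }
  one_hap(h1) + one_hap(h2)
}

#' Simulate local-ancestry copy counts for one individual
#'
#' Draws two independent haplotype ancestry tracks along the panel's
#' genetic map (exponential-switch Markov chains with stationary Native
#' probability `theta` and intensity `lambda_gens` per Morgan) and returns
#' their per-marker sum in \{0, 1, 2\}.
#'
#' @param panel a `marker_panel` (or data.frame with `chromosome`,
#'   `genetic_pos`), positions non-decreasing within chromosome.
#' @param theta Native ancestry proportion in \[0, 1\].
#' @param lambda_gens switch intensity per Morgan (> 0).
#' @param seed integer seed.
#' @return integer vector of Native-copy counts, one per marker.
#' @export
simulate_local_ancestry <- function(panel, theta, lambda_gens, seed) {
  if (theta < 0 || theta > 1) stop_adx("theta must lie in [0, 1]", "adx_config_error")
  if (lambda_gens <= 0) stop_adx("lambda_gens must be > 0", "adx_config_error")
  for (ch in unique(panel$chromosome)) {
    if (is.unsorted(panel$genetic_pos[panel$chromosome == ch])) {
      stop_adx("genetic positions must be non-decreasing within chromosome",
               "adx_validation_error")
    }
  }
  set.seed(seed)
  out <- integer(nrow(panel))
  for (ch in unique(panel$chromosome)) {
    sel <- which(panel$chromosome == ch)
    out[sel] <- as.integer(sim_tracks_chrom(panel$genetic_pos[sel], theta,
                                            lambda = lambda_gens))
  }
  out
}

# Local-ancestry matrix (n x m) for all retained individuals; the risk-locus
# chromosome, if any, is anchored at the locus so tracks are consistent with
# the copy counts that generated disease status.
sim_local_matrix <- function(panel, theta, lambda, risk_idx = NULL, j_locus = NULL) {
  n <- length(theta)
  L <- matrix(0L, n, nrow(panel))
  for (ch in unique(panel$chromosome)) {
    sel <- which(panel$chromosome == ch)
    gpos <- panel$genetic_pos[sel]
    if (!is.null(risk_idx) && risk_idx %in% sel) {
      k0 <- match(risk_idx, sel)
      # split the anchored count into exchangeable haplotype states
      h1 <- as.integer(j_locus == 2L)
      het <- j_locus == 1L
      coin <- stats::rbinom(n, 1, 0.5)
      h1[het] <- coin[het]
      h2 <- j_locus - h1
      L[, sel] <- sim_tracks_chrom(gpos, theta, anchor_idx = k0,
                                   h1 = h1, h2 = h2, lambda = lambda)
    } else {
      L[, sel] <- sim_tracks_chrom(gpos, theta, lambda = lambda)
    }
  }
  L
}

#' Simulate an admixed case-control cohort
#'
#' Generates, per individual: a Beta-distributed global Native ancestry
#' proportion; haplotype-wise local-ancestry tracks; genotypes drawn
#' binomially from the parental frequency of each haplotype's ancestry
#' (Hardy-Weinberg within ancestry); an SES band from a latent Gaussian
#' decreasing in ancestry, cut into 6 equal-probability bands; BMI linear
#' in SES band; and disease status from a logistic model with an SES effect
#' and, optionally, `log(R)` per Native copy at the risk locus. Individuals
#' are drawn until the case and control quotas are filled (retention
#' sampling), mimicking clinic-based ascertainment.
#'
#' @param config a [sim_config()].
#' @return `list(panel = marker_panel, cohort = cohort)`; the cohort
#'   carries `true_theta` and `true_local` ground truth.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  panel <- simulate_panel_impl(config)
  a <- config$theta_mean * config$theta_concentration
  b <- (1 - config$theta_mean) * config$theta_concentration
  var_theta <- config$theta_mean * (1 - config$theta_mean) /
    (config$theta_concentration + 1)
  sd_latent <- sqrt(config$ses_ancestry_slope^2 * var_theta + 1)
  cuts <- stats::qnorm((1:5) / 6, sd = sd_latent)

  risk_idx <- NULL
  logR <- 0
  if (!is.null(config$risk_locus)) {
    mk <- config$risk_locus$marker
    risk_idx <- if (is.character(mk)) match(mk, panel$marker_id) else as.integer(mk)
    if (is.na(risk_idx) || risk_idx < 1 || risk_idx > nrow(panel)) {
      stop_adx("risk locus marker not found in panel", "adx_config_error")
    }
    if (config$risk_locus$R == 0) {
      logR <- -Inf
    } else {
      logR <- log(config$risk_locus$R)
    }
  }

  need_case <- config$n_case
  need_ctrl <- config$n_control
  keep <- list()
  tries <- 0L
  max_tries <- 200L
  batch_n <- max(2000L, need_case + need_ctrl)
  while ((need_case > 0 || need_ctrl > 0) && tries < max_tries) {
    tries <- tries + 1L
    theta <- stats::rbeta(batch_n, a, b)
    z <- config$ses_ancestry_slope * (theta - config$theta_mean) +
      stats::rnorm(batch_n)
    ses <- findInterval(z, cuts) + 1L
    bmi <- config$bmi_params$mean +
      config$bmi_params$ses_slope * (ses - 3.5) +
      stats::rnorm(batch_n, sd = config$bmi_params$sd)
    bmi <- pmax(bmi, 12)
    j_locus <- if (is.null(risk_idx)) rep(0L, batch_n) else
      stats::rbinom(batch_n, 2, theta)
    eta <- config$base_prevalence_logit + config$ses_disease_effect * ses +
      ifelse(j_locus > 0, logR * j_locus, 0)
    case <- stats::runif(batch_n) < stats::plogis(eta)
    take_case <- which(case)[seq_len(min(need_case, sum(case)))]
    take_ctrl <- which(!case)[seq_len(min(need_ctrl, sum(!case)))]
    idx <- c(take_case, take_ctrl)
    if (length(idx) > 0) {
      keep[[length(keep) + 1L]] <- data.frame(
        theta = theta[idx], ses = ses[idx], bmi = bmi[idx],
        j_locus = j_locus[idx], case = case[idx])
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
  }
  if (need_case > 0 || need_ctrl > 0) {
    stop_adx(sprintf(
      "could not fill quotas after %d batches (still need %d cases, %d controls); disease model prevalence is too extreme",
      tries, need_case, need_ctrl), "adx_sim_error")
  }
  df <- do.call(rbind, keep)
  df <- df[order(!df$case), , drop = FALSE]   # cases first
  n <- nrow(df)

  L <- sim_local_matrix(panel, df$theta, config$lambda_gens,
                        risk_idx = risk_idx,
                        j_locus = if (is.null(risk_idx)) NULL else df$j_locus)
  m <- nrow(panel)
  J <- as.vector(L)
  f1 <- rep(panel$freq_pop1, each = n)
  f2 <- rep(panel$freq_pop2, each = n)
  G <- matrix(stats::rbinom(n * m, J, f1) +
                stats::rbinom(n * m, 2L - J, f2), n, m)

  age <- ifelse(df$case, stats::rnorm(n, 63.0, 10.5), stats::rnorm(n, 60.7, 10.2))
  sex <- ifelse(stats::runif(n) < 0.61, "F", "M")
  ind <- data.frame(id = sprintf("ind_%05d", seq_len(n)),
                    status = ifelse(df$case, "case", "control"),
                    ses = df$ses, bmi = round(df$bmi, 2),
                    age = round(age, 1), sex = sex,
                    stringsAsFactors = FALSE)
  list(panel = panel,
       cohort = cohort(ind, G, true_theta = df$theta, true_local = L))
}
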