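# Emission model: P(genotype g | j Native copies) under Hardy-Weinberg
# within ancestry. A haplotype of Native ancestry carries the counted
# allele with probability freq_pop1, an Old World haplotype with freq_pop2.
# Frequencies are clamped away from 0/1 so no observation ever has zero
# probability under every state.
#
# Returns three n x m matrices E0, E1, E2; missing genotypes emit 1 in all
# states (they carry no locus information).
emission_tables <- function(G, panel) {
  n <- nrow(G)
  m <- ncol(G)
  F1 <- matrix(clamp_freq(panel$freq_pop1), n, m, byrow = TRUE)
  F2 <- matrix(clamp_freq(panel$freq_pop2), n, m, byrow = TRUE)
  E0 <- stats::dbinom(G, 2, F2)
  E2 <- stats::dbinom(G, 2, F1)
  E1 <- (G == 0L) * (1 - F1) * (1 - F2) +
    (G == 1L) * (F1 + F2 - 2 * F1 * F2) +
    (G == 2L) * F1 * F2
  miss <- is.na(G)
  E0[miss] <- 1
  E1[miss] <- 1
  E2[miss] <- 1
  list(E0 = E0, E1 = E1, E2 = E2)
}

# Scaled forward-backward over one chromosome for n individuals at once.
# Hidden state = unordered pair of haplotype ancestries, i.e. the Native
# copy count j in {0,1,2} with stationary prior ((1-t)^2, 2t(1-t), t^2).
# The count transition over genetic distance d is the product of two
# independent haplotype kernels, each staying with probability
# s = exp(-lambda d) and otherwise redrawing Bernoulli(theta):
#   P(other -> Native)  = (1-s) theta          (= a)
#   P(Native -> Native) = s + (1-s) theta      (= b)
# Rows are renormalised at every step (scaling), which leaves the smoothed
# posteriors unchanged.
fb_chrom <- function(E0, E1, E2, s, theta) {
  n <- nrow(E0)
  m <- ncol(E0)
  p0 <- (1 - theta)^2
  p1 <- 2 * theta * (1 - theta)
  p2 <- theta^2

  A0 <- matrix(0, n, m); A1 <- A0; A2 <- A0
  A0[, 1] <- p0 * E0[, 1]
  A1[, 1] <- p1 * E1[, 1]
  A2[, 1] <- p2 * E2[, 1]
  cs <- A0[, 1] + A1[, 1] + A2[, 1]
  A0[, 1] <- A0[, 1] / cs; A1[, 1] <- A1[, 1] / cs; A2[, 1] <- A2[, 1] / cs

  if (m > 1) for (k in seq_len(m - 1L)) {
    a <- (1 - s[k]) * theta
    b <- s[k] + (1 - s[k]) * theta
    x0 <- A0[, k]; x1 <- A1[, k]; x2 <- A2[, k]
    y0 <- (x0 * (1 - a)^2 + x1 * (1 - b) * (1 - a) + x2 * (1 - b)^2) * E0[, k + 1L]
    y1 <- (x0 * 2 * a * (1 - a) + x1 * (b * (1 - a) + (1 - b) * a) +
             x2 * 2 * b * (1 - b)) * E1[, k + 1L]
    y2 <- (x0 * a^2 + x1 * b * a + x2 * b^2) * E2[, k + 1L]
    cs <- y0 + y1 + y2
    A0[, k + 1L] <- y0 / cs; A1[, k + 1L] <- y1 / cs; A2[, k + 1L] <- y2 / cs
  }

  B0 <- matrix(1, n, m); B1 <- B0; B2 <- B0
  if (m > 1) for (k in rev(seq_len(m - 1L))) {
    a <- (1 - s[k]) * theta
    b <- s[k] + (1 - s[k]) * theta
    z0 <- E0[, k + 1L] * B0[, k + 1L]
    z1 <- E1[, k + 1L] * B1[, k + 1L]
    z2 <- E2[, k + 1L] * B2[, k + 1L]
    w0 <- (1 - a)^2 * z0 + 2 * a * (1 - a) * z1 + a^2 * z2
    w1 <- (1 - b) * (1 - a) * z0 + (b * (1 - a) + (1 - b) * a) * z1 + b * a * z2
    w2 <- (1 - b)^2 * z0 + 2 * b * (1 - b) * z1 + b^2 * z2
    cs <- w0 + w1 + w2
    B0[, k] <- w0 / cs; B1[, k] <- w1 / cs; B2[, k] <- w2 / cs
  }

  q0 <- A0 * B0; q1 <- A1 * B1; q2 <- A2 * B2
  cs <- q0 + q1 + q2
  list(q0 = q0 / cs, q1 = q1 / cs, q2 = q2 / cs)
}

#' Maximum-likelihood global ancestry per individual
#'
#' Maximises, separately for each individual, the independent-marker
#' likelihood \eqn{\prod_m \sum_j P(j \mid \theta) P(g_m \mid j)} over the
#' Native ancestry proportion \eqn{\theta \in [0,1]}, where
#' \eqn{P(j \mid \theta)} is the Hardy-Weinberg prior over Native copy
#' counts and the emission is the within-ancestry binomial mixture. Solved
#' by bounded one-dimensional optimisation with an endpoint check, so
#' boundary maxima (0 or 1) are returned exactly.
#'
#' @param chrt a `cohort`.
#' @param panel the matching `marker_panel`.
#' @return named numeric vector of ancestry estimates, `NA` (with a
#'   warning) for individuals with no observed genotypes.
#' @export
estimate_theta <- function(chrt, panel) {
  G <- chrt$genotypes
  if (ncol(G) != nrow(panel)) {
    stop_adx("genotype matrix does not match panel size", "adx_dimension_error")
  }
  E <- emission_tables(G, panel)
  n <- nrow(G)
  theta_hat <- rep(NA_real_, n)
  none <- rowSums(!is.na(G)) == 0
  if (any(none)) {
    warn_adx(sprintf("%d individuals have no observed genotypes; theta undefined",
                     sum(none)), "adx_all_missing_warning")
  }
  for (i in which(!none)) {
    p0 <- E$E0[i, ]; p1 <- E$E1[i, ]; p2 <- E$E2[i, ]
    ll <- function(th) {
      sum(log(p0 * (1 - th)^2 + p1 * 2 * th * (1 - th) + p2 * th^2))
    }
    opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, ll(0), ll(1))
    theta_hat[i] <- cand[which.max(vals)]
  }
  names(theta_hat) <- chrt$ind$id
  theta_hat
}

#' Smoothed local-ancestry posteriors for one individual
#'
#' Runs the scaled forward-backward algorithm for the two-haplotype
#' ancestry hidden Markov model along each chromosome of the panel and
#' returns the exact smoothed posterior over Native copy counts at every
#' marker. Missing genotypes contribute emission 1 (no information); the
#' chain restarts at its stationary law on each chromosome.
#'
#' @param genotypes integer vector of counted-allele dosages over the
#'   panel's markers (`NA` = missing).
#' @param panel a `marker_panel`, positionally sorted.
#' @param theta the individual's Native ancestry proportion, in (0, 1).
#' @param lambda_gens ancestry switch intensity per Morgan (> 0).
#' @return matrix with one row per marker and columns `q0`, `q1`, `q2`.
#' @export
forward_backward <- function(genotypes, panel, theta, lambda_gens) {
  if (length(genotypes) != nrow(panel)) {
    stop_adx("genotype vector does not match panel size", "adx_dimension_error")
  }
  if (theta <= 0 || theta >= 1) {
    stop_adx("theta must lie strictly inside (0, 1)", "adx_config_error")
  }
  if (lambda_gens <= 0) stop_adx("lambda_gens must be > 0", "adx_config_error")
  G <- matrix(as.integer(genotypes), 1)
  E <- emission_tables(G, panel)
  out <- matrix(NA_real_, nrow(panel), 3,
                dimnames = list(panel$marker_id, c("q0", "q1", "q2")))
  for (ch in unique(panel$chromosome)) {
    sel <- which(panel$chromosome == ch)
    gpos <- panel$genetic_pos[sel]
    if (is.unsorted(gpos)) {
      stop_adx("genetic positions must be non-decreasing within chromosome",
               "adx_validation_error")
    }
    s <- exp(-lambda_gens * diff(gpos))
    q <- fb_chrom(E$E0[, sel, drop = FALSE], E$E1[, sel, drop = FALSE],
                  E$E2[, sel, drop = FALSE], s, theta)
    out[sel, 1] <- q$q0[1, ]
    out[sel, 2] <- q$q1[1, ]
    out[sel, 3] <- q$q2[1, ]
  }
  out
}

#' Local-ancestry posterior field for a cohort
#'
#' Estimates each individual's global ancestry (unless supplied) and
#' computes smoothed per-marker posteriors over Native copy counts for all
#' individuals. Global estimates are clamped to (0.001, 0.999) inside the
#' chain so the hidden-state prior stays proper.
#'
#' @param chrt a `cohort`.
#' @param panel the matching `marker_panel`.
#' @param lambda_gens ancestry switch intensity per Morgan.
#' @param theta_hat optional precomputed global ancestry vector.
#' @return object of class `local_ancestry_field`: matrices `q0`, `q1`,
#'   `q2` (individuals x markers), `theta_hat`, and `lambda_gens`.
#' @export
local_ancestry_field <- function(chrt, panel, lambda_gens = 10,
                                 theta_hat = NULL) {
  if (is.null(theta_hat)) theta_hat <- estimate_theta(chrt, panel)
  th <- pmin(pmax(theta_hat, 1e-3), 1 - 1e-3)
  G <- chrt$genotypes
  E <- emission_tables(G, panel)
  n <- nrow(G)
  m <- ncol(G)
  q0 <- matrix(0, n, m); q1 <- q0; q2 <- q0
  for (ch in unique(panel$chromosome)) {
    sel <- which(panel$chromosome == ch)
    s <- exp(-lambda_gens * diff(panel$genetic_pos[sel]))
    q <- fb_chrom(E$E0[, sel, drop = FALSE], E$E1[, sel, drop = FALSE],
                  E$E2[, sel, drop = FALSE], s, th)
    q0[, sel] <- q$q0; q1[, sel] <- q$q1; q2[, sel] <- q$q2
  }
  structure(list(q0 = q0, q1 = q1, q2 = q2, theta_hat = theta_hat,
                 lambda_gens = lambda_gens, marker_id = panel$marker_id),
            class = "local_ancestry_field")
}

#' Posterior mean Native dosage
#'
#' @param field a `local_ancestry_field`.
#' @return individuals x markers matrix of posterior expected copy counts.
#' @export
ancestry_dosage <- function(field) {
  field$q1 + 2 * field$q2
}
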