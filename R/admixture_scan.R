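#' Inclusive arithmetic grid of ancestry risk ratios
#'
#' @param low,high grid endpoints (low <= high).
#' @param step positive increment; the grid has
#'   `round((high - low) / step) + 1` values, so (0.2, 3.00, 0.02) gives
#'   141 single-R disease models.
#' @return numeric vector of risk ratios.
#' @export
risk_grid <- function(low, high, step) {
  if (step <= 0) stop_adx("grid step must be > 0", "adx_config_error")
  if (low > high) stop_adx("grid low must not exceed high", "adx_config_error")
  low + step * (0:round((high - low) / step))
}

#' Likelihood-ratio LOD offset for a confidence level
#'
#' Converts a chi-square(1) critical value into LOD units: a two-point
#' likelihood-ratio test at level `alpha` corresponds to a drop of
#' `qchisq(1 - alpha, 1) / (2 ln 10)` in log10 likelihood, e.g. 0.834 LOD
#' for alpha = 0.05 (critical value 3.84).
#'
#' @param alpha significance level in (0, 1).
#' @return the LOD offset.
#' @export
lod_offset_from_chisq <- function(alpha) {
  if (alpha <= 0 || alpha >= 1) {
    stop_adx("alpha must lie strictly inside (0, 1)", "adx_config_error")
  }
  stats::qchisq(1 - alpha, df = 1) / (2 * log(10))
}

#' Risk-model settings for the admixture scan
#'
#' @param scan_set risk ratios whose likelihoods are averaged in the main
#'   scan statistic; the default is symmetric on the log scale around the
#'   null R = 1.
#' @param grid single-R models evaluated for exclusion mapping, by default
#'   R = 0.2 to 3.00 in steps of 0.02 (141 models).
#' @return list of class `risk_model`.
#' @export
risk_model <- function(scan_set = c(0.5, 2 / 3, 0.8, 1.25, 1.5, 2),
                       grid = risk_grid(0.2, 3, 0.02)) {
  if (any(scan_set <= 0) || any(grid <= 0)) {
    stop_adx("risk ratios must be > 0", "adx_config_error")
  }
  structure(list(scan_set = scan_set, grid = grid), class = "risk_model")
}

#' Per-case locus Bayes factor under an ancestry risk-ratio model
#'
#' For a case with smoothed local-ancestry posterior `q = (q0, q1, q2)` and
#' genome-wide prior `pi`, the evidence for risk ratio `R` per Native copy
#' at the locus is `(sum_j q_j R^j) / (sum_j pi_j R^j)`: the risk model
#' tilts the prior by `R^j`, and the factor is 1 whenever `R = 1` or the
#' locus posterior equals the prior.
#'
#' @param q posterior over Native copy counts; vector of length 3 or an
#'   n x 3 matrix (one case per row).
#' @param pi prior of the same shape.
#' @param R ancestry risk ratio, > 0.
#' @return the Bayes factor(s).
#' @export
case_bayes_factor <- function(q, pi, R) {
  if (R <= 0) stop_adx("ancestry risk ratio R must be > 0", "adx_domain_error")
  w <- c(1, R, R^2)
  if (is.matrix(q)) {
    as.vector((q %*% w) / (pi %*% w))
  } else {
    sum(q * w) / sum(pi * w)
  }
}

#' LOD score at one evaluation point
#'
#' Cases-only admixture-mapping statistic: for each risk ratio r,
#' `lod_by_R(r)` sums `log10 case_bayes_factor(q_i, pi_i, r)` over cases,
#' with `pi_i` the individual's genome-wide Hardy-Weinberg prior from the
#' global ancestry estimate. The scan LOD averages the likelihood (not the
#' LOD) over the model set: `log10(mean over scan_set of 10^lod_by_R)`.
#'
#' @param q n x 3 matrix of case posteriors at the point.
#' @param pi n x 3 matrix of case genome-wide priors.
#' @param model a [risk_model()].
#' @return `list(lod =, lod_by_R =)` with `lod_by_R` named by grid value.
#' @export
locus_lod <- function(q, pi, model = risk_model()) {
  q <- rbind(q)
  pi <- rbind(pi)
  if (nrow(q) < 1) stop_adx("at least one case is required", "adx_domain_error")
  one <- function(r) sum(log10(case_bayes_factor(q, pi, r)))
  lod_by_R <- vapply(model$grid, one, numeric(1))
  names(lod_by_R) <- format(model$grid)
  scan_lods <- vapply(model$scan_set, one, numeric(1))
  list(lod = log10_mean(scan_lods), lod_by_R = lod_by_R)
}

#' Genome-wide LOD score
#'
#' The log10 of the arithmetic mean, over evaluation points, of the
#' per-point likelihood ratios `10^lod` -- the genome-level evidence of
#' association. Conventional thresholds: suggestive 1 and significant 2
#' genome-wide; suggestive 4 and significant 5 for a single locus.
#'
#' @param x a `scan_result` or a numeric vector of per-point LODs.
#' @return the genome-wide LOD.
#' @export
genome_lod <- function(x) {
  lod <- if (inherits(x, "scan_result")) x$points$lod else as.numeric(x)
  if (length(lod) == 0) stop_adx("no evaluation points", "adx_domain_error")
  log10_mean(lod)
}

#' Maximum-likelihood risk ratio and confidence bounds per point
#'
#' For each evaluation point, finds the grid risk ratio maximising
#' `lod_by_R` (ties broken toward the null R = 1) and the confidence
#' interval of all grid models whose LOD lies within `ci_offset` of that
#' maximum, reported as its min/max.
#'
#' @param lod_by_R points x grid matrix of single-model LODs.
#' @param grid the risk-ratio grid (length >= 2).
#' @param ci_offset LOD drop defining the interval; 0.834 corresponds to a
#'   95% likelihood-ratio interval (see [lod_offset_from_chisq()]).
#' @return data.frame with `r_ml`, `r_ci_low`, `r_ci_high`.
#' @export
exclusion_map <- function(lod_by_R, grid, ci_offset = lod_offset_from_chisq(0.05)) {
  lod_by_R <- rbind(lod_by_R)
  if (length(grid) < 2) {
    stop_adx("risk grid must contain at least 2 models for a confidence interval",
             "adx_config_error")
  }
  if (ncol(lod_by_R) != length(grid)) {
    stop_adx("lod_by_R columns do not match the grid", "adx_dimension_error")
  }
  n <- nrow(lod_by_R)
  r_ml <- numeric(n)
  lo <- numeric(n)
  hi <- numeric(n)
  for (p in seq_len(n)) {
    lods <- lod_by_R[p, ]
    mx <- max(lods)
    top <- which(lods >= mx - 1e-9)
    r_ml[p] <- grid[top[which.min(abs(grid[top] - 1))]]
    inside <- grid[mx - lods <= ci_offset]
    lo[p] <- min(inside)
    hi[p] <- max(inside)
  }
  data.frame(r_ml = r_ml, r_ci_low = lo, r_ci_high = hi)
}

#' Fraction of the genome excluding risk ratios above a threshold
#'
#' A point excludes ratios above `threshold` when the upper bound of its
#' 95% interval falls below the threshold. Points are weighted by the
#' genetic length they represent (half the gap to each neighbouring point
#' on the same chromosome), so uneven maps do not distort the fraction.
#'
#' @param scan a `scan_result`.
#' @param threshold ancestry risk ratio.
#' @return the weighted excluded fraction in \[0, 1\].
#' @export
excluded_fraction <- function(scan, threshold) {
  pts <- scan$points
  w <- numeric(nrow(pts))
  for (ch in unique(pts$chromosome)) {
    sel <- which(pts$chromosome == ch)
    if (length(sel) == 1) {
      w[sel] <- scan$spacing_morgans
    } else {
      g <- diff(pts$genetic_pos[sel])
      mid <- if (length(g) > 1) (g[-length(g)] + g[-1]) / 2 else numeric(0)
      w[sel] <- c(g[1] / 2, mid, g[length(g)] / 2)
    }
  }
  sum(w[pts$r_ci_high < threshold]) / sum(w)
}

#' Genome-wide admixture-mapping scan with exclusion map
#'
#' Runs the full scan: estimates global ancestry for every individual,
#' computes smoothed local-ancestry posteriors for the cases at evaluation
#' points every `spacing_cm` centimorgans along the genetic map (posteriors
#' at points between markers come from the same hidden Markov chain, with
#' uninformative emissions at the points), then evaluates at every point
#' the averaged-model scan LOD, the per-model LOD over the risk grid, the
#' maximum-likelihood risk ratio with its 95% interval, and the genome-wide
#' LOD. Controls inform the global ancestry estimates only.
#'
#' @param chrt a `cohort` containing at least one case.
#' @param panel the matching `marker_panel`.
#' @param lambda_gens ancestry switch intensity per Morgan.
#' @param spacing_cm evaluation-point spacing in centimorgans.
#' @param model a [risk_model()].
#' @param ci_alpha level for the risk-ratio confidence intervals.
#' @param theta_hat optional precomputed global ancestry estimates.
#' @return object of class `scan_result`: `points` (one row per evaluation
#'   point with `lod`, `r_ml`, `r_ci_low`, `r_ci_high`), `lod_by_R`
#'   (points x grid), `grid`, `scan_set`, `genome_lod`, `ci_offset`.
#' @export
admixture_scan <- function(chrt, panel, lambda_gens = 10, spacing_cm = 1,
                           model = risk_model(), ci_alpha = 0.05,
                           theta_hat = NULL) {
  is_case <- chrt$ind$status == "case"
  if (!any(is_case)) stop_adx("scan requires at least one case", "adx_domain_error")
  if (is.null(theta_hat)) theta_hat <- estimate_theta(chrt, panel)
  th_case <- pmin(pmax(theta_hat[is_case], 1e-3), 1 - 1e-3)
  n <- sum(is_case)
  pi_case <- hwe_prior(th_case)

  G <- chrt$genotypes[is_case, , drop = FALSE]
  E <- emission_tables(G, panel)
  spacing <- spacing_cm / 100

  pt_chrom <- integer(0)
  pt_gpos <- numeric(0)
  pt_bp <- numeric(0)
  q0 <- NULL; q1 <- NULL; q2 <- NULL
  for (ch in sort(unique(panel$chromosome))) {
    sel <- which(panel$chromosome == ch)
    gpos <- panel$genetic_pos[sel]
    pts <- seq(gpos[1], gpos[length(gpos)], by = spacing)
    # augment the marker chain with uninformative pseudo-markers at the
    # evaluation points; smoothing then interpolates through the kernel
    all_pos <- c(gpos, pts)
    src <- c(seq_along(sel), rep(NA_integer_, length(pts)))
    ord <- order(all_pos, is.na(src))
    all_pos <- all_pos[ord]
    src <- src[ord]
    ones <- matrix(1, n, length(all_pos))
    E0a <- ones; E1a <- ones; E2a <- ones
    mk <- !is.na(src)
    E0a[, mk] <- E$E0[, sel[src[mk]], drop = FALSE]
    E1a[, mk] <- E$E1[, sel[src[mk]], drop = FALSE]
    E2a[, mk] <- E$E2[, sel[src[mk]], drop = FALSE]
    s <- exp(-lambda_gens * diff(all_pos))
    q <- fb_chrom(E0a, E1a, E2a, s, th_case)
    at <- which(is.na(src))
    keep_pos <- all_pos[at]
    pt_chrom <- c(pt_chrom, rep(ch, length(at)))
    pt_gpos <- c(pt_gpos, keep_pos)
    bp <- if (length(sel) < 2) {
      rep(panel$position_bp[sel], length(at))
    } else {
      round(stats::approx(gpos, panel$position_bp[sel], xout = keep_pos,
                          rule = 2, ties = "ordered")$y)
    }
    pt_bp <- c(pt_bp, bp)
    q0 <- cbind(q0, q$q0[, at, drop = FALSE])
    q1 <- cbind(q1, q$q1[, at, drop = FALSE])
    q2 <- cbind(q2, q$q2[, at, drop = FALSE])
  }
  P <- length(pt_gpos)

  all_r <- sort(unique(c(model$grid, model$scan_set)))
  lodmat <- matrix(0, P, length(all_r))
  for (k in seq_along(all_r)) {
    r <- all_r[k]
    den <- sum(log10(pi_case %*% c(1, r, r^2)))
    num <- q0 + r * q1 + r^2 * q2
    lodmat[, k] <- colSums(log10(num)) - den
  }
  grid_cols <- match(model$grid, all_r)
  scan_cols <- match(model$scan_set, all_r)
  lod_by_R <- lodmat[, grid_cols, drop = FALSE]

  Ms <- lodmat[, scan_cols, drop = FALSE]
  mx <- apply(Ms, 1, max)
  lod <- mx + log10(rowMeans(10^(Ms - mx)))

  ci_offset <- lod_offset_from_chisq(ci_alpha)
  excl <- exclusion_map(lod_by_R, model$grid, ci_offset)

  points <- data.frame(
    point_id = sprintf("chr%02d_%09.4fcM", pt_chrom, pt_gpos * 100),
    chromosome = pt_chrom, genetic_pos = pt_gpos, position_bp = pt_bp,
    lod = lod, r_ml = excl$r_ml, r_ci_low = excl$r_ci_low,
    r_ci_high = excl$r_ci_high, stringsAsFactors = FALSE)

  structure(list(points = points, lod_by_R = lod_by_R, grid = model$grid,
                 scan_set = model$scan_set, genome_lod = log10_mean(lod),
                 ci_offset = ci_offset, lambda_gens = lambda_gens,
                 spacing_morgans = spacing, theta_hat = theta_hat,
                 n_cases = n),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d evaluation points, %d cases\n  max locus LOD %.3f (chr%d, %.1f Mb), genome-wide LOD %.3f\n  excluded fraction at R > 1.22: %.3f\n",
    nrow(x$points), x$n_cases, max(x$points$lod),
    x$points$chromosome[which.max(x$points$lod)],
    x$points$position_bp[which.max(x$points$lod)] / 1e6,
    x$genome_lod, excluded_fraction(x, 1.22)))
  invisible(x)
}
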